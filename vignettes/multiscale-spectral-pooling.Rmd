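---
title: "Multiscale spectral attention pooling: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale spectral attention pooling: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specpool)
```

## The model in brief

A protein is a residue contact graph $G=(V,E)$: one vertex per residue,
an edge between residues $i \ne j$ whose C$\alpha$ atoms are closer than a
threshold (default 10 Å, strict `<`). Residue features
$F \in \mathbb{R}^{n \times d}$ fuse two channels by projection and
summation: a one-hot encoding of the 20 standard amino-acid types and a
per-residue contextual embedding from a pluggable provider. $F$ is treated
as $d$ signals on $G$ and analyzed through the graph Laplacian
$L = D - A$ or its symmetric normalization $D^{-1/2} L D^{-1/2}$. With the
eigensystem $0=\lambda_1 \le \dots \le \lambda_n$,
$U = [u_1 \cdots u_n]$ orthonormal, the Graph Fourier Transform
$\hat F = U^\top F$ expresses each feature column in frequency components:
low-$\lambda$ eigenvectors vary little between vertices and carry globally
shared structure, high-$\lambda$ eigenvectors capture localized,
high-variance differences. Cutting the eigenindex range at
$k_G = \max(1, \lfloor np \rfloor)$ and
$k_D = \min(n, \max(k_G+1, \lfloor nq \rfloor))$ yields the exact
decomposition $F = F_G + F_D + F_L$ into global, domain and local bands.

Each band is pooled by one scaled dot-product attention step. Queries are
computed from the $s$ lowest-frequency eigenvectors, zero-padded to a fixed
`max_len` and passed through a scale-specific linear map, plus an additive
learned task embedding; keys are linear maps of the band signals $F_X$;
values are linear maps of the full $F$. Because the three key encoders see
signals of very different smoothness, global attention rows come out nearly
uniform (diffuse pooling over the whole protein) while local rows
concentrate on few residues — the mechanism that preserves residue-level
detail without message passing, and hence without over-smoothing. The $s$
super-node outputs per scale are averaged and the three scale vectors
concatenated ($3c$ values), then a shared one-hidden-layer trunk (width
$2c$, ReLU) and a per-task affine head produce sigmoid scores, trained with
multi-label cross-entropy under round-robin task sampling and Adam.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `contact_threshold` | 10 Å | contact edge cutoff on Cα distances; strict `<` |
| `laplacian` | normalized | spectral operator; combinatorial also provided |
| `p`, `q` | 0.01, 0.03 | band cut fractions, $0<p<q<1$ |
| `s` | 8 | super-nodes (attention queries) per scale |
| `c` | 64 | attention width; protein representation is $3c$ |
| `d` | 128 | fused feature width |
| `e` | 32 | contextual embedding width (mock provider) |
| `max_len` | 1024 | descriptor padding; must be ≥ protein length |
| `lr`, `epochs`, `batch_size` | 1e-3, 20, 16 | Adam settings |

The band fractions are deliberately small: with $p=0.01, q=0.03$ a
100-residue protein gets bands of sizes (1, 2, 97), so the global band is
essentially the graph's null-space component plus the first nontrivial
("Fiedler") directions. The clamping $k_G \ge 1$, $k_D \ge k_G+1$
guarantees non-degenerate global and domain bands for short chains where
$\lfloor np \rfloor = 0$.

## Numerical choices

* **Eigendecomposition** is dense and full (`eigen(symmetric = TRUE)`),
  with eigenvalues re-ordered ascending; this is $O(n^3)$ and capped at
  $n = 3000$ residues, ample for single protein chains. Approximate or
  partial solvers are out of scope.
* **Sign convention**: in each eigenvector, the first component with
  absolute value above $10^{-8}$ is made positive, so decompositions are
  reproducible across runs, platforms and LAPACK builds.
* **Degenerate eigenvalues** are kept in the stable order LAPACK returns;
  tests on graphs with known degeneracies assert only projector-level
  quantities, which are basis-invariant.
* **Disconnected graphs** (zero eigenvalue multiplicity above one) are
  allowed with a warning; all null vectors land in the global band by the
  ascending order.
* **Null-space constancy**: the constant null eigenvector is exact for the
  combinatorial Laplacian on connected graphs; for the normalized kind the
  null vector is $D^{1/2}\mathbf{1}$, constant only on regular graphs. The
  package provides both kinds and asserts constancy where it is
  mathematically exact (combinatorial), while the normalized kind is the
  modelling default.
* **Softmax scaling** uses $1/\sqrt{c}$, the standard scaled dot-product
  form; softmax rows are computed with max-subtraction for stability.
* **Loss clamping**: predictions are clamped to $[10^{-7}, 1-10^{-7}]$
  before the log.

## Design choices where the design was open

* **Representative atom and threshold.** Cα with a 10 Å strict cutoff,
  configurable (Cβ supported). This is the convention of the
  contact-map-based function predictors this package is aligned with.
* **"Top s" eigenvectors for queries.** Interpreted as the $s$ smallest
  eigenvalues: the low-frequency basis is the global structural descriptor;
  a switch (`which = "largest"`) provides the other reading.
* **Variable-length queries.** A linear map cannot share weights across
  descriptors of varying $n$, so eigenvectors are zero-padded to a fixed
  `max_len` before the query encoder. Padding columns receive zero weight
  gradients only when proteins never reach them; they are harmless
  otherwise.
* **Task conditioning** is an additive learned $c$-vector on the queries —
  the lightest mechanism that makes pooling task-dependent.
* **Scale reduction.** The final representation is the mean over
  super-nodes within each scale, concatenated across scales. A single
  attention layer, single head per scale.
* **Unknown residues** get an all-zero one-hot row (no 21st class); the
  contextual channel still supplies a vector. Selenomethionine and other
  common variants map to their parent residue at parsing time.
* **Training schedule.** Round-robin over tasks per optimization step;
  plain unweighted cross-entropy (per-label weighting is available through
  the loss function's `weights` argument but off by default); Adam with lr
  $10^{-3}$;
  optional early stopping on validation Fmax.
* **IC reference.** Information content for Smin is computed from the
  propagated training-set annotations; terms never seen get the finite
  ceiling $-\log_2\!\big(1/(N{+}1)\big)$. Proteins with no predicted term
  at a threshold are excluded from precision averaging, the usual
  protein-centric convention.

## The synthetic harness: what it emulates and what it does not

The generator emulates the features of real single-chain proteins that the
model's mechanism depends on: chains of tens to hundreds of residues with
the real 3.8 Å consecutive Cα spacing and a 3 Å self-avoidance limit;
contact graphs whose density is controlled by a fold class (compact walks
turn sharply, mean contact degree ≈ 11 at 10 Å; extended walks persist in
direction, mean degree ≈ 4); and labels whose signal lives at different
scales. The *global-fold* task is a whole-graph property (the fold class).
The *local-motif* task is a residue-level property: three cysteines,
pairwise at least 4 positions apart in sequence, mutually within 8 Å in
space — a disulfide/metal-site-like spatial cluster. Motif-positive chains
are generated by steering a short loop segment back around an anchor
residue so the site exists in both fold classes; motif-negative chains
place their three cysteines far apart. Labels are always *recomputed from
the realized geometry*, never taken from the generation plan, and the
dataset is stratified over the four (fold × motif) cells with 60/20/20
splits per cell. Cysteine is excluded from the background sequence
distribution so the composition channel carries (by construction) almost no
label signal — which is exactly what makes the mean-one-hot logistic
baseline a fair structure-blind control.

What it does not emulate: secondary structure, realistic Ramachandran
geometry, side chains, contact-density/length correlations of real folds,
or realistic GO-term sparsity (the toy ontology has six terms). Passing the
end-to-end test therefore shows that the architecture can extract planted
multiscale structural signal that a composition baseline cannot — it does
not certify performance on real PDB chains with real language-model
embeddings.

The mock contextual embedder is a deterministic hash-table function of each
residue's ±2-residue sequence window: reproducible, residue-local, and
deliberately structure-blind, so any structural signal the model uses must
flow through the graph spectrum.

## Problem sizes used by the test suite

The package's own verification runs at desk scale on one CPU: exact-band
reconstruction on 100 random graphs with $n \in [5, 300]$; scale-ordering
properties on 4-cluster planted-partition graphs with $n = 200$ over 20
seeds; and end-to-end learnability on five independent 300-protein datasets
(180 train / 60 validation / 60 test, lengths 30–80, $d=64$, $c=32$, $s=4$,
`max_len` 128, 25 epochs), where the trained multitask model must beat the
composition baseline on both tasks in at least four of five seeds. These
sizes were chosen so the full suite completes in minutes while every
property is measured, not assumed.

## Known limitations

* Dense eigendecomposition bounds protein length (3000 residues) and makes
  no use of sparsity.
* Training is plain R matrix algebra on CPU — fine for hundreds of short
  proteins, not for PDB-scale corpora with thousands of labels.
* Real language-model embeddings are supported only through the
  file-based embedding cache / provider contract; no model weights are
  bundled or downloaded.
* Only `is_a` ontology edges are used; other GO relationship types are out
  of scope, as are term-centric evaluation variants.
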