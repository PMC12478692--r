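# specpool

Multiscale spectral attention pooling for protein function prediction in R.

## The problem

Predicting Gene Ontology (GO) function terms from a protein's sequence and 3D
structure is usually cast as multi-label classification on a residue graph:
vertices are residues, edges connect residue pairs whose representative atoms
(Cα here) lie within a distance threshold. Message-passing networks on such
graphs tend to over-smooth — repeated neighbourhood averaging blurs exactly
the residue-level distinctions (catalytic sites, binding motifs) that carry
function — while plain pooling misses global fold organization. Function
lives at several structural scales at once, and the scales need to be kept
apart, not averaged together.

`specpool` separates the scales spectrally instead of by message passing.
Residue features **F** ∈ ℝ^(n×d) (one-hot identity fused with contextual
language-model embeddings) are treated as graph signals and projected onto
the eigenbasis of the contact-graph Laplacian **L** = **D** − **A** (or its
symmetric normalization **D**^(−1/2)**L****D**^(−1/2)). With eigenpairs
0 = λ₁ ≤ … ≤ λₙ and orthonormal eigenvectors **U**, the Graph Fourier
Transform **F̂** = **U**ᵀ**F** splits each feature column into frequency
components; partitioning the eigenindex range at fractions *p* < *q* of *n*
(defaults 0.01 and 0.03) gives an exact three-band decomposition

    F = F_G + F_D + F_L

into global (smooth, fold-level), domain, and local (high-frequency,
residue-level) signals. Each band is pooled by its own scaled dot-product
attention: queries come from the low-frequency Laplacian eigenvectors
(zero-padded to a fixed length so one weight set serves proteins of any
length) plus a learned task embedding; keys come from the band-decomposed
signal, so global keys are nearly uniform across residues (diffuse
attention) and local keys vary strongly (peaky attention); values come from
the full signal **F**. The s super-node aggregates per scale are averaged
and concatenated into a fixed-size multiscale representation, which a
shared trunk and per-task sigmoid heads map to term scores, trained with
multi-label cross-entropy

    L = − Σᵢ [ yᵢ log ŷᵢ + (1 − yᵢ) log(1 − ŷᵢ) ]

under round-robin multitask sampling, so all tasks share the trunk and
pooling parameters and only task embeddings and heads are task-specific.

The package also ships CAFA-style evaluation — ontology annotation
propagation (true-path rule), protein-centric Fmax, information-content
Smin, micro-averaged AUPR — and a deterministic synthetic-protein generator
(self-avoiding Cα walks with planted fold-class and spatial-motif labels)
so the whole pipeline is testable end to end without downloads.

## For whom

Structural bioinformaticians who want a transparent, dependency-light R
implementation of spectral multiscale pooling to experiment with contact
graphs, graph signal processing on proteins, or CAFA-style evaluation —
at desk scale, on CPU.

## Worked example

```r
library(specpool)

d <- tempfile()
run_synth(d, n_proteins = 60L, seed = 42L)          # synthetic dataset on disk

st <- parse_structure(file.path(d, "structures", "SYN0001.pdb"), chain = "A")
st
#> <protein_structure> SYN0001 chain A: 61 residues

g <- build_contact_graph(st, threshold = 10)
g
#> <contact_graph> 61 vertices, 490 edges (threshold 10.0 A)

basis <- eigendecompose(build_laplacian(g, kind = "normalized"))
round(basis$values[1:5], 4)
#> 0.0000 0.0620 0.2841 0.3351 0.5298

band_boundaries(st$n, 0.01, 0.03)
#> 1 2        # global band = eigenvector 1, domain = eigenvector 2, local = 3..61

cfg <- list(d = 32L, c = 16L, s = 4L, e = 16L, max_len = 128L,
            epochs = 8L, batch_size = 8L, seed = 42L)
model <- run_train(d, file.path(d, "run"), config = cfg, use_validation = FALSE)
model
#> <specpool_model> 2 task(s): global_fold, local_motif | d=32 c=16 s=4 | 12342 parameters

run_predict(model, d, file.path(d, "run", "predictions.tsv"), split = "test")
run_evaluate(file.path(d, "run", "predictions.tsv"), d, file.path(d, "run", "eval.tsv"))
#>         task fmax fmax_threshold      smin      aupr
#>  global_fold  0.8           0.01 0.8975275 0.8370676
#>  local_motif  0.8           0.01 0.7071068 0.8660418
```

The smallest Laplacian eigenvalue is 0 (the graph is connected); the first
two eigenvalues below the band cuts define the global/domain bands. After a
short 8-epoch run on 36 training proteins, both tasks reach Fmax 0.8 on the
12 held-out proteins — i.e. the model has learned the always-true root term
plus most leaf labels; longer training (see the vignette) separates the
planted labels much more sharply. Smin is in bits (information content of
mis- and un-predicted terms); AUPR is micro-averaged over all
(protein, term) pairs.

A command-line wrapper over the same functions is installed at
`inst/cli/specpool.R`:

```sh
Rscript inst/cli/specpool.R synth --out data --n-proteins 300 --seed 1
Rscript inst/cli/specpool.R train --data data --out run
Rscript inst/cli/specpool.R predict --model run/model.rds --data data --out run/pred.tsv
Rscript inst/cli/specpool.R evaluate --predictions run/pred.tsv --data data --out run/eval.tsv
```

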