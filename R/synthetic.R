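#' Synthetic dataset specification
#'
#' Defines the study conditions for the synthetic protein harness: chain
#' lengths, backbone geometry, fold classes realized as random-walk
#' persistence (compact chains turn sharply and make dense contact graphs;
#' extended chains persist in direction and make sparse ones), and a local
#' spatial motif (a triplet of residues of given types, mutually within a
#' spatial radius and separated in sequence) planted independently of the
#' fold class.
#'
#' @param n_proteins Number of proteins (default 300).
#' @param length_range Integer range of chain lengths (default c(30, 80)).
#' @param bond_length Consecutive C-alpha spacing in Angstrom (default 3.8,
#'   the real-protein value).
#' @param clash_distance Self-avoidance minimum distance in Angstrom
#'   (default 3.0).
#' @param persistence Named vector of direction-persistence weights per fold
#'   class, in [0, 1).
#' @param motif List with `residues` (three one-letter codes), `radius`
#'   (spatial co-location radius in Angstrom) and `min_sep` (minimum
#'   sequence separation between motif residues).
#' @param contact_threshold Contact threshold used downstream (default 10).
#' @param seed Integer seed fixing the entire dataset.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_proteins = 300L, length_range = c(30L, 80L),
                           bond_length = 3.8, clash_distance = 3.0,
                           persistence = c(compact = 0.15, extended = 0.8),
                           motif = list(residues = c("C", "C", "C"),
                                        radius = 8.0, min_sep = 4L),
                           contact_threshold = 10.0, seed = 1L) {
  if (length_range[1] < 5L) stop("minimum length is 5")
  if (bond_length <= 0) stop("bond length must be positive")
  structure(list(n_proteins = as.integer(n_proteins),
                 length_range = as.integer(length_range),
                 bond_length = bond_length, clash_distance = clash_distance,
                 persistence = persistence, motif = motif,
                 contact_threshold = contact_threshold,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

FOLD_CLASSES <- c("compact", "extended")

# one unit vector uniform on the sphere
runit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

#' Generate a synthetic protein backbone
#'
#' Self-avoiding 3D random walk with fixed consecutive C-alpha spacing.
#' The fold class controls directional persistence: `"compact"` walks turn
#' sharply and curl into dense contact neighbourhoods, `"extended"` walks
#' keep direction and stretch out. Optionally a short loop segment is
#' steered back around an anchor residue (`loop_at`), creating a spatially
#' co-located cluster of sequence-separated residues — the geometric site
#' into which the local motif is planted. The residue sequence is drawn
#' uniformly from the standard alphabet excluding cysteine, which is
#' reserved for motif planting. Deterministic per (length, fold_class,
#' seed, loop_at).
#'
#' @param length Chain length (>= 5).
#' @param fold_class `"compact"` or `"extended"`.
#' @param seed Integer seed.
#' @param spec A [synthetic_spec()] supplying geometry parameters.
#' @param id Identifier for the structure.
#' @param loop_at Optional anchor index; the following `loop_len` steps are
#'   biased back toward the anchor whenever they stray beyond ~5 Angstrom.
#' @param loop_len Length of the steered loop segment (default 10).
#' @return A [protein_structure()] with attribute `fold_class`.
#' @export
generate_structure <- function(length, fold_class = c("compact", "extended"),
                               seed = 1L, spec = synthetic_spec(), id = "synth",
                               loop_at = NULL, loop_len = 10L) {
  fold_class <- match.arg(fold_class)
  if (length < 5L) stop("length must be >= 5")
  persist <- spec$persistence[[fold_class]]
  bond <- spec$bond_length
  clash <- spec$clash_distance
  rng <- rng_substream(seed, paste0("structure_", fold_class, "_", length,
                                    "_", if (is.null(loop_at)) 0L else loop_at))
  coords <- with_rng(rng, {
    ok <- FALSE
    for (restart in 1:30) {
      pts <- matrix(NA_real_, length, 3)
      pts[1, ] <- c(0, 0, 0)
      dir <- runit()
      pts[2, ] <- pts[1, ] + bond * dir
      ok <- TRUE
      for (i in 3:length) {
        in_loop <- !is.null(loop_at) && i > loop_at && i <= loop_at + loop_len
        placed <- FALSE
        for (try in 1:100) {
          if (in_loop && try <= 50 &&
              sqrt(sum((pts[i - 1, ] - pts[loop_at, ])^2)) > 5.0) {
            back <- pts[loop_at, ] - pts[i - 1, ]
            back <- back / sqrt(sum(back^2))
            nd <- 0.7 * back + 0.3 * runit()
          } else if (in_loop) {
            nd <- runit()      # crowded loop: take any non-clashing step
          } else {
            nd <- persist * dir + (1 - persist) * runit()
          }
          nd <- nd / sqrt(sum(nd^2))
          cand <- pts[i - 1, ] + bond * nd
          d2 <- rowSums((pts[1:(i - 2), , drop = FALSE] -
                           matrix(cand, i - 2, 3, byrow = TRUE))^2)
          if (min(d2) >= clash^2) {
            pts[i, ] <- cand; dir <- nd; placed <- TRUE; break
          }
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (ok) break
    }
    if (!ok) stop("self-avoiding walk failed after retry budget")
    pts
  })
  aa_pool <- setdiff(AA_ALPHABET, "C")
  seq_rng <- rng_substream(seed, paste0("sequence_", length))
  sequence <- with_rng(seq_rng, sample(aa_pool, length, replace = TRUE))
  out <- protein_structure(id = id, chain = "A", sequence = sequence,
                           coords = coords)
  attr(out, "fold_class") <- fold_class
  out
}

# positions of motif-compatible triples: residues matching the motif types,
# pairwise sequence separation >= min_sep, and (if close = TRUE) mutual
# spatial distance < radius, else all pairwise distances > radius.
motif_triples <- function(coords, n, radius, min_sep, close = TRUE) {
  D <- as.matrix(stats::dist(coords))
  sep_ok <- abs(outer(seq_len(n), seq_len(n), "-")) >= min_sep
  pair_ok <- if (close) D < radius & sep_ok else D > radius & sep_ok
  diag(pair_ok) <- FALSE
  triples <- list()
  for (i in seq_len(n - 2)) {
    js <- which(pair_ok[i, ] & seq_len(n) > i)
    for (j in js) {
      ks <- which(pair_ok[i, ] & pair_ok[j, ] & seq_len(n) > j)
      if (length(ks)) {
        for (k in ks) triples[[length(triples) + 1L]] <- c(i, j, k)
      }
      if (length(triples) > 200L) return(triples)
    }
  }
  triples
}

# Plant the motif triplet into a structure's sequence: pick a residue triple
# satisfying the spatial condition for the wanted label and overwrite those
# positions with the motif residue types. Returns the modified structure or
# NULL when the geometry offers no such triple.
plant_motif <- function(struct, present, spec, seed = 1L) {
  tri <- motif_triples(struct$coords, struct$n, spec$motif$radius,
                       spec$motif$min_sep, close = present)
  if (length(tri) == 0L) return(NULL)
  rng <- rng_substream(seed, "motif_site")
  pick <- tri[[with_rng(rng, sample.int(length(tri), 1L))]]
  struct$sequence[pick] <- spec$motif$residues
  # planted-absent chains must not form an accidental close triple; since
  # cysteine is excluded elsewhere the only candidate triple is the planted one
  if (!present) {
    d <- stats::dist(struct$coords[pick, ])
    if (any(d < spec$motif$radius)) return(NULL)
  }
  struct
}

#' Toy ontology wrapping the planted labels
#'
#' Six terms: two roots (`fold_root`, `motif_root`) and four leaves
#' (`fold_compact`, `fold_extended`, `motif_present`, `motif_absent`).
#'
#' @return An [ontology_dag()].
#' @export
toy_ontology <- function() {
  ontology_dag(data.frame(
    child = c("fold_compact", "fold_extended", "motif_present", "motif_absent"),
    parent = c("fold_root", "fold_root", "motif_root", "motif_root")))
}

#' Task specifications for the synthetic labels
#'
#' Two tasks: `global_fold` (a whole-graph property — the fold class) and
#' `local_motif` (a residue-level property — presence of the spatial motif).
#' Each task predicts its root plus its two leaf terms.
#'
#' @return List of two [task_spec()] objects.
#' @export
synthetic_tasks <- function() {
  list(task_spec("global_fold", c("fold_root", "fold_compact", "fold_extended")),
       task_spec("local_motif", c("motif_root", "motif_present", "motif_absent")))
}

#' Derive planted labels from a synthetic structure
#'
#' The global-fold label is the structure's fold class (a whole-graph
#' property, attached at generation). The local-motif label is recomputed
#' from geometry: 1 iff a triple of residues matching the motif types occurs
#' with pairwise sequence separation `>= min_sep` and all three mutually
#' within the spatial radius.
#'
#' @param struct A generated [protein_structure()] with a `fold_class`
#'   attribute.
#' @param spec A [synthetic_spec()].
#' @return List with `global_fold`, `local_motif` (0/1) and `annotations`
#'   (leaf terms, one per task).
#' @export
plant_labels <- function(struct, spec = synthetic_spec()) {
  fold <- attr(struct, "fold_class")
  if (is.null(fold)) stop("structure lacks a fold_class attribute")
  pos <- which(struct$sequence %in% spec$motif$residues)
  has_motif <- FALSE
  if (length(pos) >= 3L) {
    sub <- motif_triples(struct$coords[pos, , drop = FALSE], length(pos),
                         spec$motif$radius, 1L, close = TRUE)
    # re-check sequence separation on original indices
    for (tr in sub) {
      orig <- pos[tr]
      if (min(abs(diff(sort(orig)))) >= spec$motif$min_sep) {
        has_motif <- TRUE; break
      }
    }
  }
  list(global_fold = fold,
       local_motif = as.integer(has_motif),
       annotations = list(
         global_fold = paste0("fold_", fold),
         local_motif = if (has_motif) "motif_present" else "motif_absent"))
}

#' Generate a complete synthetic dataset on disk
#'
#' Generates `n_proteins` structures stratified over the four
#' (fold class x motif label) cells, writes PDB coordinate files, a FASTA of
#' sequences, leaf annotations, the toy ontology as an edge TSV, a manifest,
#' and stratified 60/20/20 train/val/test splits by seeded shuffle. The same
#' spec (including seed) regenerates the dataset byte-identically.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the `manifest` data frame and file paths.
#' @export
generate_dataset <- function(spec = synthetic_spec(), dir) {
  dir.create(file.path(dir, "structures"), recursive = TRUE,
             showWarnings = FALSE)
  n <- spec$n_proteins
  strata <- expand.grid(fold = FOLD_CLASSES, motif = c(TRUE, FALSE),
                        stringsAsFactors = FALSE)
  cell <- rep(seq_len(nrow(strata)), length.out = n)
  len_rng <- rng_substream(spec$seed, "lengths")
  lengths <- with_rng(len_rng, sample(spec$length_range[1]:spec$length_range[2],
                                      n, replace = TRUE))
  rows <- vector("list", n)
  structs <- vector("list", n)
  for (i in seq_len(n)) {
    fold <- strata$fold[cell[i]]
    want_motif <- strata$motif[cell[i]]
    st <- NULL
    attempt <- 0L
    while (is.null(st)) {
      attempt <- attempt + 1L
      if (attempt > 60L) stop("could not realize stratum after 60 attempts")
      sub_seed <- (as.numeric(spec$seed) * 1000 + i * 61 + attempt) %% 2147483629
      loop_at <- if (want_motif) {
        anchor_rng <- rng_substream(sub_seed, "anchor")
        with_rng(anchor_rng, sample(3:(lengths[i] - 13L), 1L))
      } else NULL
      base <- generate_structure(lengths[i], fold, seed = sub_seed,
                                 spec = spec, id = sprintf("SYN%04d", i),
                                 loop_at = loop_at)
      st <- plant_motif(base, want_motif, spec, seed = sub_seed)
      if (!is.null(st)) {
        lab <- plant_labels(st, spec)
        if (lab$local_motif != as.integer(want_motif)) st <- NULL
      }
    }
    attr(st, "fold_class") <- fold
    structs[[i]] <- st
    lab <- plant_labels(st, spec)
    rows[[i]] <- data.frame(id = st$id, length = st$n, fold_class = fold,
                            motif_label = lab$local_motif)
  }
  manifest <- do.call(rbind, rows)

  # stratified 60/20/20 split by seeded shuffle within each cell
  manifest$split <- NA_character_
  split_rng <- rng_substream(spec$seed, "splits")
  with_rng(split_rng, {
    for (ci in seq_len(nrow(strata))) {
      idx <- which(cell == ci)
      idx <- sample(idx)
      k <- length(idx)
      n_tr <- round(0.6 * k); n_va <- round(0.2 * k)
      manifest$split[idx] <- c(rep("train", n_tr), rep("val", n_va),
                               rep("test", k - n_tr - n_va))
    }
  })

  for (i in seq_len(n)) {
    st <- structs[[i]]
    bio3d::write.pdb(file = file.path(dir, "structures",
                                      paste0(st$id, ".pdb")),
                     xyz = as.vector(t(st$coords)),
                     resno = seq_len(st$n), chain = rep("A", st$n),
                     resid = bio3d::aa123(st$sequence),
                     elety = rep("CA", st$n))
  }
  seqinr::write.fasta(lapply(structs, function(s) s$sequence),
                      names = manifest$id,
                      file.out = file.path(dir, "sequences.fasta"))
  ann <- do.call(rbind, lapply(structs, function(s) {
    lab <- plant_labels(s, spec)
    data.frame(protein_id = s$id,
               task = c("global_fold", "local_motif"),
               term = c(lab$annotations$global_fold, lab$annotations$local_motif))
  }))
  utils::write.table(ann, file.path(dir, "annotations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  dag <- toy_ontology()
  utils::write.table(dag$edges, file.path(dir, "ontology.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (sp in c("train", "val", "test")) {
    writeLines(manifest$id[manifest$split == sp],
               file.path(dir, paste0(sp, ".txt")))
  }
  invisible(list(manifest = manifest, dir = dir,
                 structures = file.path(dir, "structures"),
                 fasta = file.path(dir, "sequences.fasta"),
                 annotations = file.path(dir, "annotations.tsv"),
                 ontology = file.path(dir, "ontology.tsv")))
}
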