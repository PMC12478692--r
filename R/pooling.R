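SCALES <- c("G", "D", "L")

#' Spectral descriptor for query encoding
#'
#' Selects `s` Laplacian eigenvectors as a structural summary of the protein
#' and zero-pads each on the right to a fixed length, so proteins of any
#' length map to descriptors of identical shape and a single set of query
#' weights can serve them all. By default the `s` eigenvectors of the
#' smallest eigenvalues are used: the low-frequency basis carries the global
#' structural organization. A switch selects the largest instead.
#'
#' @param basis A `spectral_basis`.
#' @param s Number of eigenvectors (super-nodes per scale), default 8.
#' @param max_len Padding length; must be at least the protein length.
#' @param which `"smallest"` (default) or `"largest"` eigenvalues.
#' @return s x max_len matrix `S`, one selected eigenvector per row.
#' @export
select_spectral_descriptor <- function(basis, s = 8L, max_len = 1024L,
                                       which = c("smallest", "largest")) {
  which <- match.arg(which)
  stopifnot(inherits(basis, "spectral_basis"))
  n <- basis$n
  if (s > n) stop(sprintf("s = %d exceeds protein length n = %d", s, n))
  if (n > max_len) {
    stop(sprintf("protein length %d exceeds max_len = %d; raise max_len",
                 n, max_len))
  }
  idx <- if (which == "smallest") seq_len(s) else (n - s + 1L):n
  S <- matrix(0, s, max_len)
  S[, seq_len(n)] <- t(basis$vectors[, idx, drop = FALSE])
  S
}

#' Initialize attention encoder weights
#'
#' Independent fully connected layers per scale: three query maps
#' (`max_len -> c`) applied to the padded spectral descriptor, three key
#' maps (`d -> c`) applied to the band-decomposed signals, and three value
#' maps (`d -> c`) applied to the full signal `F` — nine independent
#' parameter sets plus one task embedding (a learned `c`-vector) per task.
#'
#' @param d Feature width of `F`.
#' @param c Attention width.
#' @param max_len Descriptor padding length.
#' @param tasks Character vector of task ids.
#' @param seed Integer seed.
#' @return Nested list of weight matrices and biases.
#' @export
init_pooling_weights <- function(d, c, max_len, tasks, seed = 1L) {
  mk <- function(nin, nout, label) {
    rng <- rng_substream(seed, label)
    list(W = with_rng(rng, matrix(stats::rnorm(nin * nout,
                                               sd = sqrt(2 / (nin + nout))),
                                  nin, nout)),
         b = rep(0, nout))
  }
  w <- list(
    query = lapply(stats::setNames(SCALES, SCALES),
                   function(x) mk(max_len, c, paste0("query_", x))),
    key   = lapply(stats::setNames(SCALES, SCALES),
                   function(x) mk(d, c, paste0("key_", x))),
    value = lapply(stats::setNames(SCALES, SCALES),
                   function(x) mk(d, c, paste0("value_", x))),
    task_emb = lapply(stats::setNames(tasks, tasks), function(t) {
      rng <- rng_substream(seed, paste0("task_emb_", t))
      with_rng(rng, stats::rnorm(c, sd = 0.1))
    })
  )
  w
}

fc <- function(X, layer) sweep(X %*% layer$W, 2, layer$b, "+")

#' Encode scale-specific queries
#'
#' Passes the spectral descriptor through three independent fully connected
#' layers (one per scale) and adds the task embedding to every row, so the
#' same protein yields different queries under different tasks.
#'
#' @param S s x max_len descriptor from [select_spectral_descriptor()].
#' @param task_embedding Length-`c` numeric task-conditioning vector.
#' @param weights Pooling weights from [init_pooling_weights()].
#' @return List of `Q_G`, `Q_D`, `Q_L`, each s x c.
#' @export
encode_queries <- function(S, task_embedding, weights) {
  lapply(stats::setNames(SCALES, paste0("Q_", SCALES)), function(x) {
    Q <- fc(S, weights$query[[x]])
    sweep(Q, 2, task_embedding, "+")
  })
}

#' Encode scale-specific keys from band-decomposed signals
#'
#' Each band (`F_G`, `F_D`, `F_L`) passes through its own fully connected
#' layer row-wise, giving keys whose pairwise similarity mirrors the
#' smoothness of its band: global keys are near-identical across residues,
#' local keys vary strongly.
#'
#' @param bands A `band_decomposition`.
#' @param weights Pooling weights.
#' @return List of `K_G`, `K_D`, `K_L`, each n x c.
#' @export
encode_keys <- function(bands, weights) {
  stopifnot(inherits(bands, "band_decomposition"))
  src <- list(G = bands$F_G, D = bands$F_D, L = bands$F_L)
  lapply(stats::setNames(SCALES, paste0("K_", SCALES)),
         function(x) fc(src[[x]], weights$key[[x]]))
}

#' Encode scale-specific values from the full signal
#'
#' The undecomposed signal `F` passes through one fully connected layer per
#' scale, so every scale aggregates the full semantic content while its keys
#' control where it looks.
#'
#' @param F n x d fused feature matrix.
#' @param weights Pooling weights.
#' @return List of `V_G`, `V_D`, `V_L`, each n x c.
#' @export
encode_values <- function(F, weights) {
  F <- as.matrix(F)
  lapply(stats::setNames(SCALES, paste0("V_", SCALES)),
         function(x) fc(F, weights$value[[x]]))
}

row_softmax <- function(X) {
  m <- apply(X, 1, max)
  E <- exp(X - m)
  E / rowSums(E)
}

#' Scaled dot-product attention aggregation
#'
#' `W = softmax(Q K' / sqrt(c))` row-wise, `Aggr = W V`: each super-node
#' (query row) aggregates residue values with non-negative weights summing
#' to one, so aggregated rows lie in the convex hull of the value rows.
#'
#' @param Q s x c query matrix.
#' @param K n x c key matrix.
#' @param V n x c value matrix.
#' @return List with `aggr` (s x c) and `weights` (s x n).
#' @export
attend <- function(Q, K, V) {
  if (ncol(Q) != ncol(K)) stop("query/key width mismatch")
  if (nrow(K) != nrow(V)) stop("key/value row mismatch")
  W <- row_softmax(Q %*% t(K) / sqrt(ncol(Q)))
  list(aggr = W %*% V, weights = W)
}

#' Pool a protein into a fixed-size multiscale representation
#'
#' Runs the full structure-aware attention pipeline for one protein and
#' task: queries from the padded spectral descriptor (plus task embedding),
#' keys from the band-decomposed signal, values from `F`, one attention
#' aggregation per scale, then a mean over super-nodes within each scale and
#' concatenation of the three scale vectors into a single length-`3c`
#' protein representation.
#'
#' @param F n x d fused features.
#' @param basis A `spectral_basis`.
#' @param weights Pooling weights from [init_pooling_weights()].
#' @param task_id Task identifier (must have a task embedding).
#' @param s Super-nodes per scale.
#' @param max_len Descriptor padding length.
#' @param p,q Band fractions.
#' @return An object of class `pooled_representation`: per-scale `aggr`
#'   (s x c) and attention `weights` (s x n), plus `vector` (length 3c).
#' @export
pool_protein <- function(F, basis, weights, task_id, s = 8L, max_len = 1024L,
                         p = 0.01, q = 0.03) {
  if (!task_id %in% names(weights$task_emb)) {
    stop(sprintf("unknown task '%s'; known: %s", task_id,
                 paste(names(weights$task_emb), collapse = ", ")))
  }
  S <- select_spectral_descriptor(basis, s = s, max_len = max_len)
  bands <- band_decompose(F, basis, p = p, q = q)
  Q <- encode_queries(S, weights$task_emb[[task_id]], weights)
  K <- encode_keys(bands, weights)
  V <- encode_values(F, weights)
  out <- lapply(stats::setNames(SCALES, SCALES), function(x) {
    attend(Q[[paste0("Q_", x)]], K[[paste0("K_", x)]], V[[paste0("V_", x)]])
  })
  vec <- unlist(lapply(out, function(o) colMeans(o$aggr)), use.names = FALSE)
  structure(list(scales = out, vector = vec, task_id = task_id),
            class = "pooled_representation")
}

#' Dump attention weights as TSV
#'
#' One row per (scale, super-node, residue) with the attention weight, for
#' inspection of where each super-node looks.
#'
#' @param pooled A `pooled_representation`.
#' @param path Output TSV path.
#' @param protein_id Identifier column value.
#' @return Invisibly, the path.
#' @export
write_attention_dump <- function(pooled, path, protein_id = "protein") {
  rows <- do.call(rbind, lapply(SCALES, function(x) {
    W <- pooled$scales[[x]]$weights
    data.frame(protein = protein_id,
               scale = c(G = "global", D = "domain", L = "local")[[x]],
               super_node = rep(seq_len(nrow(W)), ncol(W)),
               residue = rep(seq_len(ncol(W)), each = nrow(W)),
               weight = as.vector(W))
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
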