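#' Standard amino-acid alphabet
#'
#' The 20 standard residues in the fixed column order used by
#' [one_hot_encode()].
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' One-hot encode a residue sequence
#'
#' Each standard residue becomes a row with a single 1 in its alphabet
#' column; unknown/nonstandard residues (e.g. `"X"`) yield an all-zero row
#' rather than a 21st class, leaving their identity to the contextual
#' embedding.
#'
#' @param sequence Character vector of one-letter residue codes.
#' @return n x 20 numeric matrix with columns ordered as [AA_ALPHABET].
#' @export
one_hot_encode <- function(sequence) {
  if (length(sequence) == 0L) stop("sequence must be non-empty")
  M <- matrix(0, nrow = length(sequence), ncol = length(AA_ALPHABET),
              dimnames = list(NULL, AA_ALPHABET))
  idx <- match(toupper(sequence), AA_ALPHABET)
  hit <- which(!is.na(idx))
  M[cbind(hit, idx[hit])] <- 1
  M
}

#' Initialize feature-fusion projection weights
#'
#' Two linear maps projecting one-hot identity (width 20) and contextual
#' embeddings (width `e`) to a common `d`-dimensional space, plus a shared
#' bias. Entries are scaled Gaussian (Glorot-style), seeded.
#'
#' @param e Contextual embedding width.
#' @param d Target feature width.
#' @param seed Integer seed.
#' @return List with `W_onehot` (20 x d), `W_ctx` (e x d), `b` (length d).
#' @export
init_fusion_weights <- function(e, d, seed = 1L) {
  rng <- rng_substream(seed, "fusion")
  list(
    W_onehot = with_rng(rng, matrix(stats::rnorm(20 * d, sd = sqrt(2 / (20 + d))), 20, d)),
    W_ctx    = with_rng(rng, matrix(stats::rnorm(e * d, sd = sqrt(2 / (e + d))), e, d)),
    b        = rep(0, d)
  )
}

#' Fuse one-hot and contextual residue features
#'
#' Projects both inputs to a common `d`-dimensional space with independent
#' linear maps and combines them by summation:
#' `F = onehot W_onehot + contextual W_ctx + b`. The map is applied row-wise,
#' so there is no cross-residue mixing. Setting `use_onehot = FALSE` drops
#' the identity channel (the ablation axis).
#'
#' @param onehot n x 20 matrix from [one_hot_encode()].
#' @param contextual n x e matrix from an embedding provider.
#' @param weights Projection weights from [init_fusion_weights()].
#' @param use_onehot Include the one-hot channel (default TRUE).
#' @param embedder_name Provenance tag for the contextual provider.
#' @return n x d numeric matrix `F` (the graph signal) with attributes
#'   `one_hot_used` and `embedder_name`.
#' @export
fuse_features <- function(onehot, contextual, weights, use_onehot = TRUE,
                          embedder_name = "unknown") {
  onehot <- as.matrix(onehot); contextual <- as.matrix(contextual)
  if (nrow(onehot) != nrow(contextual)) {
    stop(sprintf("row-count mismatch: one-hot has %d rows, contextual %d",
                 nrow(onehot), nrow(contextual)))
  }
  F <- contextual %*% weights$W_ctx
  if (use_onehot) F <- F + onehot %*% weights$W_onehot
  F <- sweep(F, 2, weights$b, "+")
  if (!all(is.finite(F))) stop("non-finite values in fused features")
  attr(F, "one_hot_used") <- use_onehot
  attr(F, "embedder_name") <- embedder_name
  F
}

#' Deterministic mock per-residue contextual embedder
#'
#' A drop-in stand-in for a protein language model: each residue's embedding
#' is a deterministic function of its own identity and the identities of its
#' two sequence neighbours on each side (positions outside the chain
#' contribute a padding symbol), so the same sequence and seed always give
#' bit-identical output and a single substitution changes only rows within
#' its +/-2 window. Internally a seeded lookup table maps
#' (symbol, window offset) pairs to `width`-dimensional vectors that are
#' summed over the window.
#'
#' @param sequence Character vector of one-letter residue codes.
#' @param width Embedding width `e` (default 32).
#' @param seed Integer seed fixing the lookup table.
#' @return n x width numeric matrix.
#' @export
mock_embedder <- function(sequence, width = 32L, seed = 1L) {
  if (width <= 0) stop("width must be positive")
  n <- length(sequence)
  symbols <- c(AA_ALPHABET, "X", "-")   # "-" pads chain ends
  rng <- rng_substream(seed, "mock_embedder")
  # table[symbol, offset, ] ~ N(0, 1/sqrt(5)); 5 window offsets
  tab <- with_rng(rng, array(stats::rnorm(length(symbols) * 5 * width,
                                          sd = 1 / sqrt(5)),
                             dim = c(length(symbols), 5L, width)))
  seq_idx <- match(toupper(sequence), symbols)
  seq_idx[is.na(seq_idx)] <- match("X", symbols)
  pad <- match("-", symbols)
  E <- matrix(0, n, width)
  for (w in -2:2) {
    pos <- seq_len(n) + w
    sym <- ifelse(pos >= 1 & pos <= n, seq_idx[pmax(pmin(pos, n), 1L)], pad)
    E <- E + tab[cbind(rep(sym, width),
                       rep(w + 3L, n * width),
                       rep(seq_len(width), each = n))]
  }
  E
}

#' File-based embedding cache
#'
#' Stores one plain-text matrix file per protein id plus a manifest TSV
#' (id, length, width, provider), so heavy embedding providers need to run
#' only once per protein.
#'
#' @param dir Cache directory (created if missing).
#' @param id Protein identifier.
#' @param mat n x e embedding matrix (for [cache_embedding()]).
#' @param provider Provider name recorded in the manifest.
#' @return `cache_embedding()` returns the file path invisibly;
#'   `load_cached_embedding()` the matrix, or `NULL` if absent.
#' @export
cache_embedding <- function(dir, id, mat, provider = "unknown") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, paste0(id, ".tsv"))
  utils::write.table(mat, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  man_path <- file.path(dir, "manifest.tsv")
  entry <- data.frame(id = id, length = nrow(mat), width = ncol(mat),
                      provider = provider)
  if (file.exists(man_path)) {
    man <- utils::read.table(man_path, sep = "\t", header = TRUE,
                             colClasses = c("character", "integer", "integer",
                                            "character"))
    man <- rbind(man[man$id != id, , drop = FALSE], entry)
  } else man <- entry
  utils::write.table(man, man_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname cache_embedding
#' @export
load_cached_embedding <- function(dir, id) {
  path <- file.path(dir, paste0(id, ".tsv"))
  if (!file.exists(path)) return(NULL)
  as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
}
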