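# Largest protein for which a dense full eigendecomposition is attempted.
# O(n^3) is fine for real protein chain lengths; beyond this we refuse.
EIGEN_MAX_N <- 3000L

#' Graph Laplacian of a contact graph
#'
#' Builds either the combinatorial Laplacian `L = D - A` (degree matrix minus
#' adjacency) or the symmetric normalized Laplacian
#' `D^{-1/2} L D^{-1/2}`. Isolated vertices contribute zero rows/columns to
#' the normalized form.
#'
#' @param graph A `contact_graph` from [build_contact_graph()].
#' @param kind `"normalized"` (default) or `"combinatorial"`.
#'
#' @return An object of class `laplacian_matrix` with fields `matrix` (n x n
#'   symmetric) and `kind`.
#' @export
build_laplacian <- function(graph, kind = c("normalized", "combinatorial")) {
  kind <- match.arg(kind)
  stopifnot(inherits(graph, "contact_graph"))
  A <- graph$adjacency
  d <- graph$degrees
  L <- diag(d, nrow = graph$n) - A
  if (kind == "normalized") {
    dinv <- ifelse(d > 0, 1 / sqrt(d), 0)
    L <- L * outer(dinv, dinv)
  }
  structure(list(matrix = L, kind = kind, n = graph$n),
            class = "laplacian_matrix")
}

#' Ordered eigen-system of a graph Laplacian
#'
#' Full symmetric eigendecomposition with eigenvalues in ascending order
#' (`0 = lambda_1 <= lambda_2 <= ... <= lambda_n` for a connected graph's
#' Laplacian) and orthonormal eigenvector columns. A deterministic sign
#' convention is applied: in each eigenvector the first component with
#' absolute value above 1e-8 is made positive, so decompositions are
#' reproducible across runs and platforms. A disconnected graph (zero
#' eigenvalue of multiplicity > 1) is allowed with a warning; all its
#' zero-eigenvalue vectors fall into the lowest band by the ascending order.
#'
#' @param L A `laplacian_matrix`, or a plain symmetric matrix.
#'
#' @return An object of class `spectral_basis` with fields `values`
#'   (ascending eigenvalues), `vectors` (n x n matrix `U` with orthonormal
#'   columns) and `n`.
#' @export
eigendecompose <- function(L) {
  M <- if (inherits(L, "laplacian_matrix")) L$matrix else as.matrix(L)
  if (!isSymmetric(M, tol = 1e-8)) stop("Laplacian must be symmetric")
  n <- nrow(M)
  if (n > EIGEN_MAX_N) {
    stop(sprintf("n = %d exceeds the dense eigendecomposition cap (%d)",
                 n, EIGEN_MAX_N))
  }
  e <- eigen(M, symmetric = TRUE)
  ord <- rev(seq_len(n))            # eigen() returns descending; stable flip
  vals <- e$values[ord]
  U <- e$vectors[, ord, drop = FALSE]
  for (j in seq_len(n)) {
    lead <- which(abs(U[, j]) > 1e-8)[1]
    if (!is.na(lead) && U[lead, j] < 0) U[, j] <- -U[, j]
  }
  nzero <- sum(abs(vals) < 1e-8)
  if (nzero > 1L) {
    warning(sprintf("graph appears disconnected: zero eigenvalue multiplicity %d",
                    nzero))
  }
  structure(list(values = vals, vectors = U, n = n), class = "spectral_basis")
}

#' Graph Fourier Transform
#'
#' Projects a vertex signal onto the Laplacian eigenbasis: `Fhat = U' F`.
#' Entry (i, j) is the strength of the i-th frequency component in the j-th
#' signal column. The inverse transform [igft()] recovers `F = U Fhat`
#' exactly (orthonormal basis).
#'
#' @param F n x d numeric matrix of vertex signals (one row per vertex).
#' @param basis A `spectral_basis` from [eigendecompose()].
#' @return The transformed n x d matrix.
#' @export
gft <- function(F, basis) {
  F <- as.matrix(F)
  stopifnot(inherits(basis, "spectral_basis"))
  if (nrow(F) != basis$n) {
    stop(sprintf("signal has %d rows but basis is of size %d", nrow(F), basis$n))
  }
  crossprod(basis$vectors, F)
}

#' Inverse Graph Fourier Transform
#' @rdname gft
#' @param Fhat n x d matrix of spectral coefficients.
#' @export
igft <- function(Fhat, basis) {
  Fhat <- as.matrix(Fhat)
  stopifnot(inherits(basis, "spectral_basis"))
  if (nrow(Fhat) != basis$n) stop("coefficient rows do not match basis size")
  basis$vectors %*% Fhat
}

#' Spectral band boundaries
#'
#' Splits the eigen-index range `1..n` at fractions `p < q` of `n`:
#' `k_G = max(1, floor(n * p))` and `k_D = max(k_G + 1, floor(n * q))`
#' clamped to `n`. The clamping guarantees that the zero-frequency component
#' always lies in the global band and that the domain band is non-degenerate
#' whenever `n >= 2`.
#'
#' @param n Number of vertices.
#' @param p,q Fractional thresholds with `0 < p < q < 1`.
#' @return Integer vector `c(k_G, k_D)`.
#' @export
band_boundaries <- function(n, p = 0.01, q = 0.03) {
  if (!(p > 0 && q < 1 && p < q)) stop("require 0 < p < q < 1")
  k_g <- max(1L, as.integer(floor(n * p)))
  k_d <- max(k_g + 1L, as.integer(floor(n * q)))
  k_d <- min(k_d, as.integer(n))
  c(k_g, k_d)
}

#' Three-band spectral decomposition of a graph signal
#'
#' Decomposes the signal `F` into global, domain and local components
#' `F = F_G + F_D + F_L` by partitioning the ordered eigenbasis at the
#' boundaries from [band_boundaries()]: `F_G` uses eigenvectors `1..k_G`
#' (the smoothest, globally shared modes), `F_D` uses `k_G+1..k_D`
#' (domain-level modes) and `F_L` uses `k_D+1..n` (localized high-frequency
#' modes). An empty band yields a zero matrix. Reconstruction is exact up to
#' floating-point tolerance because the eigenbasis is orthonormal and
#' complete.
#'
#' @param F n x d numeric signal matrix.
#' @param basis A `spectral_basis`.
#' @param p,q Fractional thresholds, `0 < p < q < 1` (defaults 0.01, 0.03).
#'
#' @return An object of class `band_decomposition` with fields `F_G`, `F_D`,
#'   `F_L` (each n x d), boundaries `k_G`, `k_D`, and `p`, `q`.
#' @export
band_decompose <- function(F, basis, p = 0.01, q = 0.03) {
  F <- as.matrix(F)
  stopifnot(inherits(basis, "spectral_basis"))
  n <- basis$n
  if (nrow(F) != n) stop("signal rows do not match basis size")
  kb <- band_boundaries(n, p, q)
  k_g <- kb[1]; k_d <- kb[2]
  Fhat <- gft(F, basis)
  U <- basis$vectors
  proj <- function(idx) {
    if (length(idx) == 0L) matrix(0, n, ncol(F))
    else U[, idx, drop = FALSE] %*% Fhat[idx, , drop = FALSE]
  }
  F_G <- proj(seq_len(k_g))
  F_D <- proj(if (k_d > k_g) (k_g + 1L):k_d else integer(0))
  F_L <- proj(if (n > k_d) (k_d + 1L):n else integer(0))
  structure(list(F_G = F_G, F_D = F_D, F_L = F_L,
                 k_G = k_g, k_D = k_d, p = p, q = q),
            class = "band_decomposition")
}

#' Dump eigenvalues and band boundaries as TSV
#'
#' Diagnostic output: one row per eigen-index with its eigenvalue and the
#' band (`global`/`domain`/`local`) it falls in at the given `(p, q)`.
#'
#' @param basis A `spectral_basis`.
#' @param path Output TSV path.
#' @param p,q Band fractions.
#' @return Invisibly, the path.
#' @export
write_spectrum <- function(basis, path, p = 0.01, q = 0.03) {
  kb <- band_boundaries(basis$n, p, q)
  band <- c(rep("global", kb[1]),
            rep("domain", max(0L, kb[2] - kb[1])),
            rep("local", max(0L, basis$n - kb[2])))
  utils::write.table(
    data.frame(index = seq_len(basis$n), eigenvalue = basis$values, band = band),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
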