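make_basis <- function(n, seed = 1, kind = "normalized") {
  eigendecompose(build_laplacian(random_connected_graph(n, seed = seed), kind))
}

test_that("the spectral descriptor pads eigenvectors to a fixed shape", {
  b <- make_basis(50, seed = 1)
  S <- select_spectral_descriptor(b, s = 8, max_len = 512)
  expect_equal(dim(S), c(8L, 512L))
  expect_true(all(S[, 51:512] == 0))
  expect_equal(S[, 1:50], t(b$vectors[, 1:8]), tolerance = 1e-12)

  # s = n: every selected eigenvector appears as exactly one row
  b2 <- make_basis(10, seed = 2)
  S2 <- select_spectral_descriptor(b2, s = 10, max_len = 16)
  expect_equal(S2[, 1:10], t(b2$vectors), tolerance = 1e-12)

  # proteins of different lengths give descriptors of identical shape
  S3 <- select_spectral_descriptor(make_basis(23, seed = 3), s = 8,
                                   max_len = 512)
  expect_equal(dim(S3), dim(S))
  expect_error(select_spectral_descriptor(b, s = 8, max_len = 40), "max_len")
  # the largest-eigenvalue variant picks the other end of the spectrum
  Sl <- select_spectral_descriptor(b, s = 2, max_len = 64, which = "largest")
  expect_equal(Sl[2, 1:50], b$vectors[, 50], tolerance = 1e-12)
})

test_that("queries are task-conditioned with additive embeddings", {
  w <- init_pooling_weights(d = 6, c = 4, max_len = 32,
                            tasks = c("t1", "t2"), seed = 1)
  S <- matrix(0, 3, 32)
  Q <- encode_queries(S, w$task_emb$t1, w)
  # zero descriptor and zero bias: every row equals the task embedding
  for (x in c("Q_G", "Q_D", "Q_L")) {
    expect_equal(dim(Q[[x]]), c(3L, 4L))
    expect_equal(Q[[x]][1, ], w$task_emb$t1, tolerance = 1e-12)
    expect_equal(Q[[x]][3, ], w$task_emb$t1, tolerance = 1e-12)
  }
  # different tasks give different queries for the same protein
  b <- make_basis(20, seed = 4)
  Sd <- select_spectral_descriptor(b, s = 3, max_len = 32)
  Q1 <- encode_queries(Sd, w$task_emb$t1, w)
  Q2 <- encode_queries(Sd, w$task_emb$t2, w)
  expect_gt(max(abs(Q1$Q_G - Q2$Q_G)), 0)
})

test_that("keys and values are row-wise maps preserving n", {
  w <- init_pooling_weights(d = 5, c = 4, max_len = 32, tasks = "t", seed = 2)
  b <- make_basis(18, seed = 5)
  set.seed(5)
  F <- matrix(rnorm(18 * 5), 18, 5)
  bands <- band_decompose(F, b, 0.05, 0.2)
  K <- encode_keys(bands, w)
  V <- encode_values(F, w)
  for (x in c("K_G", "K_D", "K_L")) expect_equal(nrow(K[[x]]), 18L)
  for (x in c("V_G", "V_D", "V_L")) expect_equal(nrow(V[[x]]), 18L)
  # identical band rows give identical key rows
  bands_const <- bands
  bands_const$F_G <- matrix(1, 18, 5) %*% diag(c(1, 2, 3, 4, 5))
  Kc <- encode_keys(bands_const, w)
  expect_lt(max(abs(sweep(Kc$K_G, 2, Kc$K_G[1, ]))), 1e-12)
})

test_that("global keys are mutually more similar than local keys under random weights", {
  wins <- 0
  for (seed in 1:20) {
    g <- modular_graph(n = 120, k = 4, seed = seed)
    b <- suppressWarnings(eigendecompose(build_laplacian(g, "normalized")))
    set.seed(seed + 500)
    F <- matrix(rnorm(120 * 8), 120, 8)
    bands <- band_decompose(F, b, 0.01, 0.03)
    w <- init_pooling_weights(d = 8, c = 6, max_len = 128, tasks = "t",
                              seed = seed)
    K <- encode_keys(bands, w)
    if (mean_pairwise_cosine(K$K_G) > mean_pairwise_cosine(K$K_L)) {
      wins <- wins + 1
    }
  }
  expect_gte(wins, 18)
})

test_that("attention weights are a proper convex aggregation", {
  set.seed(9)
  s <- 4; n <- 30; cw <- 6
  Q <- matrix(rnorm(s * cw), s, cw)
  K <- matrix(rnorm(n * cw), n, cw)
  V <- matrix(rnorm(n * cw), n, cw)
  a <- attend(Q, K, V)
  expect_equal(dim(a$aggr), c(s, cw))
  expect_equal(dim(a$weights), c(s, n))
  expect_true(all(a$weights >= 0))
  expect_equal(rowSums(a$weights), rep(1, s), tolerance = 1e-6)

  # identical keys: uniform weights
  au <- attend(Q, matrix(1, n, cw), V)
  expect_lt(max(abs(au$weights - 1 / n)), 1e-6)

  # constant values: every aggregated row equals that constant
  v0 <- rnorm(cw)
  ac <- attend(Q, K, matrix(v0, n, cw, byrow = TRUE))
  for (i in seq_len(s)) expect_equal(ac$aggr[i, ], v0, tolerance = 1e-8)

  # aggregated rows lie inside the coordinate-wise hull of the value rows
  expect_true(all(a$aggr <= matrix(apply(V, 2, max), s, cw, byrow = TRUE) + 1e-12))
  expect_true(all(a$aggr >= matrix(apply(V, 2, min), s, cw, byrow = TRUE) - 1e-12))
  expect_error(attend(Q, K[, 1:3], V), "mismatch")
})

test_that("global attention rows are more entropic than local ones on modular graphs", {
  wins <- 0
  for (seed in 1:20) {
    g <- modular_graph(n = 120, k = 4, seed = seed)
    b <- suppressWarnings(eigendecompose(build_laplacian(g, "normalized")))
    set.seed(seed + 900)
    F <- matrix(rnorm(120 * 8), 120, 8)
    w <- init_pooling_weights(d = 8, c = 6, max_len = 128, tasks = "t",
                              seed = seed)
    pooled <- pool_protein(F, b, w, "t", s = 4, max_len = 128)
    eg <- mean(row_entropy(pooled$scales$G$weights))
    el <- mean(row_entropy(pooled$scales$L$weights))
    if (eg >= el) wins <- wins + 1
  }
  expect_gte(wins, 18)
})

test_that("permuting residues permutes attention columns and fixes the aggregate", {
  set.seed(11)
  s <- 3; n <- 16; cw <- 4
  Q <- matrix(rnorm(s * cw), s, cw)
  K <- matrix(rnorm(n * cw), n, cw)
  V <- matrix(rnorm(n * cw), n, cw)
  a <- attend(Q, K, V)
  perm <- sample(n)
  ap <- attend(Q, K[perm, ], V[perm, ])
  expect_equal(ap$weights, a$weights[, perm], tolerance = 1e-12)
  expect_equal(ap$aggr, a$aggr, tolerance = 1e-12)
})

test_that("the attention dump covers every (scale, super-node, residue) triple", {
  n <- 12
  b <- make_basis(n, seed = 13)
  set.seed(13)
  F <- matrix(rnorm(n * 5), n, 5)
  w <- init_pooling_weights(d = 5, c = 4, max_len = 32, tasks = "t", seed = 1)
  pooled <- pool_protein(F, b, w, "t", s = 3, max_len = 32)
  path <- tempfile(fileext = ".tsv")
  write_attention_dump(pooled, path, protein_id = "p1")
  df <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(nrow(df), 3L * 3L * n)
  sums <- tapply(df$weight, list(df$scale, df$super_node), sum)
  expect_equal(as.vector(sums), rep(1, 9), tolerance = 1e-6)
})
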