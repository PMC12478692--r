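# Shared fixtures and independent oracles for the test suite.

# --- hand-written PDB fixtures ----------------------------------------------

pdb_line <- function(serial, aname, resid, chain, resno, x, y, z) {
  sprintf("ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
          serial, aname, resid, chain, resno, x, y, z)
}

# three residues with CA at given coordinates on chain A
write_tiny_pdb <- function(path, coords = rbind(c(0, 0, 0), c(3.8, 0, 0),
                                                c(7.6, 0, 0)),
                           resids = c("ALA", "GLY", "SER"),
                           drop_ca = integer(0), chain = "A") {
  lines <- character(0)
  serial <- 0L
  for (i in seq_len(nrow(coords))) {
    serial <- serial + 1L
    aname <- if (i %in% drop_ca) "CB" else "CA"
    lines <- c(lines, pdb_line(serial, aname, resids[i], chain, i,
                               coords[i, 1], coords[i, 2], coords[i, 3]))
  }
  writeLines(c(lines, "END"), path)
  path
}

# --- graphs ------------------------------------------------------------------

# wrap a symmetric 0/1 adjacency matrix as a contact_graph
graph_from_adjacency <- function(A) {
  n <- nrow(A)
  ut <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
  structure(list(n = n, adjacency = unname(A), degrees = unname(rowSums(A)),
                 edges = data.frame(i = ut[, 1], j = ut[, 2], distance = NA_real_),
                 threshold = NA_real_),
            class = "contact_graph")
}

# planted-partition graph: k equally sized communities
modular_graph <- function(n = 200, k = 4, p_in = 0.25, p_out = 0.01,
                          seed = 1) {
  set.seed(seed)
  block <- rep(seq_len(k), length.out = n)
  P <- ifelse(outer(block, block, "=="), p_in, p_out)
  A <- matrix(0, n, n)
  up <- upper.tri(A)
  A[up] <- as.numeric(stats::runif(sum(up)) < P[up])
  A <- A + t(A)
  graph_from_adjacency(A)
}

random_connected_graph <- function(n, p = 0.2, seed = 1) {
  set.seed(seed)
  repeat {
    A <- matrix(0, n, n)
    up <- upper.tri(A)
    A[up] <- as.numeric(stats::runif(sum(up)) < p)
    A <- A + t(A)
    # connect stragglers through a chain so the graph is always connected
    for (i in seq_len(n - 1)) A[i, i + 1] <- A[i + 1, i] <- 1
    return(graph_from_adjacency(A))
  }
}

mean_pairwise_cosine <- function(M) {
  nr <- sqrt(rowSums(M^2))
  keep <- nr > 1e-12
  M <- M[keep, , drop = FALSE] / nr[keep]
  C <- M %*% t(M)
  mean(C[upper.tri(C)])
}

row_entropy <- function(W) {
  -rowSums(ifelse(W > 0, W * log(W), 0))
}

# --- brute-force metric oracles ---------------------------------------------
# Naive loop-based implementations, kept deliberately independent of the
# package's vectorized ones.

oracle_fmax <- function(scores, truth, thresholds = seq(0.01, 1, by = 0.01)) {
  ids <- rownames(scores)
  best <- 0
  for (tau in thresholds) {
    precs <- c(); recs <- c()
    for (id in ids) {
      pred <- colnames(scores)[scores[id, ] >= tau]
      tr <- intersect(truth[[id]], colnames(scores))
      if (length(pred) > 0) precs <- c(precs, length(intersect(pred, tr)) / length(pred))
      if (length(tr) > 0) recs <- c(recs, length(intersect(pred, tr)) / length(tr))
    }
    if (length(precs) == 0 || length(recs) == 0) next
    p <- mean(precs); r <- mean(recs)
    if (p + r > 0) best <- max(best, 2 * p * r / (p + r))
  }
  best
}

oracle_smin <- function(scores, truth, ic, thresholds = seq(0.01, 1, by = 0.01)) {
  ids <- rownames(scores)
  best <- Inf
  for (tau in thresholds) {
    rus <- c(); mis <- c()
    for (id in ids) {
      pred <- colnames(scores)[scores[id, ] >= tau]
      tr <- intersect(truth[[id]], colnames(scores))
      rus <- c(rus, sum(ic[setdiff(tr, pred)]))
      mis <- c(mis, sum(ic[setdiff(pred, tr)]))
    }
    best <- min(best, sqrt(mean(rus)^2 + mean(mis)^2))
  }
  best
}

oracle_aupr <- function(scores, truth) {
  ids <- rownames(scores); terms <- colnames(scores)
  lab <- c(); sc <- c()
  for (id in ids) for (t in terms) {
    lab <- c(lab, t %in% truth[[id]])
    sc <- c(sc, scores[id, t])
  }
  pos <- sum(lab)
  taus <- sort(unique(sc), decreasing = TRUE)
  area <- 0; prev_rec <- 0
  for (tau in taus) {
    tp <- sum(lab & sc >= tau); fp <- sum(!lab & sc >= tau)
    prec <- tp / (tp + fp); rec <- tp / pos
    area <- area + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  area
}

# random small prediction problems for oracle-equivalence suites
random_prediction_case <- function(seed) {
  set.seed(seed)
  np <- sample(3:6, 1); nt <- sample(4:8, 1)
  ids <- paste0("p", seq_len(np)); terms <- paste0("t", seq_len(nt))
  scores <- matrix(round(stats::runif(np * nt), 2), np, nt,
                   dimnames = list(ids, terms))
  truth <- lapply(ids, function(i) sample(terms, sample(1:nt, 1)))
  names(truth) <- ids
  ic <- stats::setNames(round(stats::runif(nt, 0.1, 4), 2), terms)
  list(scores = scores, truth = truth, ic = ic)
}

# small model + protein for model-level tests
tiny_model_setup <- function(seed = 7) {
  tasks <- list(task_spec("A", c("a1", "a2")), task_spec("B", c("b1", "b2", "b3")))
  model <- init_model(tasks, d = 6, c = 4, s = 2, max_len = 32, e = 5,
                      seed = seed)
  st <- generate_structure(14, "compact", seed = seed, id = "tiny")
  list(model = model, struct = st, pre = precompute_protein(st, model))
}
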