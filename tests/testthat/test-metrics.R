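simple_dag <- function() {
  ontology_dag(data.frame(child = c("t", "a", "t2"),
                          parent = c("a", "root", "root")))
}

test_that("ontology construction validates structure and finds roots", {
  dag <- simple_dag()
  expect_setequal(dag$roots, "root")
  expect_setequal(dag$ancestors$t, c("t", "a", "root"))
  expect_error(ontology_dag(data.frame(child = c("a", "b"),
                                       parent = c("b", "a"))), "cycle")
})

test_that("OBO and edge-TSV ontology readers agree", {
  obo <- tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "",
               "[Term]", "id: GO:1", "name: root", "",
               "[Term]", "id: GO:2", "name: mid", "is_a: GO:1 ! root", "",
               "[Term]", "id: GO:3", "name: leaf", "is_a: GO:2 ! mid"), obo)
  tsv <- tempfile(fileext = ".tsv")
  write.table(data.frame(child = c("GO:2", "GO:3"), parent = c("GO:1", "GO:2")),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  d1 <- read_ontology(obo); d2 <- read_ontology(tsv)
  expect_equal(d1$terms, d2$terms)
  expect_equal(d1$ancestors, d2$ancestors)
})

test_that("annotation propagation is the transitive closure and is idempotent", {
  dag <- simple_dag()
  prop <- propagate(list(p1 = "t", p2 = c("t", "a", "root"), p3 = character(0)),
                    dag)
  expect_equal(prop$p1, c("a", "root", "t"))
  expect_equal(prop$p2, c("a", "root", "t"))   # already closed: unchanged
  expect_equal(prop$p3, character(0))
  expect_equal(propagate(prop, dag), prop)
  expect_error(propagate(list(p = "nope"), dag), "nope")
})

test_that("information content follows propagated frequencies with a ceiling", {
  dag <- simple_dag()
  ref <- propagate(list(p1 = "t", p2 = "t", p3 = "t2", p4 = "t2"), dag)
  ic <- ic_table(ref, dag)
  expect_equal(unname(ic["root"]), 0)              # annotated everywhere
  expect_equal(unname(ic["t"]), -log2(0.5))
  expect_equal(unname(ic["a"]), -log2(0.5))
  # never-seen terms would get the finite ceiling -log2(1/(N+1))
  dag2 <- ontology_dag(data.frame(child = c("t", "u"), parent = c("r", "r")))
  ic2 <- ic_table(propagate(list(p1 = "t"), dag2), dag2)
  expect_equal(unname(ic2["u"]), -log2(1 / 2))
})

test_that("fmax reproduces the hand-derived single-protein case", {
  dag <- ontology_dag(data.frame(child = c("t1", "t2"), parent = c("r", "r")))
  truth <- list(p1 = "t1")
  scores <- matrix(c(0.4, 0.9), 1, 2, dimnames = list("p1", c("t1", "t2")))
  res <- fmax(scores, truth)
  # at tau <= 0.4 both terms are predicted: precision 1/2, recall 1, F = 2/3
  expect_equal(res$fmax, 2 / 3, tolerance = 1e-12)
  expect_lte(res$threshold, 0.4)

  # a perfect predictor reaches Fmax 1
  perfect <- matrix(c(1, 0), 1, 2, dimnames = list("p1", c("t1", "t2")))
  expect_equal(fmax(perfect, truth)$fmax, 1)
  expect_error(fmax(scores, list(p1 = character(0))), "true term")
})

test_that("smin limit cases behave as expected", {
  truth <- list(p1 = c("t1", "r"), p2 = c("t2", "r"))
  terms <- c("r", "t1", "t2")
  ic <- c(r = 0, t1 = 1, t2 = 2)
  perfect <- rbind(p1 = c(1, 1, 0), p2 = c(1, 0, 1))
  colnames(perfect) <- terms
  expect_equal(smin(perfect, truth, ic)$smin, 0)
  # a predictor silent at every threshold leaves only remaining uncertainty:
  # the mean total IC of the true terms
  silent <- perfect * 0
  expect_equal(smin(silent, truth, ic)$smin, mean(c(1, 2)), tolerance = 1e-12)
})

test_that("aupr has the textbook limit behaviours", {
  truth <- list(p1 = "t1", p2 = "t2")
  terms <- c("t1", "t2")
  sep <- rbind(p1 = c(0.9, 0.1), p2 = c(0.2, 0.8))
  colnames(sep) <- terms
  expect_equal(aupr(sep, truth)$aupr, 1)          # perfect separation
  flat <- rbind(p1 = c(0.5, 0.5), p2 = c(0.5, 0.5))
  colnames(flat) <- terms
  expect_equal(aupr(flat, truth)$aupr, 0.5)        # prevalence of positives
  expect_error(aupr(flat, list(p1 = character(0), p2 = character(0))),
               "positive")
})

test_that("all three metrics agree with brute-force oracles on random suites", {
  for (seed in 1:50) {
    case <- random_prediction_case(seed)
    expect_equal(fmax(case$scores, case$truth)$fmax,
                 oracle_fmax(case$scores, case$truth), tolerance = 1e-12)
    expect_equal(smin(case$scores, case$truth, case$ic)$smin,
                 oracle_smin(case$scores, case$truth, case$ic),
                 tolerance = 1e-12)
    expect_equal(aupr(case$scores, case$truth)$aupr,
                 oracle_aupr(case$scores, case$truth), tolerance = 1e-10)
  }
})

test_that("fmax is invariant under sub-grid rank-preserving perturbations", {
  case <- random_prediction_case(99)
  base <- fmax(case$scores, case$truth)$fmax
  # scores sit on the 0.01 grid; jitter below half the grid resolution
  set.seed(1)
  jit <- case$scores + matrix(runif(length(case$scores), 0, 0.004),
                              nrow(case$scores))
  expect_equal(fmax(jit, case$truth)$fmax, base, tolerance = 1e-12)
})

test_that("adding a correctly predicted term never worsens smin", {
  case <- random_prediction_case(7)
  s0 <- smin(case$scores, case$truth, case$ic)$smin
  sc <- case$scores
  id <- rownames(sc)[1]
  truly <- intersect(case$truth[[id]], colnames(sc))
  if (length(truly)) {
    sc[id, truly[1]] <- 1
    expect_lte(smin(sc, case$truth, case$ic)$smin, s0 + 1e-12)
  }
})

test_that("evaluation results round-trip through TSV", {
  case <- random_prediction_case(3)
  res <- evaluate_predictions(case$scores, case$truth, case$ic)
  path <- tempfile(fileext = ".tsv"); curve <- tempfile(fileext = ".tsv")
  write_eval_result(res, path, curve)
  row <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(row$fmax, res$fmax, tolerance = 1e-12)
  expect_equal(row$smin, res$smin, tolerance = 1e-12)
  expect_equal(row$aupr, res$aupr, tolerance = 1e-12)
  expect_gt(nrow(read.table(curve, header = TRUE, sep = "\t")), 0)
})
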