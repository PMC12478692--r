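test_that("forward scores are valid probabilities, task by task", {
  setup <- tiny_model_setup()
  sA <- model_forward(setup$model, setup$pre, "A")
  sB <- model_forward(setup$model, setup$pre, "B")
  expect_length(sA, 2L); expect_length(sB, 3L)
  expect_true(all(sA > 0 & sA < 1))
  expect_true(all(sB > 0 & sB < 1))
  expect_equal(names(sB), c("b1", "b2", "b3"))
  # deterministic given parameters
  expect_identical(sA, model_forward(setup$model, setup$pre, "A"))
  expect_error(model_forward(setup$model, setup$pre, "C"), "unknown task")

  # zero trunk and zero head: sigmoid(0) = 0.5 everywhere
  m0 <- setup$model
  m0$params$trunk$W[] <- 0; m0$params$trunk$b[] <- 0
  m0$params$heads$A$W[] <- 0; m0$params$heads$A$b[] <- 0
  expect_equal(unname(model_forward(m0, setup$pre, "A")), c(0.5, 0.5))
})

test_that("multi-label cross-entropy matches closed forms", {
  expect_equal(multilabel_loss(1, 0.5), log(2), tolerance = 1e-12)
  expect_equal(multilabel_loss(c(1, 0), c(0.9, 0.1)), -2 * log(0.9),
               tolerance = 1e-12)
  expect_lt(multilabel_loss(c(1, 0, 1), c(1, 0, 1)), 1e-5)
  expect_gte(multilabel_loss(c(0, 1), c(0.3, 0.7)), 0)
  expect_equal(multilabel_loss(c(1, 0), c(0.5, 0.5), weights = c(2, 0)),
               2 * log(2), tolerance = 1e-12)
  expect_error(multilabel_loss(c(1, 0), 0.5), "length")
})

test_that("analytic gradients match numerical differentiation", {
  setup <- tiny_model_setup()
  model <- setup$model; pre <- setup$pre
  y <- c(1, 0)
  fwd <- specpool:::model_forward_cache(model, pre, "A", keep = TRUE)
  grads <- specpool:::model_backward(model, pre, fwd, y)

  leaf_paths <- list(c("fusion", "W_onehot"), c("fusion", "W_ctx"),
                     c("fusion", "b"),
                     c("query", "G", "W"), c("query", "D", "b"),
                     c("query", "L", "W"),
                     c("key", "G", "W"), c("key", "D", "W"),
                     c("key", "L", "b"),
                     c("value", "G", "W"), c("value", "D", "b"),
                     c("value", "L", "W"),
                     c("task_emb", "A"),
                     c("trunk", "W"), c("trunk", "b"),
                     c("heads", "A", "W"), c("heads", "A", "b"))
  get_leaf <- function(tree, path) { for (k in path) tree <- tree[[k]]; tree }
  set_leaf <- function(tree, path, idx, val) {
    if (length(path) == 1L) { tree[[path]][idx] <- val; return(tree) }
    tree[[path[1]]] <- set_leaf(tree[[path[1]]], path[-1], idx, val)
    tree
  }
  eps <- 1e-5
  set.seed(42)
  for (path in leaf_paths) {
    g_leaf <- get_leaf(grads, path)
    idx <- sample(length(g_leaf), 1)
    for (sgn in c(1, -1)) {
      mp <- model
      v0 <- get_leaf(model$params, path)[idx]
      mp$params <- set_leaf(model$params, path, idx, v0 + sgn * eps)
      assign(if (sgn > 0) "lp" else "lm",
             multilabel_loss(y, model_forward(mp, pre, "A")))
    }
    num <- (lp - lm) / (2 * eps)
    expect_equal(g_leaf[idx], num, tolerance = 1e-4,
                 label = paste("grad", paste(path, collapse = "$")))
  }
  # gradient reaches every parameter group of the drawn task
  nz <- rapply(grads, function(x) sum(abs(x)) > 0, how = "unlist")
  zero_names <- names(nz)[!nz]
  expect_true(all(grepl("\\.B", zero_names)))   # only the undrawn task's head/embedding
})

test_that("the multitask model shares parameters across tasks", {
  tasks3 <- list(task_spec("MF", paste0("m", 1:5)),
                 task_spec("BP", paste0("b", 1:8)),
                 task_spec("CC", paste0("c", 1:4)))
  multi <- init_model(tasks3, d = 8, c = 6, s = 2, max_len = 32, e = 5)
  singles <- sum(vapply(tasks3, function(t)
    count_params(init_model(list(t), d = 8, c = 6, s = 2, max_len = 32, e = 5)),
    numeric(1)))
  expect_lt(count_params(multi), singles)
})

test_that("training is seeded-reproducible and overfits a tiny dataset", {
  tasks <- synthetic_tasks()
  model <- init_model(tasks, d = 8, c = 6, s = 2, max_len = 64, e = 8,
                      seed = 5)
  spec <- synthetic_spec(seed = 5)
  structs <- lapply(1:10, function(i) {
    st <- generate_structure(20 + i, if (i %% 2) "compact" else "extended",
                             seed = i, spec = spec, id = paste0("p", i))
    st
  })
  pre <- lapply(structs, function(st) precompute_protein(st, model))
  names(pre) <- vapply(structs, function(s) s$id, character(1))
  dag <- toy_ontology()
  ann <- lapply(structs, function(st) {
    lab <- plant_labels(st, spec)
    c(lab$annotations$global_fold, lab$annotations$local_motif)
  })
  names(ann) <- names(pre)
  prop <- propagate(ann, dag)
  labels <- lapply(model$tasks, function(t) {
    M <- matrix(0, length(pre), t$C, dimnames = list(names(pre), t$labels))
    for (id in names(pre)) M[id, intersect(prop[[id]], t$labels)] <- 1
    M
  })
  t1 <- train_model(model, pre, labels, epochs = 30, batch_size = 5,
                    lr = 5e-3, seed = 9)
  t2 <- train_model(model, pre, labels, epochs = 30, batch_size = 5,
                    lr = 5e-3, seed = 9)
  expect_equal(t1$log$loss, t2$log$loss, tolerance = 1e-6)
  expect_identical(t1$params$trunk$W, t2$params$trunk$W)
  # overfitting 10 proteins for 30 epochs must reduce the loss
  first <- mean(t1$log$loss[t1$log$epoch == 1])
  last <- mean(t1$log$loss[t1$log$epoch == 30])
  expect_lt(last, first)
  expect_error(train_model(model, list(), labels), "empty")
})

test_that("predictions export as long-format TSV", {
  setup <- tiny_model_setup()
  pre <- list(tiny = setup$pre)
  scores <- list(A = predict_scores(setup$model, pre, "A"),
                 B = predict_scores(setup$model, pre, "B"))
  path <- tempfile(fileext = ".tsv")
  write_predictions(scores, path)
  df <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(nrow(df), 5L)   # 2 + 3 terms
  expect_setequal(df$task, c("A", "B"))
  expect_true(all(df$score > 0 & df$score < 1))
})
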