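#' Multitask task specification
#'
#' @param task_id Task identifier (e.g. `"MF"`, `"BP"`, `"CC"` or synthetic
#'   task names).
#' @param labels Ordered character vector of unique term ids predicted by
#'   this task's head.
#' @return An object of class `task_spec`.
#' @export
task_spec <- function(task_id, labels) {
  labels <- as.character(labels)
  if (length(labels) < 1L) stop("task needs at least one label")
  if (anyDuplicated(labels)) stop("task labels must be unique")
  structure(list(task_id = as.character(task_id), labels = labels,
                 C = length(labels)), class = "task_spec")
}

#' Initialize the multitask spectral-attention model
#'
#' Creates the full parameter tree: feature-fusion projections (shared),
#' three query / three key / three value encoders (shared), one learned task
#' embedding per task, a shared trunk (one hidden layer of width `2c` with
#' ReLU) and one affine head per task. All tasks share trunk and pooling
#' parameters; only embeddings and heads are task-specific, which is what
#' makes the multitask model smaller than per-task clones.
#'
#' @param tasks List of [task_spec()] objects.
#' @param d Fused feature width (default 128).
#' @param c Attention width (default 64).
#' @param s Super-nodes per scale (default 8).
#' @param max_len Spectral-descriptor padding length (default 1024).
#' @param e Contextual embedding width (default 32).
#' @param p,q Spectral band fractions (defaults 0.01, 0.03).
#' @param use_onehot Include the one-hot identity channel (default TRUE).
#' @param contact_threshold Contact distance threshold in Angstrom.
#' @param laplacian Laplacian kind, `"normalized"` or `"combinatorial"`.
#' @param seed Integer seed for weight initialization.
#' @return An object of class `specpool_model` holding `params`, `tasks` and
#'   the hyperparameter list `hyper`.
#' @export
init_model <- function(tasks, d = 128L, c = 64L, s = 8L, max_len = 1024L,
                       e = 32L, p = 0.01, q = 0.03, use_onehot = TRUE,
                       contact_threshold = 10.0,
                       laplacian = c("normalized", "combinatorial"),
                       seed = 1L) {
  laplacian <- match.arg(laplacian)
  if (inherits(tasks, "task_spec")) tasks <- list(tasks)
  names(tasks) <- vapply(tasks, function(t) t$task_id, character(1))
  mk <- function(nin, nout, label) {
    rng <- rng_substream(seed, label)
    list(W = with_rng(rng, matrix(stats::rnorm(nin * nout,
                                               sd = sqrt(2 / (nin + nout))),
                                  nin, nout)),
         b = rep(0, nout))
  }
  sc <- stats::setNames(SCALES, SCALES)
  params <- list(
    fusion = init_fusion_weights(e, d, seed = seed),
    query = lapply(sc, function(x) mk(max_len, c, paste0("query_", x))),
    key   = lapply(sc, function(x) mk(d, c, paste0("key_", x))),
    value = lapply(sc, function(x) mk(d, c, paste0("value_", x))),
    task_emb = lapply(names(tasks), function(t) {
      rng <- rng_substream(seed, paste0("task_emb_", t))
      with_rng(rng, stats::rnorm(c, sd = 0.1))
    }),
    trunk = mk(3L * c, 2L * c, "trunk"),
    heads = lapply(names(tasks), function(t) mk(2L * c, tasks[[t]]$C,
                                                paste0("head_", t)))
  )
  names(params$task_emb) <- names(tasks)
  names(params$heads) <- names(tasks)
  structure(list(
    params = params, tasks = tasks,
    hyper = list(d = d, c = c, s = s, max_len = max_len, e = e, p = p, q = q,
                 use_onehot = use_onehot, contact_threshold = contact_threshold,
                 laplacian = laplacian, seed = seed)
  ), class = "specpool_model")
}

#' @export
print.specpool_model <- function(x, ...) {
  cat(sprintf("<specpool_model> %d task(s): %s | d=%d c=%d s=%d | %d parameters\n",
              length(x$tasks), paste(names(x$tasks), collapse = ", "),
              x$hyper$d, x$hyper$c, x$hyper$s, count_params(x)))
  invisible(x)
}

#' Precompute the per-protein quantities the model consumes
#'
#' Runs everything that does not depend on trainable parameters once per
#' protein: one-hot encoding, contextual embedding, contact graph,
#' Laplacian eigendecomposition, band boundaries and the padded spectral
#' descriptor. Training and prediction then reuse this cache.
#'
#' @param struct A [protein_structure()].
#' @param model A `specpool_model` (its hyperparameters are used).
#' @param contextual Optional n x e contextual embedding matrix; when `NULL`
#'   the deterministic [mock_embedder()] is used with the model's seed.
#' @return An object of class `protein_precomp`.
#' @export
precompute_protein <- function(struct, model, contextual = NULL) {
  h <- model$hyper
  graph <- build_contact_graph(struct, threshold = h$contact_threshold)
  L <- build_laplacian(graph, kind = h$laplacian)
  basis <- eigendecompose(L)
  if (is.null(contextual)) {
    contextual <- mock_embedder(struct$sequence, width = h$e, seed = h$seed)
  }
  if (nrow(contextual) != struct$n) stop("contextual embedding rows != n")
  if (ncol(contextual) != h$e) stop("contextual embedding width != e")
  kb <- band_boundaries(struct$n, h$p, h$q)
  structure(list(
    id = struct$id, n = struct$n,
    onehot = one_hot_encode(struct$sequence),
    ctx = contextual,
    U = basis$vectors, eigenvalues = basis$values,
    k_G = kb[1], k_D = kb[2],
    S = select_spectral_descriptor(basis, s = h$s, max_len = h$max_len)
  ), class = "protein_precomp")
}

# Full forward pass for one (protein, task); optionally keeps every
# intermediate needed by the analytic backward pass.
model_forward_cache <- function(model, pre, task_id, keep = FALSE) {
  p <- model$params; h <- model$hyper
  if (!task_id %in% names(model$tasks)) {
    stop(sprintf("unknown task '%s'; known: %s", task_id,
                 paste(names(model$tasks), collapse = ", ")))
  }
  n <- pre$n
  F <- pre$ctx %*% p$fusion$W_ctx
  if (h$use_onehot) F <- F + pre$onehot %*% p$fusion$W_onehot
  F <- sweep(F, 2, p$fusion$b, "+")
  # band projection via the low-frequency columns; local band by difference
  Ug <- pre$U[, seq_len(pre$k_G), drop = FALSE]
  di <- if (pre$k_D > pre$k_G) (pre$k_G + 1L):pre$k_D else integer(0)
  Ud <- pre$U[, di, drop = FALSE]
  F_G <- Ug %*% crossprod(Ug, F)
  F_D <- if (length(di)) Ud %*% crossprod(Ud, F) else matrix(0, n, h$d)
  F_L <- F - F_G - F_D
  bands <- list(G = F_G, D = F_D, L = F_L)
  temb <- p$task_emb[[task_id]]
  sc <- stats::setNames(SCALES, SCALES)
  Q <- lapply(sc, function(x) sweep(fc(pre$S, p$query[[x]]), 2, temb, "+"))
  K <- lapply(sc, function(x) fc(bands[[x]], p$key[[x]]))
  V <- lapply(sc, function(x) fc(F, p$value[[x]]))
  att <- lapply(sc, function(x) attend(Q[[x]], K[[x]], V[[x]]))
  z <- unlist(lapply(att, function(a) colMeans(a$aggr)), use.names = FALSE)
  pre1 <- drop(z %*% p$trunk$W) + p$trunk$b
  hvec <- pmax(pre1, 0)
  head <- p$heads[[task_id]]
  logits <- drop(hvec %*% head$W) + head$b
  scores <- 1 / (1 + exp(-logits))
  names(scores) <- model$tasks[[task_id]]$labels
  out <- list(scores = scores, attention = lapply(att, `[[`, "weights"))
  if (keep) {
    out$cache <- list(F = F, bands = bands, Ug = Ug, Ud = Ud, Q = Q, K = K,
                      V = V, att = att, z = z, pre1 = pre1, h = hvec,
                      logits = logits, task_id = task_id)
  }
  out
}

#' Forward pass: per-term prediction scores for one protein and task
#'
#' Deterministic given the parameters: fuses features, band-decomposes them
#' on the protein's spectral basis, runs scale-specific attention pooling,
#' and maps the concatenated multiscale representation through the shared
#' trunk and the task head to sigmoid scores in (0, 1).
#'
#' @param model A `specpool_model`.
#' @param pre A `protein_precomp` from [precompute_protein()].
#' @param task_id Task identifier.
#' @return Named numeric vector of scores in (0, 1), one per task label.
#' @export
model_forward <- function(model, pre, task_id) {
  model_forward_cache(model, pre, task_id)$scores
}

#' Multi-label cross-entropy loss
#'
#' `-sum_i [y_i log yhat_i + (1 - y_i) log(1 - yhat_i)]` over the task's
#' labels, with predictions clamped to `[eps, 1 - eps]` for numerical
#' safety. Non-negative, and zero (up to clamping) only at `yhat = y`.
#'
#' @param y Binary ground-truth vector.
#' @param yhat Predicted probability vector of the same length.
#' @param eps Clamping constant (default 1e-7).
#' @param weights Optional non-negative per-label weights (default: all 1,
#'   the plain unweighted loss used in training).
#' @return Non-negative scalar.
#' @export
multilabel_loss <- function(y, yhat, eps = 1e-7, weights = NULL) {
  if (length(y) != length(yhat)) {
    stop(sprintf("label length %d != prediction length %d",
                 length(y), length(yhat)))
  }
  if (is.null(weights)) weights <- rep(1, length(y))
  yhat <- pmin(pmax(yhat, eps), 1 - eps)
  -sum(weights * (y * log(yhat) + (1 - y) * log(1 - yhat)))
}

# Analytic gradients of the per-protein loss w.r.t. every parameter group.
# Returns a tree shaped like model$params (entries for other tasks zero).
model_backward <- function(model, pre, cache, y) {
  p <- model$params; h <- model$hyper
  ch <- cache$cache
  task_id <- ch$task_id
  s <- h$s; cw <- h$c
  yhat <- 1 / (1 + exp(-ch$logits))
  g <- zero_like(p)

  dlogits <- yhat - y                       # d loss / d logits (C)
  g$heads[[task_id]]$W <- outer(ch$h, dlogits)
  g$heads[[task_id]]$b <- dlogits
  dh <- drop(p$heads[[task_id]]$W %*% dlogits)
  dpre1 <- dh * (ch$pre1 > 0)
  g$trunk$W <- outer(ch$z, dpre1)
  g$trunk$b <- dpre1
  dz <- drop(p$trunk$W %*% dpre1)

  dF <- matrix(0, pre$n, h$d)
  dtemb <- numeric(cw)
  for (xi in seq_along(SCALES)) {
    x <- SCALES[xi]
    a <- ch$att[[x]]
    dm <- dz[((xi - 1L) * cw + 1L):(xi * cw)]
    dAggr <- matrix(dm / s, nrow = s, ncol = cw, byrow = TRUE)
    dWatt <- dAggr %*% t(ch$V[[x]])
    dV <- t(a$weights) %*% dAggr
    rs <- rowSums(a$weights * dWatt)
    dScore <- a$weights * (dWatt - rs)      # softmax backward, row-wise
    dQ <- dScore %*% ch$K[[x]] / sqrt(cw)
    dK <- t(dScore) %*% ch$Q[[x]] / sqrt(cw)

    g$query[[x]]$W <- crossprod(pre$S, dQ)
    g$query[[x]]$b <- colSums(dQ)
    dtemb <- dtemb + colSums(dQ)

    g$key[[x]]$W <- crossprod(ch$bands[[x]], dK)
    g$key[[x]]$b <- colSums(dK)
    dFx <- dK %*% t(p$key[[x]]$W)
    # band projector is symmetric: P_G, P_D from low columns, P_L = I-P_G-P_D
    pg <- ch$Ug %*% crossprod(ch$Ug, dFx)
    pd <- if (ncol(ch$Ud)) ch$Ud %*% crossprod(ch$Ud, dFx) else pg * 0
    dF <- dF + switch(x, G = pg, D = pd, L = dFx - pg - pd)

    g$value[[x]]$W <- crossprod(ch$F, dV)
    g$value[[x]]$b <- colSums(dV)
    dF <- dF + dV %*% t(p$value[[x]]$W)
  }
  g$task_emb[[task_id]] <- dtemb

  g$fusion$W_ctx <- crossprod(pre$ctx, dF)
  if (h$use_onehot) g$fusion$W_onehot <- crossprod(pre$onehot, dF)
  g$fusion$b <- colSums(dF)
  g
}

# --- parameter-tree utilities -----------------------------------------------

zero_like <- function(tree) {
  if (is.list(tree)) lapply(tree, zero_like) else tree * 0
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- mapply(tree_map2, a, b, MoreArgs = list(f = f), SIMPLIFY = FALSE)
    names(out) <- names(a)
    out
  } else f(a, b)
}

tree_sum <- function(tree) {
  if (is.list(tree)) sum(vapply(tree, tree_sum, numeric(1))) else sum(tree)
}

#' Number of trainable parameters
#'
#' @param model A `specpool_model` (or a bare parameter tree).
#' @return Integer count of scalar parameters.
#' @export
count_params <- function(model) {
  tree <- if (inherits(model, "specpool_model")) model$params else model
  cnt <- function(t) if (is.list(t)) sum(vapply(t, cnt, numeric(1))) else length(t)
  as.integer(cnt(tree))
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                   state$m, state$v)
  list(params = tree_map2(`-`, params, upd), state = state)
}

#' Train the multitask model
#'
#' First-order training with Adam. Tasks alternate round-robin: each step
#' draws the next task and a minibatch of proteins, averages the per-protein
#' loss gradients and updates all shared parameters plus the drawn task's
#' embedding and head. Fully seeded and reproducible: the same dataset,
#' configuration and seed give identical loss curves.
#'
#' @param model A `specpool_model`.
#' @param dataset Named list of `protein_precomp` objects.
#' @param labels List indexed by task id; each element a binary matrix with
#'   one row per protein (rownames = protein ids, columns = task labels).
#' @param epochs Passes over the training set per task (default 20).
#' @param batch_size Minibatch size (default 16).
#' @param lr Adam learning rate (default 1e-3).
#' @param seed Seed for minibatch shuffling.
#' @param validation Optional list with elements `dataset` and `truth`
#'   (propagated truth as returned by [propagate()]); when supplied,
#'   validation Fmax (mean over tasks) is tracked per epoch and the
#'   best-scoring parameters are restored at the end.
#' @param patience Early-stopping patience in epochs (only with validation).
#' @param verbose Print per-epoch loss.
#' @return The model with trained parameters and a `log` data frame
#'   (columns `step`, `epoch`, `task`, `loss`, and `val_fmax` per epoch
#'   when validation is used).
#' @export
train_model <- function(model, dataset, labels, epochs = 20L, batch_size = 16L,
                        lr = 1e-3, seed = 1L, validation = NULL,
                        patience = Inf, verbose = FALSE) {
  if (length(dataset) == 0L) stop("empty dataset")
  tasks <- names(model$tasks)
  for (t in tasks) {
    if (is.null(labels[[t]])) stop("no labels for task ", t)
    miss <- setdiff(names(dataset), rownames(labels[[t]]))
    if (length(miss)) stop("proteins without labels for task ", t, ": ",
                           paste(utils::head(miss, 3), collapse = ", "))
  }
  params <- model$params
  state <- list(m = zero_like(params), v = zero_like(params), t = 0L)
  log_rows <- list()
  step <- 0L
  best <- list(fmax = -Inf, params = params, epoch = 0L)
  rng <- rng_substream(seed, "train")
  ids <- names(dataset)
  with_rng(rng, {
    for (epoch in seq_len(epochs)) {
      order_by_task <- lapply(tasks, function(t) sample(ids))
      names(order_by_task) <- tasks
      n_steps <- ceiling(length(ids) / batch_size)
      for (b in seq_len(n_steps)) {
        for (t in tasks) {                       # round-robin over tasks
          take <- order_by_task[[t]][((b - 1L) * batch_size + 1L):
                                       min(b * batch_size, length(ids))]
          grads <- NULL
          loss <- 0
          model$params <- params
          for (id in take) {
            fwd <- model_forward_cache(model, dataset[[id]], t, keep = TRUE)
            y <- labels[[t]][id, ]
            loss <- loss + multilabel_loss(y, fwd$scores)
            g <- model_backward(model, dataset[[id]], fwd, y)
            grads <- if (is.null(grads)) g else tree_map2(`+`, grads, g)
          }
          grads <- rapply(grads, function(g) g / length(take), how = "replace")
          upd <- adam_step(params, grads, state, lr = lr)
          params <- upd$params; state <- upd$state
          step <- step + 1L
          log_rows[[step]] <- data.frame(step = step, epoch = epoch, task = t,
                                         loss = loss / length(take))
        }
      }
      if (!is.null(validation)) {
        model$params <- params
        vf <- mean(vapply(tasks, function(t) {
          sc <- predict_scores(model, validation$dataset, t)
          fmax(sc, validation$truth)$fmax
        }, numeric(1)))
        log_rows[[step]]$val_fmax <- vf
        if (vf > best$fmax) best <- list(fmax = vf, params = params, epoch = epoch)
        if (epoch - best$epoch >= patience) break
      }
      if (verbose) {
        ep_loss <- mean(vapply(log_rows[(step - n_steps * length(tasks) + 1L):step],
                               function(r) r$loss, numeric(1)))
        message(sprintf("epoch %d: mean loss %.4f", epoch, ep_loss))
      }
    }
  })
  model$params <- if (!is.null(validation) && is.finite(best$fmax)) best$params else params
  model$log <- do.call(rbind, lapply(log_rows, function(r) {
    if (is.null(r$val_fmax)) r$val_fmax <- NA_real_
    r
  }))
  model
}

#' Predict score matrix for a set of proteins under one task
#'
#' @param model A trained `specpool_model`.
#' @param dataset Named list of `protein_precomp` objects.
#' @param task_id Task identifier.
#' @return Numeric matrix (proteins x task labels) of scores in (0, 1).
#' @export
predict_scores <- function(model, dataset, task_id) {
  out <- t(vapply(dataset, function(pre) model_forward(model, pre, task_id),
                  numeric(model$tasks[[task_id]]$C)))
  rownames(out) <- names(dataset)
  colnames(out) <- model$tasks[[task_id]]$labels
  out
}

#' Write predictions as a long-format TSV
#'
#' One row per (protein, task, term) with the predicted score.
#'
#' @param scores_by_task Named list (by task id) of score matrices from
#'   [predict_scores()].
#' @param path Output TSV path.
#' @return Invisibly, the path.
#' @export
write_predictions <- function(scores_by_task, path) {
  rows <- do.call(rbind, lapply(names(scores_by_task), function(t) {
    S <- scores_by_task[[t]]
    data.frame(protein_id = rep(rownames(S), ncol(S)),
               task = t,
               term = rep(colnames(S), each = nrow(S)),
               score = as.vector(S))
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
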