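#' Ontology DAG from is_a edges
#'
#' Builds a validated directed acyclic graph of terms from child -> parent
#' `is_a` edges, with precomputed ancestor closures used for annotation
#' propagation (the true-path rule). Acyclicity and reachability are checked
#' at construction.
#'
#' @param edges Data frame with columns `child`, `parent` (term ids).
#' @param terms Optional character vector of additional isolated terms
#'   (roots without children).
#' @return An object of class `ontology_dag` with fields `terms`, `edges`,
#'   `roots` and `ancestors` (named list; each term's ancestor set includes
#'   the term itself).
#' @export
ontology_dag <- function(edges, terms = NULL) {
  edges <- data.frame(child = as.character(edges$child),
                      parent = as.character(edges$parent))
  all_terms <- sort(unique(c(edges$child, edges$parent, terms)))
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = all_terms)
  if (!igraph::is_dag(g)) stop("ontology edges contain a cycle")
  anc <- lapply(all_terms, function(t) {
    sort(names(igraph::subcomponent(g, t, mode = "out")))
  })
  names(anc) <- all_terms
  roots <- all_terms[!(all_terms %in% edges$child)]
  structure(list(terms = all_terms, edges = edges, roots = roots,
                 ancestors = anc),
            class = "ontology_dag")
}

#' Read an ontology from OBO or edge-list TSV
#'
#' OBO files are reduced to their `[Term]` blocks' `id:` and `is_a:` lines
#' (other relationship types are ignored); TSV files must carry `child` and
#' `parent` columns.
#'
#' @param path File path; format chosen by extension (`.obo` vs anything
#'   else, treated as TSV).
#' @return An [ontology_dag()].
#' @export
read_ontology <- function(path) {
  if (grepl("\\.obo$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    blocks <- split(lines, cumsum(lines == "[Term]"))
    blocks <- blocks[names(blocks) != "0"]
    rows <- list(); terms <- character(0)
    for (b in blocks) {
      id <- sub("^id: *", "", grep("^id:", b, value = TRUE)[1])
      terms <- c(terms, id)
      isa <- sub(" *!.*$", "", sub("^is_a: *", "", grep("^is_a:", b, value = TRUE)))
      if (length(isa)) rows[[length(rows) + 1L]] <-
          data.frame(child = id, parent = isa)
    }
    edges <- if (length(rows)) do.call(rbind, rows)
             else data.frame(child = character(0), parent = character(0))
    ontology_dag(edges, terms = terms)
  } else {
    edges <- utils::read.table(path, sep = "\t", header = TRUE,
                               colClasses = "character")
    ontology_dag(edges)
  }
}

#' Propagate annotations up the ontology (true-path rule)
#'
#' Closes each protein's term set under the ancestor relation, so an
#' annotation to a term implies annotation to all of its ancestors up to
#' the root. Idempotent on already-closed sets.
#'
#' @param annotations Named list: protein id -> character vector of terms.
#' @param dag An [ontology_dag()].
#' @return Named list of propagated (sorted, unique) term sets.
#' @export
propagate <- function(annotations, dag) {
  stopifnot(inherits(dag, "ontology_dag"))
  lapply(annotations, function(terms) {
    terms <- as.character(terms)
    unknown <- setdiff(terms, dag$terms)
    if (length(unknown)) {
      stop("unknown ontology term(s): ", paste(unknown, collapse = ", "))
    }
    if (length(terms) == 0L) return(character(0))
    sort(unique(unlist(dag$ancestors[terms], use.names = FALSE)))
  })
}

#' Per-term information content from a reference set
#'
#' `IC(t) = -log2` of the fraction of reference proteins annotated (after
#' propagation) with term `t`. Terms present in every reference protein get
#' IC 0; terms never seen get a finite ceiling `-log2(1/(N + 1))`, monotone
#' in the reference size `N`.
#'
#' @param reference Named list of propagated annotation sets (typically the
#'   training set).
#' @param dag An [ontology_dag()].
#' @return Named numeric vector of IC values for every DAG term.
#' @export
ic_table <- function(reference, dag) {
  stopifnot(inherits(dag, "ontology_dag"))
  N <- length(reference)
  if (N == 0L) stop("empty reference set")
  counts <- table(factor(unlist(reference, use.names = FALSE),
                         levels = dag$terms))
  ic <- ifelse(counts > 0, -log2(as.numeric(counts) / N), -log2(1 / (N + 1)))
  stats::setNames(pmax(ic, 0), dag$terms)
}

truth_matrix <- function(scores, truth) {
  if (is.null(rownames(scores)) || is.null(colnames(scores))) {
    stop("scores matrix needs protein rownames and term colnames")
  }
  T <- matrix(FALSE, nrow(scores), ncol(scores), dimnames = dimnames(scores))
  for (id in rownames(scores)) {
    tt <- intersect(truth[[id]], colnames(scores))
    T[id, tt] <- TRUE
  }
  T
}

#' Protein-centric maximum F-score
#'
#' Sweeps a score-threshold grid; at each threshold tau, precision is
#' averaged over proteins with at least one prediction `>= tau` and recall
#' over proteins with at least one true term (restricted to the evaluated
#' term universe, i.e. the score matrix columns). Fmax is the maximum
#' harmonic mean over the grid.
#'
#' @param scores Numeric matrix (proteins x terms), dimnames required.
#' @param truth Named list of propagated true term sets.
#' @param thresholds Threshold grid (default `seq(0.01, 1, 0.01)`).
#' @return List with `fmax` and `threshold` (the argmax tau).
#' @export
fmax <- function(scores, truth, thresholds = seq(0.01, 1, by = 0.01)) {
  T <- truth_matrix(scores, truth)
  n_true <- rowSums(T)
  with_truth <- n_true > 0
  if (!any(with_truth)) stop("no protein has a true term in the evaluated set")
  best <- c(f = 0, tau = thresholds[1])
  for (tau in thresholds) {
    P <- scores >= tau
    n_pred <- rowSums(P)
    tp <- rowSums(P & T)
    has_pred <- n_pred > 0
    if (!any(has_pred)) next
    prec <- mean(tp[has_pred] / n_pred[has_pred])
    rec <- mean(tp[with_truth] / n_true[with_truth])
    if (prec + rec > 0) {
      f <- 2 * prec * rec / (prec + rec)
      if (f > best["f"]) best <- c(f = f, tau = tau)
    }
  }
  list(fmax = unname(best["f"]), threshold = unname(best["tau"]))
}

#' Semantic-distance minimum (Smin)
#'
#' At each threshold, remaining uncertainty `ru` is the mean (over proteins)
#' total information content of true-but-unpredicted terms and
#' misinformation `mi` the mean IC of predicted-but-untrue terms; Smin is
#' the minimum Euclidean norm `sqrt(ru^2 + mi^2)` over the grid.
#'
#' @inheritParams fmax
#' @param ic Named IC vector from [ic_table()]; must cover every scored term.
#' @return List with `smin` and `threshold`.
#' @export
smin <- function(scores, truth, ic, thresholds = seq(0.01, 1, by = 0.01)) {
  T <- truth_matrix(scores, truth)
  missing_ic <- setdiff(colnames(scores), names(ic))
  if (length(missing_ic)) {
    stop("missing IC for term(s): ", paste(missing_ic, collapse = ", "))
  }
  w <- ic[colnames(scores)]
  best <- c(s = Inf, tau = thresholds[1])
  for (tau in thresholds) {
    P <- scores >= tau
    ru <- mean((T & !P) %*% w)
    mi <- mean((P & !T) %*% w)
    s <- sqrt(ru^2 + mi^2)
    if (s < best["s"]) best <- c(s = s, tau = tau)
  }
  list(smin = unname(best["s"]), threshold = unname(best["tau"]))
}

#' Micro-averaged area under the precision-recall curve
#'
#' All (protein, term) pairs are flattened into one binary classification
#' problem; the PR curve is traced over the distinct scores (ties grouped)
#' and integrated with the standard step-wise rule
#' `sum (R_k - R_{k-1}) * P_k`.
#'
#' @inheritParams fmax
#' @return List with `aupr` and the PR `curve` data frame
#'   (threshold, precision, recall).
#' @export
aupr <- function(scores, truth) {
  T <- truth_matrix(scores, truth)
  sc <- as.vector(scores)
  y <- as.vector(T)
  pos <- sum(y)
  if (pos == 0L) stop("no positive (protein, term) pairs")
  o <- order(sc, decreasing = TRUE)
  sc <- sc[o]; y <- y[o]
  tp <- cumsum(y); fp <- cumsum(!y)
  keep <- !duplicated(sc, fromLast = TRUE)   # one point per distinct score
  tp <- tp[keep]; fp <- fp[keep]
  prec <- tp / (tp + fp)
  rec <- tp / pos
  area <- sum(diff(c(0, rec)) * prec)
  list(aupr = area,
       curve = data.frame(threshold = sc[keep], precision = prec, recall = rec))
}

#' Full CAFA-style evaluation
#'
#' @inheritParams smin
#' @return An `eval_result` list: `fmax`, `fmax_threshold`, `smin`, `aupr`.
#' @export
evaluate_predictions <- function(scores, truth, ic,
                                 thresholds = seq(0.01, 1, by = 0.01)) {
  f <- fmax(scores, truth, thresholds)
  s <- smin(scores, truth, ic, thresholds)
  a <- aupr(scores, truth)
  structure(list(fmax = f$fmax, fmax_threshold = f$threshold,
                 smin = s$smin, aupr = a$aupr, pr_curve = a$curve),
            class = "eval_result")
}

#' Write evaluation results
#'
#' Writes the headline metrics as a single-row TSV and, optionally, the full
#' precision-recall curve alongside.
#'
#' @param result An `eval_result` from [evaluate_predictions()].
#' @param path Output TSV path for the metrics row.
#' @param curve_path Optional path for the PR-curve TSV.
#' @return Invisibly, `path`.
#' @export
write_eval_result <- function(result, path, curve_path = NULL) {
  utils::write.table(
    data.frame(fmax = result$fmax, fmax_threshold = result$fmax_threshold,
               smin = result$smin, aupr = result$aupr),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(curve_path)) {
    utils::write.table(result$pr_curve, curve_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read annotations from a long-format TSV
#'
#' Expects columns `protein_id`, `task`, `term` (a `score` column, if
#' present, is ignored here).
#'
#' @param path TSV path.
#' @param task Optional task id filter.
#' @return Named list: protein id -> character vector of terms.
#' @export
read_annotations <- function(path, task = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  if (!is.null(task)) df <- df[df$task == task, , drop = FALSE]
  split(df$term, df$protein_id)
}
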