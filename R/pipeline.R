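# Thin orchestration layer: each run_* function is one pipeline command,
# reads/writes the package's TSV formats, and writes a resolved-config
# snapshot so every run is reproducible from its output directory alone.

snapshot <- function(config, out_dir, command) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_config(config, file.path(out_dir, paste0(command, "-config.yaml")))
}

#' Generate a synthetic dataset (pipeline command)
#'
#' @param out_dir Output directory.
#' @param n_proteins,seed Passed to [synthetic_spec()].
#' @return Invisibly, the [generate_dataset()] result.
#' @export
run_synth <- function(out_dir, n_proteins = 300L, seed = 1L) {
  spec <- synthetic_spec(n_proteins = n_proteins, seed = seed)
  res <- generate_dataset(spec, out_dir)
  invisible(res)
}

#' Build and write a contact graph (pipeline command)
#'
#' @param pdb_path PDB file path.
#' @param out_path Output edge-list TSV.
#' @param chain Chain id (NULL = single chain).
#' @param config Configuration list (see [default_config()]).
#' @return Invisibly, the `contact_graph`.
#' @export
run_build_graph <- function(pdb_path, out_path, chain = NULL,
                            config = list()) {
  cfg <- validate_config(config)
  st <- parse_structure(pdb_path, chain = chain)
  g <- build_contact_graph(st, threshold = cfg$contact_threshold)
  write_contact_graph(g, out_path)
  invisible(g)
}

#' Spectral decomposition report for one protein (pipeline command)
#'
#' Builds the contact graph and Laplacian, eigendecomposes, and writes the
#' eigenvalue/band table. Returns (and logs) the three band sizes at the
#' configured `(p, q)`.
#'
#' @param pdb_path PDB file path.
#' @param out_dir Output directory.
#' @param chain Chain id (NULL = single chain).
#' @param config Configuration list.
#' @return Invisibly, a list with `band_sizes` and the `spectral_basis`.
#' @export
run_decompose <- function(pdb_path, out_dir, chain = NULL, config = list()) {
  cfg <- validate_config(config)
  snapshot(cfg, out_dir, "decompose")
  st <- parse_structure(pdb_path, chain = chain)
  g <- build_contact_graph(st, threshold = cfg$contact_threshold)
  basis <- eigendecompose(build_laplacian(g, kind = cfg$laplacian))
  write_spectrum(basis, file.path(out_dir, "spectrum.tsv"),
                 p = cfg$p, q = cfg$q)
  kb <- band_boundaries(st$n, cfg$p, cfg$q)
  sizes <- c(global = kb[1], domain = kb[2] - kb[1], local = st$n - kb[2])
  writeLines(c(sprintf("protein: %s (n = %d)", st$id, st$n),
               sprintf("band sizes (global, domain, local): (%d, %d, %d)",
                       sizes[1], sizes[2], sizes[3])),
             file.path(out_dir, "decompose.log"))
  invisible(list(band_sizes = sizes, basis = basis))
}

# Load a dataset directory produced by generate_dataset() (or matching its
# layout) into precomputed model inputs and propagated label matrices.
load_split <- function(data_dir, model, split = "train") {
  ids <- readLines(file.path(data_dir, paste0(split, ".txt")))
  pre <- lapply(ids, function(id) {
    st <- parse_structure(file.path(data_dir, "structures",
                                    paste0(id, ".pdb")), chain = "A", id = id)
    precompute_protein(st, model)
  })
  names(pre) <- ids
  pre
}

task_label_matrices <- function(ann_path, dag, tasks, ids) {
  labels <- list()
  for (tname in names(tasks)) {
    ann <- read_annotations(ann_path, task = tname)
    prop <- propagate(ann[ids], dag)
    M <- matrix(0, length(ids), tasks[[tname]]$C,
                dimnames = list(ids, tasks[[tname]]$labels))
    for (id in ids) {
      tt <- intersect(prop[[id]], colnames(M))
      M[id, tt] <- 1
    }
    labels[[tname]] <- M
  }
  labels
}

#' Train the multitask model on a dataset directory (pipeline command)
#'
#' Reads structures, annotations, ontology and splits from `data_dir`
#' (layout of [generate_dataset()]), derives each task's term universe from
#' the propagated annotations, trains with Adam, and writes the loss curve,
#' a resolved-config snapshot and a model checkpoint to `out_dir`.
#'
#' @param data_dir Dataset directory.
#' @param out_dir Output directory.
#' @param config Configuration list (see [default_config()]).
#' @param use_validation Track validation Fmax and keep the best epoch.
#' @return Invisibly, the trained `specpool_model`.
#' @export
run_train <- function(data_dir, out_dir, config = list(),
                      use_validation = TRUE) {
  cfg <- validate_config(config)
  snapshot(cfg, out_dir, "train")
  dag <- read_ontology(file.path(data_dir, "ontology.tsv"))
  ann_path <- file.path(data_dir, "annotations.tsv")
  ann_all <- utils::read.table(ann_path, sep = "\t", header = TRUE,
                               colClasses = "character")
  tasks <- lapply(split(ann_all$term, ann_all$task), function(terms) {
    sort(unique(unlist(dag$ancestors[unique(terms)], use.names = FALSE)))
  })
  tasks <- lapply(names(tasks), function(t) task_spec(t, tasks[[t]]))
  model <- init_model(tasks, d = cfg$d, c = cfg$c, s = cfg$s,
                      max_len = cfg$max_len, e = cfg$e, p = cfg$p, q = cfg$q,
                      use_onehot = cfg$use_onehot,
                      contact_threshold = cfg$contact_threshold,
                      laplacian = cfg$laplacian, seed = cfg$seed)
  train_pre <- load_split(data_dir, model, "train")
  labels <- task_label_matrices(ann_path, dag, model$tasks, names(train_pre))
  validation <- NULL
  if (use_validation && file.exists(file.path(data_dir, "val.txt"))) {
    val_pre <- load_split(data_dir, model, "val")
    val_ann <- read_annotations(ann_path)
    validation <- list(dataset = val_pre,
                       truth = propagate(val_ann[names(val_pre)], dag))
  }
  model <- train_model(model, train_pre, labels, epochs = cfg$epochs,
                       batch_size = cfg$batch_size, lr = cfg$lr,
                       seed = cfg$seed, validation = validation,
                       patience = cfg$patience)
  utils::write.table(model$log, file.path(out_dir, "loss.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  saveRDS(model, file.path(out_dir, "model.rds"))
  writeLines(sprintf("seed: %d; %d training proteins; tasks: %s",
                     cfg$seed, length(train_pre),
                     paste(names(model$tasks), collapse = ", ")),
             file.path(out_dir, "train.log"))
  invisible(model)
}

#' Predict scores for a dataset split (pipeline command)
#'
#' @param model A trained `specpool_model` or path to a saved checkpoint.
#' @param data_dir Dataset directory.
#' @param out_path Output predictions TSV.
#' @param split Split name (default "test").
#' @return Invisibly, the named list of score matrices by task.
#' @export
run_predict <- function(model, data_dir, out_path, split = "test") {
  if (is.character(model)) model <- readRDS(model)
  pre <- load_split(data_dir, model, split)
  scores <- lapply(names(model$tasks), function(t) predict_scores(model, pre, t))
  names(scores) <- names(model$tasks)
  write_predictions(scores, out_path)
  invisible(scores)
}

#' Evaluate predictions against annotations (pipeline command)
#'
#' Propagates truth over the ontology, computes IC from the training-split
#' reference, and writes per-task Fmax/Smin/AUPR.
#'
#' @param pred_path Predictions TSV from [run_predict()].
#' @param data_dir Dataset directory (annotations, ontology, splits).
#' @param out_path Output TSV (one row per task).
#' @param split Evaluated split (default "test").
#' @return Invisibly, a data frame of per-task metrics.
#' @export
run_evaluate <- function(pred_path, data_dir, out_path, split = "test") {
  dag <- read_ontology(file.path(data_dir, "ontology.tsv"))
  ids <- readLines(file.path(data_dir, paste0(split, ".txt")))
  train_ids <- readLines(file.path(data_dir, "train.txt"))
  ann <- read_annotations(file.path(data_dir, "annotations.tsv"))
  truth <- propagate(ann[ids], dag)
  ic <- ic_table(propagate(ann[train_ids], dag), dag)
  preds <- utils::read.table(pred_path, sep = "\t", header = TRUE,
                             colClasses = c("character", "character",
                                            "character", "numeric"))
  rows <- lapply(sort(unique(preds$task)), function(t) {
    sub <- preds[preds$task == t & preds$protein_id %in% ids, , drop = FALSE]
    terms <- sort(unique(sub$term))
    S <- matrix(0, length(ids), length(terms), dimnames = list(ids, terms))
    S[cbind(sub$protein_id, sub$term)] <- sub$score
    r <- evaluate_predictions(S, truth, ic)
    data.frame(task = t, fmax = r$fmax, fmax_threshold = r$fmax_threshold,
               smin = r$smin, aupr = r$aupr)
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, out_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(out)
}

#' Dump attention weights for one protein (pipeline command)
#'
#' @param model A trained `specpool_model` or checkpoint path.
#' @param pdb_path PDB file path.
#' @param task_id Task to condition the queries on.
#' @param out_path Output TSV.
#' @param chain Chain id.
#' @return Invisibly, the output path.
#' @export
run_attention_dump <- function(model, pdb_path, task_id, out_path,
                               chain = NULL) {
  if (is.character(model)) model <- readRDS(model)
  st <- parse_structure(pdb_path, chain = chain)
  pre <- precompute_protein(st, model)
  fwd <- model_forward_cache(model, pre, task_id)
  rows <- do.call(rbind, lapply(SCALES, function(x) {
    W <- fwd$attention[[x]]
    data.frame(protein = st$id,
               scale = c(G = "global", D = "domain", L = "local")[[x]],
               super_node = rep(seq_len(nrow(W)), ncol(W)),
               residue = rep(seq_len(ncol(W)), each = nrow(W)),
               weight = as.vector(W))
  }))
  utils::write.table(rows, out_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(out_path)
}
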