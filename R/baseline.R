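#' Mean-pooled one-hot logistic baseline
#'
#' A structure-blind reference predictor: each protein is reduced to its
#' mean one-hot vector (20-dimensional amino-acid composition) and one
#' ridge-regularized logistic regression is fitted per term. Terms that are
#' constant in the training labels are predicted at their training
#' prevalence.
#'
#' @param train_onehot List (or named list) of n x 20 one-hot matrices for
#'   training proteins.
#' @param train_labels Binary matrix (train proteins x terms).
#' @param test_onehot List of n x 20 one-hot matrices for test proteins.
#' @param lambda Ridge penalty (default 0.01).
#' @return Score matrix (test proteins x terms) in [0, 1].
#' @export
baseline_mean_onehot <- function(train_onehot, train_labels, test_onehot,
                                 lambda = 0.01) {
  X <- t(vapply(train_onehot, colMeans, numeric(20)))
  Xt <- t(vapply(test_onehot, colMeans, numeric(20)))
  out <- matrix(NA_real_, nrow(Xt), ncol(train_labels),
                dimnames = list(names(test_onehot), colnames(train_labels)))
  for (j in seq_len(ncol(train_labels))) {
    y <- train_labels[, j]
    if (length(unique(y)) < 2L) {
      out[, j] <- mean(y)
    } else {
      fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                            lambda = lambda)
      out[, j] <- drop(stats::predict(fit, Xt, type = "response"))
    }
  }
  out
}
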