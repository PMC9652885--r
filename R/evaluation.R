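#' Fisher score of a single feature
#'
#' Two-class separability filter
#' \eqn{(\mu_1-\mu_2)^2 / (\sigma_1^2+\sigma_2^2)} with unbiased class
#' variances.  Shift- and scale-invariant; 0 iff the class means coincide.
#' A zero pooled denominator yields score 0 with a warning.
#'
#' @param values Numeric vector (one value per subject).
#' @param labels Two-level factor/character vector aligned with `values`.
#' @return Nonnegative scalar.
#' @export
fisher_score <- function(values, labels) {
  g <- unique(labels)
  if (length(g) != 2) stop("exactly two classes required")
  a <- values[labels == g[1]]
  b <- values[labels == g[2]]
  den <- var(a) + var(b)
  if (!is.finite(den) || den == 0) {
    warning("zero pooled variance; Fisher score set to 0")
    return(0)
  }
  (mean(a) - mean(b))^2 / den
}

#' Leave-pair-out cross-validation folds
#'
#' One fold per (MCI, HC) subject pair: the pair is the test set, all other
#' subjects the training set.  `n_mci * n_hc` folds in MCI-major order, so
#' folds sharing an MCI test subject are contiguous (the 21 blocks used for
#' the block SD).
#'
#' @param n_mci,n_hc Class sizes (each >= 2, so training sets contain both
#'   classes).
#' @return Data frame with columns `mci` and `hc` (1-based within-class
#'   test indices).
#' @export
lpo_folds <- function(n_mci, n_hc) {
  if (n_mci < 2 || n_hc < 2)
    stop("each group needs >= 2 subjects (training set would be empty or ",
         "one-class)")
  data.frame(mci = rep(seq_len(n_mci), each = n_hc),
             hc = rep(seq_len(n_hc), times = n_mci))
}

#' Train a support-vector classifier
#'
#' C-SVC solved by deterministic sequential minimal optimization.
#' Linear kernel with unit box constraint by default; RBF available with
#' `gamma` defaulting to `1/ncol(x)`.
#'
#' @param x Numeric matrix, rows = samples.
#' @param y Labels; the first level (or `positive`) is coded +1.
#' @param kernel `"linear"` or `"rbf"`.
#' @param C Box constraint.
#' @param gamma RBF width (ignored for linear).
#' @param positive Label treated as the positive class.
#' @return An `svm_model`.
#' @export
svm_train <- function(x, y, kernel = c("linear", "rbf"), C = 1,
                      gamma = NULL, positive = NULL) {
  kernel <- match.arg(kernel)
  x <- as.matrix(x)
  positive <- positive %||% sort(unique(as.character(y)))[1]
  yy <- ifelse(as.character(y) == positive, 1, -1)
  if (length(unique(yy)) != 2) stop("both classes must be present")
  gamma <- gamma %||% (1 / ncol(x))
  K <- if (kernel == "linear") tcrossprod(x)
  else exp(-gamma * as.matrix(stats::dist(x))^2)
  fit <- .svm_smo_cpp(K, yy, C, 1e-3, 200)
  structure(list(x = x, y = yy, alpha = fit$alpha, b = fit$b,
                 kernel = kernel, gamma = gamma, C = C,
                 positive = positive),
            class = "svm_model")
}

#' Decision values / class predictions from an [svm_train()] model
#'
#' @param model An `svm_model`.
#' @param newx Matrix of new samples.
#' @param type `"class"` or `"decision"`.
#' @return Predicted labels (positive label vs `"other"`) or decision
#'   values.
#' @export
svm_predict <- function(model, newx, type = c("class", "decision")) {
  type <- match.arg(type)
  newx <- as.matrix(newx)
  K <- if (model$kernel == "linear") newx %*% t(model$x)
  else {
    d2 <- outer(rowSums(newx^2), rowSums(model$x^2), `+`) -
      2 * newx %*% t(model$x)
    exp(-model$gamma * pmax(d2, 0))
  }
  f <- drop(K %*% (model$alpha * model$y)) + model$b
  if (type == "decision") f
  else ifelse(f >= 0, model$positive, "other")
}

#' Leave-pair-out cross-validated evaluation of a feature (sub)table
#'
#' Per fold: z-scoring statistics fitted on the training rows and applied
#' to train and test; Fisher-score ranking of the normalized training
#' features (ties by column order); for each N in `1..max_features` an SVM
#' on the top-N features classifies the held-out MCI/HC pair.  Per-N
#' accuracy, sensitivity (MCI detection rate) and specificity (HC detection
#' rate) are averaged over all folds; the configuration's accuracy is the
#' best N-feature accuracy.  Because every fold holds out one subject per
#' class, accuracy is exactly `(sensitivity + specificity) / 2`.
#'
#' @param table A `feature_table` (or numeric matrix plus `labels`).
#' @param labels Optional label vector when `table` is a bare matrix.
#' @param max_features Maximum number of selected features (capped at the
#'   number of available features, with a warning).
#' @param kernel,C SVM settings, see [svm_train()].
#' @return A `cv_result`: list with `per_n` (data.frame of N, accuracy,
#'   sensitivity, specificity, all in percent), `best_n`, `accuracy`,
#'   `sensitivity`, `specificity`, `block_sd` (SD of per-MCI-block
#'   accuracies at the best N, percent), `fold_accuracy` (per-fold
#'   accuracies at the best N), `selection_counts` (how often each feature
#'   entered the top-best_n across folds), `n_folds`, `kernel`.
#' @export
evaluate_configuration <- function(table, labels = NULL, max_features = 15,
                                   kernel = c("linear", "rbf"), C = 1) {
  kernel <- match.arg(kernel)
  if (is.data.frame(table)) {
    labels <- labels %||% table$group
    X <- as.matrix(table[, setdiff(names(table), c("subject_id", "group")),
                         drop = FALSE])
  } else {
    X <- as.matrix(table)
    if (is.null(labels)) stop("labels required with a bare matrix")
  }
  if (any(!is.finite(X))) stop("feature table contains non-finite values")
  ypos <- as.integer(labels == "MCI")
  if (!all(labels %in% c("MCI", "HC"))) {
    lev <- sort(unique(as.character(labels)))
    ypos <- as.integer(labels == lev[1])
  }
  idx_pos <- which(ypos == 1)
  idx_neg <- which(ypos == 0)
  folds <- lpo_folds(length(idx_pos), length(idx_neg))
  if (max_features > ncol(X)) {
    warning("max_features reduced to the ", ncol(X), " available features")
    max_features <- ncol(X)
  }
  res <- .evaluate_cv_cpp(X, ypos, idx_pos[folds$mci], idx_neg[folds$hc],
                          as.integer(max_features),
                          if (kernel == "linear") 0L else 1L, C, 1e-3)
  sens <- colMeans(res$pos_correct) * 100
  spec <- colMeans(res$neg_correct) * 100
  acc <- (sens + spec) / 2
  best_n <- which.max(acc)
  fold_acc <- (res$pos_correct[, best_n] + res$neg_correct[, best_n]) / 2 * 100
  block <- folds$mci
  block_acc <- tapply(fold_acc, block, mean)
  sel <- res$selected[, seq_len(best_n), drop = FALSE]
  counts <- tabulate(sel, nbins = ncol(X))
  names(counts) <- colnames(X)
  structure(list(
    per_n = data.frame(n = seq_along(acc), accuracy = acc,
                       sensitivity = sens, specificity = spec),
    best_n = best_n, accuracy = acc[best_n], sensitivity = sens[best_n],
    specificity = spec[best_n],
    block_sd = if (length(block_acc) > 1) sd(block_acc) else NA_real_,
    fold_accuracy = as.numeric(fold_acc),
    selection_counts = counts, n_folds = nrow(folds), kernel = kernel),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "<cv_result> %d folds, %s kernel | best N = %d: accuracy %.2f%% (sens %.2f%%, spec %.2f%%, block SD %.2f)\n",
    x$n_folds, x$kernel, x$best_n, x$accuracy, x$sensitivity,
    x$specificity, x$block_sd))
  invisible(x)
}

#' Per-fold z-scoring statistics
#'
#' Mean and standard deviation per feature, estimated on training rows;
#' zero-variance features are flagged (they are zeroed out, not dropped, so
#' column indexing is preserved).
#'
#' @param x Training feature matrix.
#' @return List with `mean`, `sd`, `degenerate` (logical).
#' @export
normalization_stats <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, sd)
  list(mean = mu, sd = sdv, degenerate = sdv == 0)
}

#' Apply z-scoring statistics to a matrix
#'
#' @param x Matrix to normalize.
#' @param stats Output of [normalization_stats()].
#' @return Normalized matrix; degenerate features map to 0.
#' @export
apply_normalization <- function(x, stats) {
  z <- sweep(sweep(x, 2, stats$mean), 2, ifelse(stats$degenerate, 1, stats$sd),
             `/`)
  z[, stats$degenerate] <- 0
  z
}
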