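#' Exhaustive search over symmetric electrode configurations
#'
#' Enumerates every bilaterally symmetric configuration of `k` electrodes,
#' restricts the feature table to each, scores it by leave-pair-out
#' cross-validation, and ranks configurations by best accuracy (ties broken
#' by higher sensitivity, then enumeration order).
#'
#' @param k Configuration size (electrode count).
#' @param table Full-montage `feature_table`.
#' @param labels Optional labels (default: the table's `group` column).
#' @param montage An `eeg_montage`.
#' @param max_features,kernel,C Passed to [evaluate_configuration()].
#' @param keep_results `"best"` (default: keep the winner's full
#'   `cv_result`), `"all"`, or `"none"`.
#' @param verbose Progress messages every 50 configurations.
#' @return A `search_result`: list with `ranking` (data.frame sorted by
#'   accuracy), `configurations` (in ranking order), `best` (top
#'   configuration), `best_result` (its `cv_result`, if kept), `k`.
#' @export
search_optimal <- function(k, table, labels = NULL, montage = montage_32(),
                           max_features = 15, kernel = "linear", C = 1,
                           keep_results = c("best", "all", "none"),
                           verbose = FALSE) {
  keep_results <- match.arg(keep_results)
  configs <- enumerate_configurations(k, montage)
  n <- length(configs)
  rows <- vector("list", n)
  results <- if (keep_results == "all") vector("list", n) else NULL
  for (i in seq_len(n)) {
    cfg <- configs[[i]]
    sub <- restrict_features(table, cfg, montage)
    cv <- tryCatch(
      evaluate_configuration(sub, labels, max_features, kernel, C),
      error = function(e) stop("configuration ", format(cfg), ": ",
                               conditionMessage(e), call. = FALSE))
    rows[[i]] <- data.frame(
      configuration = format(cfg), n_pairs = length(cfg$pairs_used),
      n_midline = length(cfg$midline_used), accuracy = cv$accuracy,
      sensitivity = cv$sensitivity, specificity = cv$specificity,
      best_n = cv$best_n, block_sd = cv$block_sd)
    if (keep_results == "all") results[[i]] <- cv
    if (verbose && i %% 50 == 0) message("search k=", k, ": ", i, "/", n)
  }
  ranking <- do.call(rbind, rows)
  ord <- order(-ranking$accuracy, -ranking$sensitivity, seq_len(n))
  ranking <- ranking[ord, ]
  rownames(ranking) <- NULL
  best_cfg <- configs[[ord[1]]]
  best_result <- if (keep_results == "all") results[[ord[1]]]
  else if (keep_results == "best")
    evaluate_configuration(restrict_features(table, best_cfg, montage),
                           labels, max_features, kernel, C)
  else NULL
  structure(list(ranking = ranking, configurations = configs[ord],
                 results = if (keep_results == "all") results[ord],
                 best = best_cfg, best_result = best_result, k = k),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat("<search_result> k =", x$k, "|", nrow(x$ranking),
      "configurations\n")
  print(head(x$ranking, 5))
  invisible(x)
}

#' Evaluate the montages of commercial wearable EEG devices
#'
#' Each device's electrode subset is scored by the same
#' restrict-and-evaluate path used for the symmetric-configuration search.
#' Asymmetry features of a pair enter only when both members are present.
#'
#' @param table Full-montage `feature_table`.
#' @param labels Optional labels.
#' @param montage An `eeg_montage` (its `device_montages` are used).
#' @param devices Device names to evaluate (default all).
#' @param max_features,kernel,C Passed to [evaluate_configuration()].
#' @return List with `summary` (data.frame) and `results` (named list of
#'   `cv_result`).
#' @export
evaluate_devices <- function(table, labels = NULL, montage = montage_32(),
                             devices = names(montage$device_montages),
                             max_features = 15, kernel = "linear", C = 1) {
  results <- list()
  rows <- list()
  for (d in devices) {
    electrodes <- montage$device_montages[[d]]
    if (is.null(electrodes)) stop("unknown device: ", d)
    cv <- evaluate_configuration(restrict_features(table, electrodes,
                                                   montage),
                                 labels, max_features, kernel, C)
    results[[d]] <- cv
    rows[[d]] <- data.frame(device = d, n_electrodes = length(electrodes),
                            accuracy = cv$accuracy,
                            sensitivity = cv$sensitivity,
                            specificity = cv$specificity,
                            best_n = cv$best_n, block_sd = cv$block_sd)
  }
  list(summary = do.call(rbind, c(rows, make.row.names = FALSE)),
       results = results)
}
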