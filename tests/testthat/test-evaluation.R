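test_that("Fisher score matches its closed form", {
  lab <- rep(c("MCI", "HC"), each = 10)
  set.seed(1)
  same <- rnorm(20)
  expect_equal(fisher_score(rep(c(0, 1), 10)[order(lab)], lab[order(lab)]),
               fisher_score(rep(c(0, 1), 10)[order(lab)], lab[order(lab)]))
  # class means 0 and 1, unit variances -> 0.5
  a <- c(-1, 0, 1); b <- c(0, 1, 2)
  expect_equal(fisher_score(c(a, b), rep(c("MCI", "HC"), each = 3)), 0.5)
  # identical class distributions -> 0
  expect_equal(fisher_score(c(a, a), rep(c("MCI", "HC"), each = 3)), 0)
  # shift invariance
  set.seed(2)
  v <- rnorm(20)
  expect_equal(fisher_score(v + 100, lab), fisher_score(v, lab))
  expect_warning(s0 <- fisher_score(rep(1, 20), lab), "zero pooled")
  expect_identical(s0, 0)
})

test_that("LPO folds enumerate every MCI x HC pair", {
  f <- lpo_folds(21, 21)
  expect_identical(nrow(f), 441L)
  expect_identical(nrow(lpo_folds(3, 5)), 15L)
  expect_identical(anyDuplicated(f), 0L)
  # MCI-major contiguous blocks
  expect_identical(f$mci, rep(1:21, each = 21))
  expect_error(lpo_folds(1, 1), "2 subjects")
})

test_that("SMO solution matches the exact QP dual", {
  dual_obj <- function(alpha, X, y) {
    Q <- (y %*% t(y)) * tcrossprod(X)
    sum(alpha) - 0.5 * drop(t(alpha) %*% Q %*% alpha)
  }
  set.seed(3)
  for (rep in 1:5) {
    X <- rbind(matrix(rnorm(20, mean = 1.5), 10),
               matrix(rnorm(20, mean = -1.5), 10))
    y <- rep(c(1, -1), each = 10)
    qp <- svm_dual_qp(X, y, C = 1)
    m <- svm_train(X, ifelse(y == 1, "MCI", "HC"), positive = "MCI")
    # the dual objective value is unique at the optimum
    expect_equal(dual_obj(m$alpha, X, y), dual_obj(qp$alpha, X, y),
                 tolerance = 1e-3)
    expect_equal(m$alpha, qp$alpha, tolerance = 0.02)
    # with free support vectors the bias (hence the decision) is unique
    if (any(qp$alpha > 1e-5 & qp$alpha < 1 - 1e-5)) {
      grid <- matrix(rnorm(40), 20)
      expect_equal(svm_predict(m, grid, type = "decision"),
                   qp$decision(grid), tolerance = 0.05)
    }
  }
})

test_that("SVM handles the analytic two-point and XOR cases", {
  # two points at (+1,0)/(-1,0): max-margin decision is f(x) = x1
  m <- svm_train(rbind(c(1, 0), c(-1, 0)), c("A", "B"), positive = "A",
                 C = 10)
  expect_equal(svm_predict(m, rbind(c(1, 0), c(-1, 0), c(0.25, 7)),
                           type = "decision"),
               c(1, -1, 0.25), tolerance = 1e-6)
  xor_x <- rbind(c(1, 1), c(-1, -1), c(1, -1), c(-1, 1))
  m2 <- svm_train(xor_x, c("A", "A", "B", "B"), kernel = "rbf", C = 10,
                  gamma = 1, positive = "A")
  expect_identical(svm_predict(m2, xor_x), c("A", "A", "other", "other"))
})

test_that("per-fold z-scoring is exact and degenerate-safe", {
  set.seed(4)
  X <- matrix(rnorm(200), 20)
  X[, 3] <- 7                       # zero-variance feature
  st <- normalization_stats(X)
  expect_true(st$degenerate[3])
  Z <- apply_normalization(X, st)
  expect_lt(max(abs(colMeans(Z))), 1e-9)
  expect_lt(max(abs(apply(Z[, -3], 2, sd) - 1)), 1e-9)
  expect_true(all(Z[, 3] == 0))
})

test_that("CV engine agrees fold-by-fold with the R reference", {
  set.seed(5)
  n <- 12
  X <- matrix(rnorm(n * 10), n)
  X[1:6, 2] <- X[1:6, 2] + 1.5
  colnames(X) <- paste0("f", 1:10)
  labels <- rep(c("MCI", "HC"), each = 6)
  ref <- cv_reference(X, labels, max_n = 3)
  folds <- lpo_folds(6, 6)
  eng <- eegmontage:::.evaluate_cv_cpp(X, as.integer(labels == "MCI"),
                                       folds$mci, 6L + folds$hc,
                                       3L, 0L, 1, 1e-3)
  # where the SVM solution has free support vectors the decision value is
  # unique: engine and reference must agree there (and on the class calls
  # away from the numerical boundary)
  # both solvers stop at KKT tolerance 1e-3, so decisions agree to O(1e-3)
  cmp <- ref$has_free
  expect_gt(mean(cmp), 0.6)   # the oracle covers most cells
  expect_equal(eng$pos_decision[cmp], ref$dec_pos[cmp], tolerance = 0.01)
  expect_equal(eng$neg_decision[cmp], ref$dec_neg[cmp], tolerance = 0.01)
  clear_p <- cmp & abs(ref$dec_pos) > 0.02
  clear_n <- cmp & abs(ref$dec_neg) > 0.02
  expect_identical(eng$pos_correct[clear_p], ref$pos[clear_p])
  expect_identical(eng$neg_correct[clear_n], ref$neg[clear_n])
  # aggregation in evaluate_configuration mirrors the engine output
  cv <- evaluate_configuration(X, labels, max_features = 3)
  expect_equal(cv$per_n$sensitivity, colMeans(eng$pos_correct) * 100)
  expect_equal(cv$per_n$specificity, colMeans(eng$neg_correct) * 100)
})

test_that("evaluation satisfies its accuracy identities", {
  set.seed(6)
  n <- 16
  X <- matrix(rnorm(n * 30), n)
  labels <- rep(c("MCI", "HC"), each = 8)
  cv <- evaluate_configuration(X, labels, max_features = 10)
  expect_identical(cv$accuracy, (cv$sensitivity + cv$specificity) / 2)
  expect_identical(cv$per_n$accuracy,
                   (cv$per_n$sensitivity + cv$per_n$specificity) / 2)
  expect_true(all(cv$accuracy >= cv$per_n$accuracy))
  expect_identical(cv$n_folds, 64L)
  expect_true(all(cv$per_n$accuracy >= 0 & cv$per_n$accuracy <= 100))
  # a perfectly separating feature -> 100% at N = 1
  X2 <- X
  X2[, 1] <- rep(c(5, -5), each = 8) + rnorm(n, 0, 0.1)
  cv2 <- evaluate_configuration(X2, labels, max_features = 5)
  expect_identical(cv2$per_n$accuracy[1], 100)
  expect_identical(cv2$best_n, 1L)
  expect_warning(evaluate_configuration(X[, 1:4], labels, max_features = 15),
                 "reduced")
})

test_that("label permutation drives accuracy to chance", {
  set.seed(7)
  n <- 20
  X <- matrix(rnorm(n * 30), n)
  accs <- vapply(1:15, function(i) {
    evaluate_configuration(X[sample(n), ], rep(c("MCI", "HC"), each = 10),
                           max_features = 5)$per_n$accuracy[3]
  }, numeric(1))
  expect_gt(mean(accs), 35)
  expect_lt(mean(accs), 65)
})
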