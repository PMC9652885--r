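# Shared fixtures and independent oracles.  Expensive objects are built
# once per test run and cached in this environment.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

sine_wave <- function(f, fs, secs = 5, amp = 1, phase = 0)
  amp * sin(2 * pi * f * (0:(secs * fs - 1)) / fs + phase)

logistic_map <- function(n, x0 = 0.4) {
  x <- numeric(n)
  x[1] <- x0
  for (i in 2:n) x[i] <- 4 * x[i - 1] * (1 - x[i - 1])
  x
}

# tiny default-effect cohort reused across unit-test files
small_cohort <- function() cached("small_cohort", {
  simulate_cohort(cohort_spec(n_per_group = 2, epochs_per_subject = 4,
                              rng_seed = 42))
})

small_table <- function() cached("small_table",
                                 build_feature_table(small_cohort()$epoch_sets))

# --- independent oracles -------------------------------------------------

# brute-force count of symmetric configurations of size k: enumerate all
# subsets of the 18 atoms (14 pairs of size 2, 4 midline of size 1)
brute_force_config_count <- function(k) {
  sizes <- c(rep(2L, 14), rep(1L, 4))
  total <- if (k == 0) 1L else 0L
  for (j in seq_len(min(18, k))) {
    cmb <- utils::combn(18, j)
    total <- total + sum(colSums(matrix(sizes[cmb], nrow = j)) == k)
  }
  total
}

# independent LZ76 parser: grow each phrase while it is reproducible from
# the extended history (string search formulation)
lz76_reference <- function(bits) {
  s <- paste(bits, collapse = "")
  n <- nchar(s)
  c <- 0L
  i <- 1L
  while (i <= n) {
    l <- 1L
    while (i + l - 1L <= n &&
           grepl(substr(s, i, i + l - 1L), substr(s, 1, i + l - 2L),
                 fixed = TRUE))
      l <- l + 1L
    c <- c + 1L
    i <- i + l
  }
  c
}

# exact C-SVC dual solution (linear kernel) via quadratic programming
svm_dual_qp <- function(X, y, C = 1) {
  n <- nrow(X)
  K <- tcrossprod(X)
  D <- (y %*% t(y)) * K + diag(1e-9, n)
  A <- cbind(y, diag(n), -diag(n))
  b0 <- c(0, rep(0, n), rep(-C, n))
  sol <- quadprog::solve.QP(D, rep(1, n), A, b0, meq = 1)
  alpha <- pmin(C, pmax(0, sol$solution))
  f_raw <- drop(K %*% (alpha * y))
  sv <- which(alpha > 1e-5 & alpha < C - 1e-5)
  if (length(sv) > 0) {
    b <- mean(y[sv] - f_raw[sv])
  } else {
    # all multipliers at bounds: take the midpoint of the KKT-feasible
    # interval for the bias
    lo <- -Inf; hi <- Inf
    for (i in seq_len(n)) {
      if (alpha[i] < 1e-5) {               # y_i (f + b) >= 1
        if (y[i] > 0) lo <- max(lo, 1 - f_raw[i])
        else hi <- min(hi, -1 - f_raw[i])
      } else if (alpha[i] > C - 1e-5) {    # y_i (f + b) <= 1
        if (y[i] > 0) hi <- min(hi, 1 - f_raw[i])
        else lo <- max(lo, -1 - f_raw[i])
      }
    }
    b <- (lo + hi) / 2
  }
  list(alpha = alpha, b = b,
       decision = function(newx) drop(newx %*% t(X) %*% (alpha * y)) + b)
}

# reference R implementation of one leave-pair-out evaluation (z-scoring,
# Fisher ranking, N-sweep) used to cross-check the C++ CV engine
cv_reference <- function(X, labels, max_n) {
  pos <- which(labels == "MCI")
  neg <- which(labels == "HC")
  folds <- expand.grid(hc = seq_along(neg), mci = seq_along(pos))
  folds <- folds[order(folds$mci, folds$hc), ]
  out_pos <- matrix(0L, nrow(folds), max_n)
  out_neg <- matrix(0L, nrow(folds), max_n)
  dec_pos <- matrix(0, nrow(folds), max_n)
  dec_neg <- matrix(0, nrow(folds), max_n)
  # free support vectors => the bias, hence the decision value, is unique;
  # only those cells are comparable across solvers
  has_free <- matrix(FALSE, nrow(folds), max_n)
  for (f in seq_len(nrow(folds))) {
    ip <- pos[folds$mci[f]]
    iN <- neg[folds$hc[f]]
    tr <- setdiff(seq_len(nrow(X)), c(ip, iN))
    st <- normalization_stats(X[tr, , drop = FALSE])
    Z <- apply_normalization(X[tr, , drop = FALSE], st)
    zt <- apply_normalization(X[c(ip, iN), , drop = FALSE], st)
    sc <- vapply(seq_len(ncol(Z)), function(j)
      suppressWarnings(fisher_score(Z[, j], labels[tr])), numeric(1))
    ord <- order(-sc, seq_along(sc))
    for (N in seq_len(max_n)) {
      sel <- ord[seq_len(N)]
      m <- svm_train(Z[, sel, drop = FALSE], labels[tr], positive = "MCI")
      d <- svm_predict(m, zt[, sel, drop = FALSE], type = "decision")
      out_pos[f, N] <- as.integer(d[1] >= 0)
      out_neg[f, N] <- as.integer(d[2] < 0)
      dec_pos[f, N] <- d[1]
      dec_neg[f, N] <- d[2]
      has_free[f, N] <- any(m$alpha > 1e-6 & m$alpha < m$C - 1e-6)
    }
  }
  list(pos = out_pos, neg = out_neg, dec_pos = dec_pos, dec_neg = dec_neg,
       has_free = has_free)
}
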