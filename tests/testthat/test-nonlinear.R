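test_that("Shannon entropy hits its analytic bounds", {
  expect_identical(shannon_entropy(rep(3.7, 100)), 0)
  # exactly equal occupancy of all B bins -> ln B
  expect_equal(shannon_entropy(rep(1:64, each = 10), bins = 64), log(64))
  set.seed(1)
  for (i in 1:5)
    expect_lte(shannon_entropy(rnorm(1000), bins = 64), log(64))
  # uniform beats range-matched Gaussian at n = 5000, B = 64
  set.seed(2)
  u <- runif(5000, -3, 3)
  g <- rnorm(5000)
  expect_gt(shannon_entropy(u, 64), shannon_entropy(g, 64))
})

test_that("Hjorth parameters match their closed forms", {
  x <- rep(c(1, -1), 50)
  expect_equal(unname(hjorth(x)["activity"]), 1)
  fs <- 250
  for (f in c(5, 10, 25)) {
    h <- hjorth(sine_wave(f, fs, secs = 10))
    expect_equal(unname(h["mobility"]), 2 * sin(pi * f / fs),
                 tolerance = 1e-3, label = paste("mobility", f, "Hz"))
    expect_equal(unname(h["complexity"]), 1, tolerance = 1e-3)
  }
  expect_error(hjorth(rep(2, 10)), "zero-variance")
})

test_that("LZ76 complexity agrees with an independent parser", {
  # constant and alternating sequences, hand-checkable phrase counts
  expect_equal(lempel_ziv_complexity(rep(0L, 64)), 2 * log2(64) / 64)
  alt <- rep(c(0L, 1L), 32)
  expect_equal(lempel_ziv_complexity(alt), 3 * log2(64) / 64)
  expect_gt(lempel_ziv_complexity(alt), lempel_ziv_complexity(rep(0L, 64)))
  # dual route: C++ phrase count == reference R parser on random strings
  set.seed(3)
  for (n in c(32, 128, 517)) {
    bits <- as.integer(runif(n) > 0.5)
    expect_identical(eegmontage:::.lz76_cpp(bits),
                     lz76_reference(bits), label = paste("n =", n))
  }
  # i.i.d. bits approach normalized complexity 1
  set.seed(4)
  bits <- as.integer(runif(4096) > 0.5)
  expect_lt(abs(lempel_ziv_complexity(bits) - 1), 0.15)
})

test_that("Hurst estimator recovers known exponents", {
  set.seed(5)
  h_wn <- mean(vapply(1:10, function(s) {
    set.seed(s)
    hurst_exponent(rnorm(4096))
  }, numeric(1)))
  expect_lt(abs(h_wn - 0.5), 0.08)
  h_8 <- mean(vapply(1:10, function(s)
    hurst_exponent(fractional_gaussian_noise(4096, 0.8, seed = s)),
    numeric(1)))
  expect_lt(abs(h_8 - 0.8), 0.08)
  expect_error(hurst_exponent(rep(1, 4096)), "degenerate")
})

test_that("Lyapunov exponent separates chaos from periodicity", {
  expect_lt(abs(lyapunov_exponent(logistic_map(5000), fs = 1) - log(2)),
            0.05)
  # noise-free periodic orbit: per-sample divergence slope ~ 0
  fs <- 250
  set.seed(6)
  s <- sine_wave(10, fs) + rnorm(1250, 0, 1e-8)
  expect_lt(abs(lyapunov_exponent(s, fs)) / fs, 0.05)
  expect_error(lyapunov_exponent(rep(1, 1000), fs = 250), "constant")
})

test_that("PAC responds to phase-locked modulation and stays in [0,1]", {
  fs <- 250
  t <- (0:(5 * fs - 1)) / fs
  mk <- function(depth, seed) {
    set.seed(seed)
    ph <- runif(1, 0, 2 * pi)
    3 * sin(2 * pi * 6 * t + ph) +
      3 * (1 + depth * cos(2 * pi * 6 * t + ph)) / 2 *
        sin(2 * pi * 24 * t + runif(1, 0, 2 * pi)) +
      rnorm(length(t), 0, 1)
  }
  p1 <- vapply(1:20, function(s) phase_amplitude_coupling(mk(1, s), fs),
               numeric(1))
  p0 <- vapply(1:20, function(s) phase_amplitude_coupling(mk(0, s + 100), fs),
               numeric(1))
  expect_gt(mean(p1), 2 * mean(p0))        # wide margin
  expect_true(all(c(p1, p0) >= 0 & c(p1, p0) <= 1))
  # white noise sits near the few-segment coherence floor
  set.seed(7)
  wn <- vapply(1:10, function(i)
    phase_amplitude_coupling(rnorm(1250), fs), numeric(1))
  expect_lt(mean(wn), 0.3)
  expect_error(phase_amplitude_coupling(rep(0, 1250), fs), "degenerate")
})

test_that("feature families have the stated scale behaviour", {
  fs <- 250
  set.seed(8)
  x <- 5 * fractional_gaussian_noise(1250, 0.7) + sine_wave(10, fs, amp = 3)
  a <- 4.2
  expect_equal(shannon_entropy(a * x), shannon_entropy(x))
  expect_equal(lempel_ziv_complexity(a * x), lempel_ziv_complexity(x))
  expect_equal(hurst_exponent(a * x), hurst_exponent(x))
  h1 <- hjorth(x); h2 <- hjorth(a * x)
  expect_equal(h2[["mobility"]], h1[["mobility"]])
  expect_equal(h2[["complexity"]], h1[["complexity"]])
  expect_equal(h2[["activity"]], a^2 * h1[["activity"]])
  expect_equal(phase_amplitude_coupling(a * x, fs),
               phase_amplitude_coupling(x, fs))
  expect_equal(lyapunov_exponent(a * x, fs), lyapunov_exponent(x, fs))
})
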