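test_that("band-pass removes DC and passes in-band sinusoids untouched", {
  fs <- 1000
  params <- preprocess_params()
  # constant-offset channel -> ~0 after baseline + high-pass
  dc <- matrix(10, 1, 4 * fs)
  expect_lt(max(abs(preprocess_continuous(dc, fs, params))), 1e-6)
  # 10 Hz unit sine: amplitude within 1% (FFT amplitude ratio) and zero lag
  x <- sine_wave(10, fs, secs = 5)
  y <- drop(preprocess_continuous(matrix(x, 1), fs, params))
  amp <- function(v) 2 * Mod(fft(v))[10 * 5 + 1] / length(v)
  expect_lt(abs(amp(y) / amp(x) - 1), 0.01)
  cc <- ccf(x, y, lag.max = 20, plot = FALSE)
  expect_equal(as.numeric(cc$lag[which.max(cc$acf)]), 0)
})

test_that("out-of-band attenuation exceeds 20 dB at 60 Hz", {
  fs <- 1000
  filt <- butter_bandpass(0.5, 50, fs, order = 6)
  # forward-backward magnitude is |H|^2
  att_db <- 2 * 20 * log10(Mod(sos_freq_response(filt, 60)))
  expect_lt(att_db, -20)
  # and on an actual filtered sine
  x <- sine_wave(60, fs, secs = 5)
  y <- sos_filtfilt(filt, x)
  expect_lt(20 * log10(sd(y[1000:4000]) / sd(x[1000:4000])), -20)
})

test_that("zero-phase property holds across the passband", {
  fs <- 500
  filt <- butter_bandpass(0.5, 50, fs, order = 6)
  for (f in c(2, 10, 30, 45)) {
    x <- sine_wave(f, fs, secs = 4)
    y <- sos_filtfilt(filt, x)
    cc <- ccf(x[500:1500], y[500:1500], lag.max = 10, plot = FALSE)
    expect_equal(as.numeric(cc$lag[which.max(cc$acf)]), 0,
                 label = paste("lag at", f, "Hz"))
  }
})

test_that("preprocess_continuous validates its inputs", {
  expect_error(preprocess_continuous(matrix(c(1, NA), 1), 1000),
               "non-finite")
  expect_error(preprocess_continuous(matrix(rnorm(100), 1), 80),
               "too low")
})

test_that("epoch segmentation discards the remainder and reuses nothing", {
  fs <- 100
  rec <- matrix(rnorm(2 * 240 * fs), 2)
  ep <- segment_epochs(rec, fs, 5)
  expect_identical(dim(ep), c(48L, 2L, 500L))
  expect_identical(dim(segment_epochs(rec[, 1:1250, drop = FALSE], fs, 5))[1],
                   2L)
  expect_identical(dim(segment_epochs(rec[, 1:500, drop = FALSE], fs, 5))[1],
                   1L)
  expect_error(segment_epochs(rec[, 1:499, drop = FALSE], fs, 5), "shorter")
  # no sample reused, order preserved
  expect_identical(as.vector(ep[2, 1, ]), rec[1, 501:1000])
  expect_lte(dim(ep)[1] * 5 * fs, ncol(rec))
})

test_that("amplitude rejection enforces the 75 uV bound and is seeded", {
  params <- preprocess_params(epochs_per_subject = 20, rng_seed = 9)
  ep <- array(rnorm(30 * 2 * 100, sd = 5), c(30, 2, 100))
  ep[3, 1, 50] <- 80            # one 80 uV sample -> rejected
  ep[7, 2, 10] <- 74.9          # boundary, kept
  kept <- reject_and_subsample(ep, params, "s01")
  expect_identical(dim(kept)[1], 20L)
  expect_true(all(apply(abs(kept), 1, max) <= 75))
  expect_identical(kept, reject_and_subsample(ep, params, "s01"))
  # rejection is idempotent once the count matches the survivors
  p2 <- preprocess_params(epochs_per_subject = 20, rng_seed = 9)
  expect_identical(reject_and_subsample(kept, p2, "s01"),
                   reject_and_subsample(reject_and_subsample(kept, p2, "s01"),
                                        p2, "s01"))
  bad <- array(100, c(25, 2, 100))
  expect_error(reject_and_subsample(bad, params, "s07"),
               "insufficient clean epochs for s07")
})

test_that("full preprocessing chain yields a valid epoch_set", {
  fs <- 250
  raw <- matrix(rnorm(3 * 150 * fs, sd = 10), 3)
  es <- preprocess_subject(raw, fs, c("F3", "Fz", "F4"), "sub1", "MCI",
                           preprocess_params(epochs_per_subject = 10,
                                             rng_seed = 2))
  expect_s3_class(es, "epoch_set")
  expect_identical(dim(es$data), c(10L, 3L, 1250L))
  expect_identical(es$group, "MCI")
})

test_that("EDF round trip preserves data to quantization accuracy", {
  fs <- 128
  data <- matrix(rnorm(4 * 10 * fs, sd = 20), 4)
  rownames(data) <- c("F3", "F4", "C3", "C4")
  path <- tempfile(fileext = ".edf")
  write_edf(path, data, fs)
  rec <- read_edf(path)
  expect_identical(rec$labels, rownames(data))
  expect_equal(rec$fs, fs)
  q <- (max(data) - min(data)) / 65535
  expect_lt(max(abs(rec$data - data)), 2 * q)
  unlink(path)
})

test_that("epoch-set container round trip is exact", {
  es <- small_cohort()$epoch_sets[[1]]
  dir <- tempfile()
  sidecar <- write_epoch_set(es, dir)
  back <- read_epoch_set(file.path(dir, paste0(es$subject_id, ".json")))
  expect_identical(back$subject_id, es$subject_id)
  expect_identical(back$channel_labels, es$channel_labels)
  expect_equal(back$data, es$data)
  unlink(dir, recursive = TRUE)
})
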