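test_that("feature schema counts follow the 39/18 decomposition", {
  m <- montage_32()
  full <- feature_names(m$channels)
  expect_length(full, 1500)
  expect_identical(anyDuplicated(full), 0L)
  # 39 per channel = 9 APSD + 9 RPSD + 14 PAC + 3 Hjorth + SE + LE + HE + KC
  one <- feature_names("Cz")
  expect_length(one, 39)
  expect_length(grep("^PAC_", one), 14)
  # a lone pair adds 18 asymmetry columns
  expect_length(feature_names(c("F3", "F4")), 39 * 2 + 18)
  expect_true(all(c("RPSD_alphaH_F3", "PAC_theta-betaH_P8",
                    "HjorthMobility_Cz", "DASM_delta_FC5-FC6",
                    "RASM_gamma_O1-O2", "KC_Fp1", "LE_O1", "HE_C4")
                  %in% full))
})

test_that("feature table is complete, finite and deterministic", {
  tab <- small_table()
  expect_s3_class(tab, "feature_table")
  expect_identical(ncol(tab) - 2L, 1500L)
  expect_identical(nrow(tab), 4L)
  expect_false(anyNA(tab))
  expect_true(all(vapply(tab[, -(1:2)], is.finite, logical(nrow(tab)))))
  # identical epoch data -> identical rows
  es <- small_cohort()$epoch_sets[[1]]
  dup <- epoch_set("copy", es$group, es$data, es$fs, es$channel_labels)
  two <- build_feature_table(list(es, dup))
  expect_identical(unname(as.matrix(two[1, -(1:2)])),
                   unname(as.matrix(two[2, -(1:2)])))
})

test_that("scale covariance propagates to the table columns", {
  es <- small_cohort()$epoch_sets[[1]]
  scaled <- epoch_set(es$subject_id, es$group, 2 * es$data, es$fs,
                      es$channel_labels)
  t1 <- build_feature_table(list(es))
  t2 <- build_feature_table(list(scaled))
  cols <- names(t1)[-(1:2)]
  apsd <- grep("^(APSD|DASM|HjorthActivity)", cols, value = TRUE)
  invar <- grep("^(RPSD|RASM|PAC|SE_|HE_|KC_|HjorthMobility|HjorthComplexity|LE_)",
                cols, value = TRUE)
  expect_length(c(apsd, invar), length(cols))
  expect_equal(unlist(t2[, apsd]), 4 * unlist(t1[, apsd]), tolerance = 1e-8)
  expect_equal(unlist(t2[, invar]), unlist(t1[, invar]), tolerance = 1e-8)
})

test_that("restrict_features keeps exactly the configuration's columns", {
  tab <- small_table()
  expect_identical(ncol(restrict_features(tab,
                                          electrode_configuration("F3-F4")))
                   - 2L, 96L)
  mid <- restrict_features(tab, electrode_configuration(
    midline = c("Fz", "Cz")))
  expect_identical(ncol(mid) - 2L, 78L)
  expect_length(grep("^(DASM|RASM)", names(mid)), 0)
  expect_identical(ncol(restrict_features(tab, montage_32()$channels)) - 2L,
                   1500L)
  expect_error(restrict_features(tab, c("F3", "XX")), "unknown channel")
  # schema formula on random configurations
  set.seed(9)
  for (i in 1:50) {
    k <- sample(2:10, 1)
    cfgs <- enumerate_configurations(k)
    cfg <- cfgs[[sample(length(cfgs), 1)]]
    sub <- restrict_features(tab, cfg)
    expect_identical(ncol(sub) - 2L,
                     39L * length(cfg$electrodes) +
                       18L * length(cfg$pairs_used),
                     label = format(cfg))
  }
})

test_that("mismatched cohort layouts are rejected with the subject named", {
  sets <- small_cohort()$epoch_sets
  bad <- epoch_set("odd", "HC", sets[[1]]$data[, 1:10, , drop = FALSE],
                   sets[[1]]$fs, sets[[1]]$channel_labels[1:10])
  expect_error(build_feature_table(c(sets[1], list(bad))), "odd")
  renamed <- epoch_set("alien", "HC", sets[[1]]$data[, 1:2, , drop = FALSE],
                       sets[[1]]$fs, c("F3", "ZZ"))
  expect_error(build_feature_table(list(renamed)), "unknown channel")
})
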