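test_that("WS per-beat values are the stated adjacent-lead sums", {
  amps <- make_amps(r = list(V3 = 0.9), s = list(V2 = 1.2))
  expect_equal(unname(ws_per_beat(amps)[1, "V2-V3"]), 2.1)
  amps2 <- make_amps(r = list(V2 = 0.5, V3 = 0.9), s = list(V1 = 1.1, V2 = 0.9))
  expect_equal(unname(ws_per_beat(amps2)[1, ]), c(1.6, 1.8, 0, 0, 0))
  expect_equal(unname(ws_per_beat(make_amps())[1, ]), rep(0, 5))
  expect_equal(colnames(ws_per_beat(make_amps())),
               c("V1-V2", "V2-V3", "V3-V4", "V4-V5", "V5-V6"))
})

test_that("Sokolow-Lyon pairs S(V1) with R(V5) and R(V6)", {
  amps <- make_amps(r = list(V5 = 1.6, V6 = 1.2), s = list(V1 = 2.0))
  expect_equal(unname(sokolow_per_beat(amps)[1, ]), c(3.6, 3.2))
  expect_equal(unname(sokolow_per_beat(make_amps())[1, ]), c(0, 0))
  m <- mmcv(sokolow_per_beat(amps))
  expect_equal(m, 3.6)
  expect_true(classify_mmcv(m, "SOKOLOW_LYON", "male"))   # 3.6 >= 3.5
  expect_false(classify_mmcv(3.49, "SOKOLOW_LYON", "male"))
})

test_that("Cornell sums R(aVL) and S(V3) with sex-specific cutoffs", {
  amps <- make_amps(r = list(aVL = 1.0), s = list(V3 = 1.9))
  v <- cornell_per_beat(amps)[1, 1]
  expect_equal(v, 2.9)
  expect_true(classify_mmcv(v, "CORNELL", "male"))        # > 2.8
  expect_true(classify_mmcv(v, "CORNELL", "female"))      # > 2.0
  expect_warning(pos <- classify_mmcv(v, "CORNELL", "unknown"), "male")
  expect_true(pos)
  expect_equal(attr(pos, "threshold_mv"), 2.8)
  expect_false(classify_mmcv(0, "CORNELL", "male"))
})

test_that("Peguero adds the deepest S anywhere to S(V4), V4 allowed twice", {
  amps <- make_amps(s = list(V2 = 1.7, V4 = 1.0))
  expect_equal(peguero_per_beat(amps)[1, 1], 2.7)
  amps2 <- make_amps(s = list(V1 = 0.4, V4 = 1.5))
  expect_equal(peguero_per_beat(amps2)[1, 1], 3.0)
  expect_equal(peguero_per_beat(make_amps())[1, 1], 0)
})

test_that("MMCV is the max over combination medians", {
  m <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 3)
  expect_equal(mmcv(m), 5)
  expect_equal(mmcv(matrix(0.7)), 0.7)
  # permutation and duplication of beats leave MMCV unchanged
  expect_equal(mmcv(m[c(3, 1, 2), ]), mmcv(m))
  expect_equal(mmcv(rbind(m, m)), mmcv(m))
  # even beat counts average the middle two
  expect_equal(mmcv(matrix(c(1, 2, 3, 10), ncol = 1)), 2.5)
  expect_error(mmcv(matrix(numeric(0), 0, 2)), "at least one beat")
})

test_that("MMCV is monotone in every per-beat value", {
  set.seed(42)
  for (i in 1:50) {
    m <- matrix(stats::runif(12, 0, 3), 4, 3)
    m2 <- m
    idx <- sample(12, 1)
    m2[idx] <- m2[idx] + stats::runif(1, 0, 1)
    expect_gte(mmcv(m2), mmcv(m))
  }
})

test_that("WS classification is strict at the threshold", {
  expect_false(classify_mmcv(2.0, "WS", "male"))
  expect_true(classify_mmcv(2.01, "WS", "male"))
  expect_false(classify_mmcv(2.0, "WS", "female"))
})

test_that("sex-adjusted WS shifts the configured side by 10 mm", {
  cfg <- threshold_config(ws_sex_adjusted = TRUE)
  pos <- classify_mmcv(1.2, "WS", "female", cfg)
  expect_true(pos)
  expect_equal(attr(pos, "threshold_mv"), 1.0)
  expect_equal(attr(classify_mmcv(1.2, "WS", "male", cfg), "threshold_mv"), 2.0)
  cfg2 <- threshold_config(ws_sex_adjusted = TRUE,
                           ws_adjust_direction = "raise_male")
  expect_equal(attr(classify_mmcv(1.2, "WS", "male", cfg2), "threshold_mv"), 3.0)
  expect_equal(attr(classify_mmcv(1.2, "WS", "female", cfg2), "threshold_mv"), 2.0)
  # thresholds are stated in display mm and honor non-standard calibration
  cfg3 <- threshold_config(calibration_mm_per_mv = 20)
  expect_equal(attr(classify_mmcv(0.5, "WS", "male", cfg3), "threshold_mv"), 1.0)
  expect_error(threshold_config(ws_mm = -5), "positive")
})

test_that("the full chain calls an engineered overlap record positive", {
  # s(V2) + r(V3) about 2.5 mV; every other adjacent pair well under 2 mV
  m <- clean_morphology(
    r_amp_mv = c(I = 0.4, II = 0.5, III = 0.3, aVR = 0.1, aVL = 0.2, aVF = 0.4,
                 V1 = 0.2, V2 = 0.3, V3 = 1.3, V4 = 0.6, V5 = 0.7, V6 = 0.6),
    s_amp_mv = c(I = -0.1, II = -0.1, III = -0.1, aVR = -0.3, aVL = -0.1,
                 aVF = -0.1, V1 = -0.6, V2 = -1.2, V3 = -0.5, V4 = -0.3,
                 V5 = -0.2, V6 = -0.1))
  ge <- generate_ecg(m, duration_s = 10, seed = 10, sex = "male")
  calls <- evaluate_record(ge$record)
  ws <- calls$results$WS
  expect_true(ws$positive)
  expect_equal(ws$mmcv_mv, 2.5, tolerance = 0.05)
  expect_equal(names(which.max(ws$per_combination_median_mv)), "V2-V3")
  # halving every amplitude flips the call
  half <- ecg_record(ge$record$signals * 0.5, 500, sex = "male")
  expect_false(evaluate_record(half)$results$WS$positive)
})

test_that("internal consistency: positive iff MMCV exceeds its threshold", {
  ge <- generate_ecg(seed = 11, sex = "female")
  calls <- evaluate_record(ge$record)
  for (r in calls$results) {
    strict <- r$criterion_name %in% c("WS", "CORNELL")
    expected <- if (strict) r$mmcv_mv > r$threshold_mv
                else r$mmcv_mv >= r$threshold_mv
    expect_identical(r$positive, expected)
    expect_equal(r$mmcv_mv, max(r$per_combination_median_mv))
  }
})

test_that("records failing QC error unless overridden", {
  g1 <- generate_ecg(clean_morphology(heart_rate_bpm = 20), duration_s = 2.6,
                     seed = 12)
  expect_error(evaluate_record(g1$record), "TOO_FEW_BEATS")
  # unknown sex: the sex-specific criteria fall back to the male cutoff
  calls <- suppressWarnings(evaluate_record(g1$record, override_qc = TRUE))
  expect_s3_class(calls, "lvh_calls")
  expect_true("TOO_FEW_BEATS" %in% calls$qc)
})

test_that("calls flatten into a tidy table", {
  ge <- generate_ecg(seed = 13, sex = "male")
  df <- calls_table(evaluate_record(ge$record))
  expect_equal(nrow(df), 4)
  expect_setequal(df$criterion,
                  c("WS", "SOKOLOW_LYON", "CORNELL", "PEGUERO_LO_PRESTI"))
})
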