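test_that("mm/mV conversion is linear and round-trips at machine precision", {
  expect_identical(mm_to_mv(20, 10), 2)
  expect_identical(mm_to_mv(0, 10), 0)
  expect_identical(mm_to_mv(35, 10), 3.5)
  set.seed(9)
  x <- stats::rnorm(100, 0, 5)
  for (cal in c(5, 10, 20)) {
    expect_equal(mv_to_mm(mm_to_mv(x, cal), cal), x, tolerance = 1e-15)
  }
  expect_error(mm_to_mv(10, 0), "positive")
  expect_error(mv_to_mm(1, -2), "positive")
})

test_that("record construction validates leads, rates and finiteness", {
  sig <- matrix(0, 12, 500, dimnames = list(CANONICAL_LEADS, NULL))
  rec <- ecg_record(sig, 250)
  expect_s3_class(rec, "ecg_record")
  expect_equal(rec$duration_s, 2)
  # lowercase lead names normalize onto the canonical set
  sig2 <- sig
  rownames(sig2) <- tolower(CANONICAL_LEADS)
  expect_equal(ecg_record(sig2, 250)$leads, CANONICAL_LEADS)
  # a missing precordial lead is named in the error
  expect_error(ecg_record(sig[rownames(sig) != "V3", ], 250), "V3")
  expect_error(ecg_record(sig, 50), "100 Hz")
  sig3 <- sig
  sig3[4, 10] <- NA
  expect_error(ecg_record(sig3, 250), "non-finite")
})

test_that("CSV records round-trip and carry unknown columns", {
  ge <- generate_ecg(duration_s = 3, seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ecg_csv(ge$record, path)
  back <- read_ecg_csv(path, 500)
  expect_equal(back$signals[CANONICAL_LEADS, ],
               ge$record$signals[CANONICAL_LEADS, ], tolerance = 1e-9)
  # 2500 rows at 250 Hz -> 10 s
  sig <- matrix(stats::rnorm(12 * 2500), 2500, 12,
                dimnames = list(NULL, CANONICAL_LEADS))
  p2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(sig), p2, row.names = FALSE)
  expect_equal(read_ecg_csv(p2, 250)$duration_s, 10.0)
  # extra unknown column is kept but the criteria ignore it
  sig2 <- cbind(sig, X = 1.5)
  p3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(sig2), p3, row.names = FALSE)
  rec3 <- read_ecg_csv(p3, 250)
  expect_true("X" %in% rec3$leads)
  bs <- list(fiducial_samples = c(500L, 1000L))
  ws <- ws_per_beat(measure_amplitudes(rec3, bs))
  expect_equal(dim(ws), c(2, 5))
})

test_that("CSV parse errors are specific", {
  p <- withr::local_tempfile(fileext = ".csv")
  file.create(p)
  expect_error(read_ecg_csv(p, 250), "empty file")
  writeLines(c(paste(CANONICAL_LEADS, collapse = ","),
               paste(c("oops", rep("0", 11)), collapse = ",")), p)
  expect_error(read_ecg_csv(p, 250), "row 1.*'I'")
  expect_error(read_ecg_csv("/nonexistent/x.csv", 250), "no such file")
})

test_that("WFDB records round-trip within quantization tolerance", {
  ge <- generate_ecg(duration_s = 3, seed = 6)
  dir <- withr::local_tempdir()
  hea <- write_wfdb(ge$record, dir, gain = 1000)
  back <- read_wfdb(hea)
  expect_equal(back$sampling_rate_hz, 500)
  expect_equal(back$record_id, ge$record$record_id)
  expect_equal(ncol(back$signals), 1500)
  expect_lt(max(abs(back$signals[CANONICAL_LEADS, ] -
                      ge$record$signals[CANONICAL_LEADS, ])), 0.5 / 1000 + 1e-12)
  # bare record name (no .hea extension) also resolves
  back2 <- read_wfdb(file.path(dir, ge$record$record_id))
  expect_equal(back2$signals, back$signals)
  expect_error(read_wfdb(file.path(dir, "missing")), "no such file")
})

test_that("WFDB reader rejects records without the precordial set", {
  dir <- withr::local_tempdir()
  adc <- matrix(0L, 2, 100)
  writeBin(as.integer(adc), file.path(dir, "twolead.dat"), size = 2L,
           endian = "little")
  writeLines(c("twolead 2 500 100",
               "twolead.dat 16 1000/mV 16 0 0 0 0 I",
               "twolead.dat 16 1000/mV 16 0 0 0 0 II"),
             file.path(dir, "twolead.hea"))
  expect_error(read_wfdb(file.path(dir, "twolead.hea")), "V1")
})
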