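test_that("record construction validates fields and reproduces duration", {
  rec <- ecg_record(rep(0, 600), fs = 600)
  expect_equal(duration(rec), 1.0)
  expect_error(ecg_record(numeric(0), 600), "at least one")
  expect_error(ecg_record(c(0, NaN), 600), "finite")
  expect_error(ecg_record(0, fs = -1), "positive")
})

test_that("two-column files infer fs from the uniform time grid", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,voltage_mV",
               sprintf("%.8f,%.4f", (0:2) / 600, c(0.1, 0.2, 0.1))), f)
  rec <- read_record(f)
  expect_equal(rec$fs, 600)
  expect_length(rec$samples, 3)
})

test_that("single-column files need an explicit rate and honour it", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("voltage_mV", sprintf("%.4f", rep(0, 600))), f)
  rec <- read_record(f, fs_override = 600)
  expect_equal(duration(rec), 1.0)
  expect_error(read_record(f), "fs_override")
})

test_that("record write/read round-trips samples and metadata", {
  rec <- ecg_record(sin(1:50 / 5), fs = 600, t0 = 2.5, label = "rt")
  f <- withr::local_tempfile(fileext = ".csv")
  write_record(rec, f)
  back <- read_record(f)
  expect_equal(back$samples, rec$samples, tolerance = 1e-6)
  expect_equal(back$fs, rec$fs)
  expect_equal(back$t0, rec$t0)
  expect_equal(back$label, "rt")
  # byte-stable across runs
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_record(rec, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("format errors are raised, not patched over", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,voltage_mV", "0,0.1", "0.5,0.2", "0.6,0.1"), f)
  expect_error(read_record(f), "non-uniform")
  writeLines(character(0), f)
  expect_error(read_record(f), "empty")
  # declared fs conflicting with the time column beyond 0.1% is fatal
  writeLines(c("# fs=500", "time_s,voltage_mV",
               sprintf("%.8f,0.1", (0:9) / 600)), f)
  expect_error(read_record(f), "conflicts")
  expect_error(read_record(tempfile()), "no such file")
})

test_that("microvolt headers are converted to millivolts", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("voltage_uV", "1500", "-250"), f)
  rec <- read_record(f, fs_override = 600)
  expect_equal(rec$samples, c(1.5, -0.25))
})

test_that("annotation ordering is enforced at construction", {
  expect_error(beat_annotations(r_peak = 100, qrs_onset = 120), "ordering")
  expect_error(beat_annotations(r_peak = NA), "must be present")
  expect_error(beat_annotations(r_peak = 10, n_samples = 5), "bounds")
  ok <- beat_annotations(r_peak = c(100, 400), p_onset = c(60, 360),
                         qrs_onset = c(90, 390), t_end = c(180, 480))
  expect_equal(nrow(ok), 2)
  expect_s3_class(ok, "ecg_annotations")
})

test_that("annotations round-trip losslessly with absent fields as empties", {
  ann <- beat_annotations(r_peak = c(100, 400, 700),
                          p_onset = c(60, NA, 660),
                          p_peak = c(70, NA, 670),
                          p_end = c(80, NA, 680),
                          qrs_onset = c(90, 390, 690),
                          qrs_end = c(110, 410, 710),
                          t_end = c(200, NA, 800))
  f <- withr::local_tempfile(fileext = ".csv")
  write_annotations(ann, f)
  back <- read_annotations(f)
  expect_equal(as.data.frame(back), as.data.frame(ann))
  # a beat with only r_peak writes six empty fiducial fields
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_annotations(beat_annotations(r_peak = 100), f2)
  expect_match(readLines(f2)[2], "^0,,,,,100,,$")
  # empty list -> header-only file
  f3 <- withr::local_tempfile(fileext = ".csv")
  write_annotations(beat_annotations(integer(0)), f3)
  expect_length(readLines(f3), 1)
  expect_equal(nrow(read_annotations(f3)), 0)
})

test_that("malformed annotation rows report the row number", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("beat_index,p_onset,p_peak,p_end,qrs_onset,r_peak,qrs_end,t_end",
               "0,,,,90,100,110,200",
               "1,,,,x,400,410,500"), f)
  expect_error(read_annotations(f), "row 2")
})

test_that("crop_record preserves absolute time", {
  rec <- ecg_record(1:1200, fs = 600)
  cr <- crop_record(rec, 0.5, 1.5)
  expect_equal(cr$t0, 0.5)
  expect_equal(length(cr$samples), 600)
  expect_equal(cr$samples[1], rec$samples[301])
  expect_error(crop_record(rec, 5, 6), "empty")
})
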