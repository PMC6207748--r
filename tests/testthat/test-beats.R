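test_that("R-peak detection recovers every true beat on clean renders", {
  ren <- render_record(quiet_scenario(duration_s = 60, seed = 1))
  filt <- fir_bandpass(ren$record)
  det <- detect_r_peaks(filt, raw = ren$record)
  truth <- ren$truth$annotations$r_peak
  expect_equal(length(det), length(truth))
  expect_lte(max(abs(det - truth)), 2)
})

test_that("detected RR jitter on jitter-free rhythm stays under 2 samples SD", {
  sp <- quiet_scenario(duration_s = 60, seed = 1,
                       rhythm = rhythm_spec(hrv_sd_ms = 0))
  ren <- render_record(sp)
  det <- detect_r_peaks(fir_bandpass(ren$record), raw = ren$record)
  expect_lt(sd(diff(det)), 2)
})

test_that("flat input yields an empty detection, not an error", {
  flat <- ecg_record(rep(0, 3000), fs = 600)
  expect_identical(detect_r_peaks(flat), integer(0))
})

test_that("the refractory period suppresses close double detections", {
  fs <- 600
  x <- rep(0, 3000)
  spike <- exp(-((-30:30) / 4)^2)
  x[1500 + (-30:30)] <- spike            # two spikes 50 ms apart
  x[1530 + (-30:30)] <- x[1530 + (-30:30)] + 0.9 * spike
  det <- detect_r_peaks(ecg_record(x, fs))
  expect_equal(length(det), 1)
})

test_that("segmentation yields equal-length windows and drops clipped beats", {
  fs <- 600
  rec <- ecg_record(rnorm(6000), fs)
  cfg <- detector_config()          # 200 ms halfwidth
  r <- as.integer(seq(300, 5700, length.out = 10))
  w <- segment_beats(rec, r, cfg)
  expect_equal(dim(w), c(10, 2 * round(0.2 * fs) + 1))   # 241 samples
  # a beat 50 ms from the record start is excluded
  w2 <- segment_beats(rec, c(30L, r), cfg)
  expect_equal(nrow(w2), 10)
  expect_equal(attr(w2, "kept"), 2:11)
})

test_that("template averaging is the smoothed pointwise mean", {
  cfg <- detector_config(template_smooth_n = 9)
  beat <- exp(-((-120:120) / 12)^2)
  w <- rbind(beat, beat, beat)
  attr(w, "r_offset") <- 120L; attr(w, "fs") <- 600
  tmpl <- average_template(w, cfg)
  expect_equal(as.numeric(tmpl), moving_average(beat, 9), tolerance = 1e-12)
  # a single window is its own smoothed template
  w1 <- matrix(beat, nrow = 1)
  attr(w1, "r_offset") <- 120L; attr(w1, "fs") <- 600
  expect_equal(as.numeric(average_template(w1, cfg)), moving_average(beat, 9))
  expect_error(average_template(w[0, , drop = FALSE], cfg), "no beats")
})

test_that("averaging suppresses noise at the law-of-large-numbers rate", {
  cfg <- detector_config(template_smooth_n = 1)   # isolate the averaging
  beat <- exp(-((-120:120) / 12)^2)
  set.seed(42)
  rms_at <- sapply(c(10, 100, 1000), function(n) {
    w <- matrix(rep(beat, each = n) + rnorm(n * 241, 0, 0.2),
                nrow = n)
    attr(w, "r_offset") <- 120L; attr(w, "fs") <- 600
    sqrt(mean((as.numeric(average_template(w, cfg)) - beat)^2))
  })
  expect_true(all(diff(rms_at) < 0))
  # RMS error ~ 1/sqrt(n): two decades of n give about one decade of RMS
  expect_equal(rms_at[1] / rms_at[3], 10, tolerance = 0.5 * 10)
  expect_gt(rms_at[1] / rms_at[3], 4)
})

test_that("delineation of a clean averaged beat matches generator truth", {
  ren <- render_record(quiet_scenario(duration_s = 30, seed = 1))
  cfg <- detector_config()
  rp <- ren$truth$annotations$r_peak
  w <- segment_beats(ren$record, rp, cfg)
  half <- attr(w, "r_offset")
  tr <- ren$truth$annotations[3, ]
  truth_off <- c(tr$p_onset, tr$p_peak, tr$p_end, tr$qrs_onset, tr$qrs_end,
                 tr$t_end) - tr$r_peak
  keys <- c("p_onset", "p_peak", "p_end", "qrs_onset", "qrs_end", "t_end")
  # on the plain mean beat: all six fiducials within 3 ms of truth
  fid_plain <- delineate(colMeans(w), r_offset = half, fs = 600, cfg = cfg)
  expect_lte(max(abs(fid_plain[keys] - half - truth_off)) * 1000 / 600, 3)
  # through the MA-smoothed template the thresholds sit on widened flanks;
  # fiducials stay within 6 ms and the smoothing bias is outward
  fid_sm <- delineate(average_template(w, cfg), cfg = cfg)
  expect_lte(max(abs(fid_sm[keys] - half - truth_off)) * 1000 / 600, 6)
})

test_that("waves below the detectability floor are reported absent", {
  ren <- render_record(quiet_scenario(
    duration_s = 30, morphology = beat_morphology(p_amp = 0), seed = 1))
  cfg <- detector_config()
  w <- segment_beats(ren$record, ren$truth$annotations$r_peak, cfg)
  fid <- delineate(average_template(w, cfg), cfg = cfg)
  expect_true(all(is.na(fid[c("p_onset", "p_peak", "p_end")])))
  expect_false(anyNA(fid[c("qrs_onset", "qrs_end", "t_end")]))
  expect_error(delineate(average_template(w, cfg), r_offset = 9999,
                         fs = 600, cfg = cfg), "outside")
})

test_that("a symmetric wave gets symmetric bounds", {
  ren <- render_record(quiet_scenario(duration_s = 30, seed = 1))
  cfg <- detector_config()
  w <- segment_beats(ren$record, ren$truth$annotations$r_peak, cfg)
  fid <- delineate(colMeans(w), r_offset = attr(w, "r_offset"),
                   fs = 600, cfg = cfg)
  # the Gaussian P is symmetric: onset-to-peak equals peak-to-end within a sample
  expect_lte(abs((fid[["p_end"]] - fid[["p_peak"]]) -
                   (fid[["p_peak"]] - fid[["p_onset"]])), 1)
})

test_that("per-beat annotation matches truth on clean data", {
  ren <- render_record(quiet_scenario(duration_s = 60, seed = 2))
  fit <- ecg_analyze(ren$record)
  tr <- ren$truth$annotations
  kept <- attr(fit$annotations, "kept")
  expect_lte(max(abs(fit$annotations$r_peak - tr$r_peak[kept])), 1)
  for (col in c("p_onset", "qrs_onset", "qrs_end", "t_end")) {
    d <- fit$annotations[[col]] - tr[[col]][kept]
    expect_lte(max(abs(d), na.rm = TRUE), 2)   # within 2 samples
  }
  # beats whose windows clip the record edges are absent, all others kept
  half <- round(fit$detector$template_halfwidth_ms / 1000 * 600)
  n <- length(ren$record$samples)
  in_bounds <- which(fit$r_peaks - half >= 0 & fit$r_peaks + half <= n - 1)
  expect_equal(kept, in_bounds)
  # per-beat intervals match programmed truth within 2 samples
  res <- residuals(fit, truth = truth_for_fit(fit, ren$truth))
  expect_lt(max(abs(res$pr_ms), na.rm = TRUE), 2 * 1000 / 600 + 1e-9)
  expect_lt(max(abs(res$qt_ms), na.rm = TRUE), 2 * 1000 / 600 + 1e-9)
})

test_that("orphan P waves are located in dropped-QRS gaps", {
  sp <- scenario_spec("avb", duration_s = 60,
                      rhythm = rhythm_spec(dropped_qrs_prob = 0.25), seed = 5)
  ren <- render_record(sp)
  fit <- ecg_analyze(ren$record)
  n_true <- nrow(ren$truth$p_events)
  expect_gt(n_true, 3)
  expect_equal(nrow(fit$p_events), n_true, tolerance = 0.2 * n_true)
  # located near true P peaks
  d <- sapply(fit$p_events$p_peak, function(p)
    min(abs(ren$truth$p_events$p_peak - p)))
  expect_lt(median(d), 10)
})
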