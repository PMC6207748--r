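test_that("piecewise profiles evaluate hold and linear segments", {
  p <- pw_profile(c(0, 60, 120), c(155, 116, 88), interp = c("hold", "linear"))
  expect_equal(pw_eval(p, c(-5, 30, 59.9)), c(155, 155, 155))
  expect_equal(pw_eval(p, 90), 102)           # midway along the ramp
  expect_equal(pw_eval(p, c(120, 500)), c(88, 88))
  expect_error(pw_profile(c(0, 0), c(1, 2)), "strictly increasing")
  expect_equal(pw_eval(42, c(0, 10)), c(42, 42))  # scalar = constant
})

test_that("beat schedules honour the programmed rate", {
  # constant 60 bpm, no jitter: beats exactly 1 s apart
  r <- rhythm_spec(hr_bpm = 60, hrv_sd_ms = 0)
  s <- make_beat_schedule(r, 10, seed = 1)
  expect_equal(diff(s$t_s), rep(1, nrow(s) - 1))
  expect_equal(nrow(s), 10)
  # constant 148 bpm over 60 s: count within 1 of 148 * 60/60
  s2 <- make_beat_schedule(rhythm_spec(hr_bpm = 148, hrv_sd_ms = 0), 60, seed = 1)
  expect_lte(abs(nrow(s2) - 148), 1)
  expect_equal(unique(round(diff(s2$t_s), 6)), round(60 / 148, 6))
})

test_that("a step rhythm yields the closed-form RR on each side", {
  r <- rhythm_spec(hr_bpm = pw_profile(c(0, 30), c(155, 116)), hrv_sd_ms = 0)
  s <- make_beat_schedule(r, 60, seed = 1)
  rr <- s$rr_ms[-1]
  before <- rr[s$t_s[-1] < 30]
  after <- rr[s$t_s[-nrow(s)] >= 30]   # intervals started after the step
  expect_equal(mean(before), 60000 / 155, tolerance = 1e-6)
  expect_equal(mean(after), 60000 / 116, tolerance = 1e-6)
})

test_that("infeasible rhythms fail validation naming the offending time", {
  r <- rhythm_spec(hr_bpm = pw_profile(c(0, 20), c(100, 300)), qt_ms = 215)
  expect_error(make_beat_schedule(r, 60, seed = 1), "t = 2[0-9.]*")
  expect_error(make_beat_schedule(rhythm_spec(hr_bpm = 10), 10), "20, 400")
  expect_error(rhythm_spec(dropped_qrs_prob = 1), "0, 1")
})

test_that("rendering is a pure function of the scenario including seed", {
  sp <- scenario_spec("det", duration_s = 10, seed = 7)
  a <- render_record(sp)
  b <- render_record(sp)
  expect_identical(a$record$samples, b$record$samples)
  expect_identical(a$truth$annotations, b$truth$annotations)
  sp2 <- sp; sp2$seed <- 8L
  expect_false(identical(render_record(sp2)$record$samples, a$record$samples))
})

test_that("reversed polarity negates the whole trace exactly", {
  m <- beat_morphology(polarity = -1)
  sp_up <- scenario_spec("pol", duration_s = 10, seed = 3)
  sp_dn <- scenario_spec("pol", duration_s = 10, morphology = m, seed = 3)
  expect_equal(render_record(sp_dn)$record$samples,
               -render_record(sp_up)$record$samples)
})

test_that("zero-noise truth R peaks are the local maxima of the trace", {
  ren <- render_record(quiet_scenario(duration_s = 20, seed = 2))
  x <- ren$record$samples
  fs <- ren$record$fs
  w <- round(0.1 * fs)
  for (r in ren$truth$annotations$r_peak) {
    lo <- max(1, r + 1 - w); hi <- min(length(x), r + 1 + w)
    expect_equal(lo + which.max(x[lo:hi]) - 1, r + 1)
  }
})

test_that("truth fiducials reproduce the programmed intervals", {
  ren <- render_record(quiet_scenario(duration_s = 30, seed = 4))
  ann <- ren$truth$annotations
  ivl <- ren$truth$intervals
  fs <- ren$record$fs
  ok <- !is.na(ann$t_end) & !is.na(ann$p_onset)
  # within 1 sample of the schedule (index rounding)
  expect_lt(max(abs((ann$t_end - ann$qrs_onset)[ok] * 1000 / fs -
                      ivl$qt_ms[ok])), 1000 / fs)
  expect_lt(max(abs((ann$qrs_onset - ann$p_onset)[ok] * 1000 / fs -
                      ivl$pr_ms[ok])), 1000 / fs)
})

test_that("dropped beats render P-only events on the separate truth list", {
  sp <- scenario_spec("avb", duration_s = 60,
                      rhythm = rhythm_spec(dropped_qrs_prob = 0.3), seed = 5)
  ren <- render_record(sp)
  expect_gt(nrow(ren$truth$p_events), 5)
  # no annotation row for dropped beats; conducted + dropped = schedule
  expect_equal(nrow(ren$truth$annotations) + nrow(ren$truth$p_events),
               nrow(ren$truth$schedule))
  # a P-only event has no R wave nearby: trace at the expected R position
  # stays far below the R amplitude
  x <- ren$record$samples
  for (i in seq_len(min(5, nrow(ren$truth$p_events)))) {
    pk <- ren$truth$p_events$p_peak[i]
    reg <- x[(pk + 1):min(length(x), pk + 100)]
    expect_lt(max(reg), 0.5)
  }
})

test_that("morphology invariants are enforced", {
  expect_error(beat_morphology(r_amp = 0.2, t_amp = 0.25), "dominant")
  expect_error(beat_morphology(p_width_ms = 0), "widths")
  expect_error(beat_morphology(polarity = 2), "polarity")
})

test_that("presets carry the published scenario parameters", {
  expect_equal(pw_eval(ecg_preset("baseline_ab")$rhythm$hr_bpm, 0), 148)
  expect_equal(pw_eval(ecg_preset("baseline_ab")$rhythm$pr_ms, 0), 62)
  expect_equal(pw_eval(ecg_preset("baseline_ab")$rhythm$qrs_ms, 0), 44)
  expect_equal(pw_eval(ecg_preset("baseline_ab")$rhythm$qt_ms, 0), 215)
  expect_equal(pw_eval(ecg_preset("baseline_rr469")$rhythm$hr_bpm, 0),
               60000 / 469)
  expect_equal(pw_eval(ecg_preset("amiodarone_qt")$rhythm$qt_ms, 50), 481)
  expect_equal(pw_eval(ecg_preset("amiodarone_qt")$rhythm$qrs_ms, 50), 79)
  expect_equal(pw_eval(ecg_preset("quinidine_qt")$rhythm$qt_ms, c(30, 90)),
               c(200, 303))
  expect_equal(pw_eval(ecg_preset("veratridine_avblock")$rhythm$pr_ms,
                       c(30, 90)), c(58, 85))
  vera <- ecg_preset("verapamil_step")$rhythm$hr_bpm
  expect_equal(pw_eval(vera, c(30, 90, 400)), c(155, 116, 88))
  ms222 <- ecg_preset("ms222_ramp")$rhythm$hr_bpm
  expect_equal(pw_eval(ms222, c(30, 300, 600)), c(108, 89, 64))
  # isoproterenol dose ladder
  folds <- sapply(c(0.5, 1, 5, 7.5, 10), function(d)
    ecg_preset("isoproterenol_step", dose_uM = d)$fold)
  expect_equal(folds, c(1.04, 1.12, 1.14, 1.22, 1.25))
  iso <- ecg_preset("isoproterenol_step", dose_uM = 10)$rhythm$hr_bpm
  expect_equal(pw_eval(iso, 90) / pw_eval(iso, 30), 1.25)
  expect_error(ecg_preset("nonsense"), "available")
  expect_error(ecg_preset("isoproterenol_step", dose_uM = 2), "dose")
  expect_setequal(list_presets(),
                  c("baseline_ab", "baseline_rr469", "ms222_ramp",
                    "isoproterenol_step", "verapamil_step", "amiodarone_qt",
                    "quinidine_qt", "veratridine_avblock"))
})
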