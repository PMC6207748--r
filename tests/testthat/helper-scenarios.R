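# shared fixtures, built in code

quiet_scenario <- function(duration_s = 30, seed = 1, ...) {
  scenario_spec("quiet", duration_s = duration_s, noise = noise_none(),
                seed = seed, ...)
}

# sensitivity / positive predictivity of detected peaks vs truth indices
match_peaks <- function(detected, truth, tol_samples = 30) {
  used <- rep(FALSE, length(truth))
  tp <- 0L
  for (d in detected) {
    j <- which(!used & abs(truth - d) <= tol_samples)
    if (length(j) > 0) { used[j[1]] <- TRUE; tp <- tp + 1L }
  }
  c(sens = tp / max(1L, length(truth)), ppv = tp / max(1L, length(detected)))
}

# truth rows matching the beats retained by an analysis
truth_for_fit <- function(fit, truth) {
  kept <- attr(fit$annotations, "kept")
  truth$intervals[kept, c("rr_ms", "pr_ms", "qrs_ms", "qt_ms")]
}
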