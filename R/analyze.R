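#' Analyse an ECG record
#'
#' The package's main fitting function.  Runs the full measurement pipeline
#' on a single-lead record: automatic polarity correction, zero-phase FIR
#' band-pass, adaptive-threshold R-peak detection, beat segmentation,
#' template averaging, P/QRS/T delineation on the template, per-beat
#' fiducial refinement, interval measurement and Fridericia QT correction,
#' plus a scan for non-conducted P waves (atrioventricular block).
#'
#' The per-beat template window half-width is widened automatically for
#' slow rhythms (to roughly half the median RR, capped at 500 ms) so that a
#' prolonged QT still falls inside the window; set `auto_halfwidth = FALSE`
#' to use `detector$template_halfwidth_ms` verbatim.
#'
#' @param record an [ecg_record()].
#' @param filter a [filter_config()].
#' @param detector a [detector_config()].
#' @param window optional `c(start, end)` seconds; the record is cropped to
#'   this absolute-time window before analysis.
#' @param auto_halfwidth widen the template window from the detected rhythm.
#' @param bandpass set `FALSE` to skip the band-pass for already filtered
#'   input (detection then runs on the record as supplied).
#' @return an object of class `ecg_analysis` with components `record`
#'   (polarity-corrected), `flipped`, `filtered`, `r_peaks` (0-based),
#'   `template`, `template_fiducials`, `annotations`, `p_events`,
#'   `intervals`, `summary`, `filter`, `detector`.
#' @seealso [summary.ecg_analysis()], [coef.ecg_analysis()],
#'   [plot.ecg_analysis()]
#' @examples
#' ren <- render_record(ecg_preset("baseline_ab", duration_s = 30, seed = 1))
#' fit <- ecg_analyze(ren$record)
#' fit
#' coef(fit)
#' @export
ecg_analyze <- function(record, filter = filter_config(),
                        detector = detector_config(), window = NULL,
                        auto_halfwidth = TRUE, bandpass = TRUE) {
  stopifnot(inherits(record, "ecg_record"))
  if (!is.null(window)) record <- crop_record(record, window[1], window[2])

  flipped <- FALSE
  if (isTRUE(filter$polarity_auto)) {
    ap <- auto_polarity(record)
    record <- ap$record
    flipped <- ap$flipped
  }
  work <- record
  if (isTRUE(filter$notch_on)) work <- notch_filter(work, filter)
  filtered <- if (isTRUE(bandpass)) fir_bandpass(work, filter) else work

  r_peaks <- detect_r_peaks(filtered, detector, raw = record)

  if (auto_halfwidth && length(r_peaks) >= 3L) {
    med_rr_ms <- stats::median(diff(r_peaks)) / record$fs * 1000
    detector$template_halfwidth_ms <-
      min(500, max(detector$template_halfwidth_ms, 0.48 * med_rr_ms))
  }

  empty <- list(
    record = record, flipped = flipped, filtered = filtered,
    r_peaks = r_peaks, template = NULL, template_fiducials = NULL,
    annotations = beat_annotations(integer(0)),
    p_events = data.frame(p_peak = integer(0)),
    intervals = intervals_from_annotations(beat_annotations(integer(0)),
                                           record$fs, record$t0),
    summary = summarize_intervals(
      intervals_from_annotations(beat_annotations(integer(0)),
                                 record$fs, record$t0)),
    filter = filter, detector = detector
  )
  if (length(r_peaks) == 0L) return(structure(empty, class = "ecg_analysis"))

  baselined <- remove_baseline(record)
  windows <- segment_beats(baselined, r_peaks, detector)
  if (nrow(windows) == 0L) return(structure(empty, class = "ecg_analysis"))
  template <- average_template(windows, detector)
  fid <- delineate(template, cfg = detector)
  ann <- annotate_beats(record, r_peaks, fid, detector)
  ivl <- intervals_from_annotations(ann, record$fs, record$t0)
  p_ev <- find_p_events(record, ann, detector)

  structure(list(
    record = record, flipped = flipped, filtered = filtered,
    r_peaks = r_peaks, template = template, template_fiducials = fid,
    annotations = ann, p_events = p_ev, intervals = ivl,
    summary = summarize_intervals(ivl),
    filter = filter, detector = detector
  ), class = "ecg_analysis")
}

#' @export
print.ecg_analysis <- function(x, ...) {
  cat("<ecg_analysis>\n")
  cat(sprintf("  record: %d samples @ %g Hz (%.1f s)%s\n",
              length(x$record$samples), x$record$fs, duration(x$record),
              if (x$flipped) ", polarity flipped" else ""))
  cat(sprintf("  beats detected: %d; annotated: %d; orphan P events: %d\n",
              length(x$r_peaks), nrow(x$annotations), nrow(x$p_events)))
  s <- x$summary
  if (s$n_beats > 0) {
    cat(sprintf("  mean HR %.1f bpm; PR %.1f, QRS %.1f, QT %.1f, QTc %.1f ms\n",
                s$mean["hr_bpm"], s$mean["pr_ms"], s$mean["qrs_ms"],
                s$mean["qt_ms"], s$mean["qtc_ms"]))
  }
  invisible(x)
}

#' Summarise a fitted ECG analysis
#'
#' @param object an `ecg_analysis`.
#' @param window optional `c(start, end)` seconds restricting the summary.
#' @param ... unused.
#' @return an `ecg_summary` (see [summarize_intervals()]).
#' @export
summary.ecg_analysis <- function(object, window = NULL, ...) {
  summarize_intervals(object$intervals, window = window)
}

#' Mean interval measurements of a fitted analysis
#'
#' @param object an `ecg_analysis`.
#' @param ... unused.
#' @return named numeric vector of mean `hr_bpm`, `rr_ms`, `pr_ms`,
#'   `qrs_ms`, `qt_ms`, `qtc_ms`.
#' @export
coef.ecg_analysis <- function(object, ...) {
  s <- object$summary
  if (s$n_beats == 0) return(stats::setNames(rep(NA_real_, 6), .SUMMARY_METRICS))
  s$mean
}

#' Plot a fitted ECG analysis
#'
#' Trace with detected R peaks, or the averaged template with its
#' delineated fiducials.
#'
#' @param x an `ecg_analysis`.
#' @param what `"trace"` or `"template"`.
#' @param t_start,t_end optional trace window (s).
#' @param ... passed to the underlying plot.
#' @export
plot.ecg_analysis <- function(x, what = c("trace", "template"),
                              t_start = NULL, t_end = NULL, ...) {
  what <- match.arg(what)
  if (what == "template") {
    if (is.null(x$template)) stop("plot.ecg_analysis: no template (no beats)")
    plot(x$template, ...)
    fid <- x$template_fiducials
    fs <- attr(x$template, "fs")
    off <- (fid - attr(x$template, "r_offset")) / fs * 1000
    graphics::abline(v = off, lty = 3, col = "grey40")
    graphics::mtext(names(fid), at = off, side = 3, cex = 0.6, las = 2)
  } else {
    plot(x$record, t_start = t_start, t_end = t_end, ...)
    tt <- x$record$t0 + x$r_peaks / x$record$fs
    keep <- rep(TRUE, length(tt))
    if (!is.null(t_start)) keep <- keep & tt >= t_start
    if (!is.null(t_end)) keep <- keep & tt <= t_end
    graphics::points(tt[keep], x$record$samples[x$r_peaks[keep] + 1L],
                     col = "red", pch = 20)
  }
  invisible(x)
}

#' Per-beat interval residuals against a reference
#'
#' Differences between the fitted per-beat intervals and a reference table
#' (e.g. the simulator's ground truth), matched by beat order.
#'
#' @param object an `ecg_analysis`.
#' @param truth optional reference data.frame with `rr_ms`, `pr_ms`,
#'   `qrs_ms`, `qt_ms` columns; when `NULL`, residuals are taken about the
#'   per-recording means.
#' @param ... unused.
#' @return data.frame of per-beat deviations (ms).
#' @export
residuals.ecg_analysis <- function(object, truth = NULL, ...) {
  ivl <- object$intervals
  cols <- c("rr_ms", "pr_ms", "qrs_ms", "qt_ms")
  if (is.null(truth)) {
    as.data.frame(lapply(ivl[cols], function(v) v - mean(v, na.rm = TRUE)))
  } else {
    k <- min(nrow(ivl), nrow(truth))
    as.data.frame(stats::setNames(lapply(cols, function(cn) {
      ivl[[cn]][seq_len(k)] - truth[[cn]][seq_len(k)]
    }), cols))
  }
}
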