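# Interval measurement, heart rate, Fridericia-corrected QT and recording
# summaries.  Durations use the half-open convention:
# duration_ms = (end - onset) * 1000 / fs.

#' Interval table from beat annotations
#'
#' Per-beat RR (from successive R peaks; the first beat has none), heart
#' rate (`60000 / RR`), PR (`qrs_onset - p_onset`), QRS
#' (`qrs_end - qrs_onset`), QT (`t_end - qrs_onset`, i.e. onset of
#' ventricular depolarisation to end of repolarisation) and Fridericia QTc.
#' QTc uses each beat's own preceding RR and is present only where both QT
#' and RR are.
#'
#' @param beats an [beat_annotations()] table.
#' @param fs sampling rate (samples/s).
#' @param t0 record start time (s), used for the `time_s` column.
#' @return a `data.frame` of class `ecg_intervals` with columns
#'   `beat_index`, `time_s`, `rr_ms`, `hr_bpm`, `pr_ms`, `qrs_ms`, `qt_ms`,
#'   `qtc_ms`.
#' @export
intervals_from_annotations <- function(beats, fs, t0 = 0) {
  .validate_annotations(beats)
  ms <- function(a, b) (b - a) * 1000 / fs
  r <- beats$r_peak
  rr <- if (length(r) == 0L) numeric(0) else c(NA_real_, diff(r)) * 1000 / fs
  qt <- ms(beats$qrs_onset, beats$t_end)
  out <- data.frame(
    beat_index = seq_along(r) - 1L,
    time_s = t0 + r / fs,
    rr_ms = rr,
    hr_bpm = 60000 / rr,
    pr_ms = ms(beats$p_onset, beats$qrs_onset),
    qrs_ms = ms(beats$qrs_onset, beats$qrs_end),
    qt_ms = qt,
    qtc_ms = ifelse(is.na(qt) | is.na(rr), NA_real_,
                    qtc_fridericia(ifelse(is.na(qt), 1, qt),
                                   ifelse(is.na(rr), 1, rr)))
  )
  class(out) <- c("ecg_intervals", "data.frame")
  out
}

#' Fridericia heart-rate correction of the QT interval
#'
#' `QTc = QT / RR^(1/3)` with RR in seconds (the standard dimensional
#' convention, recommended for drug-safety work); both arguments and the
#' result are in milliseconds.  At RR = 1000 ms, QTc equals QT.
#'
#' @param qt_ms QT interval (ms), > 0.
#' @param rr_ms preceding RR interval (ms), > 0.
#' @return corrected QT in ms.
#' @examples
#' qtc_fridericia(480, 1000)  # 480
#' qtc_fridericia(300, 125)   # 600
#' @export
qtc_fridericia <- function(qt_ms, rr_ms) {
  if (any(qt_ms <= 0, na.rm = TRUE) || any(rr_ms <= 0, na.rm = TRUE)) {
    stop("qtc_fridericia: qt_ms and rr_ms must be > 0")
  }
  qt_ms / (rr_ms / 1000)^(1 / 3)
}

#' Bazett heart-rate correction of the QT interval
#'
#' `QTc = QT / sqrt(RR)` with RR in seconds.  Provided as a labelled
#' alternative; Fridericia is the package default.
#'
#' @inheritParams qtc_fridericia
#' @return corrected QT in ms.
#' @export
qtc_bazett <- function(qt_ms, rr_ms) {
  if (any(qt_ms <= 0, na.rm = TRUE) || any(rr_ms <= 0, na.rm = TRUE)) {
    stop("qtc_bazett: qt_ms and rr_ms must be > 0")
  }
  qt_ms / sqrt(rr_ms / 1000)
}

.SUMMARY_METRICS <- c("hr_bpm", "rr_ms", "pr_ms", "qrs_ms", "qt_ms", "qtc_ms")

#' Summarise an interval table
#'
#' Mean and sample standard deviation (n - 1) of each interval metric over
#' the beats inside an optional time window.  Dispersion is reported only
#' when at least two beats contribute.
#'
#' @param table an `ecg_intervals` table (see
#'   [intervals_from_annotations()]).
#' @param window optional `c(start, end)` in seconds (absolute time,
#'   compared against `time_s`); `NULL` keeps all beats.
#' @return an object of class `ecg_summary`: a list with `n_beats`, `mean`
#'   (named vector) and `sd` (named vector, `NULL` when `n_beats < 2`).
#' @export
summarize_intervals <- function(table, window = NULL) {
  tab <- table
  if (!is.null(window)) {
    tab <- tab[!is.na(tab$time_s) & tab$time_s >= window[1] &
                 tab$time_s < window[2], , drop = FALSE]
  }
  n <- nrow(tab)
  if (n == 0L) {
    return(structure(list(n_beats = 0L, mean = NULL, sd = NULL),
                     class = "ecg_summary"))
  }
  mu <- vapply(.SUMMARY_METRICS, function(m) mean(tab[[m]], na.rm = TRUE),
               numeric(1))
  sdv <- if (n >= 2L) {
    vapply(.SUMMARY_METRICS, function(m) stats::sd(tab[[m]], na.rm = TRUE),
           numeric(1))
  } else NULL
  structure(list(n_beats = n, mean = mu, sd = sdv), class = "ecg_summary")
}

#' @export
print.ecg_summary <- function(x, ...) {
  cat(sprintf("<ecg_summary> %d beats\n", x$n_beats))
  if (x$n_beats > 0) {
    df <- data.frame(mean = round(x$mean, 1))
    if (!is.null(x$sd)) df$sd <- round(x$sd, 1)
    print(df)
  }
  invisible(x)
}
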