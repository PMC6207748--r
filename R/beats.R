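# R-peak detection, beat segmentation, template averaging and P/QRS/T
# delineation.
#
# The detector is an adaptive-threshold peak picker on the smoothed squared
# derivative of the band-passed trace (Pan-Tompkins/Hamilton family), with a
# physiological refractory period and optional search-back for missed beats.
# Delineation runs on the averaged beat template; per-beat fiducials are then
# refined within a bounded window on the (detrended, lightly smoothed) raw
# beat so that the template's moving-average smoothing does not bias the
# measured intervals.

#' Detector configuration
#'
#' @param refractory_ms minimum R-R separation (ms).  150 ms corresponds to
#'   a maximum plausible zebrafish heart rate of ~250 bpm (RR 240 ms) and
#'   prevents T waves being counted as beats.
#' @param threshold_frac adaptive detection threshold as a fraction of the
#'   running signal-peak estimate, in (0, 1).
#' @param search_back re-scan long R-R gaps at half threshold for missed
#'   beats.
#' @param template_halfwidth_ms half-width of the per-beat window around the
#'   R peak (ms); must cover PR + QT.  [ecg_analyze()] widens it
#'   automatically for slow rhythms with long QT.
#' @param template_smooth_n moving-average window applied to each beat
#'   window before averaging (samples; around 10 at 600 samples/s, which
#'   nulls 60 Hz line residue exactly).
#' @param qrs_frac QRS onset/end threshold as a fraction of R amplitude.
#' @param p_frac,t_frac P and T bound thresholds as fractions of the wave
#'   amplitude.  Threshold fractions are used rather than tangent methods
#'   for robustness on low-amplitude zebrafish T waves.
#' @param wave_min_frac minimum wave amplitude (fraction of R) below which a
#'   P or T wave is reported absent rather than fabricated.
#' @param refine_ms bound on per-beat fiducial refinement (ms); a noisy beat
#'   cannot move a fiducial across waves.
#' @param line_hz AC-line frequency removed from measurement windows by
#'   least-squares projection onto a sinusoid (the beat waveform has
#'   negligible energy there, so the projection strips line pickup without
#'   phase distortion); `NA` disables.
#' @return an object of class `detector_config`.
#' @export
detector_config <- function(refractory_ms = 150, threshold_frac = 0.4,
                            search_back = TRUE,
                            template_halfwidth_ms = 200,
                            template_smooth_n = 10,
                            qrs_frac = 0.05, p_frac = 0.10, t_frac = 0.10,
                            wave_min_frac = 0.05, refine_ms = 10,
                            line_hz = 60) {
  if (refractory_ms <= 0) stop("detector_config: refractory_ms must be > 0")
  if (threshold_frac <= 0 || threshold_frac >= 1) {
    stop("detector_config: threshold_frac must be in (0, 1)")
  }
  structure(list(refractory_ms = refractory_ms,
                 threshold_frac = threshold_frac,
                 search_back = isTRUE(search_back),
                 template_halfwidth_ms = template_halfwidth_ms,
                 template_smooth_n = as.integer(template_smooth_n),
                 qrs_frac = qrs_frac, p_frac = p_frac, t_frac = t_frac,
                 wave_min_frac = wave_min_frac, refine_ms = refine_ms,
                 line_hz = line_hz),
            class = "detector_config")
}

#' Remove the slow baseline from a record
#'
#' Subtracts a running median (default window 0.33 s, longer than any ECG
#' wave but shorter than the baseline-wander period), the classic robust
#' baseline estimator: the median tracks the iso-electric line without
#' being pulled by the waves and is exactly zero on clean, wander-free
#' data.  Threshold-based delineation measures against this corrected
#' baseline.
#'
#' @param record an [ecg_record()].
#' @param window_s running-median window (s).
#' @return the baseline-corrected [ecg_record()].
#' @export
remove_baseline <- function(record, window_s = 0.33) {
  stopifnot(inherits(record, "ecg_record"))
  x <- record$samples
  k <- .odd(round(window_s * record$fs))
  base <- if (k >= length(x)) rep(stats::median(x), length(x)) else {
    as.numeric(stats::runmed(x, k, endrule = "median"))
  }
  ecg_record(x - base, record$fs, t0 = record$t0, label = record$label)
}

#' Detect R peaks
#'
#' Adaptive-threshold detection on the smoothed squared derivative of an
#' already band-passed record.  Detections are at least `refractory_ms`
#' apart and each index is refined to the local maximum of the
#' polarity-corrected raw trace (if supplied) within +/- 20 ms.  An empty
#' result is valid (e.g. a flat record).
#'
#' @param filtered a band-passed [ecg_record()] (see [fir_bandpass()]).
#' @param cfg a [detector_config()].
#' @param raw optional polarity-corrected raw record used for peak
#'   refinement; defaults to `filtered`.
#' @return integer vector of 0-based R-peak sample indices, strictly
#'   increasing.
#' @export
detect_r_peaks <- function(filtered, cfg = detector_config(), raw = NULL) {
  stopifnot(inherits(filtered, "ecg_record"))
  fs <- filtered$fs
  x <- filtered$samples
  n <- length(x)
  if (n < 3L) return(integer(0))
  d <- c(x[2] - x[1], diff(x)) * fs
  feat <- moving_average(d^2, max(3L, .odd(round(0.025 * fs))))

  cand <- which(diff(sign(diff(feat))) == -2) + 1L
  cand <- cand[feat[cand] > 0]
  if (length(cand) == 0L) return(integer(0))

  refr <- max(1L, round(cfg$refractory_ms / 1000 * fs))
  spk <- max(feat[seq_len(min(n, round(2 * fs)))])
  if (spk <= 0) spk <- max(feat)
  acc <- integer(0)
  for (i in cand) {
    if (feat[i] < cfg$threshold_frac * spk) next
    if (length(acc) > 0 && i - acc[length(acc)] < refr) {
      if (feat[i] > feat[acc[length(acc)]]) acc[length(acc)] <- i
      next
    }
    acc <- c(acc, i)
    spk <- 0.875 * spk + 0.125 * feat[i]
  }

  if (cfg$search_back && length(acc) >= 3L) {
    rr <- diff(acc)
    med <- stats::median(rr)
    back_thr <- 0.5 * cfg$threshold_frac * spk
    extra <- integer(0)
    for (g in which(rr > 1.66 * med)) {
      inside <- cand[cand > acc[g] + refr & cand < acc[g + 1] - refr]
      inside <- inside[feat[inside] >= back_thr]
      while (length(inside) > 0) {
        best <- inside[which.max(feat[inside])]
        extra <- c(extra, best)
        inside <- inside[abs(inside - best) >= refr]
      }
    }
    acc <- sort(c(acc, extra))
  }
  if (length(acc) == 0L) return(integer(0))

  # refine to the raw-trace local maximum
  y <- if (is.null(raw)) x else raw$samples
  w <- round(0.020 * fs)
  w <- as.integer(w)
  acc <- vapply(acc, function(i) {
    lo <- max(1L, i - w); hi <- min(n, i + w)
    lo + which.max(y[lo:hi]) - 1L
  }, integer(1))
  acc <- sort(unique(acc))
  # refractory after refinement: keep the taller of close pairs
  if (length(acc) > 1L) {
    keep <- rep(TRUE, length(acc))
    last <- 1L
    for (i in 2:length(acc)) {
      if (acc[i] - acc[last] < refr) {
        if (y[acc[i]] > y[acc[last]]) { keep[last] <- FALSE; last <- i }
        else keep[i] <- FALSE
      } else last <- i
    }
    acc <- acc[keep]
  }
  as.integer(acc - 1L)
}

.odd <- function(n) { n <- as.integer(n); if (n %% 2L == 0L) n + 1L else n }

#' Segment beats into fixed windows around each R peak
#'
#' Each window spans `r_peak +/- template_halfwidth_ms`; beats whose window
#' would be clipped at the record edges are discarded, so all returned
#' windows have equal length.
#'
#' @param record an [ecg_record()].
#' @param r_peaks 0-based R-peak indices.
#' @param cfg a [detector_config()].
#' @param detrend subtract each window's median (a robust per-beat baseline:
#'   most of a window is iso-electric, so the median tracks slow wander
#'   without being pulled by the waves, and is exactly zero on clean data).
#' @return a matrix with one row per retained beat, with attributes
#'   `r_offset` (0-based offset of the R peak within a window), `kept`
#'   (positions of the retained beats in `r_peaks`) and `fs`.
#' @export
segment_beats <- function(record, r_peaks, cfg = detector_config(),
                          detrend = FALSE) {
  stopifnot(inherits(record, "ecg_record"))
  fs <- record$fs
  n <- length(record$samples)
  half <- round(cfg$template_halfwidth_ms / 1000 * fs)
  keep <- which(r_peaks - half >= 0 & r_peaks + half <= n - 1)
  width <- 2L * half + 1L
  out <- matrix(numeric(0), nrow = 0, ncol = width)
  if (length(keep) > 0) {
    out <- t(vapply(r_peaks[keep], function(r) {
      record$samples[(r - half):(r + half) + 1L]
    }, numeric(width)))
    if (detrend) {
      out <- out - apply(out, 1L, stats::median)
    }
  }
  structure(out, r_offset = half, kept = keep, fs = fs)
}

#' Average beat windows into a reference template
#'
#' Each window is smoothed with a centred moving average of
#' `template_smooth_n` samples, then the smoothed windows are averaged
#' pointwise.  The result is the recording's reference wave used for
#' delineation.
#'
#' @param windows matrix from [segment_beats()].
#' @param cfg a [detector_config()].
#' @return numeric template of class `ecg_template` with attributes
#'   `r_offset` and `fs`.
#' @export
average_template <- function(windows, cfg = detector_config()) {
  if (is.null(dim(windows)) || nrow(windows) == 0L) {
    stop("average_template: no beats")
  }
  sm <- t(apply(windows, 1L, moving_average, n = cfg$template_smooth_n))
  structure(colMeans(sm),
            r_offset = attr(windows, "r_offset"),
            fs = attr(windows, "fs"),
            n_beats = nrow(windows),
            class = "ecg_template")
}

#' @export
print.ecg_template <- function(x, ...) {
  cat(sprintf("<ecg_template> %d samples, R at offset %d, averaged over %s beats\n",
              length(x), attr(x, "r_offset"),
              attr(x, "n_beats") %||% "?"))
  invisible(x)
}

#' @export
plot.ecg_template <- function(x, ...) {
  fs <- attr(x, "fs")
  off <- (seq_along(x) - 1 - attr(x, "r_offset")) / fs * 1000
  graphics::plot(off, as.numeric(x), type = "l",
                 xlab = "time from R peak (ms)", ylab = "voltage (mV)", ...)
  invisible(x)
}

# outward threshold-crossing search; returns 1-based index or NA.
# A point counts as a bound only if |a| stays below thr for `run` samples
# (or to the boundary), so a brief zero crossing inside the QRS does not
# terminate the search early.
.search_out <- function(a, start1, dir, thr, run = 3L) {
  L <- length(a)
  i <- start1 + dir
  while (i >= 1L && i <= L) {
    if (abs(a[i]) < thr) {
      j <- i + dir * seq_len(run - 1L)
      j <- j[j >= 1L & j <= L]
      if (all(abs(a[j]) < thr)) return(i)
    }
    i <- i + dir
  }
  NA_integer_
}

#' Delineate a beat template
#'
#' Locates the fiducial points on an averaged template: QRS onset/end where
#' the template magnitude falls below `qrs_frac` of the R amplitude moving
#' outward from R; the P peak as the maximum before the QRS (within 150 ms
#' of R), with P onset/end at `p_frac` of the P amplitude; and the T end
#' where the post-QRS deflection decays below `t_frac` of the T amplitude.
#' QT is therefore measured from the onset of ventricular depolarisation to
#' the end of repolarisation.  An undetectable wave (amplitude below
#' `wave_min_frac` of R) is reported absent (`NA`), never fabricated.
#'
#' @param template numeric template (e.g. from [average_template()]).
#' @param r_offset 0-based index of the R peak within the template.
#' @param fs sampling rate (samples/s).
#' @param cfg a [detector_config()].
#' @return named numeric vector of 0-based offsets within the template:
#'   `p_onset`, `p_peak`, `p_end`, `qrs_onset`, `qrs_end`, `t_end`, plus
#'   `t_peak` for reference; `NA` where absent.
#' @export
delineate <- function(template, r_offset = attr(template, "r_offset"),
                      fs = attr(template, "fs"), cfg = detector_config()) {
  a <- as.numeric(template)
  L <- length(a)
  if (is.null(r_offset) || r_offset < 0 || r_offset > L - 1) {
    stop("delineate: r_offset outside template")
  }
  r1 <- r_offset + 1L
  r_amp <- a[r1]
  if (!is.finite(r_amp) || r_amp <= 0) {
    stop("delineate: non-positive R amplitude; correct polarity first")
  }
  ms <- function(v) max(1L, round(v / 1000 * fs))

  qrs_on1 <- .search_out(a, r1, -1L, cfg$qrs_frac * r_amp)
  qrs_end1 <- .search_out(a, r1, +1L, cfg$qrs_frac * r_amp)

  p_on1 <- p_peak1 <- p_end1 <- NA_integer_
  if (!is.na(qrs_on1)) {
    lo <- max(1L, r1 - ms(150))
    hi <- qrs_on1 - ms(2)
    if (hi > lo) {
      p_peak1 <- lo + which.max(a[lo:hi]) - 1L
      p_amp <- a[p_peak1]
      if (p_amp >= cfg$wave_min_frac * r_amp) {
        p_on1 <- .search_out(a, p_peak1, -1L, cfg$p_frac * p_amp)
        p_end1 <- .search_out(a, p_peak1, +1L, cfg$p_frac * p_amp)
        if (!is.na(p_end1) && p_end1 > qrs_on1) p_end1 <- NA_integer_
      } else p_peak1 <- NA_integer_
    }
  }

  t_peak1 <- t_end1 <- NA_integer_
  if (!is.na(qrs_end1)) {
    lo <- min(L, qrs_end1 + ms(10))
    if (lo < L) {
      t_peak1 <- lo + which.max(a[lo:L]) - 1L
      t_amp <- a[t_peak1]
      if (t_amp >= cfg$wave_min_frac * r_amp && t_peak1 < L) {
        t_end1 <- .search_out(a, t_peak1, +1L, cfg$t_frac * t_amp)
      } else t_peak1 <- NA_integer_
    }
  }

  c(p_onset = p_on1 - 1L, p_peak = p_peak1 - 1L, p_end = p_end1 - 1L,
    qrs_onset = qrs_on1 - 1L, qrs_end = qrs_end1 - 1L, t_end = t_end1 - 1L,
    t_peak = t_peak1 - 1L)
}

# crossing of |v| with thr nearest the anchor, within +/- rw samples;
# returns 0-based offset, or the anchor when no crossing is found.
.refine_crossing <- function(v, anchor0, thr, rw) {
  if (is.na(anchor0)) return(NA_integer_)
  L <- length(v)
  lo <- max(1L, anchor0 + 1L - rw)
  hi <- min(L, anchor0 + 1L + rw)
  if (hi - lo < 1L) return(anchor0)
  g <- abs(v[lo:hi]) - thr
  s <- sign(g)
  cross <- which(s[-length(s)] * s[-1] < 0)
  if (length(cross) == 0L) return(anchor0)
  pos <- vapply(cross, function(i) {
    f <- g[i] / (g[i] - g[i + 1])
    (lo + i - 1L) + f - 1      # 0-based fractional position
  }, numeric(1))
  round(pos[which.min(abs(pos - anchor0))])
}

#' Annotate every beat from template fiducials
#'
#' Projects the reference fiducials onto each detected beat and refines each
#' per-beat fiducial to the local feature within `refine_ms`: peaks to the
#' local maximum, onsets/ends to the nearest threshold crossing on the
#' baseline-corrected, lightly smoothed beat.
#'
#' Two refinements make the per-beat measurements unbiased.  First, each
#' beat's baseline is referenced to its own iso-electric TP segment (the
#' quiet zone just before the P wave, located via the template fiducials) —
#' the standard clinical baseline reference — rather than to a global
#' filter, so slow wander cannot shift threshold crossings.  Second, the
#' anchor fiducials are re-delineated on the plain (unsmoothed) mean beat,
#' which removes the small outward bias that the template's moving-average
#' smoothing puts on threshold crossings.  Beats whose refined fiducials
#' would violate the physiological ordering fall back to the anchor
#' projection.
#'
#' @param record the polarity-corrected [ecg_record()].
#' @param r_peaks 0-based R-peak indices (see [detect_r_peaks()]).
#' @param template_fiducials output of [delineate()]; used to locate the
#'   quiet zone and as fallback anchors.
#' @param cfg a [detector_config()].
#' @return an [beat_annotations()] table (absolute 0-based indices) for the
#'   beats retained by segmentation, with attributes `kept` and
#'   `refined_offsets`.
#' @export
annotate_beats <- function(record, r_peaks, template_fiducials,
                           cfg = detector_config()) {
  stopifnot(inherits(record, "ecg_record"))
  fs <- record$fs
  w <- segment_beats(record, r_peaks, cfg)
  kept <- attr(w, "kept")
  half <- attr(w, "r_offset")
  if (nrow(w) == 0L) return(beat_annotations(integer(0)))
  L <- ncol(w)
  rw <- max(1L, round(cfg$refine_ms / 1000 * fs))
  fid0 <- template_fiducials

  # strip AC-line pickup from every measurement window (LS projection)
  lhz <- cfg$line_hz %||% NA
  if (!is.na(lhz) && lhz > 0 && fs > 2 * lhz) {
    tau <- (0:(L - 1)) / fs
    X <- cbind(sin(2 * pi * lhz * tau), cos(2 * pi * lhz * tau))
    w <- w - (w %*% X) %*% (solve(crossprod(X)) %*% t(X))
  }

  # quiet (TP) zone just before the P wave, or failing that well before the
  # QRS onset; per-beat baseline is the median of the raw beat over it
  ms <- function(v) max(1L, round(v / 1000 * fs))
  zone_hi <- if (!is.na(fid0[["p_peak"]])) fid0[["p_peak"]] - ms(25) else
    if (!is.na(fid0[["qrs_onset"]])) fid0[["qrs_onset"]] - ms(60) else
      half - ms(120)
  zone_lo <- zone_hi - ms(30)
  zone1 <- max(1L, zone_lo + 1L):max(1L, zone_hi + 1L)
  base_k <- apply(w[, zone1, drop = FALSE], 1L, stats::median)
  w <- w - base_k
  mean_beat <- colMeans(w)

  # unbiased anchors: delineate the plain mean beat
  fid <- delineate(mean_beat, r_offset = half, fs = fs, cfg = cfg)
  for (nm in names(fid)) if (is.na(fid[[nm]])) fid[[nm]] <- fid0[[nm]]

  # re-reference the T end to the local post-T baseline: on the shallow T
  # tail a 10% threshold is sensitive to the low-frequency noise residual
  # of the mean beat, so measure the crossing against the iso-electric
  # segment just after the T wave when the window reaches that far
  if (!is.na(fid[["t_end"]]) && !is.na(fid[["t_peak"]])) {
    zlo <- fid[["t_end"]] + ms(8)
    zhi <- min(L - 1L, fid[["t_end"]] + ms(45))
    if (zhi - zlo >= 8L) {
      post_base <- stats::median(mean_beat[(zlo:zhi) + 1L])
      t_amp_loc <- mean_beat[fid[["t_peak"]] + 1L] - post_base
      if (is.finite(t_amp_loc) && t_amp_loc > 0) {
        new_t <- .search_out(mean_beat - post_base, fid[["t_peak"]] + 1L,
                             +1L, cfg$t_frac * t_amp_loc)
        if (!is.na(new_t)) fid[["t_end"]] <- new_t - 1L
      }
    }
  }

  r_amp_m <- mean_beat[half + 1L]
  peak_refine <- function(v, anchor0) {
    if (is.na(anchor0)) return(NA_integer_)
    lo <- max(1L, anchor0 + 1L - rw); hi <- min(L, anchor0 + 1L + rw)
    lo + which.max(v[lo:hi]) - 2L    # 0-based
  }
  p_amp_m <- if (!is.na(fid[["p_peak"]])) mean_beat[fid[["p_peak"]] + 1L] else NA_real_
  t_amp_m <- if (!is.na(fid[["t_peak"]])) mean_beat[fid[["t_peak"]] + 1L] else NA_real_

  thr_of <- list(qrs_onset = cfg$qrs_frac * r_amp_m,
                 qrs_end = cfg$qrs_frac * r_amp_m,
                 p_onset = cfg$p_frac * p_amp_m,
                 p_end = cfg$p_frac * p_amp_m,
                 t_end = cfg$t_frac * t_amp_m)
  anchors <- c(p_onset = fid[["p_onset"]], p_peak = fid[["p_peak"]],
               p_end = fid[["p_end"]], qrs_onset = fid[["qrs_onset"]],
               qrs_end = fid[["qrs_end"]], t_end = fid[["t_end"]])

  nb <- nrow(w)
  cols <- c("p_onset", "p_peak", "p_end", "qrs_onset", "qrs_end", "t_end")
  out <- matrix(NA_integer_, nrow = nb, ncol = length(cols),
                dimnames = list(NULL, cols))
  for (b in seq_len(nb)) {
    v <- w[b, ]
    sm <- moving_average(v, 3L)
    scale_b <- v[half + 1L] / r_amp_m
    scale_b <- min(2, max(0.5, if (is.finite(scale_b)) scale_b else 1))
    row <- c(
      p_onset = .refine_crossing(sm, anchors[["p_onset"]],
                                 thr_of$p_onset * scale_b, rw),
      p_peak = peak_refine(v, anchors[["p_peak"]]),
      p_end = .refine_crossing(sm, anchors[["p_end"]],
                               thr_of$p_end * scale_b, rw),
      qrs_onset = .refine_crossing(sm, anchors[["qrs_onset"]],
                                   thr_of$qrs_onset * scale_b, rw),
      qrs_end = .refine_crossing(sm, anchors[["qrs_end"]],
                                 thr_of$qrs_end * scale_b, rw),
      t_end = .refine_crossing(sm, anchors[["t_end"]],
                               thr_of$t_end * scale_b, rw)
    )
    seqv <- c(row[["p_onset"]], row[["p_peak"]], row[["p_end"]],
              row[["qrs_onset"]], half, row[["qrs_end"]], row[["t_end"]])
    if (is.unsorted(seqv[!is.na(seqv)])) {
      row <- anchors[cols]
    }
    out[b, ] <- row
  }

  r_abs <- r_peaks[kept]
  shift <- function(col) ifelse(is.na(out[, col]), NA_integer_,
                                r_abs + (out[, col] - half))
  ann <- beat_annotations(
    r_peak = r_abs,
    p_onset = shift("p_onset"), p_peak = shift("p_peak"),
    p_end = shift("p_end"), qrs_onset = shift("qrs_onset"),
    qrs_end = shift("qrs_end"), t_end = shift("t_end"),
    n_samples = length(record$samples)
  )
  attr(ann, "kept") <- kept
  attr(ann, "refined_offsets") <- anchors
  ann
}

#' Locate non-conducted P waves in long R-R gaps
#'
#' In high-degree atrioventricular block, P waves occur without a following
#' QRS.  Gaps longer than 1.6x the median R-R are scanned at the expected
#' beat positions for a P-like deflection (at the beat-relative P-peak
#' latency, above half the typical P amplitude).
#'
#' @param record the polarity-corrected [ecg_record()].
#' @param annotations an [beat_annotations()] table with P fiducials.
#' @param cfg a [detector_config()].
#' @return data.frame with a `p_peak` column of 0-based indices (possibly
#'   empty).
#' @export
find_p_events <- function(record, annotations, cfg = detector_config()) {
  empty <- data.frame(p_peak = integer(0))
  r <- annotations$r_peak
  if (length(r) < 3L) return(empty)
  fs <- record$fs
  x <- record$samples
  n <- length(x)
  local_base <- function(i1) {
    lo <- max(1L, i1 - round(0.1 * fs)); hi <- min(n, i1 + round(0.1 * fs))
    stats::median(x[lo:hi])
  }
  has_p <- !is.na(annotations$p_peak)
  if (!any(has_p)) return(empty)
  p_lat <- stats::median(annotations$p_peak[has_p] - r[has_p])
  p_amp <- stats::median(vapply(which(has_p), function(i) {
    i1 <- annotations$p_peak[i] + 1L
    x[i1] - local_base(i1)
  }, numeric(1)))
  if (!is.finite(p_amp) || p_amp <= 0) return(empty)

  rr <- diff(r)
  med <- stats::median(rr)
  sw <- round(0.03 * fs)
  hits <- integer(0)
  for (g in which(rr > 1.6 * med)) {
    k <- max(1L, round(rr[g] / med) - 1L)
    for (j in seq_len(k)) {
      r_exp <- r[g] + round(j * rr[g] / (k + 1))
      c0 <- r_exp + p_lat
      lo <- max(1L, c0 + 1L - sw); hi <- min(n, c0 + 1L + sw)
      if (hi <= lo) next
      i1 <- lo + which.max(x[lo:hi]) - 1L
      if (x[i1] - local_base(i1) > 0.5 * p_amp) hits <- c(hits, i1 - 1L)
    }
  }
  data.frame(p_peak = as.integer(hits))
}
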