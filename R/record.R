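#' Construct an ECG record
#'
#' An `ecg_record` is a uniformly sampled single-lead voltage trace.  Voltage
#' is held in millivolts internally; sample indices used throughout the
#' package (annotations, detected peaks) are 0-based, so sample `i` occurs at
#' time `t0 + i / fs` seconds.
#'
#' @param samples numeric vector of voltages in millivolts; all finite,
#'   length >= 1.
#' @param fs sampling rate in samples per second (> 0).  Zebrafish recordings
#'   from the kit this package targets run at 600 samples/s.
#' @param t0 start time of the first sample in seconds (default 0).
#' @param label free-text identifier.
#' @return an object of class `ecg_record`.
#' @examples
#' rec <- ecg_record(sin(2 * pi * 5 * (0:599) / 600), fs = 600)
#' duration(rec)
#' @export
ecg_record <- function(samples, fs, t0 = 0, label = "") {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("ecg_record: need at least one sample")
  if (!all(is.finite(samples))) stop("ecg_record: all samples must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("ecg_record: fs must be a single positive number")
  }
  structure(
    list(samples = samples, fs = fs, t0 = as.numeric(t0),
         label = as.character(label)),
    class = "ecg_record"
  )
}

#' Duration of an ECG record in seconds
#' @param record an [ecg_record()].
#' @return duration in seconds (`length(samples) / fs`).
#' @export
duration <- function(record) {
  stopifnot(inherits(record, "ecg_record"))
  length(record$samples) / record$fs
}

#' Sample times of a record
#' @param record an [ecg_record()].
#' @return numeric vector of sample times in seconds.
#' @export
record_times <- function(record) {
  record$t0 + (seq_along(record$samples) - 1) / record$fs
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %s\n", if (nzchar(x$label)) x$label else "(unlabelled)"))
  cat(sprintf("  %d samples @ %g Hz  (%.2f s, t0 = %g s)\n",
              length(x$samples), x$fs, duration(x), x$t0))
  cat(sprintf("  voltage range [%.3f, %.3f] mV\n",
              min(x$samples), max(x$samples)))
  invisible(x)
}

#' @export
plot.ecg_record <- function(x, t_start = NULL, t_end = NULL, ...) {
  tt <- record_times(x)
  keep <- rep(TRUE, length(tt))
  if (!is.null(t_start)) keep <- keep & tt >= t_start
  if (!is.null(t_end)) keep <- keep & tt <= t_end
  graphics::plot(tt[keep], x$samples[keep], type = "l",
                 xlab = "time (s)", ylab = "voltage (mV)",
                 main = x$label, ...)
  invisible(x)
}

#' Crop a record to a time window
#'
#' Returns the sub-record covering `[t_start, t_end)` in absolute time.
#' `t0` of the result is the time of its first sample, so absolute timing is
#' preserved.
#'
#' @param record an [ecg_record()].
#' @param t_start,t_end window bounds in seconds.
#' @return an [ecg_record()].
#' @export
crop_record <- function(record, t_start, t_end) {
  stopifnot(inherits(record, "ecg_record"))
  tt <- record_times(record)
  keep <- which(tt >= t_start & tt < t_end)
  if (length(keep) == 0L) stop("crop_record: empty window")
  ecg_record(record$samples[keep], record$fs, t0 = tt[keep[1]],
             label = record$label)
}

# ---- signal file I/O --------------------------------------------------------

#' Read an ECG signal file
#'
#' The signal format is UTF-8 delimited text.  Comment lines start with `#`
#' (an optional `# fs=600` comment declares the sampling rate, `# t0=` the
#' start time and `# label=` an identifier).  The header row is either
#' `time_s,voltage_mV` (two columns) or `voltage_mV` (single column, in which
#' case the sampling rate must come from `fs_override` or a `# fs=` comment).
#' A `voltage_uV` header is accepted and converted to millivolts.
#'
#' When a time column is present the sampling rate is inferred from the
#' median time step and the grid is required to be uniform to 1 part in 10^3;
#' a time column always wins over `fs_override`, and a disagreement beyond
#' 0.1% is an error rather than a warning, because a wrong acquisition rate
#' corrupts every interval measured downstream.
#'
#' @param path file path.
#' @param fs_override sampling rate in samples/s for single-column files.
#' @return an [ecg_record()].
#' @export
read_record <- function(path, fs_override = NULL) {
  if (!file.exists(path)) stop(sprintf("read_record: no such file '%s'", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop(sprintf("read_record: '%s' is empty", path))

  meta <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  fs_meta <- .meta_value(meta, "fs")
  t0_meta <- .meta_value(meta, "t0")
  label_meta <- .meta_value(meta, "label", numeric = FALSE)
  if (length(body) == 0L) stop(sprintf("read_record: '%s' has no data", path))

  header <- trimws(strsplit(body[1], ",")[[1]])
  has_header <- any(grepl("voltage", header, ignore.case = TRUE))
  if (has_header) body <- body[-1] else header <- NULL
  if (length(body) == 0L) stop(sprintf("read_record: '%s' has no data rows", path))

  fields <- strsplit(body, ",")
  ncol <- length(fields[[1]])
  if (!all(lengths(fields) == ncol)) {
    bad <- which(lengths(fields) != ncol)[1]
    stop(sprintf("read_record: ragged row %d in '%s'", bad, path))
  }
  vals <- suppressWarnings(matrix(as.numeric(unlist(fields)),
                                  ncol = ncol, byrow = TRUE))
  if (anyNA(vals)) stop(sprintf("read_record: non-numeric data in '%s'", path))

  uV <- has_header && any(grepl("voltage_uV", header, fixed = TRUE))
  if (ncol == 2L) {
    tcol <- vals[, 1]; v <- vals[, 2]
    if (nrow(vals) < 2L) stop("read_record: need >= 2 rows to infer fs")
    dt <- diff(tcol)
    med <- stats::median(dt)
    if (med <= 0 || any(abs(dt - med) > 1e-3 * med)) {
      stop(sprintf("read_record: non-uniform timestamps in '%s'", path))
    }
    fs <- 1 / med
    for (declared in c(fs_meta, fs_override)) {
      if (!is.null(declared) && abs(declared - fs) > 1e-3 * fs) {
        stop(sprintf(
          "read_record: declared fs %g conflicts with time column (%g)",
          declared, fs))
      }
    }
    # snap to integer rate when the grid agrees with one
    if (abs(fs - round(fs)) < 1e-3 * fs) fs <- round(fs)
    t0 <- tcol[1]
  } else if (ncol == 1L) {
    v <- vals[, 1]
    fs <- fs_override %||% fs_meta
    if (is.null(fs)) {
      stop("read_record: single-column file needs fs_override or '# fs=' comment")
    }
    t0 <- t0_meta %||% 0
  } else {
    stop(sprintf("read_record: expected 1 or 2 columns, got %d", ncol))
  }
  if (uV) v <- v / 1000
  ecg_record(v, fs, t0 = t0, label = label_meta %||% basename(path))
}

#' Write an ECG signal file
#'
#' Writes the two-column delimited-text format accepted by [read_record()]:
#' comment lines with the sampling rate, start time and label, a
#' `time_s,voltage_mV` header, then one row per sample.  Output is stable
#' across runs for a fixed record.
#'
#' @param record an [ecg_record()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path) {
  stopifnot(inherits(record, "ecg_record"))
  tt <- record_times(record)
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop(sprintf("write_record: cannot open '%s' for writing", path))
  })
  on.exit(close(con))
  writeLines(c(
    sprintf("# fs=%.10g", record$fs),
    sprintf("# t0=%.10g", record$t0),
    sprintf("# label=%s", record$label),
    "time_s,voltage_mV",
    sprintf("%.6f,%.6f", tt, record$samples)
  ), con)
  invisible(path)
}

# ---- beat annotations -------------------------------------------------------

.FIDUCIAL_COLS <- c("p_onset", "p_peak", "p_end", "qrs_onset",
                    "r_peak", "qrs_end", "t_end")

#' Construct a beat-annotation table
#'
#' One row per beat, holding 0-based sample indices of the per-beat fiducial
#' points: P onset/peak/end, QRS onset, R peak, QRS end, T end.  `r_peak` is
#' always present; other fiducials may be `NA` (e.g. an undetectable P wave).
#' The physiological ordering
#' `p_onset <= p_peak <= p_end <= qrs_onset <= r_peak <= qrs_end <= t_end`
#' is enforced at construction; violating input is an error, never silently
#' reordered.
#'
#' @param r_peak integer vector of R-peak sample indices (0-based).
#' @param p_onset,p_peak,p_end,qrs_onset,qrs_end,t_end per-beat fiducial
#'   indices, `NA` where absent.
#' @param n_samples optional record length used for bounds checking.
#' @return a `data.frame` of class `ecg_annotations` with a `beat_index`
#'   column and one column per fiducial.
#' @export
beat_annotations <- function(r_peak,
                             p_onset = NA, p_peak = NA, p_end = NA,
                             qrs_onset = NA, qrs_end = NA, t_end = NA,
                             n_samples = NULL) {
  n <- length(r_peak)
  df <- data.frame(
    beat_index = seq_len(n) - 1L,
    p_onset = .as_idx(p_onset, n), p_peak = .as_idx(p_peak, n),
    p_end = .as_idx(p_end, n), qrs_onset = .as_idx(qrs_onset, n),
    r_peak = .as_idx(r_peak, n), qrs_end = .as_idx(qrs_end, n),
    t_end = .as_idx(t_end, n)
  )
  if (anyNA(df$r_peak)) stop("beat_annotations: r_peak must be present for every beat")
  .validate_annotations(df, n_samples)
  class(df) <- c("ecg_annotations", "data.frame")
  df
}

.as_idx <- function(x, n) {
  x <- suppressWarnings(as.integer(round(as.numeric(x))))
  rep_len(x, n)
}

.validate_annotations <- function(df, n_samples = NULL) {
  idx <- as.matrix(df[.FIDUCIAL_COLS])
  if (any(idx < 0, na.rm = TRUE)) stop("beat_annotations: negative sample index")
  if (!is.null(n_samples) && any(idx >= n_samples, na.rm = TRUE)) {
    stop("beat_annotations: index beyond record bounds")
  }
  for (r in seq_len(nrow(idx))) {
    present <- idx[r, !is.na(idx[r, ])]
    if (is.unsorted(present)) {
      stop(sprintf("beat_annotations: fiducial ordering violated in beat %d",
                   df$beat_index[r]))
    }
  }
  invisible(df)
}

#' Write a beat-annotation file
#'
#' Delimited text with columns
#' `beat_index,p_onset,p_peak,p_end,qrs_onset,r_peak,qrs_end,t_end`;
#' absent fiducials are encoded as empty fields.  Round-trips losslessly
#' through [read_annotations()].
#'
#' @param beats an [beat_annotations()] table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(beats, path) {
  cols <- c("beat_index", .FIDUCIAL_COLS)
  stopifnot(all(cols %in% names(beats)))
  m <- as.matrix(beats[cols])
  txt <- apply(m, 1L, function(row) {
    paste(ifelse(is.na(row), "", format(row, scientific = FALSE, trim = TRUE)),
          collapse = ",")
  })
  writeLines(c(paste(cols, collapse = ","), txt), path)
  invisible(path)
}

#' Read a beat-annotation file
#'
#' @param path file written by [write_annotations()].
#' @return an annotation table of class `ecg_annotations`.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop(sprintf("read_annotations: no such file '%s'", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  if (length(lines) == 0L) stop("read_annotations: empty file")
  cols <- trimws(strsplit(lines[1], ",")[[1]])
  expected <- c("beat_index", .FIDUCIAL_COLS)
  if (!identical(cols, expected)) {
    stop("read_annotations: unexpected header; want ",
         paste(expected, collapse = ","))
  }
  body <- lines[-1]
  if (length(body) == 0L) {
    df <- as.data.frame(stats::setNames(rep(list(integer(0)), length(expected)),
                                        expected))
    class(df) <- c("ecg_annotations", "data.frame")
    return(df)
  }
  parts <- strsplit(body, ",")
  out <- matrix(NA_integer_, nrow = length(body), ncol = length(expected))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    length(p) <- length(expected)  # trailing empties
    p[p == "" | is.na(p)] <- NA
    v <- suppressWarnings(as.integer(p))
    if (any(is.na(v) & !(is.na(p)))) {
      stop(sprintf("read_annotations: malformed row %d", i))
    }
    out[i, ] <- v
  }
  df <- as.data.frame(out)
  names(df) <- expected
  .validate_annotations(df)
  class(df) <- c("ecg_annotations", "data.frame")
  df
}

# ---- small shared helpers ---------------------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

.meta_value <- function(meta, key, numeric = TRUE) {
  pat <- paste0("^#\\s*", key, "\\s*=\\s*")
  hit <- grep(pat, meta, value = TRUE)
  if (length(hit) == 0L) return(NULL)
  val <- sub(pat, "", hit[1])
  if (numeric) as.numeric(val) else trimws(val)
}
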