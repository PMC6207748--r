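# Drug-response analysis: paired pre/post comparison, fold and percent
# change, dose-response tables and atrioventricular-block classification.

#' Paired two-sided Student t-test
#'
#' Computed from its formula: `t = mean(d) / (sd(d) / sqrt(n))` on the
#' paired differences, with the two-sided p-value obtained from the
#' regularised incomplete beta function
#' (`pbeta(df / (df + t^2), df / 2, 1/2)`).  When the paired differences
#' have zero variance the statistic is undefined and a `no_variance` flag is
#' set instead.
#'
#' @param pre,post paired numeric vectors (per-subject values).
#' @return list with `t`, `df`, `p`, `mean_diff`, `sd_diff`, `n`,
#'   `no_variance`.
#' @export
paired_t_test <- function(pre, post) {
  if (length(pre) != length(post)) stop("paired_t_test: unpaired input")
  n <- length(pre)
  if (n < 2L) stop("paired_t_test: need at least 2 pairs")
  d <- post - pre
  md <- mean(d)
  sdd <- stats::sd(d)
  if (sdd == 0) {
    return(list(t = NA_real_, df = n - 1L, p = NA_real_, mean_diff = md,
                sd_diff = 0, n = n, no_variance = TRUE))
  }
  t <- md / (sdd / sqrt(n))
  df <- n - 1L
  p <- stats::pbeta(df / (df + t^2), df / 2, 1 / 2)
  list(t = t, df = df, p = p, mean_diff = md, sd_diff = sdd, n = n,
       no_variance = FALSE)
}

.subject_means <- function(tables, metric) {
  if (is.numeric(tables)) return(as.numeric(tables))
  vapply(tables, function(tab) {
    if (inherits(tab, "ecg_summary")) return(unname(tab$mean[metric]))
    mean(tab[[metric]], na.rm = TRUE)
  }, numeric(1))
}

#' Paired pre/post drug comparison
#'
#' Takes per-subject interval tables (or per-subject metric means) for the
#' pre- and post-treatment conditions, in paired order, and reports the
#' per-subject fold changes (`post_i / pre_i`), their mean, the mean percent
#' change, and the paired t-test on the per-subject means.  Percent change
#' is computed per subject then averaged, matching the fold-change
#' convention; `percent_reduction` is its negation, positive for
#' rate-lowering drugs.
#'
#' @param pre_tables,post_tables lists of `ecg_intervals` tables (or
#'   `ecg_summary` objects, or plain numeric vectors of per-subject means),
#'   equal length, paired order.
#' @param metric interval column to compare (default `"hr_bpm"`).
#' @return an object of class `ecg_comparison`.
#' @export
compare_pre_post <- function(pre_tables, post_tables, metric = "hr_bpm") {
  pre <- .subject_means(pre_tables, metric)
  post <- .subject_means(post_tables, metric)
  if (length(pre) != length(post)) {
    stop("compare_pre_post: pre and post subject counts differ (pairing error)")
  }
  n <- length(pre)
  if (n < 1L) stop("compare_pre_post: no subjects")
  folds <- post / pre
  if (any(folds <= 0, na.rm = TRUE)) {
    stop("compare_pre_post: non-positive fold change; check metric sign")
  }
  res <- list(
    metric = metric, n_subjects = n,
    pre = list(mean = mean(pre), sd = if (n >= 2) stats::sd(pre) else NULL,
               values = pre),
    post = list(mean = mean(post), sd = if (n >= 2) stats::sd(post) else NULL,
                values = post),
    delta = mean(post - pre),
    folds = folds,
    fold_change = mean(folds),
    percent_change = mean((folds - 1) * 100),
    percent_reduction = mean((1 - folds) * 100),
    t_statistic = NA_real_, p_value = NA_real_, no_variance = NA
  )
  if (n >= 2L) {
    tt <- paired_t_test(pre, post)
    res$t_statistic <- tt$t
    res$p_value <- tt$p
    res$no_variance <- tt$no_variance
  }
  structure(res, class = "ecg_comparison")
}

#' @export
print.ecg_comparison <- function(x, ...) {
  cat(sprintf("<ecg_comparison> %s, n = %d subjects\n", x$metric, x$n_subjects))
  cat(sprintf("  pre  %.2f%s\n", x$pre$mean,
              if (!is.null(x$pre$sd)) sprintf(" +/- %.2f", x$pre$sd) else ""))
  cat(sprintf("  post %.2f%s\n", x$post$mean,
              if (!is.null(x$post$sd)) sprintf(" +/- %.2f", x$post$sd) else ""))
  cat(sprintf("  fold change %.3f (percent change %+.1f%%)\n",
              x$fold_change, x$percent_change))
  if (isTRUE(x$no_variance)) {
    cat("  paired t: no variance in differences\n")
  } else if (!is.na(x$t_statistic)) {
    cat(sprintf("  paired t = %.3f, p = %.4g\n", x$t_statistic, x$p_value))
  }
  invisible(x)
}

#' Dose-response table
#'
#' Summarises per-subject fold changes at each dose as mean and sd against
#' log10 dose.  No curve is fitted; the table mirrors a points-only
#' dose-response plot.
#'
#' @param folds named list mapping dose (numeric, > 0) to a vector of
#'   per-subject fold changes.
#' @return data.frame with columns `dose`, `log10_dose`, `mean_fold`,
#'   `sd_fold`, `n`, sorted by ascending dose.
#' @export
dose_response <- function(folds) {
  doses <- as.numeric(names(folds))
  if (anyNA(doses) || any(doses <= 0)) {
    stop("dose_response: doses must be positive numbers (list names)")
  }
  ord <- order(doses)
  out <- data.frame(
    dose = doses[ord],
    log10_dose = log10(doses[ord]),
    mean_fold = vapply(folds[ord], mean, numeric(1)),
    sd_fold = vapply(folds[ord], function(v) {
      if (length(v) >= 2) stats::sd(v) else NA_real_
    }, numeric(1)),
    n = vapply(folds[ord], length, integer(1))
  )
  rownames(out) <- NULL
  out
}

#' Classify atrioventricular block
#'
#' Grades a recording against a baseline PR reference:
#' \itemize{
#'   \item `high_degree` when the dropped-QRS ratio (P events without a
#'     following QRS over all P events) exceeds 0.05;
#'   \item `first_degree` when the mean PR exceeds
#'     `baseline_pr_mean + 3 * baseline_pr_sd` with all P waves conducted;
#'   \item `none` otherwise.
#' }
#' With no usable PR data the call is `none` with evidence flag
#' `"insufficient"`.
#'
#' @param table an `ecg_intervals` table for the recording.
#' @param p_events data.frame of non-conducted P events (see
#'   [find_p_events()]), or an integer count.
#' @param baseline_pr_mean,baseline_pr_sd baseline PR reference (ms).
#' @return an object of class `av_block_call` with fields `grade`,
#'   `pr_mean_ms`, `baseline_pr_mean`, `baseline_pr_sd`, `dropped_ratio`,
#'   `evidence`.
#' @export
classify_av_block <- function(table, p_events, baseline_pr_mean,
                              baseline_pr_sd) {
  n_orphan <- if (is.data.frame(p_events)) nrow(p_events) else as.integer(p_events)
  n_conducted <- sum(!is.na(table$pr_ms))
  total_p <- n_orphan + n_conducted
  dropped_ratio <- if (total_p > 0) n_orphan / total_p else 0
  pr_mean <- if (n_conducted > 0) mean(table$pr_ms, na.rm = TRUE) else NA_real_

  if (n_conducted == 0L) {
    grade <- "none"; evidence <- "insufficient"
  } else if (dropped_ratio > 0.05) {
    grade <- "high_degree"; evidence <- "dropped_qrs"
  } else if (pr_mean > baseline_pr_mean + 3 * baseline_pr_sd) {
    grade <- "first_degree"; evidence <- "pr_prolongation"
  } else {
    grade <- "none"; evidence <- "within_baseline"
  }
  structure(list(grade = grade, pr_mean_ms = pr_mean,
                 baseline_pr_mean = baseline_pr_mean,
                 baseline_pr_sd = baseline_pr_sd,
                 dropped_ratio = dropped_ratio, evidence = evidence),
            class = "av_block_call")
}

#' @export
print.av_block_call <- function(x, ...) {
  cat(sprintf("<av_block_call> grade: %s (%s)\n", x$grade, x$evidence))
  cat(sprintf("  mean PR %.1f ms vs baseline %.1f +/- %.1f ms; dropped-QRS ratio %.3f\n",
              x$pr_mean_ms, x$baseline_pr_mean, x$baseline_pr_sd,
              x$dropped_ratio))
  invisible(x)
}
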