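test_that("the paired t statistic matches its hand-computed value", {
  pre <- c(10, 12, 14); post <- c(11, 13, 16)
  tt <- paired_t_test(pre, post)
  expect_equal(tt$mean_diff, 4 / 3)
  expect_equal(tt$sd_diff, sd(c(1, 1, 2)))
  expect_equal(round(tt$sd_diff, 3), 0.577)
  expect_equal(tt$t, 4, tolerance = 1e-12)
  # dual route: the incomplete-beta p equals stats::t.test's
  ref <- t.test(post, pre, paired = TRUE)
  expect_equal(tt$t, unname(ref$statistic))
  expect_equal(tt$p, ref$p.value, tolerance = 1e-12)
  expect_error(paired_t_test(1:3, 1:4), "unpaired")
})

test_that("fold and percent change follow the per-subject convention", {
  cmp <- compare_pre_post(c(100, 100), c(125, 125))
  expect_equal(cmp$fold_change, 1.25)
  expect_equal(cmp$percent_change, 25)
  expect_equal(cmp$percent_reduction, -25)
  # identical pre/post: zero difference, no-variance flag instead of a t
  same <- compare_pre_post(c(100, 100), c(100, 100))
  expect_true(same$no_variance)
  expect_true(is.na(same$t_statistic))
  expect_error(compare_pre_post(1:3, 1:2), "pairing")
})

test_that("comparison accepts interval tables and picks the metric column", {
  mk <- function(hr) {
    ann <- beat_annotations(r_peak = round(cumsum(rep(60000 / hr, 20)) * 0.6))
    intervals_from_annotations(ann, fs = 600)
  }
  cmp <- compare_pre_post(list(mk(100), mk(100)), list(mk(125), mk(125)),
                          metric = "hr_bpm")
  expect_equal(cmp$fold_change, 1.25, tolerance = 0.01)
  expect_equal(cmp$n_subjects, 2)
})

test_that("swapping pre and post negates the t and inverts per-subject folds", {
  set.seed(9)
  pre <- rnorm(8, 100, 5); post <- rnorm(8, 120, 5)
  a <- compare_pre_post(pre, post)
  b <- compare_pre_post(post, pre)
  expect_equal(b$t_statistic, -a$t_statistic)
  expect_equal(b$p_value, a$p_value)
  expect_equal(b$folds, 1 / a$folds)
  expect_equal(b$fold_change, 1 / a$fold_change, tolerance = 0.01)
})

test_that("the paired test keeps its nominal type-I error under the null", {
  set.seed(2024)
  n_rep <- 1000
  rej <- replicate(n_rep, {
    pre <- rnorm(10, 100, 8)
    post <- pre + rnorm(10, 0, 5)     # null: zero mean difference
    paired_t_test(pre, post)$p < 0.05
  })
  expect_equal(mean(rej), 0.05, tolerance = 0.015 / 0.05)
  expect_lte(abs(mean(rej) - 0.05), 0.015)
})

test_that("dose-response tables are sorted and summarise folds", {
  folds <- list("10" = c(1.24, 1.26), "0.5" = c(1.03, 1.05), "5" = c(1.14, 1.14))
  dr <- dose_response(folds)
  expect_equal(dr$dose, c(0.5, 5, 10))
  expect_equal(dr$log10_dose, log10(c(0.5, 5, 10)))
  expect_equal(dr$mean_fold, c(1.04, 1.14, 1.25))
  expect_equal(dr$n, c(2L, 2L, 2L))
  one <- dose_response(list("1" = 1.1))
  expect_equal(nrow(one), 1)
  expect_true(is.na(one$sd_fold))
  expect_error(dose_response(list("-1" = 1.1)), "positive")
})

test_that("AV-block grading follows the PR and dropped-QRS rules", {
  mk_tab <- function(pr) data.frame(pr_ms = pr, time_s = seq_along(pr))
  # PR 85 vs baseline 62 +/- 4: beyond mean + 3 SD, all P conducted
  call1 <- classify_av_block(mk_tab(rep(85, 20)), 0, 62, 4)
  expect_equal(call1$grade, "first_degree")
  # any dropped-QRS ratio above 5% dominates
  call2 <- classify_av_block(mk_tab(rep(62, 20)), 3, 62, 4)
  expect_equal(call2$grade, "high_degree")
  expect_gt(call2$dropped_ratio, 0.05)
  # baseline against itself
  call3 <- classify_av_block(mk_tab(rep(62, 20)), 0, 62, 4)
  expect_equal(call3$grade, "none")
  # no PR data: insufficient evidence
  call4 <- classify_av_block(mk_tab(rep(NA_real_, 5)), 0, 62, 4)
  expect_equal(call4$grade, "none")
  expect_equal(call4$evidence, "insufficient")
  # invariant to a uniform time shift
  tab <- mk_tab(rep(85, 20)); tab2 <- tab; tab2$time_s <- tab2$time_s + 500
  expect_equal(classify_av_block(tab2, 0, 62, 4)$grade, call1$grade)
})
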