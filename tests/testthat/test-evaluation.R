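test_that("goodness of fit matches hand arithmetic", {
  y <- c(0, 1, 2, 3)
  expect_equal(unname(goodness_of_fit(y, y)), c(1, 0))
  g0 <- goodness_of_fit(rep(mean(y), 4), y)
  expect_equal(g0[["r2"]], 0)
  g <- goodness_of_fit(c(0, 1, 2, 5), y)
  expect_equal(g[["rmse"]], 1.0)
  expect_equal(g[["r2"]], 0.2)
  # normalized RMSE divides by the max truth magnitude
  gn <- goodness_of_fit(c(0, 1, 2, 5), y, normalize_by_max = TRUE)
  expect_equal(gn[["rmse"]], 1 / 3)
  gm <- goodness_of_fit(c(0, 1, 2, 5), y, normalize_by_max = TRUE,
                        max_value = 6)
  expect_equal(gm[["rmse"]], 1 / 6)
  expect_true(is.na(goodness_of_fit(y, rep(1, 4))[["r2"]]))
})

test_that("the percentile ROC sweep matches exhaustive confusion counts", {
  # perfectly separated classes
  v <- c(stats::rnorm(50, 10, 0.1), stats::rnorm(50, 0, 0.1))
  lab <- c(rep(FALSE, 50), rep(TRUE, 50))
  roc <- percentile_roc(v, lab, "low_is_positive")
  expect_equal(roc$auroc, 1.0)
  expect_length(roc$thresholds, 100L)
  expect_true(all(roc$tpr >= 0 & roc$tpr <= 1))
  expect_true(all(roc$fpr >= 0 & roc$fpr <= 1))

  # 10-point toy: brute-force verification of every threshold
  v10 <- c(5, 3, 8, 1, 9, 2, 7, 4, 6, 0)
  l10 <- c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE)
  r10 <- percentile_roc(v10, l10, "low_is_positive")
  for (i in c(1L, 25L, 50L, 75L, 100L)) {
    thr <- r10$thresholds[i]
    expect_equal(r10$tpr[i], sum(v10 < thr & l10) / sum(l10))
    expect_equal(r10$fpr[i], sum(v10 < thr & !l10) / sum(!l10))
  }

  # label-independent metric: AUROC near chance
  set.seed(202)
  vr <- stats::runif(10000)
  lr <- rep(c(TRUE, FALSE), 5000)
  a <- percentile_roc(vr, lr, "low_is_positive")$auroc
  expect_gt(a, 0.45); expect_lt(a, 0.55)

  expect_error(percentile_roc(vr, rep(TRUE, 10000)), "classes")
})

test_that("AUROC is invariant to monotone transforms up to the grid", {
  set.seed(7)
  v <- c(stats::rnorm(300, 1), stats::rnorm(300, 0))
  lab <- c(rep(FALSE, 300), rep(TRUE, 300))
  a1 <- percentile_roc(v, lab, "low_is_positive")$auroc
  a2 <- percentile_roc(exp(v), lab, "low_is_positive")$auroc
  expect_lt(abs(a1 - a2), 0.02)
})

test_that("detection time implements the percentile + run-length rule", {
  ph <- c(baseline_start = 0, hemorrhage_start = 600, resus_start = 1200)
  tt <- seq(0, 1199, by = 1)
  base_vals <- stats::rnorm(600, 1, 0.001)
  # step down at t = 700, held for >= 100 readings
  vals <- c(base_vals, rep(1, 100), rep(0, 500))
  m <- metric_series(tt, vals)
  expect_equal(detection_time(m, ph, "low_is_positive"), 100)

  # runs of only 99 beyond-threshold readings: capped
  vals99 <- c(base_vals, rep(c(rep(0, 99), 1), 6))
  m99 <- metric_series(tt, vals99)
  expect_equal(detection_time(m99, ph, "low_is_positive"), 600)

  # rising-metric orientation uses the 95th percentile
  vals_up <- c(base_vals, rep(1, 100), rep(2, 500))
  expect_equal(detection_time(metric_series(tt, vals_up), ph,
                              "high_is_positive"), 100)

  # monotone in run length: longer runs never detect earlier
  set.seed(31)
  noisy <- c(stats::rnorm(600, 1, 0.05),
             1 - 0.002 * (1:600) + stats::rnorm(600, 0, 0.05))
  mn <- metric_series(tt, noisy)
  d20 <- detection_time(mn, ph, "low_is_positive", run_length = 20L)
  d60 <- detection_time(mn, ph, "low_is_positive", run_length = 60L)
  d150 <- detection_time(mn, ph, "low_is_positive", run_length = 150L)
  expect_lte(d20, d60); expect_lte(d60, d150)
})

test_that("the resuscitation ratio compares the two 5-minute windows", {
  ph <- c(resus_start = 1000, resus_end = 1600)
  tt <- seq(0, 1600, by = 1)
  vals <- ifelse(tt < 1000, 0.2, 0.8)
  m <- metric_series(tt, vals)
  expect_equal(as.numeric(resuscitation_ratio(m, ph)), 4.0)
  # unchanged metric: ratio 1
  expect_equal(as.numeric(resuscitation_ratio(
    metric_series(tt, rep(0.6, 1601)), ph)), 1.0)
  # piecewise-constant windows recovered exactly
  vals2 <- ifelse(tt < 1000, 0.25, ifelse(tt < 1300, 5, 0.75))
  expect_equal(as.numeric(resuscitation_ratio(metric_series(tt, vals2), ph)),
               3.0)
  expect_warning(resuscitation_ratio(metric_series(tt, rep(0, 1601)), ph),
                 "guarded")
})

test_that("report summaries are exact aggregates of the per-record rows", {
  pipe <- cached_pipeline()
  rep1 <- pipe$report
  for (m in unique(rep1$summary$metric)) {
    d <- rep1$per_record[rep1$per_record$metric == m, ]
    s <- rep1$summary[rep1$summary$metric == m, ]
    expect_equal(s$r2_mean, mean(d$r2))
    expect_equal(s$r2_median, stats::median(d$r2))
    expect_equal(s$rmse_mean, mean(d$rmse))
    expect_equal(s$auroc_mean, mean(d$auroc))
    expect_equal(s$detection_time_mean_s, mean(d$detection_time_s))
    expect_equal(s$resus_ratio_mean, mean(d$resus_ratio))
    expect_equal(s$resus_ratio_cv_pct,
                 coefficient_of_variation(d$resus_ratio))
    expect_equal(s$n_records, nrow(d))
  }
  # regeneration from the same persisted LOSO result is deterministic
  rep2 <- build_report(pipe$loso, pipe$subjects)
  expect_equal(rep1$per_record, rep2$per_record)
  expect_equal(rep1$summary, rep2$summary)
})

test_that("the coefficient of variation is a scale-free percentage", {
  expect_equal(coefficient_of_variation(rep(4, 10)), 0)
  expect_equal(coefficient_of_variation(c(1, 3)), 100 * sqrt(2) / 2,
               tolerance = 1e-9)
  expect_equal(round(coefficient_of_variation(c(1, 3)), 2), 70.71)
  x <- c(2, 5, 9, 4)
  expect_equal(coefficient_of_variation(3 * x), coefficient_of_variation(x))
  expect_error(coefficient_of_variation(c(-1, 1)), "zero mean")
})
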