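test_that("BLVM follows the loss/recovery closed form", {
  # pure hemorrhage 0 -> 900 mL, then 300 mL whole blood given back
  times <- 0:120
  hem <- c(seq(0, 900, length.out = 61), rep(900, 60))
  wb <- c(rep(0, 61), seq(5, 300, length.out = 60))
  v <- make_volume_series(times, hem, wb)
  blvm <- compute_blvm(v)
  expect_equal(blvm$values[1], 1)                       # zero loss
  expect_equal(blvm$values[61], 0)                      # maximum loss
  expect_equal(blvm$values[121], 300 / 900)             # 0 + 300/900
  # non-increasing during pure hemorrhage, non-decreasing during infusion
  expect_true(all(diff(blvm$values[1:61]) <= 0))
  expect_true(all(diff(blvm$values[61:121]) >= 0))
  expect_true(all(blvm$values <= 1))

  expect_error(compute_blvm(make_volume_series(0:5, rep(0, 6))), "zero")
})

test_that("PEBL is net loss over the estimated blood volume", {
  v <- make_volume_series(0:10, seq(0, 600, length.out = 11))
  pebl <- compute_pebl(v, weight_kg = 50)
  expect_equal(pebl$values[11], 600 / (60 * 50))        # 0.20
  expect_equal(pebl$values[1], 0)
  expect_true(all(pebl$values >= 0))
  # canine constant
  v2 <- make_volume_series(0:10, seq(0, 800, length.out = 11))
  expect_equal(compute_pebl(v2, 20, ebv_constant = 80)$values[11], 0.5)
  expect_error(compute_pebl(v, -3), "positive")
})

test_that("HemArea integrates blood loss over time", {
  # constant loss L for T minutes -> L*T mL.min
  v <- make_volume_series(seq(0, 600, by = 1), rep(500, 601))
  ha <- compute_hemarea(v)
  expect_equal(ha$values[601], 500 * 10, tolerance = 1e-9)
  # zero loss
  expect_equal(max(abs(compute_hemarea(
    make_volume_series(0:60, c(0, rep(0, 60))))$values)), 0)
  # linear ramp 0 -> 600 mL over 10 min: triangle area 3000 mL.min
  v3 <- make_volume_series(seq(0, 600, by = 1),
                           seq(0, 600, length.out = 601))
  expect_equal(compute_hemarea(v3)$values[601], 3000, tolerance = 1e-9)
  expect_true(all(diff(compute_hemarea(v3)$values) >= 0))
})

test_that("the legacy BLVM-area form matches the direct integral", {
  b1 <- metric_series(seq(0, 600, 1), rep(1, 601), "BLVM")
  expect_equal(max(abs(hemarea_from_blvm(b1)$values)), 0)
  b0 <- metric_series(seq(0, 600, 1), rep(0, 601), "BLVM")
  expect_equal(hemarea_from_blvm(b0)$values[601], 10)   # T = 10 min

  # algebraic identity on a hemorrhage-only profile:
  # |BLVM - 1| * dt accumulates to HemArea / total_shed
  times <- seq(0, 1200, by = 0.5)
  hem <- pmin(600, pmax(0, (times - 100) * 1.1))
  v <- make_volume_series(times, hem)
  direct <- compute_hemarea(v)
  legacy <- hemarea_from_blvm(compute_blvm(v))
  expect_equal(legacy$values, direct$values / v$total_shed,
               tolerance = 1e-6)
})

test_that("CRM maps the LBNP staircase onto the unit reserve scale", {
  rec <- simulate_lbnp_subject(sim_config(seed = 2L), 9L)
  crm <- compute_crm(rec, rate = 1)
  expect_true(all(crm$values >= 0 & crm$values <= 1))
  expect_equal(crm$values[1], 1)                        # full reserve
  expect_equal(min(crm$values), 0)                      # decompensation
  # recovers the configured staircase exactly at step midpoints
  sched <- rec$lbnp_schedule
  mid_t <- sched$time_s + 50
  expect_equal(sample_metric_at(crm, mid_t)$values,
               1 - sched$lbnp_mmhg / rec$lbnp_hdd, tolerance = 1e-9)
  bad <- rec; bad$lbnp_hdd <- 0
  expect_error(compute_crm(bad), "lbnp_hdd")
})

test_that("the trailing moving mean is causal with expanding edges", {
  x <- metric_series(1:200, rep(3.5, 200))
  expect_equal(moving_mean(x, 50)$values, rep(3.5, 200))
  expect_equal(moving_mean(x, 1)$values, x$values)      # identity
  imp <- c(rep(0, 99), 1, rep(0, 100))
  sm <- moving_mean(imp, 50)
  expect_equal(sm[100:149], rep(1 / 50, 50))
  expect_equal(sm[150], 0)
  expect_equal(sm[99], 0)
  expect_error(moving_mean(x, 0), "window")
})

test_that("shift regression reports slope, intercept and fit", {
  y <- c(0.1, 0.4, 0.5, 0.9, 1.3)
  r <- shift_regression(y, y)
  expect_equal(r$slope, 1); expect_equal(r$intercept, 0)
  expect_equal(r$r2, 1)
  r2 <- shift_regression(y + 0.2, y)
  expect_equal(r2$slope, 1); expect_equal(r2$intercept, -0.2)
  r3 <- shift_regression(2 * y, y)
  expect_equal(r3$slope, 0.5); expect_equal(r3$intercept, 0, tolerance = 1e-12)
  expect_error(shift_regression(rep(1, 5), y), "zero-variance")
})

test_that("metric series round-trip through the text format", {
  m <- metric_series(seq(0, 10, 0.5), sin(seq(0, 10, 0.5)), "BLVM")
  p <- withr::local_tempfile(fileext = ".tsv")
  write_metric_series(m, p)
  back <- read_metric_series(p)
  expect_equal(back$values, m$values, tolerance = 1e-9)
  expect_equal(back$name, "BLVM")
})

test_that("subject ground-truth metrics respect the phase structure", {
  fx <- cached_subject()
  truth <- subject_truth_metrics(fx$rec, fx$beats, fx$sig)
  ph <- fx$rec$phases
  blvm <- truth$BLVM; pebl <- truth$PEBL; ha <- truth$HemArea

  hem_idx <- blvm$times >= ph[["hemorrhage_start"]] &
    blvm$times < ph[["hold_start"]]
  resus_idx <- blvm$times >= ph[["resus_start"]] + 30 &
    blvm$times < ph[["resus_end"]]
  expect_true(all(diff(blvm$values[hem_idx]) <= 1e-9))
  expect_true(all(diff(blvm$values[resus_idx]) >= -1e-9))
  expect_lt(blvm$values[sum(blvm$times <= ph[["resus_end"]])], 1)
  expect_true(all(pebl$values >= 0))
  expect_true(all(ha$values >= -1e-9))
  expect_true(all(diff(ha$values) >= -1e-9))
  # baseline: full blood volume
  expect_true(all(blvm$values[blvm$times < ph[["hemorrhage_start"]]] == 1))
  expect_true(all(pebl$values[pebl$times < ph[["hemorrhage_start"]]] == 0))
})
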