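test_that("base descriptors encode the landmark geometry", {
  train <- template_train(n_beats = 10, hr = 60, dbp = 60, pp = 40)
  b <- detect_beats(train)
  seg <- train$values[b$foot_idx[3]:b$end_idx[3]]
  d <- base_descriptors(seg, b[3, ], train$rate)
  expect_length(d, 48L)
  expect_named(d)
  expect_equal(unname(d["pulse_pressure"]),
               unname(d["amp_peak"] - d["amp_foot"]))
  expect_equal(unname(d["beat_duration"]), unname(d["t_end"]))
  expect_equal(unname(d["hr_inst"]), 60 / unname(d["t_end"]))
  expect_equal(unname(d["dt_foot_end"]), unname(d["t_end"]))
  expect_gt(d["samp_max"], d["samp_min"])

  # symmetric triangular beat: up and down slopes mirror
  tri <- c(seq(0, 1, length.out = 26), seq(1, 0, length.out = 26)[-1])
  lm <- list(foot_idx = 1L, halfrise_idx = 13L, peak_idx = 26L,
             infl_idx = 38L, end_idx = 51L)
  dtri <- base_descriptors(tri, lm, 100)
  expect_equal(unname(dtri["slope_up_max"]), -unname(dtri["slope_down_max"]))
})

test_that("pairwise expansion has the exact combinatorial structure", {
  base <- stats::setNames(seq_len(48) + 0.5,
                          hemotrace:::base_feature_names())
  ex <- pairwise_expand(base)
  nm <- names(ex)
  expect_length(ex, 4512L)
  expect_length(grep("^diff\\(", nm), 1128L)
  expect_length(grep("^prod\\(", nm), 1128L)
  expect_length(grep("^ratio\\(", nm), 2256L)
  expect_false(any(duplicated(nm)))
  # no self-ratios; antisymmetric diffs deduplicated to one column
  expect_false(any(grepl("ratio\\((.+),\\1\\)", nm)))
  expect_false("diff(t_peak,amp_foot)" %in% nm &&
                 "diff(amp_foot,t_peak)" %in% nm)
  expect_equal(unname(ex["diff(amp_foot,amp_halfrise)"]),
               unname(base["amp_foot"] - base["amp_halfrise"]))
  expect_equal(unname(ex["ratio(amp_peak,amp_foot)"]),
               unname(base["amp_peak"] / base["amp_foot"]))
  # guarded denominator
  base2 <- base; base2["amp_foot"] <- 0
  ex2 <- pairwise_expand(base2)
  expect_equal(unname(ex2["ratio(amp_peak,amp_foot)"]), 0)
})

test_that("spectral descriptors match a direct DFT evaluation", {
  # pure fundamental, exactly periodic over the beat span
  beat <- 80 + 10 * sin(2 * pi * seq(0, 1, length.out = 100))
  sp <- spectral_descriptors(beat, 100)
  mags <- sp[paste0("fft_mag_", 1:8)]
  expect_gt(mags[1], 4.9)
  expect_true(all(mags[2:8] < 0.01 * mags[1]))

  tb <- 60 + 40 * pulse_template((0:79) / 80)
  sp2 <- spectral_descriptors(tb, 100)
  # independent oracle on the same 64-point resampled grid
  grid <- stats::approx(seq(0, 1, length.out = 80), tb,
                        xout = (0:63) / 64)$y
  expect_equal(unname(sp2[paste0("fft_mag_", 1:8)]), oracle_dft_mag(grid),
               tolerance = 1e-10)
  # linearity: amplitude doubling doubles magnitudes
  sp3 <- spectral_descriptors(60 + 80 * pulse_template((0:79) / 80), 100)
  expect_equal(unname(sp3[paste0("fft_mag_", 1:8)]),
               2 * unname(sp2[paste0("fft_mag_", 1:8)]), tolerance = 1e-9)

  expect_error(spectral_descriptors(1:5, 100), "short")
})

test_that("trailing statistics handle constants, ramps, and edges exactly", {
  M <- cbind(const = rep(4, 60), ramp = seq(2, by = 0.5, length.out = 60))
  ts <- trailing_stats(M, windows = c(10L))
  expect_equal(unname(ts[, "trail_sd_10(const)"]), rep(0, 60))
  expect_equal(unname(ts[, "trail_slope_10(const)"]), rep(0, 60))
  expect_equal(unname(ts[, "trail_mean_10(const)"]), rep(4, 60))
  # exact linear fit: slope equals the per-beat increment
  expect_equal(unname(ts[11:60, "trail_slope_10(ramp)"]), rep(0.5, 50))
  # first beat: trailing mean is its own value
  expect_equal(unname(ts[1, "trail_mean_10(ramp)"]), 2)
})

test_that("the extracted bank is large, named, deterministic, and shift-invariant", {
  train <- template_train(n_beats = 70, hr = 80)
  fm <- extract_feature_matrix(train, "non_detrended")
  expect_gte(ncol(fm$X), 4200L)
  expect_false(any(duplicated(colnames(fm$X))))
  expect_true(all(is.finite(fm$X)))
  expect_identical(colnames(fm$X), feature_bank_names())

  fm2 <- extract_feature_matrix(train, "non_detrended")
  expect_identical(fm$X, fm2$X)

  # shifting the signal start shifts beat times, not feature values
  k <- 137L
  shifted <- uniform_series(train$values[-seq_len(k)], train$rate,
                            start_time = k / train$rate)
  fms <- extract_feature_matrix(shifted, "non_detrended")
  n1 <- nrow(fm$X); n2 <- nrow(fms$X)
  # align on common beats via foot times
  common <- intersect(round(fm$beat_times, 6), round(fms$beat_times, 6))
  expect_gt(length(common), 50)
  i1 <- match(common, round(fm$beat_times, 6))
  i2 <- match(common, round(fms$beat_times, 6))
  # trailing features depend on history length; compare the other layers
  nontrail <- seq_len(4576L)
  skip_edge <- common > min(common) + 1   # first aligned beat differs upstream
  expect_equal(fm$X[i1[skip_edge], nontrail], fms$X[i2[skip_edge], nontrail],
               tolerance = 1e-9)
})

test_that("feature names and drift-invariant columns agree across variants", {
  train <- template_train(n_beats = 60, hr = 75)
  fm_raw <- extract_feature_matrix(train, "non_detrended")
  det <- detrend_polynomial(train, 5)$detrended
  fm_det <- extract_feature_matrix(det, "detrended", )
  expect_identical(colnames(fm_raw$X), colnames(fm_det$X))
  # drift-free record: time-interval features match across variants
  tcols <- grep("^dt_", colnames(fm_raw$X), value = TRUE)
  expect_equal(fm_raw$X[, tcols], fm_det$X[, tcols], tolerance = 1e-9)
})

test_that("non-finite entries are imputed from the previous valid beat", {
  train <- template_train(n_beats = 30, hr = 70)
  fm <- extract_feature_matrix(train, "non_detrended")
  x <- c(1, 2, NaN, Inf, 5)
  f <- hemotrace:::fill_forward(x)
  expect_equal(f$x, c(1, 2, 2, 2, 5))
  expect_equal(f$n, 2L)
  f2 <- hemotrace:::fill_forward(c(NA, NA, 3))
  expect_equal(f2$x, c(0, 0, 3))
})
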