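## Per-beat feature bank: 48 base landmark/shape descriptors, their full
## pairwise algebraic expansion (differences, products, directed ratios),
## 8 Fourier harmonics (magnitude + phase), and trailing-window statistics,
## giving > 4200 named features per signal variant. The bank is a documented
## reconstruction at the scale and of the categories used in arterial-
## waveform hemorrhage tracking (the original proprietary list is not
## public); feature names are a function of the bank configuration only, so
## columns align across subjects.

landmark_names <- c("foot", "halfrise", "peak", "infl", "end")

base_feature_names <- function() {
  lm <- landmark_names
  pairs <- utils::combn(lm, 2)
  c(paste0("amp_", lm),
    paste0("t_", lm[-1L]),
    paste0("damp_", pairs[1L, ], "_", pairs[2L, ]),
    paste0("dt_", pairs[1L, ], "_", pairs[2L, ]),
    paste0("slope_", lm[-5L], "_", lm[-1L]),
    paste0("area_", lm[-5L], "_", lm[-1L]),
    "beat_duration", "hr_inst", "pulse_pressure",
    "samp_mean", "samp_sd", "samp_min", "samp_max", "samp_skew", "samp_kurt",
    "slope_up_max", "slope_down_max")
}

guard_div <- function(num, den, eps = 1e-9) {
  out <- num / den
  out[abs(den) < eps] <- 0
  out
}

#' Base beat descriptors
#'
#' 48 named descriptors of one beat: the 5 landmark amplitudes; the 4
#' landmark times relative to the foot; all 10 pairwise amplitude differences
#' and 10 pairwise time intervals among the landmarks; 4 inter-landmark chord
#' slopes; 4 inter-landmark trapezoidal areas above the foot level; beat
#' duration, instantaneous heart rate, pulse pressure; mean, SD, min, max,
#' skewness and kurtosis of the beat samples; and the maximum upstroke and
#' downstroke slopes.
#'
#' @param beat_samples Pressure samples of the beat (foot to next foot),
#'   mmHg.
#' @param landmarks One row of a `beat_landmarks` table.
#' @param rate Sampling rate, Hz.
#' @return Named numeric vector of length 48.
#' @export
base_descriptors <- function(beat_samples, landmarks, rate) {
  l <- as.list(landmarks)
  out <- base_descriptors_idx(
    beat_samples,
    c(1L, l$halfrise_idx - l$foot_idx + 1L, l$peak_idx - l$foot_idx + 1L,
      l$infl_idx - l$foot_idx + 1L, l$end_idx - l$foot_idx + 1L),
    rate)
  names(out) <- base_feature_names()
  out
}

## pair index constants for the 5 landmarks (combn(5, 2) order)
.lm_pair_a <- c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 4L)
.lm_pair_b <- c(2L, 3L, 4L, 5L, 3L, 4L, 5L, 4L, 5L, 5L)

## hot path: unnamed computation from within-beat landmark indices
base_descriptors_idx <- function(x, rel, rate) {
  amps <- x[rel]
  times <- (rel - 1L) / rate
  damp <- amps[.lm_pair_a] - amps[.lm_pair_b]
  dtv <- times[.lm_pair_b] - times[.lm_pair_a]
  dts <- times[2:5] - times[1:4]
  slopes <- ifelse(dts > 0, (amps[2:5] - amps[1:4]) / dts, 0)
  areas <- numeric(4L)
  for (i in 1:4) {
    idx <- rel[i]:rel[i + 1L]
    if (length(idx) >= 2L) {
      yy <- x[idx] - amps[1L]
      areas[i] <- (sum(yy) - (yy[1L] + yy[length(yy)]) / 2) / rate
    }
  }
  dur <- times[5L]
  d <- (x[-1L] - x[-length(x)]) * rate
  n <- length(x)
  mu <- sum(x) / n
  xc <- x - mu
  m2 <- sum(xc * xc) / n
  sdv <- sqrt(m2 * n / (n - 1L))
  skew <- if (m2 > 0) sum(xc^3) / n / m2^1.5 else NaN
  kurt <- if (m2 > 0) sum(xc^4) / n / m2^2 - 3 else NaN
  c(amps, times[-1L], damp, dtv, slopes, areas,
    dur, if (dur > 0) 60 / dur else 0, amps[3L] - amps[1L],
    mu, sdv, min(x), max(x), skew, kurt, max(d), min(d))
}

pairwise_names <- function(base_names = base_feature_names()) {
  p <- utils::combn(base_names, 2)
  rn <- expand.grid(a = base_names, b = base_names,
                    stringsAsFactors = FALSE)
  rn <- rn[rn$a != rn$b, ]
  list(diff = paste0("diff(", p[1L, ], ",", p[2L, ], ")"),
       prod = paste0("prod(", p[1L, ], ",", p[2L, ], ")"),
       ratio = paste0("ratio(", rn$a, ",", rn$b, ")"),
       pairs = p, directed = rn)
}

#' Pairwise algebraic expansion of the base descriptors
#'
#' For the ordered base set of size B: all C(B,2) differences (antisymmetric
#' duplicates removed), all C(B,2) products, and all B(B-1) directed ratios
#' with guarded denominators (|denominator| < 1e-9 yields 0). With B = 48
#' this is 1128 + 1128 + 2256 = 4512 composed features.
#'
#' @param base Named numeric vector from [base_descriptors()] (or a numeric
#'   matrix with those columns, one row per beat).
#' @return Named vector (or matrix) of composed features.
#' @export
pairwise_expand <- function(base) {
  if (is.matrix(base)) return(pairwise_expand_matrix(base))
  m <- pairwise_expand_matrix(matrix(base, nrow = 1L,
                                     dimnames = list(NULL, names(base))))
  stats::setNames(as.numeric(m), colnames(m))
}

pairwise_expand_matrix <- function(M, out = NULL, at = 1L) {
  nm <- pairwise_names(colnames(M))
  if (is.null(out)) {
    out <- matrix(NA_real_, nrow(M), 4512L)
    colnames(out) <- c(nm$diff, nm$prod, nm$ratio)
    named <- TRUE
  } else named <- FALSE
  ia <- match(nm$pairs[1L, ], colnames(M))
  ib <- match(nm$pairs[2L, ], colnames(M))
  A <- M[, ia, drop = FALSE]; Bm <- M[, ib, drop = FALSE]
  out[, at:(at + 1127L)] <- A - Bm
  out[, (at + 1128L):(at + 2255L)] <- A * Bm
  ra <- match(nm$directed$a, colnames(M))
  rb <- match(nm$directed$b, colnames(M))
  den <- M[, rb, drop = FALSE]
  R <- M[, ra, drop = FALSE] / den
  R[abs(den) < 1e-9] <- 0
  out[, (at + 2256L):(at + 4511L)] <- R
  out
}

#' Spectral beat descriptors
#'
#' Magnitudes and phases of the first 8 discrete-Fourier harmonics of the
#' mean-removed, duration-normalized beat (the beat is resampled to a common
#' 64-point phase grid so harmonics are relative to the beat period).
#'
#' @param beat_samples Pressure samples of the beat.
#' @param rate Sampling rate, Hz.
#' @param n_harmonics Number of harmonics; default 8.
#' @return Named numeric vector `fft_mag_1..8`, `fft_phase_1..8`.
#' @export
spectral_descriptors <- function(beat_samples, rate, n_harmonics = 8L) {
  if (length(beat_samples) < 8L) stop("beat too short for spectral features")
  ngrid <- 64L
  u <- seq(0, 1, length.out = length(beat_samples))
  x <- stats::approx(u, beat_samples,
                     xout = (seq_len(ngrid) - 1L) / ngrid)$y
  x <- x - mean(x)
  X <- stats::fft(x) / ngrid
  k <- seq_len(n_harmonics) + 1L
  stats::setNames(c(Mod(X[k]), Arg(X[k])),
                  c(paste0("fft_mag_", seq_len(n_harmonics)),
                    paste0("fft_phase_", seq_len(n_harmonics))))
}

trailing_names <- function(base_names = base_feature_names(),
                           windows = c(10L, 50L)) {
  unlist(lapply(windows, function(w)
    c(paste0("trail_mean_", w, "(", base_names, ")"),
      paste0("trail_sd_", w, "(", base_names, ")"),
      paste0("trail_slope_", w, "(", base_names, ")"))))
}

## trailing mean/sd/slope of one column, expanding-window edges
trailing_one <- function(x, w) {
  n <- length(x)
  wl <- pmin(seq_len(n), w)
  lo <- seq_len(n) - wl
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x * x))
  k <- seq_len(n)
  csk <- c(0, cumsum(k * x))
  s1 <- cs[k + 1L] - cs[lo + 1L]
  s2 <- cs2[k + 1L] - cs2[lo + 1L]
  sky <- (csk[k + 1L] - csk[lo + 1L]) - lo * s1   # sum of j*y, j = 1..wl
  mu <- s1 / wl
  varr <- pmax(0, (s2 - s1 * s1 / wl) / pmax(wl - 1L, 1L))
  sx <- wl * (wl + 1) / 2
  sxx <- wl * (wl + 1) * (2 * wl + 1) / 6
  den <- sxx - sx * sx / wl
  slope <- ifelse(den > 0, (sky - sx * s1 / wl) / den, 0)
  cbind(mean = mu, sd = sqrt(varr), slope = slope)
}

#' Trailing-window statistics over the beat sequence
#'
#' For each base column and each window (in beats): the trailing mean, SD and
#' least-squares slope (per beat) over the most recent `window` beats; edges
#' use the available history.
#'
#' @param M Numeric matrix of base descriptors, one row per beat.
#' @param windows Integer vector of window lengths in beats.
#' @return Matrix with `3 * ncol(M) * length(windows)` named columns.
#' @export
trailing_stats <- function(M, windows = c(10L, 50L)) {
  cols <- lapply(windows, function(w) {
    per <- lapply(seq_len(ncol(M)), function(j) trailing_one(M[, j], w))
    cbind(do.call(cbind, lapply(per, function(p) p[, "mean"])),
          do.call(cbind, lapply(per, function(p) p[, "sd"])),
          do.call(cbind, lapply(per, function(p) p[, "slope"])))
  })
  out <- do.call(cbind, cols)
  colnames(out) <- trailing_names(colnames(M), windows)
  out
}

fill_forward <- function(x) {
  bad <- !is.finite(x)
  if (!any(bad)) return(list(x = x, n = 0L))
  n <- length(x)
  x[bad] <- NA_real_
  ok <- which(!is.na(x))
  if (length(ok) == 0L) return(list(x = rep(0, n), n = n))
  filled <- stats::approx(ok, x[ok], xout = seq_len(n), method = "constant",
                          rule = 2, f = 0)$y
  filled[seq_len(ok[1L] - 1L)] <- 0              # leading gap -> 0
  list(x = filled, n = sum(bad))
}

#' Extract the full feature matrix for one signal
#'
#' Orchestrates beat detection, base descriptors, pairwise expansion,
#' spectral descriptors, and trailing statistics into one named matrix with
#' at least 4200 columns. Non-finite entries are imputed with the previous
#' valid beat's value (0 when none exists) and counted.
#'
#' @param signal Preprocessed `uniform_series` (one variant).
#' @param variant `"non_detrended"` or `"detrended"`.
#' @param beats Optional precomputed `beat_landmarks`; detected when `NULL`.
#' @param trailing_windows Trailing windows in beats.
#' @return Object of class `feature_matrix`: `beat_times`, `variant`, and
#'   numeric matrix `X` (beats x features); the count of imputed entries in
#'   attribute `"imputed"`.
#' @export
extract_feature_matrix <- function(signal,
                                   variant = c("non_detrended", "detrended"),
                                   beats = NULL,
                                   trailing_windows = c(10L, 50L)) {
  variant <- match.arg(variant)
  if (is.null(beats)) beats <- detect_beats(signal)
  if (nrow(beats) == 0L) stop("no beats detected; cannot extract features")
  v <- signal$values
  n <- nrow(beats)
  base_M <- matrix(NA_real_, n, 48L,
                   dimnames = list(NULL, base_feature_names()))
  spec_M <- matrix(NA_real_, n, 16L)
  f1 <- beats$foot_idx; hr <- beats$halfrise_idx; pk <- beats$peak_idx
  il <- beats$infl_idx; f2 <- beats$end_idx
  u64 <- (seq_len(64L) - 1L) / 64L
  for (i in seq_len(n)) {
    seg <- v[f1[i]:f2[i]]
    base_M[i, ] <- base_descriptors_idx(
      seg, c(1L, hr[i] - f1[i] + 1L, pk[i] - f1[i] + 1L,
             il[i] - f1[i] + 1L, f2[i] - f1[i] + 1L), signal$rate)
    if (length(seg) >= 8L) {
      x <- stats::approx(seq(0, 1, length.out = length(seg)), seg,
                         xout = u64)$y
      X <- stats::fft(x - mean(x)) / 64
      spec_M[i, ] <- c(Mod(X[2:9]), Arg(X[2:9]))
    }
  }
  all_names <- feature_bank_names(trailing_windows)
  X <- matrix(NA_real_, n, length(all_names))
  colnames(X) <- all_names
  X[, 1:48] <- base_M
  X <- pairwise_expand_matrix(base_M, out = X, at = 49L)
  X[, 4561:4576] <- spec_M
  X[, 4577:ncol(X)] <- trailing_stats(base_M, trailing_windows)
  imputed <- 0L
  if (!all(is.finite(X))) {
    for (j in seq_len(ncol(X))) {
      if (!all(is.finite(X[, j]))) {
        f <- fill_forward(X[, j])
        X[, j] <- f$x
        imputed <- imputed + f$n
      }
    }
  }
  structure(list(beat_times = beats$foot_time, variant = variant, X = X),
            class = "feature_matrix", imputed = imputed)
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %s: %d beats x %d features (%d imputed)\n",
              x$variant, nrow(x$X), ncol(x$X),
              attr(x, "imputed") %||% 0L))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Names of the full feature bank
#' @param trailing_windows Trailing windows in beats.
#' @return Character vector of all feature names (>= 4200).
#' @export
feature_bank_names <- function(trailing_windows = c(10L, 50L)) {
  nm <- pairwise_names()
  c(base_feature_names(), nm$diff, nm$prod, nm$ratio,
    paste0("fft_mag_", 1:8), paste0("fft_phase_", 1:8),
    trailing_names(windows = trailing_windows))
}

#' Write a feature matrix as delimited text with a JSON sidecar
#' @param fm A `feature_matrix`.
#' @param path Output TSV path (sidecar written next to it).
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  d <- data.frame(beat_time = fm$beat_times, fm$X, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(variant = fm$variant, n_features = ncol(fm$X),
         imputed = attr(fm, "imputed") %||% 0L),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
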