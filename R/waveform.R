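#' Uniformly sampled series
#'
#' Lightweight container for a uniformly sampled signal (arterial pressure in
#' mmHg, or an upsampled volume log in mL).
#'
#' @param values Numeric vector of samples.
#' @param rate Sampling rate in Hz (> 0).
#' @param start_time Time of the first sample, seconds.
#' @return An object of class `uniform_series` with fields `values`, `rate`,
#'   `start_time`.
#' @export
uniform_series <- function(values, rate, start_time = 0) {
  stopifnot(is.numeric(values), length(values) >= 1L,
            is.numeric(rate), length(rate) == 1L, rate > 0)
  structure(list(values = as.numeric(values), rate = as.numeric(rate),
                 start_time = as.numeric(start_time)),
            class = "uniform_series")
}

#' @export
print.uniform_series <- function(x, ...) {
  cat(sprintf("<uniform_series> %d samples @ %g Hz, t = [%.2f, %.2f] s\n",
              length(x$values), x$rate, x$start_time,
              x$start_time + (length(x$values) - 1L) / x$rate))
  invisible(x)
}

#' Sample times of a uniform series
#' @param series A `uniform_series`.
#' @return Numeric vector of times in seconds.
#' @export
series_times <- function(series) {
  series$start_time + (seq_along(series$values) - 1L) / series$rate
}

## Causal FIR convolution with reflective edge padding and group-delay
## compensation, so the output is time-aligned and equal-length.
fir_apply <- function(values, coef) {
  ord <- length(coef) - 1L
  half <- ord %/% 2L
  n <- length(values)
  if (n <= ord) stop("signal shorter than the filter order")
  pad_l <- values[(ord + 1L):2L]            # reflect, excluding the endpoint
  pad_r <- values[(n - 1L):(n - ord)]
  x <- c(pad_l, values, pad_r)
  y <- stats::filter(x, coef, method = "convolution", sides = 1L)
  y <- as.numeric(y)
  # causal filter output at index i uses x[i-ord..i]; compensate delay half
  y[(ord + half + 1L):(ord + half + n)]
}

#' Resample a uniform series to a new rate
#'
#' Downsampling applies an anti-alias FIR lowpass before decimation;
#' upsampling (used for the 1/5 Hz volume logs) interpolates linearly
#' between ticks.
#'
#' @param series A `uniform_series`.
#' @param target_rate Target sampling rate, Hz.
#' @return A `uniform_series` at `target_rate` spanning the same interval.
#' @export
resample_uniform <- function(series, target_rate) {
  stopifnot(inherits(series, "uniform_series"), target_rate > 0)
  n <- length(series$values)
  if (n < 2L) stop("cannot resample an empty or single-sample series")
  t_old <- series_times(series)
  duration <- (n - 1L) / series$rate
  n_new <- floor(duration * target_rate) + 1L
  t_new <- series$start_time + (seq_len(n_new) - 1L) / target_rate
  v <- series$values
  if (target_rate < series$rate) {
    # anti-alias lowpass at 80% of the new Nyquist
    cutoff <- 0.8 * target_rate / 2
    ord <- 64L
    if (n > ord + 1L) {
      coef <- signal::fir1(ord, 2 * cutoff / series$rate, type = "low")
      v <- fir_apply(v, coef / sum(coef))
    }
  }
  out <- stats::approx(t_old, v, xout = t_new, rule = 2)$y
  uniform_series(out, target_rate, series$start_time)
}

#' FIR window lowpass filter
#'
#' Window-method (Hamming) FIR lowpass with unit DC gain, applied with
#' group-delay compensation and reflective edge padding so the output is
#' time-aligned and the same length as the input.
#'
#' @param signal A `uniform_series` (arterial pressure at 100 Hz in the
#'   standard pipeline).
#' @param order Filter order (number of taps minus one); default 512.
#' @param cutoff Cutoff frequency in Hz; default 6.
#' @return Filtered `uniform_series`.
#' @export
fir_lowpass <- function(signal, order = 512L, cutoff = 6) {
  stopifnot(inherits(signal, "uniform_series"), order >= 2, cutoff > 0,
            cutoff < signal$rate / 2)
  if (length(signal$values) <= order)
    stop("signal shorter than the filter order")
  coef <- signal::fir1(as.integer(order), 2 * cutoff / signal$rate,
                       type = "low")
  coef <- coef / sum(coef)                  # exact unit DC gain
  uniform_series(fir_apply(signal$values, coef), signal$rate,
                 signal$start_time)
}

#' Polynomial detrending
#'
#' Least-squares polynomial fit over the full record; the detrended signal is
#' the residual, so `detrended + trend` reconstructs the input exactly.
#'
#' @param signal A `uniform_series`.
#' @param degree Polynomial degree; default 5.
#' @return List with `detrended` and `trend`, both `uniform_series`.
#' @export
detrend_polynomial <- function(signal, degree = 5L) {
  stopifnot(inherits(signal, "uniform_series"), degree >= 1)
  n <- length(signal$values)
  if (n <= degree + 1L) stop("signal too short for the requested degree")
  tt <- series_times(signal)
  if (diff(range(tt)) <= 0) stop("degenerate (constant-time) input")
  fit <- stats::lm.fit(cbind(1, stats::poly(tt, degree = degree)),
                       signal$values)
  trend <- signal$values - fit$residuals
  list(detrended = uniform_series(fit$residuals, signal$rate,
                                  signal$start_time),
       trend = uniform_series(trend, signal$rate, signal$start_time))
}

#' Detect beats and pulse landmarks
#'
#' Segments a filtered arterial waveform into beats. Feet are local minima
#' preceding steep upstrokes (adaptive slope threshold, 0.25 s refractory
#' period); the systolic peak is the maximum between consecutive feet; the
#' half-rise is the first upstroke crossing of the foot/peak midpoint; the
#' first inflection point is the first zero-crossing of the second derivative
#' after the peak, and when none exists before the next foot the half-drop
#' (first downstroke crossing of the peak/next-foot midpoint) is used instead
#' and flagged. The segment end is the next foot.
#'
#' @param signal A `uniform_series` (lowpass-filtered pressure).
#' @param min_pulse_pressure Beats with peak-foot amplitude below this (mmHg)
#'   are skipped as malformed.
#' @return A data frame of class `beat_landmarks`, one row per beat, with
#'   `*_time` / `*_value` columns for foot, half-rise, peak,
#'   inflection-or-half-drop (plus `infl_kind`), and segment end. The number
#'   of skipped malformed beats is stored in the `"skipped"` attribute.
#' @export
detect_beats <- function(signal, min_pulse_pressure = 1.0) {
  stopifnot(inherits(signal, "uniform_series"))
  v <- signal$values
  n <- length(v)
  rate <- signal$rate
  refractory <- as.integer(round(0.25 * rate))
  empty <- function() {
    warning("no beats detected")
    structure(data.frame(), class = c("beat_landmarks", "data.frame"),
              skipped = 0L)
  }
  if (n < 2L * refractory) return(empty())

  d <- c(0, diff(v)) * rate                     # mmHg/s
  # blockwise adaptive slope threshold (10 s blocks) tracks shrinking pulses
  block <- as.integer(round(10 * rate))
  nb <- ceiling(n / block)
  idx_block <- rep(seq_len(nb), each = block, length.out = n)
  bmax <- tapply(d, idx_block, max)
  thr <- 0.35 * pmax(bmax[idx_block], 1e-6)

  cand <- which(d > thr)
  if (length(cand) == 0L) return(empty())
  starts <- cand[c(TRUE, diff(cand) > 1L)]      # run starts of steep upstroke
  # refractory filtering
  keep <- integer(0)
  last <- -Inf
  for (s in starts) {
    if (s - last > refractory) { keep <- c(keep, as.integer(s)); last <- s }
  }
  if (length(keep) < 2L) return(empty())

  feet <- vapply(keep, function(s) {
    lo <- max(1L, s - as.integer(round(0.4 * rate)))
    lo + which.min(v[lo:s]) - 1L
  }, integer(1))
  feet <- sort(unique(feet))
  feet <- feet[c(TRUE, diff(feet) > refractory)]
  if (length(feet) < 2L) return(empty())

  rows <- vector("list", length(feet) - 1L)
  skipped <- 0L
  for (k in seq_len(length(feet) - 1L)) {
    f1 <- feet[k]; f2 <- feet[k + 1L]
    seg <- v[f1:f2]
    pk <- f1 + which.max(seg) - 1L
    if (pk <= f1 + 1L || pk >= f2 - 1L || v[pk] - v[f1] < min_pulse_pressure) {
      skipped <- skipped + 1L
      next
    }
    mid_up <- (v[f1] + v[pk]) / 2
    hr_rel <- which(v[(f1 + 1L):pk] >= mid_up)
    if (length(hr_rel) == 0L) { skipped <- skipped + 1L; next }
    hr <- f1 + hr_rel[1L]
    if (!(f1 < hr && hr < pk)) { skipped <- skipped + 1L; next }
    # first inflection: second-derivative zero-crossing after the peak
    infl <- NA_integer_; kind <- "half-drop"
    if (pk + 2L <= f2 - 2L) {
      j <- (pk + 2L):(f2 - 2L)   # keep clear of the slope corner at the foot
      d2 <- v[j + 1L] - 2 * v[j] + v[j - 1L]
      cross <- which(d2[-length(d2)] < 0 & d2[-1L] >= 0)
      if (length(cross) > 0L) {
        infl <- j[cross[1L] + 1L]
        kind <- "inflection"
      }
    }
    if (is.na(infl)) {
      mid_dn <- (v[pk] + v[f2]) / 2
      dn_rel <- which(v[pk:f2] <= mid_dn)
      if (length(dn_rel) == 0L) { skipped <- skipped + 1L; next }
      infl <- pk + dn_rel[1L] - 1L
    }
    if (!(pk < infl && infl <= f2)) { skipped <- skipped + 1L; next }
    rows[[k]] <- data.frame(
      foot_idx = f1, halfrise_idx = hr, peak_idx = pk, infl_idx = infl,
      end_idx = f2, infl_kind = kind, stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty())
  b <- do.call(rbind, rows)
  t0 <- signal$start_time
  out <- data.frame(
    foot_time = t0 + (b$foot_idx - 1L) / rate,      foot_value = v[b$foot_idx],
    halfrise_time = t0 + (b$halfrise_idx - 1L) / rate,
    halfrise_value = v[b$halfrise_idx],
    peak_time = t0 + (b$peak_idx - 1L) / rate,      peak_value = v[b$peak_idx],
    infl_time = t0 + (b$infl_idx - 1L) / rate,      infl_value = v[b$infl_idx],
    infl_kind = b$infl_kind,
    end_time = t0 + (b$end_idx - 1L) / rate,        end_value = v[b$end_idx],
    foot_idx = b$foot_idx, halfrise_idx = b$halfrise_idx,
    peak_idx = b$peak_idx, infl_idx = b$infl_idx, end_idx = b$end_idx,
    stringsAsFactors = FALSE)
  structure(out, class = c("beat_landmarks", "data.frame"), skipped = skipped)
}

#' Preprocess a raw arterial waveform
#'
#' Standard pipeline: resample to 100 Hz, 512th-order FIR lowpass at 6 Hz,
#' and (for the detrended variant) 5th-order polynomial detrending.
#'
#' @param waveform Raw `uniform_series` (e.g. 500 Hz analog pressure).
#' @param variant `"non_detrended"` or `"detrended"`.
#' @param target_rate Working rate, Hz; default 100.
#' @return A filtered (and possibly detrended) `uniform_series` at
#'   `target_rate`.
#' @export
preprocess_waveform <- function(waveform,
                                variant = c("non_detrended", "detrended"),
                                target_rate = 100) {
  variant <- match.arg(variant)
  x <- resample_uniform(waveform, target_rate)
  x <- fir_lowpass(x, order = 512L, cutoff = 6)
  if (variant == "detrended") x <- detrend_polynomial(x, degree = 5L)$detrended
  x
}

#' Write / read a uniform series as two-column delimited text
#' @param series A `uniform_series`.
#' @param path Output file path.
#' @return `read_series` returns a `uniform_series`.
#' @export
write_series <- function(series, path) {
  stopifnot(inherits(series, "uniform_series"))
  utils::write.table(
    data.frame(time_s = series_times(series), value = series$values),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a beat-landmark table as delimited text
#'
#' One row per beat with the time, value (and kind, for the
#' inflection-or-half-drop landmark) of each of the five landmarks.
#'
#' @param beats A `beat_landmarks` table from [detect_beats()].
#' @param path Output TSV path.
#' @export
write_beats <- function(beats, path) {
  stopifnot(inherits(beats, "beat_landmarks"))
  cols <- c("foot_time", "foot_value", "halfrise_time", "halfrise_value",
            "peak_time", "peak_value", "infl_time", "infl_value",
            "infl_kind", "end_time", "end_value")
  utils::write.table(as.data.frame(beats)[, cols], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  rate <- 1 / stats::median(diff(d[[1L]]))
  uniform_series(d[[2L]], rate, d[[1L]][1L])
}
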