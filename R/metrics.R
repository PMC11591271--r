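## Ground-truth blood-loss metrics.
##
## BLVM: 1 - hemorrhaged volume / total shed volume, with infused whole blood
## added back after the point of maximum blood loss, so the balance
## "recovers" during resuscitation. PEBL: net shed volume over the estimated
## blood volume (60 mL/kg x weight for swine). HemArea: time-integral of net
## blood loss (mL.min). CRM: 1 - LBNP/LBNP_HDD on [0, 1].

#' Metric series
#'
#' A time-aligned metric (ground truth or prediction).
#'
#' @param times Times, seconds.
#' @param values Metric values (unitless for BLVM/PEBL/CRM; mL.min for
#'   HemArea; mmHg for MAP).
#' @param name One of `"BLVM"`, `"PEBL"`, `"HemArea"`, `"CRM"`, `"MAP"`, or a
#'   free label for predictions.
#' @return Object of class `metric_series`.
#' @export
metric_series <- function(times, values, name = "metric") {
  stopifnot(length(times) == length(values))
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 name = name), class = "metric_series")
}

#' @export
print.metric_series <- function(x, ...) {
  cat(sprintf("<metric_series> %s: %d points, range [%.4g, %.4g]\n",
              x$name, length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Build a volume series from a subject's volume log
#'
#' Upsamples the 1/5 Hz cumulative hemorrhage/infusion log to a working rate
#' by linear interpolation and derives the total shed volume and net balance.
#'
#' @param record A `subject_record`.
#' @param rate Working rate, Hz; default 100.
#' @return A list of class `volume_series`: `times`, `cum_hemorrhaged`,
#'   `cum_wb_infused`, `net_balance` (all aligned), `total_shed` (mL).
#' @export
volume_series <- function(record, rate = 100) {
  stopifnot(inherits(record, "subject_record"))
  vl <- record$volume_log
  t_end <- max(vl$time_s)
  tt <- seq(0, t_end, by = 1 / rate)
  hem <- stats::approx(vl$time_s, vl$cum_hem_ml, xout = tt, rule = 2)$y
  wb <- stats::approx(vl$time_s, vl$cum_wb_ml, xout = tt, rule = 2)$y
  structure(list(times = tt, cum_hemorrhaged = hem, cum_wb_infused = wb,
                 net_balance = hem - wb, total_shed = max(hem)),
            class = "volume_series")
}

#' Blood Loss Volume Metric (BLVM)
#'
#' Before the time of maximum blood loss, `1 - cum_hemorrhaged / total_shed`;
#' from that point on, the value at maximum loss plus
#' `cum_wb_infused / total_shed` (infused whole blood is added instead of
#' subtracted, so the balance recovers). Under an infusion volume smaller
#' than the shed volume the metric stays in \[0, 1\].
#'
#' @param v A `volume_series`.
#' @param phases Named phase times (unused in the computation; accepted for
#'   interface symmetry).
#' @return A `metric_series` named `"BLVM"`.
#' @export
compute_blvm <- function(v, phases = NULL) {
  stopifnot(inherits(v, "volume_series"))
  if (v$total_shed <= 0) stop("total shed volume is zero")
  i_max <- which.max(v$cum_hemorrhaged)           # first point of maximum loss
  val <- 1 - v$cum_hemorrhaged / v$total_shed
  post <- seq_along(val) >= i_max
  val[post] <- (1 - v$cum_hemorrhaged[i_max] / v$total_shed) +
    v$cum_wb_infused[post] / v$total_shed
  metric_series(v$times, val, "BLVM")
}

#' Percent Estimated Blood Loss (PEBL)
#'
#' Net blood loss over the estimated blood volume (`ebv_constant` mL/kg times
#' weight). Whole-blood infusion "gives back" shed blood, so the net balance
#' is used; clipped below at 0.
#'
#' @param v A `volume_series`.
#' @param weight_kg Subject weight, kg (> 0).
#' @param ebv_constant Estimated blood volume constant, mL/kg: 60 for swine,
#'   80 for canines.
#' @return A `metric_series` named `"PEBL"`.
#' @export
compute_pebl <- function(v, weight_kg, ebv_constant = 60) {
  stopifnot(inherits(v, "volume_series"))
  if (!is.numeric(weight_kg) || weight_kg <= 0)
    stop("weight must be strictly positive")
  metric_series(v$times, pmax(0, v$net_balance / (ebv_constant * weight_kg)),
                "PEBL")
}

#' Hemorrhage area (direct form)
#'
#' Running trapezoidal integral of net blood loss over time, in mL.min.
#'
#' @param v A `volume_series`.
#' @return A `metric_series` named `"HemArea"`.
#' @export
compute_hemarea <- function(v) {
  stopifnot(inherits(v, "volume_series"))
  area <- pracma::cumtrapz(v$times / 60, v$net_balance)
  metric_series(v$times, as.numeric(area), "HemArea")
}

#' Hemorrhage area from BLVM (legacy indirect form)
#'
#' Running sum of `|BLVM - 1| * dt` (dt in minutes). Proportional to
#' [compute_hemarea()] with the total-shed normalization undone, provided no
#' infusion occurs before the point of maximum loss.
#'
#' @param blvm A `metric_series` named `"BLVM"`.
#' @return A `metric_series` named `"HemArea"` (units: minutes of BLVM
#'   deficit).
#' @export
hemarea_from_blvm <- function(blvm) {
  stopifnot(inherits(blvm, "metric_series"))
  dt <- diff(blvm$times) / 60
  mid <- (abs(blvm$values - 1)[-1L] + abs(blvm$values - 1)[-length(blvm$values)]) / 2
  metric_series(blvm$times, c(0, cumsum(mid * dt)), "HemArea")
}

#' Compensatory Reserve Measurement (CRM)
#'
#' `1 - LBNP(t) / LBNP_HDD` on \[0, 1\]: 1 at full reserve, 0 at the point of
#' hemodynamic decompensation.
#'
#' @param rec An `lbnp_record`.
#' @param rate Output sampling rate, Hz.
#' @return A `metric_series` named `"CRM"` (stepwise, following the LBNP
#'   staircase).
#' @export
compute_crm <- function(rec, rate = 1) {
  stopifnot(inherits(rec, "lbnp_record"))
  if (rec$lbnp_hdd <= 0) stop("lbnp_hdd must be strictly positive")
  t_end <- length(rec$waveform$values) / rec$waveform$rate
  tt <- seq(0, t_end, by = 1 / rate)
  lbnp <- stats::approx(rec$lbnp_schedule$time_s, rec$lbnp_schedule$lbnp_mmhg,
                        xout = tt, method = "constant", rule = 2)$y
  metric_series(tt, 1 - lbnp / rec$lbnp_hdd, "CRM")
}

#' Trailing moving mean
#'
#' Causal moving mean over `min(window, available history)` points; length
#' preserved. Window 50 is the standard prediction smoother.
#'
#' @param series A `metric_series` or numeric vector.
#' @param window Window size in points (>= 1).
#' @return Same type as the input.
#' @export
moving_mean <- function(series, window = 50L) {
  if (window < 1L) stop("window must be at least 1")
  smooth_vec <- function(x) {
    n <- length(x)
    cs <- cumsum(x)
    w <- pmin(seq_len(n), window)
    lo <- seq_len(n) - w                          # index before window start
    (cs - c(0, cs)[lo + 1L]) / w
  }
  if (inherits(series, "metric_series"))
    metric_series(series$times, smooth_vec(series$values), series$name)
  else smooth_vec(series)
}

#' Shift diagnostic: linear regression of truth on prediction
#'
#' Ordinary least squares of `truth` on `pred`; reported for diagnostics only
#' (no automatic correction is applied).
#'
#' @param pred,truth `metric_series` or numeric vectors of equal length.
#' @return List with `slope`, `intercept`, `r2`.
#' @export
shift_regression <- function(pred, truth) {
  p <- if (inherits(pred, "metric_series")) pred$values else pred
  y <- if (inherits(truth, "metric_series")) truth$values else truth
  stopifnot(length(p) == length(y), length(p) >= 2L)
  if (stats::var(p) == 0) stop("zero-variance prediction")
  fit <- stats::lm.fit(cbind(1, p), y)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  list(slope = unname(fit$coefficients[2L]),
       intercept = unname(fit$coefficients[1L]),
       r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_)
}

#' Sample a metric series at arbitrary times
#' @param series A `metric_series`.
#' @param times Times, s.
#' @return A `metric_series` at `times` (linear interpolation).
#' @export
sample_metric_at <- function(series, times) {
  v <- stats::approx(series$times, series$values, xout = times, rule = 2)$y
  metric_series(times, v, series$name)
}

#' Write / read a metric series as delimited text with a JSON sidecar
#' @param series A `metric_series`.
#' @param path Output TSV path; the sidecar is written at `<path>.json`.
#' @return `read_metric_series` returns a `metric_series`.
#' @export
write_metric_series <- function(series, path) {
  stopifnot(inherits(series, "metric_series"))
  utils::write.table(data.frame(time_s = series$times, value = series$values),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(name = series$name, n = length(series$values)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_metric_series
#' @export
read_metric_series <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  metric_series(d$time_s, d$value, meta$name)
}

#' Ground-truth metrics for one subject at beat times
#'
#' Computes BLVM, PEBL, and HemArea at the working rate from the volume log,
#' then samples them at the supplied beat times; also returns per-beat MAP
#' (mean filtered pressure per beat).
#'
#' @param record A `subject_record`.
#' @param beats A `beat_landmarks` table from [detect_beats()].
#' @param signal The preprocessed `uniform_series` the beats were detected on.
#' @return Named list of `metric_series` (`BLVM`, `PEBL`, `HemArea`, `MAP`)
#'   at beat foot times.
#' @export
subject_truth_metrics <- function(record, beats, signal) {
  v <- volume_series(record, rate = signal$rate)
  bt <- beats$foot_time
  map_beat <- vapply(seq_len(nrow(beats)), function(i)
    mean(signal$values[beats$foot_idx[i]:beats$end_idx[i]]), numeric(1))
  list(BLVM = sample_metric_at(compute_blvm(v), bt),
       PEBL = sample_metric_at(compute_pebl(v, record$weight_kg), bt),
       HemArea = sample_metric_at(compute_hemarea(v), bt),
       MAP = metric_series(bt, map_beat, "MAP"))
}
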