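## Model-comparison statistics: goodness of fit, percentile-sweep ROC and
## AUROC over the baseline + initial-hemorrhage region, hemorrhage detection
## time (5th-percentile baseline threshold held for 100 consecutive
## readings), resuscitation responsiveness (5-minute window ratio), and the
## coefficient of variation.

#' Orientation of each metric under hemorrhage
#'
#' BLVM, CRM and MAP decrease during blood loss (a reading is
#' hemorrhage-positive when below threshold); PEBL and HemArea increase.
#'
#' @param name Metric name.
#' @return `"low_is_positive"` or `"high_is_positive"`.
#' @export
metric_orientation <- function(name) {
  if (name %in% c("PEBL", "HemArea")) "high_is_positive" else "low_is_positive"
}

#' Goodness of fit
#'
#' `r2 = 1 - SS_res / SS_tot` and root mean squared error; optionally RMSE is
#' normalized by the maximum |truth| over the evaluation set (pass
#' `max_value` to normalize by a cross-validation-wide maximum).
#'
#' @param pred,truth `metric_series` or numeric vectors, equal length >= 2.
#' @param normalize_by_max Divide RMSE by `max_value`.
#' @param max_value Normalizer; defaults to `max(abs(truth))`.
#' @return Named vector `c(r2, rmse)`; `r2` is `NA` for zero-variance truth.
#' @export
goodness_of_fit <- function(pred, truth, normalize_by_max = FALSE,
                            max_value = NULL) {
  p <- if (inherits(pred, "metric_series")) pred$values else pred
  y <- if (inherits(truth, "metric_series")) truth$values else truth
  stopifnot(length(p) == length(y), length(p) >= 2L)
  ss_res <- sum((y - p)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  rmse <- sqrt(mean((y - p)^2))
  if (normalize_by_max) {
    if (is.null(max_value)) max_value <- max(abs(y))
    rmse <- rmse / max_value
  }
  c(r2 = r2, rmse = rmse)
}

#' Percentile-sweep ROC curve
#'
#' Threshold grid: 100 equal steps across the 5th-95th percentile of the
#' metric over the evaluated region (baseline + initial hemorrhage). A
#' sample is called hemorrhage-positive when the metric is beyond the
#' threshold in the declared orientation; AUROC by the trapezoid rule with
#' anchoring at (0,0) and (1,1).
#'
#' @param values Metric values over the region.
#' @param labels Logical, `TRUE` for hemorrhage samples.
#' @param orientation `"low_is_positive"` or `"high_is_positive"`.
#' @param n_thresholds Number of thresholds; default 100.
#' @return Object of class `roc_curve`: `thresholds`, `tpr`, `fpr`, `auroc`,
#'   `orientation`.
#' @export
percentile_roc <- function(values, labels,
                           orientation = c("low_is_positive",
                                           "high_is_positive"),
                           n_thresholds = 100L) {
  orientation <- match.arg(orientation)
  stopifnot(length(values) == length(labels))
  labels <- as.logical(labels)
  if (all(labels) || !any(labels))
    stop("both classes must be present in the evaluated region")
  q <- stats::quantile(values, c(0.05, 0.95), names = FALSE)
  thr <- seq(q[1L], q[2L], length.out = n_thresholds)
  npos <- sum(labels); nneg <- sum(!labels)
  tpr <- numeric(n_thresholds); fpr <- numeric(n_thresholds)
  for (i in seq_len(n_thresholds)) {
    call_pos <- if (orientation == "low_is_positive") values < thr[i]
                else values > thr[i]
    tpr[i] <- sum(call_pos & labels) / npos
    fpr[i] <- sum(call_pos & !labels) / nneg
  }
  o <- order(fpr, tpr)
  fx <- c(0, fpr[o], 1); fy <- c(0, tpr[o], 1)
  auroc <- pracma::trapz(fx, fy)
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr,
                 auroc = auroc, orientation = orientation),
            class = "roc_curve")
}

#' Hemorrhage detection time
#'
#' Threshold: the 5th percentile of the baseline readings in the adverse
#' direction (the 95th for metrics that rise under hemorrhage). Returns the
#' time, relative to hemorrhage onset, of the first reading of the earliest
#' run of at least `run_length` consecutive beyond-threshold readings within
#' the hemorrhage window; when no such run exists the window duration (the
#' cap) is returned.
#'
#' @param metric A `metric_series` at reading (beat) cadence, smoothed.
#' @param phases Named phase times with `baseline_start`,
#'   `hemorrhage_start`, `resus_start`.
#' @param orientation See [metric_orientation()].
#' @param run_length Required run of consecutive beyond-threshold readings.
#' @return Detection time in seconds (capped at the hemorrhage-window
#'   duration).
#' @export
detection_time <- function(metric, phases,
                           orientation = c("low_is_positive",
                                           "high_is_positive"),
                           run_length = 100L) {
  orientation <- match.arg(orientation)
  tt <- metric$times; vv <- metric$values
  base <- vv[tt >= phases[["baseline_start"]] &
               tt < phases[["hemorrhage_start"]]]
  if (length(base) == 0L) stop("empty baseline region")
  win <- tt >= phases[["hemorrhage_start"]] & tt < phases[["resus_start"]]
  cap <- phases[["resus_start"]] - phases[["hemorrhage_start"]]
  wt <- tt[win]; wv <- vv[win]
  if (length(wv) == 0L) return(cap)
  if (orientation == "low_is_positive") {
    thr <- stats::quantile(base, 0.05, names = FALSE)
    beyond <- wv < thr
  } else {
    thr <- stats::quantile(base, 0.95, names = FALSE)
    beyond <- wv > thr
  }
  r <- rle(beyond)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= run_length)
  if (length(hit) == 0L) return(cap)
  wt[starts[hit[1L]]] - phases[["hemorrhage_start"]]
}

#' Resuscitation responsiveness ratio
#'
#' Mean metric value over the final `window` seconds of whole-blood
#' resuscitation divided by the mean over the `window` seconds immediately
#' before resuscitation.
#'
#' @param metric A `metric_series`.
#' @param phases Named phase times with `resus_start`, `resus_end`.
#' @param window Window length, s; default 300 (5 min).
#' @return Ratio (post / pre). A near-zero denominator is guarded and
#'   flagged via the `"guarded"` attribute.
#' @export
resuscitation_ratio <- function(metric, phases, window = 300) {
  tt <- metric$times; vv <- metric$values
  pre <- vv[tt >= phases[["resus_start"]] - window &
              tt < phases[["resus_start"]]]
  post <- vv[tt >= phases[["resus_end"]] - window &
               tt <= phases[["resus_end"]]]
  if (length(pre) == 0L || length(post) == 0L)
    stop("both 5-minute windows must lie inside the record")
  den <- mean(pre)
  guarded <- FALSE
  if (abs(den) < 1e-9) {
    warning("near-zero pre-resuscitation mean; ratio guarded")
    den <- sign(den + (den == 0)) * 1e-9
    guarded <- TRUE
  }
  structure(mean(post) / den, guarded = guarded)
}

#' Coefficient of variation
#' @param values Numeric vector (length >= 2, nonzero mean).
#' @return `100 * sd / mean`, percent.
#' @export
coefficient_of_variation <- function(values) {
  stopifnot(length(values) >= 2L)
  m <- mean(values)
  if (m == 0) stop("zero mean; coefficient of variation undefined")
  100 * stats::sd(values) / m
}

#' Aggregate evaluation report over a LOSO result
#'
#' Per blind-test record and per metric: R2/RMSE overall and by region
#' (baseline; hemorrhage including the shock hold; whole-blood
#' resuscitation, trend-only), AUROC over baseline + initial hemorrhage,
#' detection time (and MAP's detection time on the same subject),
#' resuscitation ratio; plus averages and the coefficient of variation of
#' the ratios. Region columns use the suffixes `_base`, `_hem`, `_resus`.
#'
#' @param loso A `loso_result`.
#' @param subjects Named list: subject id -> list with `phases` (named
#'   times) and `truth` (named list of `metric_series`, including `MAP`).
#' @param normalize_rmse Metrics whose RMSE is reported normalized by the
#'   maximum truth value over the whole LOSO process.
#' @return Object of class `evaluation_report`: `per_record` (data frame),
#'   `summary` (data frame of means/medians per metric), `map` (MAP
#'   detection/ratio reference values), `resus_trend_only = TRUE`.
#' @export
build_report <- function(loso, subjects, normalize_rmse = "HemArea") {
  stopifnot(inherits(loso, "loso_result"))
  recs <- loso$records
  out <- vector("list", nrow(recs))
  # LOSO-wide truth maxima for normalized RMSE
  tmax <- lapply(unique(recs$metric), function(m)
    max(abs(unlist(lapply(subjects, function(s) s$truth[[m]]$values)))))
  names(tmax) <- unique(recs$metric)

  region_gof <- function(pred, truth, lo, hi, max_value, normalize) {
    sel <- pred$times >= lo & pred$times < hi
    if (sum(sel) < 2L) return(c(r2 = NA_real_, rmse = NA_real_))
    goodness_of_fit(pred$values[sel], truth$values[sel],
                    normalize_by_max = normalize, max_value = max_value)
  }

  for (i in seq_len(nrow(recs))) {
    m <- recs$metric[i]; s <- recs$blind_subject[i]
    info <- subjects[[s]]
    if (is.null(info$phases)) stop("missing region annotations for ", s)
    ph <- info$phases
    pred <- loso$predictions[[m]][[s]]
    truth <- sample_metric_at(info$truth[[m]], pred$times)
    orient <- metric_orientation(m)
    norm <- m %in% normalize_rmse
    roc_sel <- pred$times < ph[["hold_start"]]
    roc <- percentile_roc(pred$values[roc_sel],
                          pred$times[roc_sel] >= ph[["hemorrhage_start"]],
                          orient)
    map_s <- sample_metric_at(info$truth[["MAP"]], pred$times)
    map_s$values <- moving_mean(map_s$values, 50L)
    gof_all <- goodness_of_fit(pred, truth, normalize_by_max = norm,
                               max_value = tmax[[m]])
    gb <- region_gof(pred, truth, ph[["baseline_start"]],
                     ph[["hemorrhage_start"]], tmax[[m]], norm)
    gh <- region_gof(pred, truth, ph[["hemorrhage_start"]],
                     ph[["resus_start"]], tmax[[m]], norm)
    gr <- region_gof(pred, truth, ph[["resus_start"]], ph[["resus_end"]],
                     tmax[[m]], norm)
    out[[i]] <- data.frame(
      metric = m, model_id = recs$model_id[i], blind_subject = s,
      r2 = gof_all[["r2"]], rmse = gof_all[["rmse"]],
      r2_base = gb[["r2"]], rmse_base = gb[["rmse"]],
      r2_hem = gh[["r2"]], rmse_hem = gh[["rmse"]],
      r2_resus = gr[["r2"]], rmse_resus = gr[["rmse"]],
      auroc = roc$auroc,
      detection_time_s = detection_time(pred, ph, orient),
      map_detection_time_s = detection_time(map_s, ph, "low_is_positive"),
      resus_ratio = as.numeric(resuscitation_ratio(pred, ph)),
      map_resus_ratio = as.numeric(resuscitation_ratio(map_s, ph)),
      stringsAsFactors = FALSE)
  }
  per_record <- do.call(rbind, out)
  summarize <- function(d) {
    data.frame(metric = d$metric[1L], n_records = nrow(d),
               r2_mean = mean(d$r2), r2_median = stats::median(d$r2),
               rmse_mean = mean(d$rmse),
               auroc_mean = mean(d$auroc),
               detection_time_mean_s = mean(d$detection_time_s),
               map_detection_time_mean_s = mean(d$map_detection_time_s),
               resus_ratio_mean = mean(d$resus_ratio),
               resus_ratio_cv_pct = coefficient_of_variation(d$resus_ratio),
               map_resus_ratio_mean = mean(d$map_resus_ratio),
               stringsAsFactors = FALSE)
  }
  summ <- do.call(rbind, lapply(split(per_record, per_record$metric),
                                summarize))
  rownames(summ) <- NULL
  structure(list(per_record = per_record, summary = summ,
                 resus_trend_only = TRUE),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report> (resuscitation region: trend-only)\n")
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}
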