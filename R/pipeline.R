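## End-to-end orchestration: simulate -> preprocess -> features -> targets
## -> LOSO -> report, and the CRM transfer (train on LBNP, apply to swine).

#' Process one subject record into features and targets
#'
#' Resamples to 100 Hz, filters, optionally detrends, detects beats,
#' extracts the feature matrix, and computes ground-truth metrics at beat
#' times.
#'
#' @param record A `subject_record`.
#' @param variant Signal variant for feature extraction.
#' @return List: `features` (`feature_matrix`), `truth` (named list of
#'   `metric_series` incl. `MAP`), `phases`, `beats`, `subject_id`,
#'   `group_id`.
#' @export
process_subject <- function(record,
                            variant = c("non_detrended", "detrended")) {
  variant <- match.arg(variant)
  sig <- preprocess_waveform(record$waveform, variant)
  beats <- detect_beats(sig)
  fm <- extract_feature_matrix(sig, variant, beats = beats)
  truth <- subject_truth_metrics(record, beats, sig)
  list(features = fm, truth = truth, phases = record$phases, beats = beats,
       subject_id = record$subject_id, group_id = record$group_id)
}

#' Run the full swine LOSO pipeline
#'
#' Simulates (or takes) a cohort, processes every subject, runs the 4-group
#' leave-one-subject-group-out procedure for the requested target metrics,
#' and builds the evaluation report.
#'
#' @param config A [sim_config()].
#' @param targets Metric names to model (subset of `"BLVM"`, `"PEBL"`,
#'   `"HemArea"`).
#' @param variant Signal variant.
#' @param params [boosted_tree_params()].
#' @param cohort Optional pre-simulated cohort (list of `subject_record`).
#' @param processed Optional pre-processed subjects from [process_subject()].
#' @return List: `loso` (`loso_result`), `report` (`evaluation_report`),
#'   `subjects` (per-subject truth/phases), `groups`, `config`.
#' @export
run_swine_pipeline <- function(config = sim_config(),
                               targets = c("BLVM", "PEBL"),
                               variant = "non_detrended",
                               params = boosted_tree_params(),
                               cohort = NULL, processed = NULL) {
  if (is.null(processed)) {
    if (is.null(cohort)) cohort <- simulate_swine_cohort(config)
    processed <- lapply(cohort, process_subject, variant = variant)
    names(processed) <- vapply(processed, `[[`, "", "subject_id")
  }
  groups <- vapply(processed, `[[`, integer(1), "group_id")
  features <- lapply(processed, `[[`, "features")
  target_lists <- lapply(targets, function(m)
    lapply(processed, function(p) p$truth[[m]]))
  names(target_lists) <- targets
  loso <- run_loso(features, target_lists, groups, params = params)
  subjects <- lapply(processed, function(p)
    list(phases = p$phases, truth = p$truth))
  report <- build_report(loso, subjects)
  list(loso = loso, report = report, subjects = subjects, groups = groups,
       config = config)
}

#' Train a CRM model on synthetic LBNP records
#'
#' Extracts features from each LBNP subject's waveform, samples the
#' ground-truth compensatory reserve (1 - LBNP/LBNP_HDD) at beat times,
#' ranks features by MRMR on the pooled records, and fits one boosted-tree
#' model. The model is meant to be applied blind to swine records (a
#' cross-population transfer); no swine CRM ground truth exists.
#'
#' @param lbnp_cohort List of `lbnp_record`s.
#' @param params [boosted_tree_params()].
#' @param k Number of MRMR-selected features.
#' @param variant Signal variant.
#' @return A `boosted_trees` model with target name `"CRM"`.
#' @export
train_crm_model <- function(lbnp_cohort, params = boosted_tree_params(),
                            k = 20L, variant = "non_detrended") {
  Xs <- list(); ys <- list()
  for (rec in lbnp_cohort) {
    sig <- preprocess_waveform(rec$waveform, variant)
    beats <- detect_beats(sig)
    fm <- extract_feature_matrix(sig, variant, beats = beats)
    crm <- sample_metric_at(compute_crm(rec), fm$beat_times)
    Xs[[rec$subject_id]] <- fm$X
    ys[[rec$subject_id]] <- crm$values
  }
  X <- do.call(rbind, Xs)
  y <- unlist(ys, use.names = FALSE)
  sel <- mrmr_rank(X, y, k = k)
  fit_boosted_trees(X[, sel, drop = FALSE], y, params, target_name = "CRM")
}

#' Apply a CRM model blind to processed swine subjects
#'
#' @param crm_model Model from [train_crm_model()].
#' @param processed Named list from [process_subject()].
#' @return Data frame with per-subject AUROC (baseline vs initial
#'   hemorrhage), detection time, MAP detection time, and resuscitation
#'   ratio for the CRM predictions (trend-only; no CRM ground truth).
#' @export
crm_transfer <- function(crm_model, processed) {
  rows <- lapply(processed, function(p) {
    pred <- stats::predict(crm_model, p$features, smooth = TRUE)
    ph <- p$phases
    roc_sel <- pred$times < ph[["hold_start"]]
    roc <- percentile_roc(pred$values[roc_sel],
                          pred$times[roc_sel] >= ph[["hemorrhage_start"]],
                          "low_is_positive")
    map_s <- p$truth[["MAP"]]
    map_sm <- metric_series(map_s$times, moving_mean(map_s$values, 50L),
                            "MAP")
    data.frame(subject_id = p$subject_id, auroc = roc$auroc,
               detection_time_s = detection_time(pred, ph,
                                                 "low_is_positive"),
               map_detection_time_s = detection_time(map_sm, ph,
                                                     "low_is_positive"),
               resus_ratio = as.numeric(resuscitation_ratio(pred, ph)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
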