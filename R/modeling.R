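## Feature ranking and regression: plug-in mutual information on
## equal-frequency bins, greedy MRMR (mutual-information-quotient variant),
## least-squares gradient-boosted regression trees (rpart base learners),
## and the 4-group leave-one-subject-group-out procedure with per-subject
## blind tests.

#' Equal-frequency binning
#' @param x Numeric vector.
#' @param bins Number of bins.
#' @return Integer bin labels in 1..bins (all 1 for a constant input).
#' @export
equal_freq_bin <- function(x, bins = 16L) {
  n <- length(x)
  r <- rank(x, ties.method = "average")
  b <- as.integer(ceiling(r * bins / n))
  pmin.int(pmax.int(b, 1L), bins)
}

## MI in bits between two pre-binned integer vectors
mi_binned <- function(bx, by, bins) {
  n <- length(bx)
  joint <- tabulate((bx - 1L) * bins + by, nbins = bins * bins)
  px <- tabulate(bx, nbins = bins) / n
  py <- tabulate(by, nbins = bins) / n
  nz <- which(joint > 0L)
  p <- joint[nz] / n
  i <- (nz - 1L) %/% bins + 1L
  j <- (nz - 1L) %% bins + 1L
  sum(p * log2(p / (px[i] * py[j])))
}

#' Mutual information (plug-in, equal-frequency bins)
#'
#' Symmetric, non-negative plug-in estimate in bits from equal-frequency
#' binning of both variables. Constant input returns 0 by convention.
#'
#' @param x,y Numeric vectors of equal length.
#' @param bins Number of bins per variable; default 16.
#' @return MI estimate in bits.
#' @export
mutual_information <- function(x, y, bins = 16L) {
  stopifnot(length(x) == length(y), length(x) >= bins)
  if (stats::var(x) == 0 || stats::var(y) == 0) return(0)
  mi_binned(equal_freq_bin(x, bins), equal_freq_bin(y, bins), bins)
}

#' MRMR feature ranking (mutual-information quotient)
#'
#' Greedy forward selection: the first feature maximizes MI with the target;
#' each subsequent feature maximizes the quotient
#' `MI(f, target) / mean MI(f, selected)`. Ties are broken by lexicographic
#' feature name; the procedure is deterministic.
#'
#' @param features A `feature_matrix`, numeric matrix, or data frame with
#'   column names.
#' @param target A `metric_series` or numeric vector aligned to the rows.
#' @param k Number of features to rank; default 20.
#' @param bins MI binning resolution.
#' @return Character vector of `k` feature names in selection order.
#' @export
mrmr_rank <- function(features, target, k = 20L, bins = 16L) {
  X <- if (inherits(features, "feature_matrix")) features$X
       else as.matrix(features)
  y <- if (inherits(target, "metric_series")) target$values
       else as.numeric(target)
  stopifnot(nrow(X) == length(y))
  if (k > ncol(X)) stop("k exceeds the number of feature columns")
  B <- apply(X, 2L, equal_freq_bin, bins = bins)
  mrmr_rank_binned(B, equal_freq_bin(y, bins), k, bins)
}

## core greedy loop on pre-binned columns
mrmr_rank_binned <- function(B, ty, k, bins) {
  nm <- colnames(B)
  p <- ncol(B)
  rel <- vapply(seq_len(p), function(j) mi_binned(B[, j], ty, bins),
                numeric(1))
  pick <- function(score, cand) cand[order(-score[cand], nm[cand])[1L]]
  cand <- seq_len(p)
  first <- pick(rel, cand)
  sel <- first
  cand <- cand[cand != first]
  redsum <- numeric(p)
  while (length(sel) < k) {
    s_new <- sel[length(sel)]
    redsum[cand] <- redsum[cand] + vapply(
      cand, function(j) mi_binned(B[, j], B[, s_new], bins), numeric(1))
    score <- rel / pmax(redsum / length(sel), 1e-12)
    nxt <- pick(score, cand)
    sel <- c(sel, nxt)
    cand <- cand[cand != nxt]
  }
  nm[sel]
}

#' Boosted-tree parameters
#'
#' Standard settings: minimum leaf size 8, learning rate 0.1, 30 learning
#' cycles; tree depth capped at 6.
#'
#' @param n_cycles Number of boosting cycles.
#' @param learning_rate Shrinkage in (0, 1].
#' @param min_leaf Minimum observations per leaf.
#' @param max_depth Maximum tree depth.
#' @param seed Stored for provenance (tree fitting is deterministic).
#' @return List of class `boosted_tree_params`.
#' @export
boosted_tree_params <- function(n_cycles = 30L, learning_rate = 0.1,
                                min_leaf = 8L, max_depth = 6L, seed = 1L) {
  stopifnot(n_cycles >= 1L, learning_rate > 0, learning_rate <= 1,
            min_leaf >= 1L)
  structure(list(n_cycles = as.integer(n_cycles),
                 learning_rate = learning_rate,
                 min_leaf = as.integer(min_leaf),
                 max_depth = as.integer(max_depth),
                 seed = as.integer(seed)),
            class = "boosted_tree_params")
}

#' Fit least-squares gradient-boosted regression trees
#'
#' Initializes with the mean of the target; each cycle fits a
#' depth/leaf-constrained regression tree (rpart, `cp = 0`) to the current
#' residuals and adds it scaled by the learning rate. The per-cycle training
#' RMSE is recorded and is non-increasing.
#'
#' @param X Numeric matrix or data frame of predictors (named columns,
#'   typically the MRMR-selected features).
#' @param y Numeric target or `metric_series`.
#' @param params A [boosted_tree_params()].
#' @param target_name Label stored on the model.
#' @return Object of class `boosted_trees` with fields `f0`, `trees`,
#'   `selected_features`, `params`, `training_log`.
#' @export
fit_boosted_trees <- function(X, y, params = boosted_tree_params(),
                              target_name = "target") {
  if (inherits(X, "feature_matrix")) X <- X$X
  if (inherits(y, "metric_series")) y <- y$values
  X <- as.data.frame(X, check.names = FALSE)
  stopifnot(nrow(X) == length(y))
  if (any(!is.finite(y))) stop("non-finite target values")
  if (nrow(X) < 2L * params$min_leaf)
    stop("too few rows for the minimum leaf size")
  ctrl <- rpart::rpart.control(
    minsplit = 2L * params$min_leaf, minbucket = params$min_leaf,
    cp = 0, maxdepth = params$max_depth, xval = 0L,
    maxcompete = 0L, maxsurrogate = 0L, usesurrogate = 0L)
  f0 <- mean(y)
  fit <- rep(f0, length(y))
  trees <- vector("list", params$n_cycles)
  log_rmse <- numeric(params$n_cycles)
  dat <- X
  for (m in seq_len(params$n_cycles)) {
    dat$.resid <- y - fit
    tr <- rpart::rpart(.resid ~ ., data = dat, method = "anova",
                       control = ctrl)
    trees[[m]] <- tr
    fit <- fit + params$learning_rate * stats::predict(tr, X)
    log_rmse[m] <- sqrt(mean((y - fit)^2))
  }
  structure(list(f0 = f0, trees = trees,
                 selected_features = colnames(X),
                 params = params, training_log = log_rmse,
                 target_name = target_name),
            class = "boosted_trees")
}

#' Predict from a boosted-tree model
#'
#' Mean initialization plus the sum of scaled tree outputs; by default the
#' prediction is then smoothed with a 50-point trailing moving mean (the
#' standard prediction smoother).
#'
#' @param object A `boosted_trees` model.
#' @param newdata A `feature_matrix`, matrix, or data frame containing all
#'   selected feature columns (matched by name; column order is irrelevant).
#' @param smooth Apply the moving-mean smoother.
#' @param window Smoother window in beats.
#' @param ... Unused.
#' @return A `metric_series` when `newdata` is a `feature_matrix`, otherwise
#'   a numeric vector.
#' @export
predict.boosted_trees <- function(object, newdata, smooth = TRUE,
                                  window = 50L, ...) {
  times <- NULL
  if (inherits(newdata, "feature_matrix")) {
    times <- newdata$beat_times
    newdata <- newdata$X
  }
  miss <- setdiff(object$selected_features, colnames(newdata))
  if (length(miss) > 0L)
    stop("missing feature column(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(newdata[, object$selected_features, drop = FALSE],
                      check.names = FALSE)
  pred <- rep(object$f0, nrow(df))
  for (tr in object$trees)
    pred <- pred + object$params$learning_rate *
      unname(stats::predict(tr, df))
  if (smooth) pred <- moving_mean(pred, window)
  if (!is.null(times)) metric_series(times, pred, object$target_name)
  else pred
}

#' Leave-one-subject-group-out cross-validation
#'
#' For each of the `n_groups` folds: concatenate the remaining groups,
#' rank features by MRMR on that training set only, take the top `k`, fit
#' one boosted-tree model per target, and blind-predict each held-out
#' subject separately. With 12 subjects in 4 groups this emits exactly 12
#' prediction/evaluation records per target.
#'
#' @param features Named list: subject id -> `feature_matrix` (or matrix).
#' @param targets Either a named list subject id -> target (numeric or
#'   `metric_series`), or a named list of such lists, one per metric.
#' @param groups Named integer vector: subject id -> group id.
#' @param params A [boosted_tree_params()].
#' @param k Number of MRMR-selected features per model.
#' @param bins MI binning resolution.
#' @return Object of class `loso_result`: `records` (data frame with
#'   `metric`, `model_id`, `blind_subject`, `r2`, `rmse`, `n_beats`),
#'   `predictions[[metric]][[subject]]` (`metric_series`),
#'   `selected[[metric]][[fold]]`, `models[[metric]][[fold]]`.
#' @export
run_loso <- function(features, targets, groups,
                     params = boosted_tree_params(), k = 20L, bins = 16L) {
  subjects <- names(features)
  stopifnot(!is.null(subjects), all(subjects %in% names(groups)))
  groups <- groups[subjects]
  if (is.numeric(targets[[1L]]) || inherits(targets[[1L]], "metric_series"))
    targets <- list(target = targets)
  for (m in names(targets))
    stopifnot(all(subjects %in% names(targets[[m]])))
  gids <- sort(unique(groups))
  if (any(table(factor(groups, levels = gids)) == 0L))
    stop("every group must contain at least one subject")

  get_X <- function(s) {
    f <- features[[s]]
    if (inherits(f, "feature_matrix")) f$X else as.matrix(f)
  }
  get_t <- function(m, s) {
    tt <- targets[[m]][[s]]
    if (inherits(tt, "metric_series")) tt$values else as.numeric(tt)
  }
  get_times <- function(s) {
    f <- features[[s]]
    if (inherits(f, "feature_matrix")) f$beat_times
    else seq_len(nrow(as.matrix(f)))
  }

  records <- list()
  predictions <- stats::setNames(
    replicate(length(targets), list(), simplify = FALSE), names(targets))
  selected <- stats::setNames(
    replicate(length(targets), list(), simplify = FALSE), names(targets))
  models <- stats::setNames(
    replicate(length(targets), list(), simplify = FALSE), names(targets))

  ## training columns are assembled per column (never as one concatenated
  ## matrix) to keep the peak footprint at one integer bin matrix per fold
  gather_col <- function(subs, j) {
    unlist(lapply(subs, function(s) features[[s]]$X[, j]), use.names = FALSE)
  }
  has_fm <- all(vapply(features, inherits, logical(1), "feature_matrix"))

  for (fold in seq_along(gids)) {
    g <- gids[fold]
    tr_sub <- subjects[groups != g]
    te_sub <- subjects[groups == g]
    if (has_fm) {
      n_tr <- sum(vapply(tr_sub, function(s) nrow(features[[s]]$X),
                         integer(1)))
      fnames <- colnames(features[[tr_sub[1L]]]$X)
      B <- matrix(0L, n_tr, length(fnames))
      colnames(B) <- fnames
      for (j in seq_along(fnames))
        B[, j] <- equal_freq_bin(gather_col(tr_sub, j), bins)
    } else {
      Xtr_full <- do.call(rbind, lapply(tr_sub, get_X))
      B <- apply(Xtr_full, 2L, equal_freq_bin, bins = bins)
      colnames(B) <- colnames(Xtr_full)
    }
    for (mname in names(targets)) {
      ytr <- unlist(lapply(tr_sub, function(s) get_t(mname, s)),
                    use.names = FALSE)
      sel <- mrmr_rank_binned(B, equal_freq_bin(ytr, bins), k, bins)
      Xtr_sel <- if (has_fm) {
        m <- matrix(NA_real_, length(ytr), length(sel),
                    dimnames = list(NULL, sel))
        for (jj in seq_along(sel)) m[, jj] <- gather_col(tr_sub, sel[jj])
        m
      } else Xtr_full[, sel, drop = FALSE]
      model <- fit_boosted_trees(Xtr_sel, ytr, params, target_name = mname)
      selected[[mname]][[fold]] <- sel
      models[[mname]][[fold]] <- model
      for (s in te_sub) {
        pred <- stats::predict(model, get_X(s), smooth = TRUE)
        truth <- get_t(mname, s)
        gof <- goodness_of_fit(pred, truth)
        predictions[[mname]][[s]] <- metric_series(get_times(s), pred, mname)
        records[[length(records) + 1L]] <- data.frame(
          metric = mname, model_id = fold - 1L, blind_subject = s,
          r2 = gof[["r2"]], rmse = gof[["rmse"]], n_beats = length(pred),
          stringsAsFactors = FALSE)
      }
    }
    rm(B)
    if (!has_fm) rm(Xtr_full)
    gc(FALSE)
  }
  structure(list(records = do.call(rbind, records),
                 predictions = predictions, selected = selected,
                 models = models, params = params, k = k),
            class = "loso_result")
}

#' Write a LOSO result as a summary table plus per-subject predictions
#'
#' The record table goes to `<dir>/loso_records.tsv`; each blind subject's
#' prediction series goes to `<dir>/pred_<metric>_<subject>.tsv`.
#'
#' @param loso A `loso_result`.
#' @param dir Output directory (created if needed).
#' @export
write_loso_result <- function(loso, dir) {
  stopifnot(inherits(loso, "loso_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(loso$records, file.path(dir, "loso_records.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  for (m in names(loso$predictions))
    for (s in names(loso$predictions[[m]]))
      write_metric_series(loso$predictions[[m]][[s]],
                          file.path(dir, sprintf("pred_%s_%s.tsv", m, s)))
  invisible(dir)
}

#' @export
print.loso_result <- function(x, ...) {
  cat(sprintf("<loso_result> %d records (%s)\n", nrow(x$records),
              paste(unique(x$records$metric), collapse = ", ")))
  agg <- stats::aggregate(cbind(r2, rmse) ~ metric, x$records, mean)
  print(agg, row.names = FALSE)
  invisible(x)
}
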