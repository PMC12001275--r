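# Predictive-performance evaluation: error metrics, goodness-of-fit
# export, prediction-corrected visual predictive checks, and the repeated
# patient-level cross-validation loop.

#' Prediction error metrics
#'
#' Mean absolute error and root mean squared error, in the concentration
#' units of the inputs; RMSE >= MAE always.
#'
#' @param observed,predicted numeric vectors of equal length >= 1.
#' @return Named list `mae`, `rmse`.
#' @export
compute_metrics <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  if (length(observed) == 0L) stop("empty input", call. = FALSE)
  err <- observed - predicted
  list(mae = mean(abs(err)), rmse = sqrt(mean(err^2)))
}

#' Aggregate per-fold metrics
#'
#' Mean and sample (n-1) standard deviation across folds.
#'
#' @param fold_metrics data frame with numeric columns (e.g. `mae`,
#'   `rmse`), one row per fold.
#' @return Data frame with rows `mean` and `sd`.
#' @export
aggregate_metrics <- function(fold_metrics) {
  num <- fold_metrics[vapply(fold_metrics, is.numeric, logical(1))]
  data.frame(statistic = c("mean", "sd"),
             rbind(colMeans(num), vapply(num, stats::sd, numeric(1))),
             row.names = NULL)
}

#' Prediction-corrected visual predictive check
#'
#' Bergstrand-style correction: within each time bin, every observed and
#' simulated value is rescaled by `median(PRED in bin) / PRED_ij`, where
#' `PRED_ij` is the typical-value (zero random effect) prediction matched
#' to that observation. Observed 5th/50th/95th percentiles per bin are
#' compared to the 90% confidence band of the same percentile across
#' simulated replicates.
#'
#' @param time observation times (or times after dose), length n.
#' @param observed observed concentrations, length n.
#' @param pred typical-value predictions matched to the observations
#'   (all > 0).
#' @param sims n x n_reps matrix of simulated replicates, rows aligned
#'   with `observed`.
#' @param bins number of equal-count time bins, or an explicit vector of
#'   bin edges (left-closed). Empty bins are dropped with a warning.
#' @param ci confidence level of the simulation band (default 0.90).
#' @return A data frame of class `vpc_result`: per bin, `n`, edges, the
#'   observed prediction-corrected percentiles `obs_p5, obs_p50, obs_p95`
#'   and the simulation band `lo_p5/hi_p5, lo_p50/hi_p50, lo_p95/hi_p95`.
#' @export
pcvpc <- function(time, observed, pred, sims, bins = 1, ci = 0.90) {
  n <- length(observed)
  stopifnot(length(time) == n, length(pred) == n, nrow(sims) == n)
  if (any(pred <= 0))
    stop("typical predictions must be positive for prediction correction",
         call. = FALSE)
  if (length(bins) == 1L) {
    nb <- as.integer(bins)
    edges <- if (nb == 1L) range(time) else
      unique(stats::quantile(time, probs = seq(0, 1, length.out = nb + 1)))
  } else edges <- sort(unique(bins))
  edges[length(edges)] <- edges[length(edges)] + 1e-9
  bin_id <- findInterval(time, edges, rightmost.closed = TRUE)
  bin_id[bin_id == 0L] <- 1L
  bin_id[bin_id >= length(edges)] <- length(edges) - 1L
  qs <- c(0.05, 0.5, 0.95)
  alpha <- (1 - ci) / 2
  rows <- list()
  for (bid in sort(unique(bin_id))) {
    j <- which(bin_id == bid)
    if (length(j) == 0L) next
    med_pred <- stats::median(pred[j])
    corr <- med_pred / pred[j]
    obs_pc <- observed[j] * corr
    obs_q <- stats::quantile(obs_pc, qs, names = FALSE)
    sim_q <- apply(sims[j, , drop = FALSE] * corr, 2L,
                   stats::quantile, probs = qs, names = FALSE)
    if (is.null(dim(sim_q))) sim_q <- matrix(sim_q, nrow = 3L)
    band <- apply(sim_q, 1L, stats::quantile,
                  probs = c(alpha, 1 - alpha), names = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      bin = bid, t_lo = edges[bid], t_hi = edges[bid + 1L],
      n = length(j),
      obs_p5 = obs_q[1L], obs_p50 = obs_q[2L], obs_p95 = obs_q[3L],
      lo_p5 = band[1L, 1L], hi_p5 = band[2L, 1L],
      lo_p50 = band[1L, 2L], hi_p50 = band[2L, 2L],
      lo_p95 = band[1L, 3L], hi_p95 = band[2L, 3L])
  }
  out <- do.call(rbind, rows)
  class(out) <- c("vpc_result", "data.frame")
  out
}

#' Export a goodness-of-fit table
#'
#' Writes a tidy `patient, time, analyte, observed, predicted[, fold]`
#' table and returns identity-line summary statistics of observed against
#' predicted.
#'
#' @param predictions data frame as returned by [predict.vampk()]
#'   (optionally with a `fold` column).
#' @param path output CSV path, or `NULL` to skip writing.
#' @return List `slope`, `intercept`, `r` (Pearson), `n`.
#' @export
gof_export <- function(predictions, path = NULL) {
  stopifnot(all(c("observed", "predicted") %in% names(predictions)))
  if (!is.null(path))
    utils::write.csv(predictions, path, row.names = FALSE)
  if (stats::var(predictions$predicted) > 0) {
    fit <- stats::lm(observed ~ predicted, data = predictions)
    slope <- unname(stats::coef(fit)[2L])
    intercept <- unname(stats::coef(fit)[1L])
    r <- stats::cor(predictions$observed, predictions$predicted)
  } else {
    slope <- NA_real_; intercept <- NA_real_; r <- NA_real_
  }
  list(slope = slope, intercept = intercept, r = r,
       n = nrow(predictions))
}

#' Subset a dataset to a set of patients
#'
#' @param ds a [pk_dataset()].
#' @param ids patient identifiers to keep.
#' @return A [pk_dataset()].
#' @export
pk_subset <- function(ds, ids) {
  stopifnot(inherits(ds, "pk_dataset"))
  pk_dataset(ds$events[ds$events$ID %in% ids, , drop = FALSE],
             drug_type = ds$drug_type, provenance = ds$provenance)
}

#' Repeated patient-level cross-validation
#'
#' For every repeat x fold split: train the model on the training
#' patients (with weight imputation from training-set means where the
#' structural model needs weight), predict the test patients via the
#' posterior-mean protocol, and accumulate MAE/RMSE. Fold seeds derive
#' deterministically from the master seed.
#'
#' @param ds preprocessed [pk_dataset()].
#' @param control a [vampk_control()].
#' @param n_repeats,n_folds cross-validation layout (default 10 x 5).
#' @param seed master seed.
#' @param keep_fits retain the per-fold model objects.
#' @return A list of class `vampk_cv`: `folds` (per-fold metrics),
#'   `aggregate` (mean and sample SD across all folds), `predictions`
#'   (pooled test-set predictions with fold labels) and optionally
#'   `fits`.
#' @export
run_cv <- function(ds, control = vampk_control(), n_repeats = 10,
                   n_folds = 5, seed, keep_fits = FALSE) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  splits <- split_cv(ds, n_repeats, n_folds, seed)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  fold_seeds <- sample.int(.Machine$integer.max, length(splits))
  rows <- list(); preds <- list(); fits <- list()
  for (i in seq_along(splits)) {
    sp <- splits[[i]]
    train <- pk_subset(ds, sp$train_patient_ids)
    test <- pk_subset(ds, sp$test_patient_ids)
    if (ds$drug_type == "sunitinib") {
      test <- impute_weight_by_sex(train, test)
      train <- impute_weight_by_sex(train, train)
    }
    fit <- tryCatch(
      vampk(train, control = control, seed = fold_seeds[i]),
      error = function(e)
        stop("fold ", sp$fold_index, " of repeat ", sp$repeat_index,
             " failed: ", conditionMessage(e), call. = FALSE))
    pr <- predict(fit, test)
    m <- compute_metrics(pr$observed, pr$predicted)
    rows[[i]] <- data.frame(repeat_index = sp$repeat_index,
                            fold_index = sp$fold_index,
                            n_test_patients = length(sp$test_patient_ids),
                            mae = m$mae, rmse = m$rmse)
    pr$fold <- paste0(sp$repeat_index, ".", sp$fold_index)
    preds[[i]] <- pr
    if (keep_fits) fits[[i]] <- fit
  }
  folds <- do.call(rbind, rows)
  out <- list(folds = folds,
              aggregate = aggregate_metrics(folds[, c("mae", "rmse")]),
              predictions = do.call(rbind, preds),
              splits = splits)
  if (keep_fits) out$fits <- fits
  class(out) <- "vampk_cv"
  out
}

#' @export
print.vampk_cv <- function(x, ...) {
  agg <- x$aggregate
  cat("Cross-validation over", nrow(x$folds), "folds\n")
  cat(sprintf("  MAE  %.4g +/- %.4g\n", agg$mae[1L], agg$mae[2L]))
  cat(sprintf("  RMSE %.4g +/- %.4g\n", agg$rmse[1L], agg$rmse[2L]))
  invisible(x)
}
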