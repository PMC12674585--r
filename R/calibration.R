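#' Cross-validation protocol
#'
#' @param n_folds Folds per repetition (default 5).
#' @param n_repeats Repetitions (default 5).
#' @param trim_fraction Fraction of calibration samples removed by residual
#'   trimming (default 0.20).
#' @param split_fraction Calibration share of the plot-level split (default 0.80).
#' @param seed Master seed; every fold assignment and stochastic engine draw
#'   is derived from it.
#' @return A `cv_protocol` record.
#' @export
cv_protocol <- function(n_folds = 5, n_repeats = 5, trim_fraction = 0.20,
                        split_fraction = 0.80, seed = 1L) {
  if (n_folds < 2) stopf("need at least 2 folds")
  if (trim_fraction < 0 || trim_fraction >= 1) stopf("trim_fraction must be in [0, 1)")
  if (split_fraction <= 0 || split_fraction >= 1) stopf("split_fraction must be in (0, 1)")
  structure(list(n_folds = as.integer(n_folds), n_repeats = as.integer(n_repeats),
                 trim_fraction = trim_fraction, split_fraction = split_fraction,
                 seed = as.integer(seed)),
            class = "cv_protocol")
}

#' Plot-level calibration/holdout split
#'
#' Randomly assigns whole plots to the calibration or holdout partition so
#' that all readings and aggregates of a plot stay together; disjoint and
#' exhaustive, seeded through the protocol.
#'
#' @param plot_ids Character vector of unique plot ids.
#' @param protocol A [cv_protocol()].
#' @return List with character vectors `calibration` and `holdout`.
#' @export
split_dataset <- function(plot_ids, protocol) {
  plot_ids <- unique(plot_ids)
  n <- length(plot_ids)
  if (n < 10) stopf("refusing to split fewer than 10 plots")
  n_cal <- floor(protocol$split_fraction * n)
  cal <- local_seed(derive_seed(protocol$seed, 11L),
                    sample(plot_ids, n_cal))
  list(calibration = sort(cal), holdout = sort(setdiff(plot_ids, cal)))
}

#' Aggregate readings to plot-level mean spectra
#'
#' @param ds A [spectral_dataset()].
#' @return List with `plot_ids` and matrix `X` (plots x channels, rownames =
#'   plot ids), one row per distinct plot (mean over its readings).
#' @export
aggregate_readings <- function(ds) {
  ids <- ds$metadata$plot_id
  plots <- unique(ids)
  X <- rowsum(ds$absorbance, group = ids, reorder = FALSE)
  X <- X / as.vector(table(ids)[rownames(X)])
  X <- X[plots, , drop = FALSE]
  list(plot_ids = plots, X = X)
}

fold_assignment <- function(n, n_folds, seed) {
  local_seed(seed, sample(rep_len(seq_len(n_folds), n)))
}

#' Repeated k-fold cross-validation of one engine
#'
#' For each repetition, draws a seeded fold assignment, pools the
#' out-of-fold predictions over folds, and computes the metric suite on the
#' pooled predictions; reported metrics are the element-wise mean over
#' repetitions. Fold assignments depend only on the protocol seed, never on
#' the engine, so engines can be compared on identical partitions.
#'
#' @param X Predictor matrix (samples x channels, rownames = sample ids).
#' @param y Response vector.
#' @param spec An [engine_spec()].
#' @param protocol A [cv_protocol()].
#' @return List: `predictions` (samples x repeats matrix of out-of-fold
#'   predictions), `per_repeat_metrics` (list of `metric_set`), `metrics`
#'   (their mean), `fold_ids` (samples x repeats).
#' @export
repeated_cv <- function(X, y, spec, protocol) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2 * protocol$n_folds) stopf("too few samples for %d-fold CV", protocol$n_folds)
  preds <- matrix(NA_real_, n, protocol$n_repeats)
  folds <- matrix(NA_integer_, n, protocol$n_repeats)
  per_repeat <- vector("list", protocol$n_repeats)
  for (rep_i in seq_len(protocol$n_repeats)) {
    f <- fold_assignment(n, protocol$n_folds, derive_seed(protocol$seed, 29L, rep_i))
    folds[, rep_i] <- f
    for (k in seq_len(protocol$n_folds)) {
      test <- f == k
      if (sum(test) < 1 || sum(!test) < 2) stopf("degenerate fold (too few samples)")
      fit <- fit_engine(X[!test, , drop = FALSE], y[!test], spec,
                        seed = derive_seed(protocol$seed, 31L, rep_i, k))
      preds[test, rep_i] <- predict(fit, X[test, , drop = FALSE])
    }
    per_repeat[[rep_i]] <- compute_metrics(y, preds[, rep_i])
  }
  rownames(preds) <- rownames(X)
  list(predictions = preds, per_repeat_metrics = per_repeat,
       metrics = average_metric_sets(per_repeat), fold_ids = folds)
}

#' Select the number of PLS components by the one-standard-error rule
#'
#' Runs repeated cross-validation of the NIPALS PLS engine for each component
#' count up to the cap and returns the smallest count whose mean CV RMSE is
#' within one standard error (over repetitions) of the global minimum.
#'
#' @param X Predictor matrix.
#' @param y Response vector.
#' @param protocol A [cv_protocol()].
#' @param max_components Cap (default 20), further limited by the data size.
#' @return Integer component count.
#' @export
select_pls_components <- function(X, y, protocol, max_components = 20) {
  X <- as.matrix(X)
  n <- nrow(X)
  ## components must survive the smallest training fold
  min_train <- n - ceiling(n / protocol$n_folds)
  cap <- max(1, min(max_components, min_train - 1, ncol(X)))
  rmse_mat <- matrix(NA_real_, protocol$n_repeats, cap)
  for (rep_i in seq_len(protocol$n_repeats)) {
    f <- fold_assignment(n, protocol$n_folds, derive_seed(protocol$seed, 29L, rep_i))
    pred <- matrix(NA_real_, n, cap)
    for (k in seq_len(protocol$n_folds)) {
      test <- f == k
      fit <- fit_pls(X[!test, , drop = FALSE], y[!test], cap)
      for (a in seq_len(cap)) {
        pred[test, a] <- predict(fit, X[test, , drop = FALSE],
                                 ncomp = min(a, fit$ncomp))
      }
    }
    rmse_mat[rep_i, ] <- sqrt(colMeans((pred - y)^2))
  }
  m <- colMeans(rmse_mat)
  se <- apply(rmse_mat, 2, stats::sd) / sqrt(protocol$n_repeats)
  best <- which.min(m)
  as.integer(min(which(m <= m[best] + se[best])))
}

#' Residual-trim refit: the two-stage calibration protocol
#'
#' Stage 1 runs repeated cross-validation on the full calibration set and
#' scores each sample by its absolute cross-validated residual averaged over
#' repetitions; the `trim_fraction` share with the largest residuals
#' (`floor(trim_fraction * n)` samples) is removed exactly once. Stage 2
#' reruns repeated cross-validation on the retained samples (the reported
#' calibration metrics) and refits the final model on them; if holdout data
#' are supplied, holdout predictions and validation metrics come from that
#' final model. Residuals are taken from cross-validated predictions, not
#' from a refit, to avoid optimistic trimming.
#'
#' @param X,y Calibration predictors (rownames = sample ids) and response.
#' @param spec An [engine_spec()]; a `NULL` `pls_components` is resolved once
#'   on the full calibration set via [select_pls_components()].
#' @param protocol A [cv_protocol()].
#' @param X_val,y_val Optional holdout data for external validation.
#' @param trait,sample_type,treatment Optional provenance labels stored in
#'   the run.
#' @return A `calibration_run`: `trimmed_ids`, `cv` (stage-2 repeated CV),
#'   `metrics_cv`, `model` (final fit), `holdout_predictions`, `metrics_val`,
#'   `chosen_pls_components`, labels.
#' @export
residual_trim_refit <- function(X, y, spec, protocol, X_val = NULL, y_val = NULL,
                                trait = NA_character_, sample_type = NA_character_,
                                treatment = NA_character_) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (is.null(rownames(X))) rownames(X) <- sprintf("s%04d", seq_len(n))
  n_trim <- floor(protocol$trim_fraction * n)
  if (n - n_trim < 2 * protocol$n_folds) {
    stopf("trimming would leave fewer than %d samples", 2 * protocol$n_folds)
  }
  if (spec$engine == "pls" && is.null(spec$pls_components)) {
    spec$pls_components <- select_pls_components(X, y, protocol,
                                                 spec$pls_max_components)
  }

  stage1 <- repeated_cv(X, y, spec, protocol)
  resid <- abs(y - rowMeans(stage1$predictions))
  trimmed_ids <- if (n_trim > 0) {
    rownames(X)[order(resid, decreasing = TRUE)[seq_len(n_trim)]]
  } else {
    character(0)
  }
  keep <- !(rownames(X) %in% trimmed_ids)

  stage2 <- repeated_cv(X[keep, , drop = FALSE], y[keep], spec, protocol)
  final <- fit_engine(X[keep, , drop = FALSE], y[keep], spec,
                      seed = derive_seed(protocol$seed, 37L))

  holdout_predictions <- NULL
  metrics_val <- NULL
  if (!is.null(X_val)) {
    holdout_predictions <- predict(final, X_val)
    names(holdout_predictions) <- rownames(X_val)
    if (!is.null(y_val)) metrics_val <- compute_metrics(y_val, holdout_predictions)
  }
  structure(list(trait = trait, sample_type = sample_type, treatment = treatment,
                 engine = spec$engine, spec = spec,
                 trimmed_ids = trimmed_ids, cv = stage2,
                 metrics_cv = stage2$metrics, model = final,
                 holdout_predictions = holdout_predictions,
                 metrics_val = metrics_val,
                 chosen_pls_components = spec$pls_components %||% NA),
            class = "calibration_run")
}

#' @export
print.calibration_run <- function(x, ...) {
  cat(sprintf("<calibration_run> trait=%s type=%s treatment=%s engine=%s | CV r=%.3f rmse=%.3f%s\n",
              x$trait, x$sample_type, x$treatment, x$engine,
              x$metrics_cv$r, x$metrics_cv$rmse,
              if (is.null(x$metrics_val)) "" else
                sprintf(" | val r=%.3f rmse=%.3f", x$metrics_val$r, x$metrics_val$rmse)))
  invisible(x)
}

#' Pick the pre-treatment that wins across both sample types
#'
#' Given PLS calibration runs for each treatment in each sample type, ranks
#' treatments by cross-validated Pearson R (descending) and RMSE (ascending)
#' within each sample type, averages the ranks over both metrics and both
#' sample types, and returns the single winner. Exact ties are broken by the
#' canonical treatment order (raw, d1, snv, msc, d1_dt, d1_msc, sg_snv).
#'
#' @param runs List of `calibration_run` objects (PLS engine), each carrying
#'   `treatment` and `sample_type` labels.
#' @return List: `treatment` (winning name), `ranking` (data frame of
#'   per-treatment mean ranks and metrics).
#' @export
select_treatment <- function(runs) {
  if (length(runs) == 0) stopf("no calibration runs supplied")
  tab <- do.call(rbind, lapply(runs, function(r) {
    data.frame(treatment = r$treatment, sample_type = r$sample_type,
               r = r$metrics_cv$r, rmse = r$metrics_cv$rmse,
               stringsAsFactors = FALSE)
  }))
  ranks <- do.call(rbind, lapply(split(tab, tab$sample_type), function(d) {
    data.frame(treatment = d$treatment,
               rank_r = rank(-d$r, ties.method = "average"),
               rank_rmse = rank(d$rmse, ties.method = "average"),
               stringsAsFactors = FALSE)
  }))
  agg <- stats::aggregate(cbind(rank_r, rank_rmse) ~ treatment, data = ranks, FUN = mean)
  agg$mean_rank <- (agg$rank_r + agg$rank_rmse) / 2
  agg$order_tiebreak <- match(agg$treatment, TREATMENT_NAMES)
  agg <- agg[order(agg$mean_rank, agg$order_tiebreak), ]
  list(treatment = agg$treatment[1], ranking = agg, metrics = tab)
}
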