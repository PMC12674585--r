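#' Chemometric evaluation metrics for a prediction set
#'
#' Computes the metric suite used throughout the pipeline: Pearson
#' correlation `r` between observed and predicted values, `r2` (the square of
#' `r` by default, matching the usual chemometric reporting where e.g.
#' R = 0.97 pairs with R2 = 0.94), root mean squared error, additive bias
#' `mean(predicted - observed)`, the OLS `slope` of predicted on observed
#' (reported alongside because "bias" in calibration tables is sometimes this
#' slope-like quantity), and the two scale-free quality ratios
#' `rpd = sd(observed) / rmse` and `rpiq = IQR(observed) / rmse` (type-7
#' quartiles, n-1 standard deviation of the reference values).
#'
#' @param observed,predicted Numeric vectors of equal length >= 2; `observed`
#'   must have nonzero variance.
#' @param r2_method `"pearson"` (square of r; default) or `"ss"`
#'   (`1 - SSE/SST`).
#' @return A `metric_set` list: `r`, `r2`, `rmse`, `bias_additive`, `slope`,
#'   `rpd`, `rpiq`, `n`. A perfect fit (`rmse = 0`) reports `rpd`/`rpiq` as
#'   `Inf` with a warning.
#' @export
compute_metrics <- function(observed, predicted, r2_method = c("pearson", "ss")) {
  r2_method <- match.arg(r2_method)
  if (length(observed) != length(predicted)) stopf("observed/predicted length mismatch")
  n <- length(observed)
  if (n < 2) stopf("need at least 2 observations")
  if (stats::sd(observed) == 0) stopf("observed values have zero variance; r undefined")

  r <- stats::cor(observed, predicted)
  rmse <- sqrt(mean((predicted - observed)^2))
  bias <- mean(predicted - observed)
  slope <- stats::cov(observed, predicted) / stats::var(observed)
  r2 <- if (r2_method == "pearson") r^2 else {
    1 - sum((observed - predicted)^2) / sum((observed - mean(observed))^2)
  }
  if (rmse == 0) {
    warnf("rmse is 0: rpd and rpiq reported as Inf")
    rpd <- Inf
    rpiq <- Inf
  } else {
    rpd <- stats::sd(observed) / rmse
    q <- stats::quantile(observed, c(0.25, 0.75), type = 7, names = FALSE)
    rpiq <- (q[2] - q[1]) / rmse
  }
  structure(list(r = r, r2 = r2, rmse = rmse, bias_additive = bias,
                 slope = slope, rpd = rpd, rpiq = rpiq, n = n),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("<metric_set n=%d> r=%.3f r2=%.3f rmse=%.3f bias=%.3f slope=%.3f rpd=%.2f rpiq=%.2f\n",
              x$n, x$r, x$r2, x$rmse, x$bias_additive, x$slope, x$rpd, x$rpiq))
  invisible(x)
}

#' @export
as.data.frame.metric_set <- function(x, ...) {
  as.data.frame(unclass(x), stringsAsFactors = FALSE)
}

## element-wise mean of a list of metric_sets (used to average over CV repeats)
average_metric_sets <- function(sets) {
  fields <- c("r", "r2", "rmse", "bias_additive", "slope", "rpd", "rpiq")
  out <- lapply(fields, function(f) mean(vapply(sets, `[[`, numeric(1), f)))
  names(out) <- fields
  out$n <- sets[[1]]$n
  structure(out, class = "metric_set")
}

#' Interpret an RPD value
#'
#' Maps a ratio-of-performance-to-deviation value onto the conventional
#' qualitative categories at configurable, left-closed cut points: below the
#' first cut is "poor", then "fair", "good" and "excellent" (so the default
#' boundary 2.0 falls in "good").
#'
#' @param rpd Numeric RPD value(s).
#' @param cuts Ascending cut points (default `c(1.5, 2, 3)`).
#' @return Character vector of categories.
#' @export
interpret_rpd <- function(rpd, cuts = c(1.5, 2, 3)) {
  labs <- c("poor", "fair", "good", "excellent")
  labs[findInterval(rpd, cuts) + 1]
}
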