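#' Specify a regression engine
#'
#' The three calibration engines compared in the pipeline, with the gradient
#' boosting hyperparameters fixed at their published operating point
#' (`nrounds = 200`, `max_depth = 5`, `eta = 0.3`, `gamma = 5`,
#' `subsample = 0.7`, `colsample_bytree = 0.7`, `min_child_weight = 1`) and
#' support vector regression at the standard RBF configuration with `C = 1`.
#'
#' @param engine `"pls"`, `"svm"` or `"xgb"`.
#' @param pls_components Fixed number of PLS components, or `NULL` to select
#'   by cross-validation (see [select_pls_components()]).
#' @param pls_max_components Cap on selectable PLS components.
#' @param svm_cost,svm_epsilon SVR cost and epsilon-insensitive margin.
#' @param svm_gamma RBF width, or `NULL` for the data-driven rule
#'   `1 / (n_channels * mean channel variance)`.
#' @param xgb XGB parameter list; defaults are the published configuration.
#' @return An `engine_spec` record.
#' @export
engine_spec <- function(engine = c("pls", "svm", "xgb"),
                        pls_components = NULL, pls_max_components = 20,
                        svm_cost = 1, svm_epsilon = 0.1, svm_gamma = NULL,
                        xgb = list(nrounds = 200, max_depth = 5, eta = 0.3,
                                   gamma = 5, subsample = 0.7,
                                   colsample_bytree = 0.7, min_child_weight = 1)) {
  engine <- match.arg(engine)
  structure(list(engine = engine,
                 pls_components = pls_components,
                 pls_max_components = pls_max_components,
                 svm = list(kernel = "rbf", cost = svm_cost,
                            epsilon = svm_epsilon, gamma = svm_gamma),
                 xgb = xgb),
            class = "engine_spec")
}

#' Fit a regression engine under a uniform contract
#'
#' Dispatches to the NIPALS PLS1 implementation, to `e1071::svm` (epsilon
#' regression, RBF kernel) or to `xgboost` with the hyperparameters recorded
#' in `spec`. All engines return an `engine_fit` exposing the same
#' `predict()` contract; the stochastic engine (xgb) draws its subsampling
#' from `seed`.
#'
#' @param X Predictor matrix (samples x channels).
#' @param y Response vector.
#' @param spec An [engine_spec()].
#' @param seed Integer seed for stochastic engines.
#' @return An `engine_fit`.
#' @export
fit_engine <- function(X, y, spec, seed = 1L) {
  stopifnot(inherits(spec, "engine_spec"))
  X <- as.matrix(X)
  if (stats::sd(y) == 0) {
    ## all engines degenerate gracefully to the constant
    return(structure(list(spec = spec, constant = y[1]), class = "engine_fit"))
  }
  model <- switch(spec$engine,
    pls = {
      ncomp <- spec$pls_components %||%
        min(spec$pls_max_components, nrow(X) - 1, ncol(X), 10)
      fit_pls(X, y, min(ncomp, nrow(X) - 1, ncol(X)))
    },
    svm = {
      gamma <- spec$svm$gamma %||% {
        v <- mean(apply(X, 2, stats::var))
        if (v <= 0) 1 / ncol(X) else 1 / (ncol(X) * v)
      }
      e1071::svm(x = X, y = y, type = "eps-regression", kernel = "radial",
                 cost = spec$svm$cost, epsilon = spec$svm$epsilon,
                 gamma = gamma, scale = FALSE)
    },
    xgb = local_seed(seed, {
      p <- spec$xgb
      dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
      xgboost::xgb.train(
        params = list(max_depth = p$max_depth, eta = p$eta, gamma = p$gamma,
                      subsample = p$subsample, colsample_bytree = p$colsample_bytree,
                      min_child_weight = p$min_child_weight,
                      objective = "reg:squarederror", nthread = 1),
        data = dtrain, nrounds = p$nrounds, verbose = 0
      )
    }),
    stopf("unknown engine '%s'", spec$engine)
  )
  structure(list(spec = spec, model = model), class = "engine_fit")
}

#' @export
predict.engine_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(object$constant)) return(rep(object$constant, nrow(newdata)))
  switch(object$spec$engine,
    pls = predict(object$model, newdata),
    svm = as.numeric(stats::predict(object$model, newdata)),
    xgb = as.numeric(stats::predict(object$model,
                                    xgboost::xgb.DMatrix(newdata, nthread = 1)))
  )
}

#' Report the effective configuration of a fitted engine
#'
#' @param fit An `engine_fit`.
#' @return Named list echoing the hyperparameters actually used.
#' @export
engine_config <- function(fit) {
  spec <- fit$spec
  switch(spec$engine,
    pls = list(engine = "pls",
               n_components = if (inherits(fit$model, "pls_fit")) fit$model$ncomp else NA),
    svm = list(engine = "svm", kernel = "rbf", C = spec$svm$cost,
               epsilon = spec$svm$epsilon),
    xgb = c(list(engine = "xgb"), spec$xgb)
  )
}
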