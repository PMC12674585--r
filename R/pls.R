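#' Fit a PLS1 regression by NIPALS
#'
#' Classical NIPALS partial least squares for a single response: predictors
#' and response are column-centered; components are extracted iteratively as
#' weight vectors `w = X'y / ||X'y||`, scores `t = Xw`, X-loadings
#' `p = X't / t't` and y-loading `q = y't / t't`, with X and y deflated after
#' each component. Regression coefficients for any number of components up to
#' `ncomp` are recovered as `B = W (P'W)^{-1} q` and re-expressed in the
#' original units through the stored centering parameters.
#'
#' @param X Numeric predictor matrix (samples x channels).
#' @param y Numeric response vector (nonzero variance).
#' @param ncomp Number of latent components,
#'   `<= min(nrow(X) - 1, ncol(X))`.
#' @return A `pls_fit` with weights, loadings, scores, coefficients per
#'   component count, and centering parameters.
#' @export
fit_pls <- function(X, y, ncomp) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stopf("X/y size mismatch")
  if (stats::sd(y) == 0) stopf("response has zero variance")
  ncomp <- as.integer(ncomp)
  if (ncomp < 1 || ncomp > min(n - 1, p)) {
    stopf("ncomp must be in [1, %d]", min(n - 1, p))
  }

  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2, x_mean)
  yc <- y - y_mean

  W <- matrix(0, p, ncomp)   # weights
  P <- matrix(0, p, ncomp)   # X loadings
  Tm <- matrix(0, n, ncomp)  # scores
  q <- numeric(ncomp)        # y loadings
  actual <- 0L
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xc, yc)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break  # X carries no further covariance with y
    w <- w / nw
    tt <- Xc %*% w
    tt2 <- sum(tt^2)
    if (tt2 < 1e-24) break
    pp <- crossprod(Xc, tt) / tt2
    qq <- sum(yc * tt) / tt2
    Xc <- Xc - tt %*% t(pp)
    yc <- yc - qq * tt
    W[, a] <- w; P[, a] <- pp; Tm[, a] <- tt; q[a] <- qq
    actual <- a
  }
  if (actual == 0L) stopf("no PLS component could be extracted")
  W <- W[, seq_len(actual), drop = FALSE]
  P <- P[, seq_len(actual), drop = FALSE]
  Tm <- Tm[, seq_len(actual), drop = FALSE]
  q <- q[seq_len(actual)]

  ## coefficients for every component count 1..actual
  coefs <- matrix(0, p, actual)
  for (a in seq_len(actual)) {
    Wa <- W[, seq_len(a), drop = FALSE]
    Pa <- P[, seq_len(a), drop = FALSE]
    R <- Wa %*% solve(t(Pa) %*% Wa)
    coefs[, a] <- R %*% q[seq_len(a)]
  }
  structure(list(ncomp = actual, requested_ncomp = ncomp,
                 weights = W, loadings = P, scores = Tm, y_loadings = q,
                 coefficients = coefs, x_mean = x_mean, y_mean = y_mean),
            class = "pls_fit")
}

#' Predict from a NIPALS PLS fit
#'
#' @param object A `pls_fit`.
#' @param newdata Matrix of predictors on the training wavelength grid.
#' @param ncomp Number of components to use (default: all fitted).
#' @param ... Unused.
#' @return Numeric vector of predictions in original response units.
#' @export
predict.pls_fit <- function(object, newdata, ncomp = object$ncomp, ...) {
  ncomp <- min(as.integer(ncomp), object$ncomp)
  b <- object$coefficients[, ncomp]
  as.numeric(sweep(as.matrix(newdata), 2, object$x_mean) %*% b + object$y_mean)
}
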