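# Independent brute-force oracles used to validate the package's numerics.
# Each is written as a direct transliteration of the defining formula, with
# loops and dense algebra, sharing no code with the implementation under test.

## local polynomial least-squares fit evaluated at a window center:
## the defining computation behind Savitzky-Golay
sg_point_oracle <- function(x, i, window, polyorder, deriv_order = 0, spacing = 1) {
  h <- (window - 1) / 2
  idx <- (i - h):(i + h)
  t_rel <- (idx - i) * spacing
  B <- outer(t_rel, 0:polyorder, `^`)
  beta <- solve(t(B) %*% B, t(B) %*% x[idx])
  factorial(deriv_order) * beta[deriv_order + 1]
}

## gap-segment derivative by explicit loops
gapseg_oracle <- function(x, window, segment, spacing = 1) {
  n <- length(x)
  h <- (window - 1) %/% 2
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    li <- (i - h - segment + 1):(i - h)
    ri <- (i + h):(i + h + segment - 1)
    if (min(li) < 1 || max(ri) > n) next
    left <- 0; right <- 0
    for (j in li) left <- left + x[j]
    for (j in ri) right <- right + x[j]
    out[i] <- (right / segment - left / segment) / ((2 * h + segment - 1) * spacing)
  }
  valid <- which(!is.na(out))
  out[seq_len(min(valid) - 1)] <- out[min(valid)]
  out[seq(max(valid) + 1, length.out = n - max(valid))] <- out[max(valid)]
  out
}

## independent PLS1: cross-covariance SVD per component on explicitly
## deflated matrices, coefficients assembled from first principles
pls_svd_oracle <- function(X, y, ncomp) {
  X <- as.matrix(X); y <- as.numeric(y)
  xm <- colMeans(X); ym <- mean(y)
  E <- sweep(X, 2, xm); f <- y - ym
  W <- NULL; P <- NULL; Q <- NULL
  for (a in seq_len(ncomp)) {
    s <- t(E) %*% f                       # cross-covariance vector
    sv <- svd(s)                          # first left singular vector
    w <- sv$u[, 1, drop = FALSE]
    tt <- E %*% w
    p <- t(E) %*% tt / c(t(tt) %*% tt)
    q <- c(t(f) %*% tt / c(t(tt) %*% tt))
    E <- E - tt %*% t(p)
    f <- f - q * tt
    W <- cbind(W, w); P <- cbind(P, p); Q <- c(Q, q)
  }
  B <- W %*% solve(t(P) %*% W) %*% Q
  list(coefficients = as.numeric(B), intercept = ym - sum(xm * B))
}

## metric suite recomputed from defining formulas with explicit sums
metrics_oracle <- function(obs, pred) {
  n <- length(obs)
  mo <- sum(obs) / n; mp <- sum(pred) / n
  sxo <- sqrt(sum((obs - mo)^2) / (n - 1))
  sxp <- sqrt(sum((pred - mp)^2) / (n - 1))
  r <- sum((obs - mo) * (pred - mp)) / ((n - 1) * sxo * sxp)
  rmse <- sqrt(sum((pred - obs)^2) / n)
  bias <- sum(pred - obs) / n
  slope <- sum((obs - mo) * (pred - mp)) / sum((obs - mo)^2)
  so <- sort(obs)
  q7 <- function(p) {
    hh <- (n - 1) * p + 1
    lo <- floor(hh)
    so[lo] + (hh - lo) * (so[min(lo + 1, n)] - so[lo])
  }
  list(r = r, r2 = r^2, rmse = rmse, bias_additive = bias, slope = slope,
       rpd = sxo / rmse, rpiq = (q7(0.75) - q7(0.25)) / rmse)
}

## kappa by exhaustive confusion-table counting over an explicit universe
kappa_enum_oracle <- function(n, k_a, k_b, overlap) {
  both <- overlap
  neither <- n - k_a - k_b + overlap
  po <- (both + neither) / n
  pe <- (k_a / n) * (k_b / n) + (1 - k_a / n) * (1 - k_b / n)
  if (abs(1 - pe) < 1e-12) return(if (abs(po - 1) < 1e-12) 1 else NA_real_)
  (po - pe) / (1 - pe)
}

## balanced one-way ANOVA (expected mean squares) variance-component estimator
anova_sigma_oracle <- function(values, clone, n_rep) {
  cm <- tapply(values, clone, mean)
  mse <- sum(tapply(values, clone, function(v) sum((v - mean(v))^2))) /
    (length(values) - length(cm))
  msb <- n_rep * sum((cm - mean(cm))^2) / (length(cm) - 1)
  c(sigma2_g = (msb - mse) / n_rep, sigma2_e = mse)
}
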