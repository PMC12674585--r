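#' Fit the multi-environment mixed model by REML
#'
#' Fits, for one trait,
#' \deqn{Y_{ijlk} = \mu + g_i + \beta_j + r_{l(j)} + \rho_{k(l)} + g\beta_{ij} + \epsilon_{ijlk}}
#' with environment fixed and clone, replication-within-environment,
#' block-within-replication and clone-by-environment random. Variance
#' components are estimated by REML: the residual variance is profiled out
#' and the profiled restricted log-likelihood, evaluated through Henderson's
#' mixed-model equations with a sparse Cholesky factorization, is maximized
#' by Nelder-Mead search over the log variance ratios. At the optimum, BLUPs
#' are the random-effect solutions of the mixed-model equations and each
#' clone's prediction error variance is the corresponding diagonal element of
#' the inverse coefficient matrix scaled by the residual variance.
#'
#' @param traits Trait table (as from [simulate_traits()]).
#' @param trait_name Column to analyse (`"StC"`, `"DMCo"` or `"DMCg"`).
#' @param model_terms Random terms to include, a subset of
#'   `c("clone", "rep", "block", "gxe")`; `"clone"` is mandatory. Dropping
#'   `"rep"`/`"block"` accommodates simpler designs.
#' @param max_iter Maximum Nelder-Mead iterations.
#' @return A `mixed_model_fit`: `variance_components`, `fixed_effects`
#'   (intercept and environment effects), `clone_effects` (data frame with
#'   `clone_id`, `blup`, `pev`, `reliability`), `converged`, `n_iterations`,
#'   `logl` (profiled restricted log-likelihood, up to a constant).
#' @export
fit_mixed_model <- function(traits, trait_name,
                            model_terms = c("clone", "rep", "block", "gxe"),
                            max_iter = 2000) {
  model_terms <- match.arg(model_terms, several.ok = TRUE)
  if (!"clone" %in% model_terms) stopf("'clone' must be among model_terms")
  if (!trait_name %in% names(traits)) stopf("trait '%s' not in table", trait_name)
  y <- traits[[trait_name]]
  if (anyNA(y)) stopf("missing trait values are not supported")
  clone <- factor(traits$clone_id)
  env <- factor(traits$env_id)
  if (nlevels(clone) < 2) stopf("need at least 2 clones")

  X <- if (nlevels(env) > 1) stats::model.matrix(~env) else matrix(1, length(y), 1,
                                                                   dimnames = list(NULL, "(Intercept)"))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stopf("singular fixed-effects design")
  p <- ncol(X)
  n <- length(y)

  Zs <- list()
  Zs$clone <- Matrix::sparse.model.matrix(~ 0 + clone)
  if ("rep" %in% model_terms && length(unique(paste(env, traits$rep_id))) > nlevels(env)) {
    rep_f <- factor(paste(traits$env_id, traits$rep_id, sep = ":"))
    Zs$rep <- Matrix::sparse.model.matrix(~ 0 + rep_f)
  }
  if ("block" %in% model_terms) {
    blk_f <- factor(paste(traits$env_id, traits$rep_id, traits$block_id, sep = ":"))
    n_rep_lvls <- if (is.null(Zs$rep)) nlevels(env) else ncol(Zs$rep)
    if (nlevels(blk_f) > n_rep_lvls && nlevels(blk_f) < n) {
      Zs$block <- Matrix::sparse.model.matrix(~ 0 + blk_f)
    }
  }
  if ("gxe" %in% model_terms && nlevels(env) > 1) {
    ge_f <- factor(paste(traits$clone_id, traits$env_id, sep = ":"))
    Zs$gxe <- Matrix::sparse.model.matrix(~ 0 + ge_f)
  }
  terms_used <- names(Zs)
  q_sizes <- vapply(Zs, ncol, integer(1))
  Z <- do.call(cbind, Zs)
  M <- cbind(Matrix::Matrix(X, sparse = TRUE), Z)
  MtM <- Matrix::crossprod(M)
  Mty <- as.numeric(Matrix::crossprod(M, y))
  ran_ix <- rep(seq_along(terms_used), q_sizes) # random cols after the p fixed
  ## y'Py computed as ||y - Mb||^2 + b'Db: both terms positive, avoiding the
  ## catastrophic cancellation of the y'y - b'M'y form
  quad_form <- function(b, dvec) {
    r <- y - as.numeric(M %*% b)
    sum(r^2) + sum(b^2 * dvec)
  }

  ## profiled -2 restricted log-likelihood (up to an additive constant), as a
  ## function of log variance ratios lambda_k = sigma2_k / sigma2_e
  ## log variance ratios are confined to a generous box: beyond it the MME
  ## coefficient matrix is numerically singular and the profiled likelihood
  ## is meaningless (a ratio of 4e5 is already "effectively fixed"/"zero")
  LOG_LAMBDA_BOX <- 13
  neg2logl <- function(log_lambda) {
    clamped <- pmin(pmax(log_lambda, -LOG_LAMBDA_BOX), LOG_LAMBDA_BOX)
    penalty <- 1e4 * sum((log_lambda - clamped)^2)
    log_lambda <- clamped
    lambda <- exp(log_lambda)
    dvec <- c(rep(0, p), 1 / lambda[ran_ix])
    C <- MtM + Matrix::Diagonal(x = dvec)
    ch <- tryCatch(Matrix::Cholesky(Matrix::forceSymmetric(C), LDL = FALSE, perm = TRUE),
                   error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    b <- as.numeric(Matrix::solve(ch, Mty))
    q_form <- quad_form(b, dvec)
    if (q_form <= 0) return(1e10)
    ldC <- as.numeric(Matrix::determinant(ch, sqrt = FALSE)$modulus) # log det C
    (n - p) * log(q_form) + sum(q_sizes * log_lambda) + ldC + penalty
  }

  start <- rep(0, length(terms_used))
  if (length(start) == 1) {
    o <- stats::optimize(neg2logl, c(-13, 13), tol = 1e-10)
    opt <- list(par = o$minimum, value = o$objective, convergence = 0,
                counts = c("function" = NA_integer_))
  } else {
    opt <- stats::optim(start, neg2logl, method = "Nelder-Mead",
                        control = list(maxit = max_iter, reltol = 1e-10))
  }
  converged <- opt$convergence == 0 && is.finite(opt$value) && opt$value < 1e10
  if (!converged) warnf("REML search did not converge cleanly (code %d)", opt$convergence)

  lambda <- exp(pmin(pmax(opt$par, -13), 13))
  dvec <- c(rep(0, p), 1 / lambda[ran_ix])
  C <- MtM + Matrix::Diagonal(x = dvec)
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(C), LDL = FALSE, perm = TRUE)
  b <- as.numeric(Matrix::solve(ch, Mty))
  q_form <- quad_form(b, dvec)
  sigma2_e <- q_form / (n - p)
  sigma2 <- stats::setNames(lambda * sigma2_e, terms_used)

  beta <- b[seq_len(p)]
  u_all <- b[-seq_len(p)]
  g_cols <- p + which(ran_ix == match("clone", terms_used))
  ## PEV: diagonal of the clone block of C^{-1}, times sigma2_e
  Eg <- Matrix::sparseMatrix(i = g_cols, j = seq_along(g_cols),
                             x = 1, dims = c(ncol(M), length(g_cols)))
  CinvG <- Matrix::solve(ch, Eg)
  pev <- sigma2_e * vapply(seq_along(g_cols),
                           function(j) CinvG[g_cols[j], j], numeric(1))
  blup <- u_all[ran_ix == match("clone", terms_used)]
  s2g <- sigma2[["clone"]]
  reliability <- if (s2g > 0) pmax(0, pmin(1, 1 - pev / s2g)) else rep(0, length(blup))

  vc <- c(sigma2_g = unname(sigma2["clone"]),
          sigma2_r = unname(sigma2["rep"]),
          sigma2_k = unname(sigma2["block"]),
          sigma2_ge = unname(sigma2["gxe"]),
          sigma2_e = sigma2_e)
  vc[is.na(vc)] <- NA_real_

  structure(list(
    trait = trait_name,
    variance_components = vc,
    fixed_effects = stats::setNames(beta, colnames(X)),
    clone_effects = data.frame(clone_id = levels(clone), blup = blup,
                               pev = pev, reliability = reliability,
                               stringsAsFactors = FALSE),
    terms = terms_used, converged = converged,
    n_iterations = opt$counts[["function"]],
    logl = -opt$value / 2
  ), class = "mixed_model_fit")
}

#' @export
print.mixed_model_fit <- function(x, ...) {
  cat(sprintf("<mixed_model_fit> trait=%s, %d clones, converged=%s\n",
              x$trait, nrow(x$clone_effects), x$converged))
  print(round(x$variance_components, 4))
  invisible(x)
}

#' Deregress BLUPs
#'
#' Removes shrinkage from clone BLUPs for downstream selection:
#' `dblup = blup / (1 - PEV / sigma2_g)`, i.e. the BLUP divided by its
#' reliability. Clones whose reliability falls at or below the floor receive
#' a missing dBLUP with a warning record rather than an exploding value.
#'
#' @param fit A `mixed_model_fit` with positive genotypic variance.
#' @param reliability_floor Minimum reliability for a defined dBLUP
#'   (default 0.05).
#' @return The `clone_effects` data frame with a `dblup` column appended.
#' @export
deregress <- function(fit, reliability_floor = 0.05) {
  stopifnot(inherits(fit, "mixed_model_fit"))
  s2g <- fit$variance_components[["sigma2_g"]]
  if (!is.finite(s2g) || s2g <= 0) {
    stopf("genotypic variance is zero: dBLUPs undefined")
  }
  ce <- fit$clone_effects
  rel <- 1 - ce$pev / s2g
  ok <- rel > reliability_floor
  if (any(!ok)) {
    warnf("%d clone(s) below the reliability floor (%.2f): dBLUP set to NA",
          sum(!ok), reliability_floor)
  }
  ce$dblup <- ifelse(ok, ce$blup / rel, NA_real_)
  ce
}
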