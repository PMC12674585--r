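test_that("plot-level split is exact, seeded and disjoint", {
  prot <- cv_protocol(seed = 21)
  ids <- sprintf("p%03d", 1:100)
  sp <- split_dataset(ids, prot)
  expect_length(sp$calibration, 80)
  expect_length(sp$holdout, 20)
  expect_length(intersect(sp$calibration, sp$holdout), 0)
  expect_setequal(c(sp$calibration, sp$holdout), ids)
  expect_identical(split_dataset(ids, prot), sp)
  expect_false(identical(split_dataset(ids, cv_protocol(seed = 22)), sp))
  expect_error(split_dataset(ids[1:5], prot), "fewer than 10")
})

test_that("aggregation averages readings per plot", {
  wl <- seq(740, 760)
  A <- rbind(rep(0, 21), rep(2, 21), rep(5, 21))
  meta <- data.frame(reading_id = c("r1", "r2", "r3"),
                     plot_id = c("p1", "p1", "p2"), sample_type = "mashed")
  agg <- aggregate_readings(spectral_dataset(wl, A, meta))
  expect_equal(agg$plot_ids, c("p1", "p2"))
  expect_equal(unname(agg$X["p1", ]), rep(1, 21))
  expect_equal(unname(agg$X["p2", ]), rep(5, 21))
})

test_that("NIPALS PLS recovers exact linear responses and matches the SVD oracle", {
  set.seed(31)
  X <- matrix(rnorm(40 * 6), 40)
  y <- as.numeric(X %*% rnorm(6)) + 3
  f <- fit_pls(X, y, 6)
  expect_lt(max(abs(predict(f, X) - y)), 1e-8)
  ## single latent factor: one component suffices
  t1 <- rnorm(30)
  X1 <- outer(t1, rnorm(8)) + matrix(rnorm(30 * 8, 0, 1e-9), 30)
  y1 <- 2 * t1 + 1
  p1 <- predict(fit_pls(X1, y1, 1), X1)
  p5 <- predict(fit_pls(X1, y1, 5), X1)
  expect_lt(max(abs(p1 - p5)), 1e-6)
  ## coefficients match the independent SVD-based oracle on 8x5 problems
  for (i in 1:5) {
    Xs <- matrix(rnorm(8 * 5), 8)
    ys <- rnorm(8)
    for (nc in c(1, 3, 5)) {
      got <- fit_pls(Xs, ys, nc)
      want <- pls_svd_oracle(Xs, ys, nc)
      expect_equal(unname(got$coefficients[, nc]), want$coefficients,
                   tolerance = 1e-8)
    }
  }
  expect_error(fit_pls(X, rep(1, 40), 2), "zero variance")
})

test_that("component selection follows the one-standard-error rule", {
  set.seed(32)
  prot <- cv_protocol(n_repeats = 3, seed = 33)
  ## noise-free rank-2 response needs exactly 2 components
  t1 <- rnorm(60); t2 <- rnorm(60)
  X <- outer(t1, rnorm(20)) + outer(t2, rnorm(20))
  y <- t1 - t2
  expect_equal(select_pls_components(X, y, prot), 2L)
  ## pure-noise response collapses to 1
  yn <- rnorm(60)
  expect_equal(select_pls_components(X, yn, prot), 1L)
  ## cap respected
  expect_lte(select_pls_components(X, y, prot, max_components = 1), 1L)
})

test_that("engines echo their configuration and honor the uniform contract", {
  set.seed(34)
  X <- matrix(rnorm(50 * 12), 50)
  y <- as.numeric(X %*% rnorm(12))
  xf <- fit_engine(X, y, engine_spec("xgb"), seed = 1)
  cfgx <- engine_config(xf)
  expect_equal(cfgx[c("nrounds", "max_depth", "eta", "gamma", "subsample",
                      "colsample_bytree", "min_child_weight")],
               list(nrounds = 200, max_depth = 5, eta = 0.3, gamma = 5,
                    subsample = 0.7, colsample_bytree = 0.7, min_child_weight = 1))
  sf <- fit_engine(X, y, engine_spec("svm"))
  expect_equal(engine_config(sf)$kernel, "rbf")
  expect_equal(engine_config(sf)$C, 1)
  ## constant response: every engine predicts the constant
  yc <- rep(7, 50)
  for (eng in c("pls", "svm", "xgb")) {
    fit <- fit_engine(X, yc, engine_spec(eng), seed = 1)
    expect_equal(predict(fit, X[1:5, ]), rep(7, 5), tolerance = 1e-6, info = eng)
  }
  expect_error(engine_spec("mlp"))
})

test_that("repeated CV is reproducible, engine-invariant in folds, and accurate on clean data", {
  set.seed(35)
  X <- matrix(rnorm(60 * 10), 60)
  rownames(X) <- sprintf("s%02d", 1:60)
  y <- as.numeric(X %*% rnorm(10)) + 20
  prot <- cv_protocol(n_repeats = 5, seed = 41)
  cv1 <- repeated_cv(X, y, engine_spec("pls", pls_components = 5), prot)
  cv2 <- repeated_cv(X, y, engine_spec("pls", pls_components = 5), prot)
  expect_identical(cv1$predictions, cv2$predictions)
  expect_length(cv1$per_repeat_metrics, 5)
  expect_gte(cv1$metrics$r, 0.999)
  ## fold assignments are identical across engines for a fixed seed
  cv_svm <- repeated_cv(X, y, engine_spec("svm"), prot)
  expect_identical(cv1$fold_ids, cv_svm$fold_ids)
})

test_that("residual trimming removes the planted corrupted samples", {
  set.seed(36)
  n <- 60
  X <- matrix(rnorm(n * 10), n)
  rownames(X) <- sprintf("s%02d", 1:n)
  y <- as.numeric(X %*% rnorm(10)) + 30
  prot <- cv_protocol(n_repeats = 2, seed = 42)
  ## corrupt 20% of responses by +10 sd
  bad <- sample(n, floor(0.2 * n))
  y_bad <- y
  y_bad[bad] <- y_bad[bad] + 10 * sd(y)
  run <- residual_trim_refit(X, y_bad, engine_spec("pls", pls_components = 5), prot)
  expect_length(run$trimmed_ids, floor(0.2 * n))
  hit <- mean(rownames(X)[bad] %in% run$trimmed_ids)
  expect_gte(hit, 0.8)
  ## trim_fraction = 0 reduces to plain repeated CV
  prot0 <- cv_protocol(n_repeats = 2, trim_fraction = 0, seed = 42)
  run0 <- residual_trim_refit(X, y, engine_spec("pls", pls_components = 5), prot0)
  cv <- repeated_cv(X, y, engine_spec("pls", pls_components = 5), prot0)
  expect_equal(run0$metrics_cv, cv$metrics)
  expect_length(run0$trimmed_ids, 0)
})

test_that("treatment selection ranks by R and RMSE across sample types", {
  mk_run <- function(tr, st, r, rmse) {
    structure(list(treatment = tr, sample_type = st,
                   metrics_cv = list(r = r, rmse = rmse)),
              class = "calibration_run")
  }
  ## dominance: sg_snv beats raw in both metrics in both sample types
  runs <- list(mk_run("raw", "mashed", 0.80, 1.4), mk_run("sg_snv", "mashed", 0.90, 1.1),
               mk_run("raw", "fresh", 0.60, 1.7), mk_run("sg_snv", "fresh", 0.70, 1.5))
  expect_equal(select_treatment(runs)$treatment, "sg_snv")
  ## exact tie: canonical treatment order breaks it (raw before snv)
  ties <- list(mk_run("snv", "mashed", 0.8, 1.2), mk_run("raw", "mashed", 0.8, 1.2))
  expect_equal(select_treatment(ties)$treatment, "raw")
  expect_error(select_treatment(list()), "no calibration runs")
})

test_that("holdout data never leak into calibration-partition statistics", {
  cfg <- tiny_sim_config(seed = 51)
  tr <- simulate_traits(cfg)
  prot <- cv_protocol(n_repeats = 2, seed = 52)
  m <- treated_matrices(cfg, tr, "mashed", "snv", prot)
  spec <- engine_spec("pls")
  run1 <- residual_trim_refit(m$X_cal, m$y_cal, spec, prot, m$X_val, m$y_val)
  ## permute holdout responses: calibration metrics and trimming unchanged
  run2 <- residual_trim_refit(m$X_cal, m$y_cal, spec, prot, m$X_val,
                              sample(m$y_val))
  expect_identical(run1$metrics_cv, run2$metrics_cv)
  expect_identical(run1$trimmed_ids, run2$trimmed_ids)
  expect_identical(run1$cv$predictions, run2$cv$predictions)
  ## and the holdout spectra matrix is untouched by the run
  expect_identical(m$X_val, treated_matrices(cfg, tr, "mashed", "snv", prot)$X_val)
})
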