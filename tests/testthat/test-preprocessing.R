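test_that("snv centers and scales a spectrum and is affine-invariant", {
  expect_equal(snv(c(1, 2, 3)), c(-1, 0, 1))
  expect_error(snv(c(5, 5, 5)), "constant")
  expect_error(snv(5), "2 channels")
  set.seed(1)
  for (i in 1:5) {
    x <- rnorm(50)
    expect_equal(snv(3.2 * x + 7), snv(x), tolerance = 1e-12)
    y <- snv(x)
    expect_equal(mean(y), 0, tolerance = 1e-12)
    expect_equal(sd(y), 1, tolerance = 1e-12)
  }
  ## idempotence
  x <- rnorm(40)
  expect_equal(snv(snv(x)), snv(x), tolerance = 1e-12)
})

test_that("msc inverts affine scatter against the reference", {
  set.seed(2)
  ref <- abs(rnorm(60)) + 1
  x <- 2 * ref + 1
  corrected <- msc(rbind(x), reference = ref)
  expect_equal(as.numeric(corrected[1, ]), ref, tolerance = 1e-10)
  ## identical spectra: every output equals the (mean) reference
  X <- matrix(rep(x, 4), nrow = 4, byrow = TRUE)
  out <- msc(X)
  expect_equal(unname(out[, 1:60]), matrix(rep(x, 4), 4, byrow = TRUE), tolerance = 1e-10)
  ## per-spectrum OLS coefficients match explicit normal equations
  X <- matrix(rnorm(5 * 60), 5) + matrix(rep(ref, 5), 5, byrow = TRUE)
  out <- msc(X)
  mref <- colMeans(X)
  for (i in 1:5) {
    B <- cbind(1, mref)
    beta <- solve(t(B) %*% B, t(B) %*% X[i, ])
    expect_equal(as.numeric(out[i, ]), (X[i, ] - beta[1]) / beta[2], tolerance = 1e-10)
  }
})

test_that("savitzky_golay reproduces polynomials and local least-squares fits", {
  x <- seq(740, 1070)
  cub <- 2 + 0.01 * x - 1e-5 * x^2 + 1e-8 * x^3
  expect_lt(max(abs(savitzky_golay(cub, 11, 3, 0) - cub)), 1e-9)
  lin <- 0.02 * x + 5
  expect_equal(savitzky_golay(lin, 11, 3, deriv_order = 1, spacing = 1),
               rep(0.02, length(x)), tolerance = 1e-9)
  ## interior points equal the explicit local polynomial fit
  set.seed(3)
  r <- rnorm(60)
  sm <- savitzky_golay(r, 11, 3, 0)
  d1 <- savitzky_golay(r, 11, 3, 1)
  for (i in c(10, 25, 47)) {
    expect_equal(sm[i], sg_point_oracle(r, i, 11, 3, 0), tolerance = 1e-9)
    expect_equal(d1[i], sg_point_oracle(r, i, 11, 3, 1), tolerance = 1e-9)
  }
  expect_error(savitzky_golay(rnorm(5), 11, 3), "shorter")
  expect_error(savitzky_golay(rnorm(50), 10, 3), "odd")
})

test_that("gap_segment_derivative recovers slopes, kills baselines, matches loops", {
  x <- seq(740, 1070, by = 2)
  lin <- 0.03 * x + 4
  d <- gap_segment_derivative(lin, 11, 7, spacing = 2)
  expect_equal(d, rep(0.03, length(x)), tolerance = 1e-10)
  set.seed(4)
  r <- rnorm(50)
  expect_equal(gap_segment_derivative(r + 5, 11, 7), gap_segment_derivative(r, 11, 7),
               tolerance = 1e-10)
  expect_equal(gap_segment_derivative(r, 11, 7), gapseg_oracle(r, 11, 7),
               tolerance = 1e-12)
  expect_error(gap_segment_derivative(rnorm(10), 11, 7), "too short")
})

test_that("detrend removes polynomial baselines and is idempotent", {
  wl <- seq(740, 1070)
  quad <- 3 + 0.01 * wl - 2e-5 * wl^2
  expect_lt(max(abs(detrend(quad, wl, 2))), 1e-9)
  set.seed(5)
  x <- rnorm(length(wl))
  out <- detrend(x, wl, 2)
  fit <- lm(out ~ wl + I(wl^2))
  expect_lt(max(abs(coef(fit))), 1e-8)
  expect_equal(detrend(out, wl, 2), out, tolerance = 1e-9)
  ## degree-1 detrend of line + sine equals sine minus its own best-fit line
  s <- sin(wl / 20)
  B <- cbind(1, wl)
  beta <- solve(t(B) %*% B, t(B) %*% s)
  expect_equal(detrend(5 + 0.01 * wl + s, wl, 1), as.numeric(s - B %*% beta),
               tolerance = 1e-8)
})

test_that("apply_treatment composes transforms in the documented order", {
  cfg <- tiny_sim_config(seed = 11)
  tr <- simulate_traits(cfg)[1:10, ]
  ds <- simulate_spectra(tr, "mashed", cfg)
  expect_identical(apply_treatment(ds, "raw")$absorbance, ds$absorbance)
  ## sg_snv ends with SNV: unit rows
  out <- apply_treatment(ds, "sg_snv")
  expect_equal(unname(rowMeans(out$absorbance)), rep(0, nrow(out$absorbance)),
               tolerance = 1e-12)
  expect_equal(unname(apply(out$absorbance, 1, sd)), rep(1, nrow(out$absorbance)),
               tolerance = 1e-12)
  ## d1_dt is invariant to constant + linear baselines
  base <- outer(rep(1, nrow(ds$absorbance)), 0.5 + 0.001 * ds$wavelengths)
  ds_shift <- spectral_dataset(ds$wavelengths, ds$absorbance + base, ds$metadata)
  expect_equal(apply_treatment(ds_shift, "d1_dt")$absorbance,
               apply_treatment(ds, "d1_dt")$absorbance, tolerance = 1e-8,
               ignore_attr = TRUE)
  ## provenance round-trip: replay the recorded spec bit-identically
  t1 <- apply_treatment(ds, treatment_spec("sg_snv"))
  t2 <- apply_treatment(ds, t1$treatment)
  expect_identical(t1$absorbance, t2$absorbance)
  expect_equal(t1$treatment$name, "sg_snv")
})

test_that("snv and msc remove nearly all multiplicative scatter variance", {
  set.seed(6)
  wl <- seq(740, 1070)
  s <- exp(-0.5 * ((wl - 950) / 40)^2) + 0.3
  n <- 30
  A <- sapply(seq_len(n), function(i) (1 + rnorm(1, 0, 0.2)) * s + rnorm(1, 0, 0.1))
  A <- t(A) + matrix(rnorm(n * length(wl), 0, 1e-4), n)
  meta <- data.frame(reading_id = sprintf("r%02d", 1:n), plot_id = "p1",
                     sample_type = "mashed")
  ds <- spectral_dataset(wl, A, meta)
  bt_var <- function(M) mean(apply(M, 2, var))
  v_raw <- bt_var(ds$absorbance)
  v_snv <- bt_var(apply_treatment(ds, "snv")$absorbance)
  v_msc <- bt_var(apply_treatment(ds, "msc")$absorbance)
  expect_lt(v_snv, 0.1 * v_raw)
  expect_lt(v_msc, 0.1 * v_raw)
})

test_that("treatments preserve reading and channel counts", {
  cfg <- tiny_sim_config(seed = 12)
  tr <- simulate_traits(cfg)[1:6, ]
  ds <- simulate_spectra(tr, "fresh", cfg)
  for (nm in c("raw", "d1", "snv", "msc", "d1_dt", "d1_msc", "sg_snv")) {
    out <- apply_treatment(ds, nm)
    expect_equal(dim(out$absorbance), dim(ds$absorbance), info = nm)
  }
})

test_that("iqr filter flags gross outliers and nothing else", {
  cfg <- tiny_sim_config(seed = 13)
  tr <- simulate_traits(cfg)[1:25, ]
  ds <- simulate_spectra(tr, "mashed", cfg) # 100 readings
  ## identical spectra: fence-boundary values are kept
  same <- spectral_dataset(ds$wavelengths,
                           matrix(rep(ds$absorbance[1, ], 10), 10, byrow = TRUE),
                           ds$metadata[1:10, ])
  expect_length(iqr_outlier_filter(same)$flagged_ids, 0)
  ## homogeneous band-model spectra + one gross offset: exactly that one flagged
  ov <- noiseless_overrides()
  vc0 <- list(StC = c(sigma2_g = 0, sigma2_r = 0, sigma2_k = 0, sigma2_ge = 0, sigma2_e = 0),
              DMCo = c(sigma2_g = 0, sigma2_r = 0, sigma2_k = 0, sigma2_ge = 0, sigma2_e = 0))
  cfg0 <- simulation_config(n_clones = 40, n_envs = 2, n_reps = 2, seed = 14,
                            variance_components = vc0, env_sd = 0, dmcg_noise_sd = 0,
                            scatter = ov$scatter, noise_sd = ov$noise_sd,
                            trait_jitter_sd = ov$trait_jitter_sd,
                            trait_bias_sd = ov$trait_bias_sd)
  tr0 <- simulate_traits(cfg0)[1:25, ]
  ds0 <- simulate_spectra(tr0, "mashed", cfg0)
  mag <- 10 * diff(range(ds0$absorbance))
  inj0 <- inject_spectral_outliers(ds0, fraction = 1 / nrow(ds0$absorbance),
                                   magnitude = mag, seed = 3)
  expect_setequal(iqr_outlier_filter(inj0$dataset)$flagged_ids, inj0$flagged_ids)
  ## on realistic noisy spectra the injected reading is always among the flags
  inj <- inject_spectral_outliers(ds, fraction = 1 / nrow(ds$absorbance),
                                  magnitude = 10 * diff(range(ds$absorbance)),
                                  seed = 3)
  expect_true(all(inj$flagged_ids %in% iqr_outlier_filter(inj$dataset)$flagged_ids))
  ## unbounded fences flag nothing
  expect_length(iqr_outlier_filter(inj$dataset, k = 1e9)$flagged_ids, 0)
  ## too few readings: skipped with a warning
  expect_warning(small <- iqr_outlier_filter(nirscassava:::subset_readings(ds, 1:3)),
                 "fewer than 4")
  expect_equal(nrow(small$kept$absorbance), 3)
})
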