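test_that("degenerate noise-free configuration yields constant trait values", {
  vc0 <- list(StC = c(sigma2_g = 0, sigma2_r = 0, sigma2_k = 0, sigma2_ge = 0, sigma2_e = 0),
              DMCo = c(sigma2_g = 0, sigma2_r = 0, sigma2_k = 0, sigma2_ge = 0, sigma2_e = 0))
  cfg <- simulation_config(n_clones = 10, n_envs = 2, n_reps = 2,
                           variance_components = vc0, env_sd = 0,
                           trait_means = c(StC = 30, DMCo = 35), seed = 1)
  tr <- simulate_traits(cfg)
  expect_true(all(tr$StC == 30))
  expect_true(all(tr$DMCo == 35))
})

test_that("trait table respects the trial design and plot uniqueness", {
  cfg <- tiny_sim_config(seed = 3)
  tr <- simulate_traits(cfg)
  expect_equal(nrow(tr), 40 * 2 * 2)
  expect_equal(anyDuplicated(tr$plot_id), 0L)
  expect_equal(anyDuplicated(tr[, c("clone_id", "env_id", "rep_id")]), 0L)
  expect_true(all(tr$StC > 0 & tr$StC < 100))
  expect_true(all(tr$DMCo > 0 & tr$DMCo < 100))
  expect_error(simulation_config(n_clones = 0), "design counts")
})

test_that("clone-effect variance matches the configured genotypic variance", {
  ## Monte-Carlo check: with only sigma2_g and sigma2_e nonzero on a balanced
  ## design, the clone-mean ANOVA estimator recovers sigma2_g = 4
  vc <- list(StC = c(sigma2_g = 4, sigma2_r = 0, sigma2_k = 0, sigma2_ge = 0, sigma2_e = 2),
             DMCo = c(sigma2_g = 4, sigma2_r = 0, sigma2_k = 0, sigma2_ge = 0, sigma2_e = 2))
  est <- vapply(1:20, function(s) {
    cfg <- simulation_config(n_clones = 200, n_envs = 3, n_reps = 2,
                             variance_components = vc, env_sd = 0, seed = s)
    tr <- simulate_traits(cfg)
    anova_sigma_oracle(tr$StC, tr$clone_id, 6)[["sigma2_g"]]
  }, numeric(1))
  expect_lt(abs(mean(est) - 4), 1.2)
})

test_that("seeded generation is bit-identical and seed-sensitive", {
  cfg <- tiny_sim_config(seed = 7)
  t1 <- simulate_traits(cfg)
  t2 <- simulate_traits(cfg)
  expect_identical(t1, t2)
  s1 <- simulate_spectra(t1, "mashed", cfg)
  s2 <- simulate_spectra(t1, "mashed", cfg)
  expect_identical(s1$absorbance, s2$absorbance)
  cfg2 <- tiny_sim_config(seed = 8)
  expect_false(identical(simulate_traits(cfg2)$StC, t1$StC))
})

test_that("noise-free spectra are deterministic functions of traits", {
  cfg <- noiseless_config(seed = 2)
  tr <- simulate_traits(cfg)
  ## force two plots to identical trait values
  tr$StC[2] <- tr$StC[1]; tr$DMCo[2] <- tr$DMCo[1]; tr$DMCg[2] <- tr$DMCg[1]
  ds <- simulate_spectra(tr, "mashed", cfg)
  rows_1 <- ds$absorbance[ds$metadata$plot_id == tr$plot_id[1], ]
  rows_2 <- ds$absorbance[ds$metadata$plot_id == tr$plot_id[2], ]
  expect_equal(rows_1, rows_2, ignore_attr = TRUE, tolerance = 1e-12)
  ## and equal to the analytic band model
  G <- sapply(cfg$bands, function(b) exp(-0.5 * ((cfg$wavelength_grid - b$center) / b$width)^2))
  load_mat <- sapply(cfg$bands, function(b) {
    v <- c(StC = 0, DMCo = 0); v[names(b$loading)] <- b$loading; v
  })
  expected <- cfg$base_absorbance +
    as.numeric((c(tr$StC[1], tr$DMCo[1]) %*% load_mat) %*% t(G))
  expect_equal(unname(rows_1[1, ]), expected, tolerance = 1e-10)
})

test_that("reading counts and regime contrasts match the acquisition design", {
  cfg <- tiny_sim_config(seed = 5, readings_per_plot = c(fresh = 47, mashed = 4))
  tr <- simulate_traits(cfg)[1:10, ]
  ds_m <- simulate_spectra(tr, "mashed", cfg)
  expect_equal(nrow(ds_m$absorbance), 40)
  ds_f <- simulate_spectra(tr, "fresh", cfg)
  expect_equal(nrow(ds_f$absorbance), 470)
  ## fresh readings are more variable within a plot than mashed readings
  within_var <- function(ds) {
    mean(tapply(seq_len(nrow(ds$absorbance)), ds$metadata$plot_id, function(ix) {
      mean(apply(ds$absorbance[ix, , drop = FALSE], 2, var))
    }))
  }
  expect_gt(within_var(ds_f), within_var(ds_m))
  expect_error(simulate_spectra(tr, "frozen", cfg), "unknown sample_type")
})

test_that("stronger band loading increases the trait information in spectra", {
  r2_at_loading <- function(l) {
    bands <- list(absorption_band(970, 35, c(DMCo = -0.006)),
                  absorption_band(910, 25, c(StC = l, DMCo = 0.002)))
    ov <- noiseless_overrides()
    cfg <- simulation_config(n_clones = 40, n_envs = 1, n_reps = 1, bands = bands,
                             scatter = ov$scatter, noise_sd = ov$noise_sd,
                             trait_jitter_sd = ov$trait_jitter_sd,
                             trait_bias_sd = ov$trait_bias_sd, seed = 9)
    tr <- simulate_traits(cfg)
    ds <- simulate_spectra(tr, "mashed", cfg)
    agg <- aggregate_readings(ds)
    a910 <- agg$X[, which(cfg$wavelength_grid == 910)]
    y <- stats::setNames(tr$StC, tr$plot_id)[agg$plot_ids]
    summary(stats::lm(y ~ a910))$r.squared
  }
  r2 <- vapply(c(0.001, 0.004, 0.012), r2_at_loading, numeric(1))
  expect_true(all(diff(r2) > 0))
})

test_that("outlier injection hits exactly the requested readings", {
  cfg <- tiny_sim_config(seed = 4)
  tr <- simulate_traits(cfg)[1:25, ]
  ds <- simulate_spectra(tr, "mashed", cfg) # 100 readings
  expect_identical(inject_spectral_outliers(ds, 0, 1)$dataset$absorbance, ds$absorbance)
  out <- inject_spectral_outliers(ds, 0.05, 3, seed = 2)
  expect_length(out$flagged_ids, 5)
  changed <- rowSums(out$dataset$absorbance != ds$absorbance) > 0
  expect_equal(sort(ds$metadata$reading_id[changed]), sort(out$flagged_ids))
})

test_that("spectra CSV round-trips through the writer and reader", {
  cfg <- tiny_sim_config(seed = 6)
  tr <- simulate_traits(cfg)[1:5, ]
  ds <- simulate_spectra(tr, "mashed", cfg)
  f <- withr::local_tempfile(fileext = ".csv")
  write_spectra_csv(ds, f)
  back <- read_spectra_csv(f)
  expect_equal(back$wavelengths, ds$wavelengths)
  expect_equal(back$absorbance, ds$absorbance, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$metadata, ds$metadata, ignore_attr = TRUE)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_traits_csv(tr, f2)
  expect_equal(read_traits_csv(f2)$StC, tr$StC, tolerance = 1e-12)
})
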