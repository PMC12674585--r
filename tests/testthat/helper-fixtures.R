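# Shared miniature configurations for the test suite. Sizes are chosen so a
# single test runs in seconds while keeping the signal-to-noise structure of
# the full-scale generator defaults.

tiny_sim_config <- function(seed = 1, ...) {
  simulation_config(n_clones = 40, n_envs = 2, n_reps = 2, seed = seed, ...)
}

## noise-free spectra: no scatter, no channel noise, no within-plot jitter
noiseless_overrides <- function() {
  z <- list(slope_sd = 0, offset_sd = 0, tilt_sd = 0,
            plot_slope_sd = 0, plot_offset_sd = 0, plot_tilt_sd = 0)
  list(scatter = list(fresh = z, mashed = z),
       noise_sd = c(fresh = 0, mashed = 0),
       trait_jitter_sd = c(fresh = 0, mashed = 0),
       trait_bias_sd = c(fresh = 0, mashed = 0))
}

noiseless_config <- function(seed = 1, ...) {
  ov <- noiseless_overrides()
  simulation_config(n_clones = 40, n_envs = 2, n_reps = 2, seed = seed,
                    scatter = ov$scatter, noise_sd = ov$noise_sd,
                    trait_jitter_sd = ov$trait_jitter_sd,
                    trait_bias_sd = ov$trait_bias_sd, ...)
}

## heavy multiplicative-scatter regime for the treatment-selection scenario:
## slope/offset/tilt contamination dominates the trait signal in both
## preparations, the condition under which scatter correction must pay off
heavy_scatter <- function() {
  h <- list(slope_sd = 0.40, offset_sd = 0.20, tilt_sd = 0.08,
            plot_slope_sd = 0.40, plot_offset_sd = 0.20, plot_tilt_sd = 0.08)
  list(fresh = h, mashed = h)
}

## balanced single-environment clone/replicate table with known variances
make_balanced_gclone <- function(n_clones, n_rep, sigma_g, sigma_e, seed,
                                 mu = 30) {
  set.seed(seed)
  g <- rnorm(n_clones, 0, sigma_g)
  d <- expand.grid(clone = seq_len(n_clones), rep = seq_len(n_rep))
  data.frame(clone_id = sprintf("C%03d", d$clone), env_id = "E01",
             rep_id = sprintf("R%d", d$rep), block_id = "B1",
             plot_id = sprintf("P%04d", seq_len(nrow(d))),
             StC = mu + g[d$clone] + rnorm(nrow(d), 0, sigma_e),
             DMCo = 35, DMCg = 35)
}

## plot-level treated design matrices for one sample type, split by plots
treated_matrices <- function(cfg, traits_tab, sample_type, treatment, protocol) {
  ds <- simulate_spectra(traits_tab, sample_type, cfg)
  split <- split_dataset(traits_tab$plot_id, protocol)
  in_cal <- ds$metadata$plot_id %in% split$calibration
  ds_cal <- nirscassava:::subset_readings(ds, in_cal)
  ds_val <- nirscassava:::subset_readings(ds, !in_cal)
  t_cal <- apply_treatment(ds_cal, treatment)
  t_val <- apply_treatment(ds_val, treatment,
                           msc_reference = attr(t_cal, "msc_reference"))
  agg_cal <- aggregate_readings(t_cal)
  agg_val <- aggregate_readings(t_val)
  y <- stats::setNames(traits_tab$DMCo, traits_tab$plot_id)
  list(X_cal = agg_cal$X, y_cal = y[rownames(agg_cal$X)],
       X_val = agg_val$X, y_val = y[rownames(agg_val$X)], split = split)
}
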