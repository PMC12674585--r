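#' Define a Gaussian absorption band
#'
#' The simulator represents near-infrared absorption as a sum of Gaussian
#' bands; each band contributes absorbance proportional to the trait values of
#' the plot being scanned. Band placement stands in for the overtone bands of
#' O-H and C-H bonds that dominate the 740-1070 nm window.
#'
#' @param center Band center (nm).
#' @param width Gaussian standard deviation (nm), must be positive.
#' @param loading Named numeric vector: absorbance contributed per trait-percent,
#'   names drawn from `c("StC", "DMCo")`.
#' @return An `absorption_band` record.
#' @export
absorption_band <- function(center, width, loading) {
  if (width <= 0) stopf("band width must be > 0")
  if (is.null(names(loading)) || !all(names(loading) %in% c("StC", "DMCo"))) {
    stopf("loading must be a named vector with names in {StC, DMCo}")
  }
  structure(list(center = center, width = width, loading = loading),
            class = "absorption_band")
}

default_bands <- function() {
  list(
    ## water overtone: absorbance falls as dry matter displaces water
    absorption_band(970, 35, c(DMCo = -0.0060)),
    ## C-H / starch band
    absorption_band(910, 25, c(StC = 0.0050, DMCo = 0.0020)),
    ## secondary combination band
    absorption_band(1020, 30, c(StC = 0.0020, DMCo = 0.0030))
  )
}

default_scatter <- function() {
  list(
    ## per-reading multiplicative slope / additive offset / linear tilt sds,
    ## plus plot-level components shared by all readings of a plot (surface
    ## condition of that plot's roots); fresh roots are far more contaminated
    fresh  = list(slope_sd = 0.10, offset_sd = 0.050, tilt_sd = 0.020,
                  plot_slope_sd = 0.15, plot_offset_sd = 0.080, plot_tilt_sd = 0.030),
    mashed = list(slope_sd = 0.02, offset_sd = 0.010, tilt_sd = 0.005,
                  plot_slope_sd = 0.01, plot_offset_sd = 0.005, plot_tilt_sd = 0.002)
  )
}

default_variance_components <- function() {
  list(
    StC  = c(sigma2_g = 6, sigma2_r = 0.5, sigma2_k = 0.25, sigma2_ge = 1.5, sigma2_e = 2.0),
    DMCo = c(sigma2_g = 8, sigma2_r = 0.5, sigma2_k = 0.25, sigma2_ge = 1.5, sigma2_e = 1.5)
  )
}

#' Build a simulation configuration
#'
#' Collects every knob of the synthetic-data generator: the multi-environment
#' trial design (clones, environments, replications, incomplete blocks nested
#' in replications), the variance components of the trait model, the spectral
#' forward model (absorption bands, scatter, noise) and the acquisition regime
#' (47 readings per plot on fresh roots, 4 on mashed pulp).
#'
#' @param n_clones,n_envs,n_reps,n_blocks_per_rep Trial design counts (all >= 1).
#' @param variance_components Per-trait named vectors
#'   `c(sigma2_g, sigma2_r, sigma2_k, sigma2_ge, sigma2_e)` in trait-percent^2,
#'   for traits `StC` and `DMCo`.
#' @param trait_means Named vector of population means (percent) for `StC` and `DMCo`.
#' @param env_sd Standard deviation (percent) from which the fixed environment
#'   effects are drawn once and then held fixed.
#' @param dmcg_noise_sd Extra measurement noise sd (percent) that turns the
#'   oven-dried value DMCo into its noisier gravimetric proxy DMCg.
#' @param wavelength_grid Wavelength grid in nm.
#' @param bands List of [absorption_band()] records.
#' @param base_absorbance Constant baseline absorbance added to every spectrum.
#' @param scatter Per-sample-type scatter parameters; see [default_bands()]
#'   source for the record layout.
#' @param noise_sd Named per-sample-type channel noise sd (absorbance units).
#' @param readings_per_plot Named per-sample-type reading counts.
#' @param trait_jitter_sd Per-reading trait perturbation sd (percent) by sample
#'   type: fresh readings probe heterogeneous root tissue, mashed pulp is
#'   homogeneous.
#' @param trait_bias_sd Plot-level trait sampling-bias sd (percent) by sample
#'   type: the scanned roots of a fresh plot need not match the plot's
#'   reference assay exactly.
#' @param seed Integer master seed for the generator.
#' @return A `simulation_config` list, validated.
#' @export
simulation_config <- function(n_clones = 200, n_envs = 3, n_reps = 2, n_blocks_per_rep = 2,
                              variance_components = default_variance_components(),
                              trait_means = c(StC = 30, DMCo = 35),
                              env_sd = 2,
                              dmcg_noise_sd = 1.5,
                              wavelength_grid = seq(740, 1070, by = 1),
                              bands = default_bands(),
                              base_absorbance = 0.25,
                              scatter = default_scatter(),
                              noise_sd = c(fresh = 0.008, mashed = 0.002),
                              readings_per_plot = c(fresh = 47, mashed = 4),
                              trait_jitter_sd = c(fresh = 1.5, mashed = 0.1),
                              trait_bias_sd = c(fresh = 1.0, mashed = 0.1),
                              seed = 20260101) {
  counts <- c(n_clones = n_clones, n_envs = n_envs, n_reps = n_reps,
              n_blocks_per_rep = n_blocks_per_rep)
  if (any(counts < 1)) stopf("design counts must all be >= 1")
  for (tr in names(variance_components)) {
    vc <- variance_components[[tr]]
    if (any(vc < 0)) stopf("variance components for %s must be >= 0", tr)
  }
  if (any(diff(wavelength_grid) <= 0)) stopf("wavelength grid must be strictly increasing")
  for (st in c("fresh", "mashed")) {
    if (!st %in% names(readings_per_plot)) stopf("readings_per_plot lacks '%s'", st)
    if (readings_per_plot[[st]] < 1) stopf("readings_per_plot must be >= 1")
  }
  structure(
    list(n_clones = as.integer(n_clones), n_envs = as.integer(n_envs),
         n_reps = as.integer(n_reps), n_blocks_per_rep = as.integer(n_blocks_per_rep),
         variance_components = variance_components, trait_means = trait_means,
         env_sd = env_sd, dmcg_noise_sd = dmcg_noise_sd,
         wavelength_grid = as.numeric(wavelength_grid), bands = bands,
         base_absorbance = base_absorbance, scatter = scatter, noise_sd = noise_sd,
         readings_per_plot = readings_per_plot,
         trait_jitter_sd = trait_jitter_sd, trait_bias_sd = trait_bias_sd,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Simulate a plot-level trait table
#'
#' Generates trait observations under the multi-environment mixed model
#' \deqn{Y_{ijlk} = \mu + g_i + \beta_j + r_{l(j)} + \rho_{k(l)} + g\beta_{ij} + \epsilon_{ijlk}}
#' with the clone effect \eqn{g_i} shared across environments, environment
#' effects \eqn{\beta_j} drawn once and held fixed, and independent zero-mean
#' Gaussian replication-within-environment, block-within-replication,
#' clone-by-environment and residual effects at the configured variances.
#' DMCg is produced as DMCo plus independent measurement noise, mirroring the
#' gravimetric (air/water weighing) method being the noisier proxy for the
#' oven reference.
#'
#' @param config A [simulation_config()].
#' @return A data frame with columns `clone_id`, `env_id`, `rep_id`,
#'   `block_id`, `plot_id`, `StC`, `DMCo`, `DMCg`; one row per plot,
#'   `plot_id` unique.
#' @export
simulate_traits <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  nc <- config$n_clones; ne <- config$n_envs; nr <- config$n_reps
  nb <- config$n_blocks_per_rep

  design <- expand.grid(clone = seq_len(nc), rep = seq_len(nr), env = seq_len(ne),
                        KEEP.OUT.ATTRS = FALSE)
  ## round-robin assignment of clones to incomplete blocks within each rep
  design$block <- ((design$clone - 1L) %% nb) + 1L

  local_seed(derive_seed(config$seed, 101L), {
    beta <- rnorm(ne, 0, config$env_sd) # fixed environment effects

    traits <- list()
    for (tr in c("StC", "DMCo")) {
      vc <- config$variance_components[[tr]]
      g  <- rnorm(nc, 0, sqrt(vc[["sigma2_g"]]))
      r  <- matrix(rnorm(ne * nr, 0, sqrt(vc[["sigma2_r"]])), ne, nr)
      k  <- array(rnorm(ne * nr * nb, 0, sqrt(vc[["sigma2_k"]])), c(ne, nr, nb))
      ge <- matrix(rnorm(nc * ne, 0, sqrt(vc[["sigma2_ge"]])), nc, ne)
      e  <- rnorm(nrow(design), 0, sqrt(vc[["sigma2_e"]]))
      traits[[tr]] <- config$trait_means[[tr]] +
        g[design$clone] + beta[design$env] +
        r[cbind(design$env, design$rep)] +
        k[cbind(design$env, design$rep, design$block)] +
        ge[cbind(design$clone, design$env)] + e
    }
    dmcg <- traits$DMCo + rnorm(nrow(design), 0, config$dmcg_noise_sd)

    data.frame(
      clone_id = sprintf("C%04d", design$clone),
      env_id   = sprintf("E%02d", design$env),
      rep_id   = sprintf("R%d", design$rep),
      block_id = sprintf("B%d", design$block),
      plot_id  = sprintf("E%02d_R%d_C%04d", design$env, design$rep, design$clone),
      StC = traits$StC, DMCo = traits$DMCo, DMCg = dmcg,
      stringsAsFactors = FALSE
    )
  })
}

gaussian_band_matrix <- function(config) {
  wl <- config$wavelength_grid
  sapply(config$bands, function(b) exp(-0.5 * ((wl - b$center) / b$width)^2))
}

band_loading_matrix <- function(config, traits = c("StC", "DMCo")) {
  sapply(config$bands, function(b) {
    v <- stats::setNames(numeric(length(traits)), traits)
    v[names(b$loading)] <- b$loading
    v
  })
}

#' Simulate SCiO-like absorbance spectra for a trait table
#'
#' For every plot, generates `readings_per_plot[sample_type]` readings from
#' the forward model
#' \deqn{A_r(\lambda) = a_r \sum_k G_k(\lambda)\, l_k^\top t_r + b_r + c_r \tilde\lambda + \epsilon_r(\lambda)}
#' where \eqn{G_k} are Gaussian absorption bands, \eqn{l_k} their trait
#' loadings, \eqn{t_r} the trait values seen by reading r, \eqn{a_r} a
#' multiplicative scatter factor, \eqn{b_r} an additive baseline offset,
#' \eqn{c_r} a linear baseline tilt over the centred wavelength axis and
#' \eqn{\epsilon} iid channel noise. Fresh readings additionally perturb the
#' plot's trait values per reading (within-root heterogeneity) and per plot
#' (sampling bias of the scanned roots); scatter and noise are drawn at the
#' fresh or mashed level of the configuration.
#'
#' @param traits Trait table from [simulate_traits()].
#' @param sample_type `"fresh"` or `"mashed"`.
#' @param config The [simulation_config()] used for the traits.
#' @return A [spectral_dataset()].
#' @export
simulate_spectra <- function(traits, sample_type, config) {
  stopifnot(inherits(config, "simulation_config"))
  if (!sample_type %in% c("fresh", "mashed")) {
    stopf("unknown sample_type '%s' (use 'fresh' or 'mashed')", sample_type)
  }
  wl <- config$wavelength_grid
  nchan <- length(wl)
  nread <- as.integer(config$readings_per_plot[[sample_type]])
  nplot <- nrow(traits)
  sc <- config$scatter[[sample_type]]
  nsd <- config$noise_sd[[sample_type]]
  jit <- config$trait_jitter_sd[[sample_type]]
  bias <- config$trait_bias_sd[[sample_type]]

  G <- gaussian_band_matrix(config)          # nchan x nbands
  L <- band_loading_matrix(config)           # ntraits x nbands
  tilt_axis <- (wl - mean(range(wl))) / diff(range(wl))

  st_code <- if (sample_type == "fresh") 1L else 2L
  local_seed(derive_seed(config$seed, 202L, st_code), {
    T0 <- as.matrix(traits[, c("StC", "DMCo")])          # nplot x 2
    plot_bias <- matrix(rnorm(nplot * 2, 0, bias), nplot, 2)
    pa <- 1 + rnorm(nplot, 0, sc$plot_slope_sd)
    pb <- rnorm(nplot, 0, sc$plot_offset_sd)
    pc <- rnorm(nplot, 0, sc$plot_tilt_sd)

    n <- nplot * nread
    plot_ix <- rep(seq_len(nplot), each = nread)
    Tread <- T0[plot_ix, , drop = FALSE] + plot_bias[plot_ix, , drop = FALSE] +
      matrix(rnorm(n * 2, 0, jit), n, 2)
    a <- pa[plot_ix] * (1 + rnorm(n, 0, sc$slope_sd))
    b <- pb[plot_ix] + rnorm(n, 0, sc$offset_sd)
    cc <- pc[plot_ix] + rnorm(n, 0, sc$tilt_sd)

    signal <- (Tread %*% L) %*% t(G)                     # n x nchan
    A <- config$base_absorbance + a * signal +
      b + outer(cc, tilt_axis) +
      matrix(rnorm(n * nchan, 0, nsd), n, nchan)

    meta <- data.frame(
      reading_id = sprintf("%s_%s_r%02d", sample_type, traits$plot_id[plot_ix],
                           rep(seq_len(nread), times = nplot)),
      plot_id = traits$plot_id[plot_ix],
      sample_type = sample_type,
      stringsAsFactors = FALSE
    )
    spectral_dataset(wl, A, meta)
  })
}

#' Inject gross additive outliers into a spectral dataset
#'
#' Adds a constant absorbance offset to a random subset of readings,
#' emulating aberrant scans (stray light, bad contact) so that outlier
#' screening can be exercised end to end.
#'
#' @param ds A [spectral_dataset()].
#' @param fraction Fraction of readings to perturb; `ceiling(fraction * n)`
#'   readings are hit.
#' @param magnitude Absorbance offset added across all channels.
#' @param seed Integer seed.
#' @return A list with elements `dataset` (the perturbed data) and
#'   `flagged_ids` (reading ids that were perturbed).
#' @export
inject_spectral_outliers <- function(ds, fraction, magnitude, seed = 1L) {
  stopifnot(inherits(ds, "spectral_dataset"))
  n <- nrow(ds$absorbance)
  n_out <- ceiling(fraction * n)
  if (n_out == 0) return(list(dataset = ds, flagged_ids = character(0)))
  idx <- local_seed(derive_seed(seed, 303L), sample.int(n, n_out))
  A <- ds$absorbance
  A[idx, ] <- A[idx, ] + magnitude
  list(dataset = spectral_dataset(ds$wavelengths, A, ds$metadata, ds$treatment),
       flagged_ids = ds$metadata$reading_id[idx])
}
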