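#!/usr/bin/env Rscript
# Stage 1: simulate the multi-environment trial and its SCiO-like spectra.
#
# Generates plot-level StC / DMCo / DMCg under the variance-component model,
# then per-reading absorbance spectra for both sample preparations (47
# readings/plot fresh, 4 readings/plot mashed) and writes everything as CSV
# for the downstream stages.

source("analysis/00_config.R")

traits <- simulate_traits(SIM_CONFIG)
write_traits_csv(traits, file.path(DATA_DIR, "traits.csv"))

cat(sprintf("simulated %d plots (%d clones x %d envs x %d reps)\n",
            nrow(traits), SIM_CONFIG$n_clones, SIM_CONFIG$n_envs, SIM_CONFIG$n_reps))
cat(sprintf("trait summary: StC %.1f +/- %.1f %%, DMCo %.1f +/- %.1f %%, DMCg %.1f +/- %.1f %%\n",
            mean(traits$StC), sd(traits$StC), mean(traits$DMCo), sd(traits$DMCo),
            mean(traits$DMCg), sd(traits$DMCg)))

for (st in SAMPLE_TYPES) {
  ds <- simulate_spectra(traits, st, SIM_CONFIG)
  path <- file.path(DATA_DIR, sprintf("spectra_%s.csv", st))
  write_spectra_csv(ds, path)
  ## within-plot reading variability: the fresh regime should be far noisier
  wv <- mean(tapply(seq_len(nrow(ds$absorbance)), ds$metadata$plot_id, function(ix) {
    mean(apply(ds$absorbance[ix, , drop = FALSE], 2, var))
  }))
  cat(sprintf("%s: %d readings, mean within-plot channel variance %.2e -> %s\n",
              st, nrow(ds$absorbance), wv, path))
}
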