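# Shared configuration for the analysis scripts. Sourced by 01..05.
#
# The study replica runs at demonstration scale (100 clones, 2 environments,
# 2 replications) so the whole sequence finishes in a few minutes on one CPU
# while preserving the structure of the full design: both sample
# preparations, the pre-treatment comparison, all three engines, mixed-model
# deregression and selection concordance.

library(nirscassava)

MASTER_SEED <- 20260922L

SIM_CONFIG <- simulation_config(n_clones = 100, n_envs = 2, n_reps = 2,
                                seed = derive_seed(MASTER_SEED, 1L))
PROTOCOL <- cv_protocol(n_folds = 5, n_repeats = 2,
                        seed = derive_seed(MASTER_SEED, 2L))
TREATMENTS <- c("raw", "d1", "snv", "sg_snv")
ENGINES <- c("pls", "svm", "xgb")
TRAITS <- c("StC", "DMCo", "DMCg")
SAMPLE_TYPES <- c("fresh", "mashed")
SELECTION_FRACTION <- 0.20

RESULTS_DIR <- "results"
DATA_DIR <- file.path(RESULTS_DIR, "data")
dir.create(DATA_DIR, recursive = TRUE, showWarnings = FALSE)

## plot-level treated matrices for one sample type and treatment, with the
## calibration/holdout split learned once from the protocol seed
treated_split <- function(ds, treatment, traits_tab) {
  split <- split_dataset(traits_tab$plot_id, PROTOCOL)
  in_cal <- ds$metadata$plot_id %in% split$calibration
  ds_cal <- nirscassava:::subset_readings(ds, in_cal)
  ds_val <- nirscassava:::subset_readings(ds, !in_cal)
  t_cal <- apply_treatment(ds_cal, treatment)
  t_val <- apply_treatment(ds_val, treatment,
                           msc_reference = attr(t_cal, "msc_reference"))
  f_cal <- iqr_outlier_filter(t_cal)
  f_val <- iqr_outlier_filter(t_val, fences = f_cal$fences)
  list(cal = aggregate_readings(f_cal$kept), val = aggregate_readings(f_val$kept),
       split = split, n_flagged = length(f_cal$flagged_ids) + length(f_val$flagged_ids))
}
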