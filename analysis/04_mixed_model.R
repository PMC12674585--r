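#!/usr/bin/env Rscript
# Stage 4: multi-environment mixed model, BLUPs and deregression.
#
# Fits the variance-component model (clone, replication-in-environment,
# block-in-replication, clone-by-environment random; environment fixed) by
# REML for each trait, extracts clone BLUPs with prediction error variances,
# and deregresses them (dBLUP = BLUP / reliability) for selection.

source("analysis/00_config.R")

traits <- read_traits_csv(file.path(DATA_DIR, "traits.csv"))

rows <- list()
for (trait in TRAITS) {
  fit <- fit_mixed_model(traits, trait)
  ce <- deregress(fit)
  ce$trait <- trait
  vc <- fit$variance_components
  rows[[trait]] <- cbind(ce, as.data.frame(as.list(vc), check.names = FALSE))
  h2 <- vc[["sigma2_g"]] / sum(vc, na.rm = TRUE)
  cat(sprintf("%s: sigma2_g=%.2f sigma2_ge=%.2f sigma2_e=%.2f (variance share of clone: %.2f); mean reliability %.2f\n",
              trait, vc[["sigma2_g"]], vc[["sigma2_ge"]], vc[["sigma2_e"]],
              h2, mean(ce$reliability)))
}

blups <- do.call(rbind, rows)
write.csv(blups, file.path(RESULTS_DIR, "blups.csv"), row.names = FALSE)
cat(sprintf("wrote %s (%d clone x trait records)\n",
            file.path(RESULTS_DIR, "blups.csv"), nrow(blups)))
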