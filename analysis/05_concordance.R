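#!/usr/bin/env Rscript
# Stage 5: selection concordance between phenotype- and model-based rankings.
#
# Ranks clones by deregressed BLUPs of the observed traits (phenotype
# selection) and by deregressed BLUPs of each engine's plot-level
# predictions (model selection), selects the top 20% under each ranking,
# and quantifies agreement with Cohen's unweighted kappa, including all
# pairwise engine comparisons.

source("analysis/00_config.R")

traits <- read_traits_csv(file.path(DATA_DIR, "traits.csv"))
blups <- read.csv(file.path(RESULTS_DIR, "blups.csv"))
predictions <- jsonlite::read_json(file.path(RESULTS_DIR, "plot_predictions.json"),
                                   simplifyVector = TRUE)

dblup_rank <- function(plot_scores) {
  tab <- traits[traits$plot_id %in% names(plot_scores), ]
  tab$pred <- unname(unlist(plot_scores)[tab$plot_id])
  fit <- fit_mixed_model(tab, "pred")
  ce <- suppressWarnings(deregress(fit))
  setNames(ce$dblup, ce$clone_id)
}

rows <- list()
for (trait in TRAITS) {
  ce <- blups[blups$trait == trait, ]
  pheno <- setNames(ce$dblup, ce$clone_id)
  universe <- names(pheno)[!is.na(pheno)]
  for (st in SAMPLE_TYPES) {
    sels <- list(phenotype = select_top_fraction(pheno[universe], SELECTION_FRACTION))
    for (eng in ENGINES) {
      sc <- dblup_rank(predictions[[paste(trait, st, eng, sep = ".")]])
      sels[[eng]] <- suppressWarnings(
        select_top_fraction(sc[universe], SELECTION_FRACTION))
    }
    cm <- concordance_matrix(sels, universe)
    cm$long$trait <- trait
    cm$long$sample_type <- st
    rows[[paste(trait, st)]] <- cm$long
    ik <- cm$long[cm$long$method_a == "phenotype" | cm$long$method_b == "phenotype", ]
    cat(sprintf("%s %s: phenotype-vs-model kappa %s\n", trait, st,
                paste(sprintf("%s=%.2f",
                              ifelse(ik$method_a == "phenotype", ik$method_b, ik$method_a),
                              ik$kappa), collapse = " ")))
  }
}

kappa <- do.call(rbind, rows)
write.csv(kappa, file.path(RESULTS_DIR, "kappa.csv"), row.names = FALSE)
cat(sprintf("wrote %s (%d pairwise comparisons)\n",
            file.path(RESULTS_DIR, "kappa.csv"), nrow(kappa)))
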