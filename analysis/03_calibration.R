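#!/usr/bin/env Rscript
# Stage 3: calibrate PLS, SVM and XGB on the winning pre-treatment.
#
# For every trait and sample type, runs the two-stage residual-trim
# protocol (repeated 5-fold CV, 20% residual trim, refit) on the selected
# pre-treatment from stage 2, validates on the held-out 20% of plots, and
# saves the metric table plus plot-level predictions for the concordance
# stage.

source("analysis/00_config.R")

traits <- read_traits_csv(file.path(DATA_DIR, "traits.csv"))
winners <- jsonlite::read_json(file.path(RESULTS_DIR, "selected_treatments.json"),
                               simplifyVector = TRUE)
spectra <- lapply(setNames(nm = SAMPLE_TYPES), function(st) {
  read_spectra_csv(file.path(DATA_DIR, sprintf("spectra_%s.csv", st)))
})

metric_rows <- list()
predictions <- list()
for (trait in TRAITS) {
  trt <- winners[[trait]]
  y_all <- setNames(traits[[trait]], traits$plot_id)
  for (st in SAMPLE_TYPES) {
    m <- treated_split(spectra[[st]], trt, traits)
    for (eng in ENGINES) {
      run <- residual_trim_refit(m$cal$X, y_all[rownames(m$cal$X)],
                                 engine_spec(eng), PROTOCOL,
                                 m$val$X, y_all[rownames(m$val$X)],
                                 trait = trait, sample_type = st, treatment = trt)
      all_X <- rbind(m$cal$X, m$val$X)
      predictions[[paste(trait, st, eng, sep = ".")]] <-
        as.list(setNames(predict(run$model, all_X), rownames(all_X)))
      for (part in c("cv", "validation")) {
        ms <- if (part == "cv") run$metrics_cv else run$metrics_val
        metric_rows[[paste(trait, st, eng, part)]] <- cbind(
          data.frame(trait = trait, sample_type = st, treatment = trt,
                     engine = eng, partition = part),
          as.data.frame(ms))
      }
      cat(sprintf("%s %s/%s %s: CV R=%.3f RMSE=%.3f | val R=%.3f RMSE=%.3f RPD=%.2f (%s)\n",
                  trait, st, trt, eng, run$metrics_cv$r, run$metrics_cv$rmse,
                  run$metrics_val$r, run$metrics_val$rmse, run$metrics_val$rpd,
                  interpret_rpd(run$metrics_val$rpd)))
    }
  }
}

metrics <- do.call(rbind, metric_rows)
write.csv(metrics, file.path(RESULTS_DIR, "calibration_metrics.csv"), row.names = FALSE)
jsonlite::write_json(predictions, file.path(RESULTS_DIR, "plot_predictions.json"),
                     auto_unbox = TRUE, digits = NA)

cvm <- metrics[metrics$partition == "cv", ]
cat(sprintf("\nmean CV R: mashed %.3f vs fresh %.3f across all engines and traits\n",
            mean(cvm$r[cvm$sample_type == "mashed"]),
            mean(cvm$r[cvm$sample_type == "fresh"])))
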