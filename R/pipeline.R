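#' Assemble a pipeline configuration
#'
#' One configuration object drives the whole study replica: simulation,
#' pre-treatment comparison, engine calibration, mixed-model BLUPs and
#' selection concordance. All stage seeds are derived from `master_seed`, so
#' a fixed configuration is fully deterministic for deterministic engines.
#'
#' @param simulation A [simulation_config()]; its `seed` is overridden from
#'   `master_seed`.
#' @param treatments Character vector of treatment names to compare.
#' @param engines Character vector among `c("pls", "svm", "xgb")`.
#' @param protocol A [cv_protocol()]; its `seed` is overridden from
#'   `master_seed`.
#' @param traits Subset of `c("StC", "DMCo", "DMCg")`.
#' @param sample_types Subset of `c("fresh", "mashed")`.
#' @param selection_fraction Top fraction for clone selection (default 0.20).
#' @param output_dir Output directory for tables and the manifest.
#' @param master_seed Integer master seed.
#' @param full_factorial If `TRUE`, every engine is calibrated for every
#'   treatment; by default non-PLS engines run only on the treatment that
#'   wins the PLS-based comparison, matching the study workflow.
#' @param write_spectra If `TRUE`, simulated spectra are also written as CSV
#'   (large); trait tables are always written.
#' @param resume If `TRUE`, factorial cells whose per-run JSON already exists
#'   in `output_dir/runs` are loaded instead of recomputed.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(simulation = simulation_config(),
                            treatments = TREATMENT_NAMES,
                            engines = c("pls", "svm", "xgb"),
                            protocol = cv_protocol(),
                            traits = c("StC", "DMCo", "DMCg"),
                            sample_types = c("fresh", "mashed"),
                            selection_fraction = 0.20,
                            output_dir = tempfile("nirs_run_"),
                            master_seed = 1L,
                            full_factorial = FALSE,
                            write_spectra = FALSE,
                            resume = FALSE) {
  if (!length(traits) || !length(engines) || !length(treatments)) {
    stopf("traits, engines and treatments must all be non-empty")
  }
  stopifnot(all(traits %in% c("StC", "DMCo", "DMCg")),
            all(sample_types %in% c("fresh", "mashed")),
            all(engines %in% c("pls", "svm", "xgb")),
            all(treatments %in% TREATMENT_NAMES))
  simulation$seed <- derive_seed(master_seed, 1L)
  protocol$seed <- derive_seed(master_seed, 2L)
  structure(list(simulation = simulation, treatments = treatments,
                 engines = engines, protocol = protocol, traits = traits,
                 sample_types = sample_types,
                 selection_fraction = selection_fraction,
                 output_dir = output_dir, master_seed = as.integer(master_seed),
                 full_factorial = full_factorial, write_spectra = write_spectra,
                 resume = resume),
            class = "pipeline_config")
}

## Treat calibration and holdout readings without leakage: MSC references and
## IQR fences are learned on the calibration readings only, then applied to
## the holdout readings; both partitions are aggregated to plot-mean spectra.
prepare_treated_matrices <- function(ds, treatment, cal_plots, val_plots) {
  in_cal <- ds$metadata$plot_id %in% cal_plots
  ds_cal <- subset_readings(ds, in_cal)
  ds_val <- subset_readings(ds, !in_cal)
  t_cal <- apply_treatment(ds_cal, treatment)
  t_val <- apply_treatment(ds_val, treatment,
                           msc_reference = attr(t_cal, "msc_reference"))
  filt_cal <- iqr_outlier_filter(t_cal)
  filt_val <- iqr_outlier_filter(t_val, fences = filt_cal$fences)
  agg_cal <- aggregate_readings(filt_cal$kept)
  agg_val <- aggregate_readings(filt_val$kept)
  list(X_cal = agg_cal$X, X_val = agg_val$X,
       flagged = c(filt_cal$flagged_ids, filt_val$flagged_ids))
}

run_one_cell <- function(X_cal, y_cal, X_val, y_val, engine, protocol,
                         trait, sample_type, treatment, all_X, plot_to_clone) {
  spec <- engine_spec(engine)
  run <- residual_trim_refit(X_cal, y_cal, spec, protocol, X_val, y_val,
                             trait = trait, sample_type = sample_type,
                             treatment = treatment)
  ## plot-level predictions over the whole trial, for the mixed-model-based
  ## clone ranking used in the concordance stage
  pred_all <- predict(run$model, all_X)
  run$plot_predictions <- stats::setNames(pred_all, rownames(all_X))
  run
}

## clone ranking from plot-level scores: fit the multi-environment mixed
## model to the scores and deregress, so model-based and phenotype-based
## selections are compared on the same (dBLUP) footing. If the predictions
## carry no detectable genetic variance (sigma2_g at the boundary, all
## deregressions undefined) the ranking falls back to plain clone means.
dblup_scores <- function(traits_tab, plot_scores) {
  tab <- traits_tab[traits_tab$plot_id %in% names(plot_scores), ]
  tab$pred <- unname(plot_scores[tab$plot_id])
  dbl <- tryCatch({
    fit <- fit_mixed_model(tab, "pred")
    ce <- suppressWarnings(deregress(fit))
    stats::setNames(ce$dblup, ce$clone_id)
  }, error = function(e) NULL)
  if (is.null(dbl) || mean(is.na(dbl)) > 0.5) {
    cm <- tapply(tab$pred, tab$clone_id, mean)
    dbl <- stats::setNames(as.vector(cm), names(cm))
  }
  dbl
}

run_record <- function(run) {
  list(trait = run$trait, sample_type = run$sample_type,
       treatment = run$treatment, engine = run$engine,
       chosen_pls_components = run$chosen_pls_components,
       trimmed_ids = run$trimmed_ids,
       metrics_cv = unclass(run$metrics_cv),
       metrics_val = if (!is.null(run$metrics_val)) unclass(run$metrics_val),
       holdout_predictions = as.list(run$holdout_predictions),
       plot_predictions = as.list(run$plot_predictions))
}

#' Run the full study replica
#'
#' Executes simulate -> pre-treat -> calibrate -> validate -> BLUP ->
#' concordance from one [pipeline_config()]. Per-treatment PLS runs feed the
#' treatment comparison for each trait; every configured engine is then
#' calibrated (on the winning treatment by default, on all treatments under
#' `full_factorial`) with residual trimming and holdout validation. Trait
#' dBLUPs from the multi-environment mixed model define the phenotype-based
#' ranking against which model-based selections are scored with Cohen's
#' kappa, including all pairwise engine comparisons. Each factorial cell is
#' written as JSON under `output_dir/runs` as it completes; a failed cell is
#' logged in the manifest and the remaining cells continue.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the tables written to `output_dir`:
#'   `treatment_selection`, `metrics` (cv + validation per cell), `blups`,
#'   `kappa`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$output_dir
  dir.create(file.path(out, "runs"), recursive = TRUE, showWarnings = FALSE)
  errors <- list()

  traits_tab <- simulate_traits(config$simulation)
  write_traits_csv(traits_tab, file.path(out, "traits.csv"))
  plot_to_clone <- stats::setNames(traits_tab$clone_id, traits_tab$plot_id)

  spectra <- lapply(stats::setNames(nm = config$sample_types), function(st) {
    ds <- simulate_spectra(traits_tab, st, config$simulation)
    if (config$write_spectra) write_spectra_csv(ds, file.path(out, sprintf("spectra_%s.csv", st)))
    ds
  })

  split <- split_dataset(traits_tab$plot_id, config$protocol)
  y_of <- function(trait, plots) {
    stats::setNames(traits_tab[[trait]], traits_tab$plot_id)[plots]
  }

  ## treated plot-level matrices per sample_type x treatment
  mats <- list()
  for (st in config$sample_types) {
    for (tr in config$treatments) {
      mats[[st]][[tr]] <- prepare_treated_matrices(spectra[[st]], tr,
                                                   split$calibration, split$holdout)
    }
  }

  cell_path <- function(trait, st, tr, eng) {
    file.path(out, "runs", sprintf("%s_%s_%s_%s.json", trait, st, tr, eng))
  }
  exec_cell <- function(trait, st, tr, eng) {
    pth <- cell_path(trait, st, tr, eng)
    if (config$resume && file.exists(pth)) {
      rec <- jsonlite::read_json(pth, simplifyVector = TRUE)
      rec$metrics_cv <- structure(as.list(rec$metrics_cv), class = "metric_set")
      if (!is.null(rec$metrics_val)) {
        rec$metrics_val <- structure(as.list(rec$metrics_val), class = "metric_set")
      }
      rec$plot_predictions <- unlist(rec$plot_predictions)
      return(rec)
    }
    m <- mats[[st]][[tr]]
    all_X <- rbind(m$X_cal, m$X_val)
    run <- run_one_cell(m$X_cal, y_of(trait, rownames(m$X_cal)),
                        m$X_val, y_of(trait, rownames(m$X_val)),
                        eng, config$protocol, trait, st, tr, all_X, plot_to_clone)
    jsonlite::write_json(run_record(run), pth, auto_unbox = TRUE, digits = NA,
                         null = "null")
    run
  }
  safe_cell <- function(trait, st, tr, eng) {
    tryCatch(exec_cell(trait, st, tr, eng), error = function(e) {
      errors[[length(errors) + 1]] <<- list(trait = trait, sample_type = st,
                                            treatment = tr, engine = eng,
                                            message = conditionMessage(e))
      NULL
    })
  }

  ## stage 1: PLS per treatment -> treatment selection per trait
  selection_tabs <- list()
  chosen <- list()
  pls_runs <- list()
  for (trait in config$traits) {
    runs <- list()
    for (st in config$sample_types) {
      for (tr in config$treatments) {
        r <- safe_cell(trait, st, tr, "pls")
        if (!is.null(r)) {
          runs[[paste(st, tr, sep = ".")]] <- r
          pls_runs[[paste(trait, st, tr, sep = ".")]] <- r
        }
      }
    }
    sel <- select_treatment(runs)
    chosen[[trait]] <- sel$treatment
    sel$ranking$trait <- trait
    selection_tabs[[trait]] <- sel$ranking
  }

  ## stage 2: all engines on the selected treatment (or full factorial)
  all_runs <- list()
  for (trait in config$traits) {
    trs <- if (config$full_factorial) config$treatments else chosen[[trait]]
    for (st in config$sample_types) {
      for (tr in trs) {
        for (eng in config$engines) {
          key <- paste(trait, st, tr, eng, sep = ".")
          r <- if (eng == "pls" && !is.null(pls_runs[[paste(trait, st, tr, sep = ".")]])) {
            pls_runs[[paste(trait, st, tr, sep = ".")]]
          } else {
            safe_cell(trait, st, tr, eng)
          }
          if (!is.null(r)) all_runs[[key]] <- r
        }
      }
    }
  }

  ## mixed model + dBLUPs per trait
  blup_tabs <- list()
  for (trait in config$traits) {
    fit <- fit_mixed_model(traits_tab, trait)
    ce <- deregress(fit)
    ce$trait <- trait
    blup_tabs[[trait]] <- cbind(ce,
      as.data.frame(as.list(fit$variance_components), check.names = FALSE))
  }
  blups <- do.call(rbind, blup_tabs)
  utils::write.csv(blups, file.path(out, "blups.csv"), row.names = FALSE)

  ## selection concordance per trait x sample_type
  kappa_rows <- list()
  for (trait in config$traits) {
    ce <- blup_tabs[[trait]]
    pheno_scores <- stats::setNames(ce$dblup, ce$clone_id)
    for (st in config$sample_types) {
      tr <- chosen[[trait]]
      sels <- list()
      universe <- names(pheno_scores)[!is.na(pheno_scores)]
      for (eng in config$engines) {
        r <- all_runs[[paste(trait, st, tr, eng, sep = ".")]]
        if (is.null(r)) next
        sc <- dblup_scores(traits_tab, r$plot_predictions)[universe]
        sels[[eng]] <- suppressWarnings(
          select_top_fraction(sc, config$selection_fraction))
      }
      sels[["phenotype"]] <- select_top_fraction(pheno_scores[universe],
                                                 config$selection_fraction)
      if (length(sels) >= 2) {
        cm <- concordance_matrix(sels, universe)
        cm$long$trait <- trait
        cm$long$sample_type <- st
        cm$long$treatment <- tr
        kappa_rows[[paste(trait, st)]] <- cm$long
      }
    }
  }
  kappa_tab <- do.call(rbind, kappa_rows)
  utils::write.csv(kappa_tab, file.path(out, "kappa.csv"), row.names = FALSE)

  metrics_tab <- do.call(rbind, lapply(all_runs, function(r) {
    cbind(data.frame(trait = r$trait, sample_type = r$sample_type,
                     treatment = r$treatment, engine = r$engine,
                     partition = c("cv", "validation"),
                     stringsAsFactors = FALSE),
          rbind(as.data.frame(r$metrics_cv),
                as.data.frame(r$metrics_val %||% r$metrics_cv)))
  }))
  utils::write.csv(metrics_tab, file.path(out, "metrics.csv"), row.names = FALSE)
  sel_tab <- do.call(rbind, selection_tabs)
  utils::write.csv(sel_tab, file.path(out, "treatment_selection.csv"), row.names = FALSE)

  files <- list.files(out, recursive = TRUE, full.names = TRUE)
  manifest <- list(
    master_seed = config$master_seed,
    simulation_seed = config$simulation$seed,
    protocol_seed = config$protocol$seed,
    chosen_treatments = chosen,
    n_cells = length(all_runs),
    errors = errors,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    files = lapply(stats::setNames(files, basename(files)),
                   function(f) unname(tools::md5sum(f)))
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(treatment_selection = sel_tab, metrics = metrics_tab,
                 blups = blups, kappa = kappa_tab, runs = all_runs,
                 chosen_treatments = chosen, manifest = manifest,
                 traits_table = traits_tab, split = split))
}

#' A small demonstration configuration
#'
#' A reduced-scale configuration (fewer clones and treatments) that runs the
#' whole pipeline in a few minutes on one CPU while preserving the study
#' structure: both sample types, all three engines, treatment comparison,
#' BLUP deregression and kappa concordance.
#'
#' @param output_dir Output directory.
#' @param master_seed Integer master seed.
#' @return A [pipeline_config()].
#' @export
demo_config <- function(output_dir = tempfile("nirs_demo_"), master_seed = 1L) {
  pipeline_config(
    simulation = simulation_config(n_clones = 100, n_envs = 2, n_reps = 2),
    treatments = c("raw", "d1", "snv", "sg_snv"),
    engines = c("pls", "svm", "xgb"),
    protocol = cv_protocol(n_folds = 5, n_repeats = 2),
    traits = c("StC", "DMCo"),
    sample_types = c("fresh", "mashed"),
    output_dir = output_dir,
    master_seed = master_seed
  )
}
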