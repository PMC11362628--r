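# End-to-end orchestration: simulate -> label -> fit -> predict ->
# evaluate -> screen, with per-stage seeds derived from one master seed and
# a manifest recording counts and configuration, so a rerun with the same
# configuration is byte-identical.

#' Pipeline configuration
#'
#' @param sim A `sim_config` (its `seed` is overridden by the derived
#'   simulate-stage seed).
#' @param gap A `fairness_gap`.
#' @param fies A `fies_config`.
#' @param formula Fixed-effect design for model fitting.
#' @param horizons Prediction horizons in days.
#' @param group_by Grouping variables for the fairness report.
#' @param cutoff_mode,outcome_mode,B,level Evaluation options (see
#'   [fairness_report()]).
#' @param fit_model TRUE to estimate model parameters from the simulated
#'   registry; FALSE to forecast under the generative parameters.
#' @param n_samples Monte Carlo samples per encounter forecast.
#' @param seed Master seed; stage seeds are derived by hashing stage names.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), gap = fairness_gap("none"),
                            fies = fies_config(),
                            formula = default_lung_formula(),
                            horizons = default_horizons(),
                            group_by = c("race", "ethnicity"),
                            cutoff_mode = "shared",
                            outcome_mode = "any_visit_in_horizon",
                            B = 2000, level = 0.95, fit_model = TRUE,
                            n_samples = 500, seed = 1L) {
  stopifnot(inherits(sim, "sim_config"), inherits(gap, "fairness_gap"),
            inherits(fies, "fies_config"))
  structure(list(sim = sim, gap = gap, fies = fies, formula = formula,
                 horizons = horizons, group_by = group_by,
                 cutoff_mode = cutoff_mode, outcome_mode = outcome_mode,
                 B = B, level = level, fit_model = fit_model,
                 n_samples = n_samples, seed = as.integer(seed)),
            class = "pipeline_config")
}

config_hash <- function(config) {
  string_hash(paste(deparse(config), collapse = ""))
}

#' Run the full fairness-audit pipeline
#'
#' Executes all stages in dependency order on synthetic data and writes the
#' documented CSV artifacts plus a JSON manifest to `out_dir`.
#'
#' @param config A `pipeline_config`.
#' @param out_dir Optional output directory; when NULL nothing is written.
#' @param quiet Suppress per-stage progress lines.
#' @return Invisibly, a list with `registry`, `labels`, `fit` (or NULL),
#'   `params`, `probabilities`, `report`, `screening`, `rates`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  manifest <- list(config_hash = config_hash(config), master_seed = config$seed,
                   stages = list())
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- c(list(seed = stage_seed(config$seed, stage)), list(...))
  }

  sim <- config$sim
  sim$seed <- stage_seed(config$seed, "simulate")
  reg <- generate_registry(sim, config$gap)
  note("simulate", n_patients = nrow(reg$patients),
       n_encounters = nrow(reg$encounters),
       n_clipped = attr(reg, "n_clipped"), gap_mode = config$gap$gap_mode)
  say("simulate: %d patients, %d encounters", nrow(reg$patients), nrow(reg$encounters))

  labels <- fies_label_registry(reg, config$fies)
  note("label", n_labeled = sum(!is.na(labels$is_pex)),
       n_pex = sum(labels$is_pex, na.rm = TRUE),
       n_unlabeled = sum(is.na(labels$is_pex)))
  say("label: %d PEx among %d labeled encounters",
      sum(labels$is_pex, na.rm = TRUE), sum(!is.na(labels$is_pex)))

  fit <- NULL
  if (config$fit_model) {
    fit <- fit_lung_model(reg, config$formula)
    params <- fit$params
    note("fit", converged = fit$converged, loglik = fit$loglik,
         iterations = fit$iterations)
    say("fit: logLik %.2f, converged %s", fit$loglik, fit$converged)
  } else {
    params <- config$sim$true_params
    note("fit", skipped = TRUE)
    say("fit: skipped (using generative parameters)")
  }

  probs <- predict_pex(reg, labels, params, fies = config$fies,
                       horizons = config$horizons, n_samples = config$n_samples,
                       seed = stage_seed(config$seed, "predict"))
  note("predict", n_rows = nrow(probs),
       n_encounters_scored = length(unique(paste(probs$patient_id, probs$t))))
  say("predict: %d probability rows", nrow(probs))

  report <- fairness_report(reg, labels, probs, horizons = config$horizons,
                            group_by = config$group_by,
                            cutoff_mode = config$cutoff_mode,
                            outcome_mode = config$outcome_mode,
                            B = config$B, level = config$level,
                            seed = stage_seed(config$seed, "evaluate"))
  note("evaluate", n_rows = nrow(report),
       n_dropped = unname(report$n_dropped[1]))
  say("evaluate: %d report rows", nrow(report))

  screening <- screening_table(reg)
  rates <- encounter_rates(reg, labels)
  note("screen", n_rows = nrow(screening))
  say("screen: %d rows", nrow(screening))

  out <- list(registry = reg, labels = labels, fit = fit, params = params,
              probabilities = probs, report = report, screening = screening,
              rates = rates, manifest = manifest)
  if (!is.null(out_dir)) {
    write_pipeline_outputs(out, config, out_dir)
    say("wrote outputs to %s", out_dir)
  }
  invisible(out)
}

write_pipeline_outputs <- function(out, config, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_registry(out$registry, out_dir)
  wcsv <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE, quote = FALSE)
  }
  wcsv(out$labels, "labels.csv")
  wcsv(out$probabilities, "predictions.csv")
  wcsv(out$report, "fairness_report.csv")
  wcsv(out$screening, "screening_table.csv")
  wcsv(out$rates, "encounter_rates.csv")
  wcsv(genotype_by_race(out$registry), "genotype_by_race.csv")
  params <- out$params
  jsonlite::write_json(
    list(beta = as.list(params$beta), G = params$G,
         sigma_w2 = params$sigma_w2, sigma_e2 = params$sigma_e2),
    file.path(out_dir, "model_params.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(out$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
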