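#' Read a cohort from CSV files
#'
#' Trials CSV schema: `participant_id` (string), `familiarity` (`FM`/`NM`),
#' `context` (`SC`/`OC`), `rt_s` (seconds), `response` (1 correct /
#' 0 error), optional `censored` (0/1). Covariates CSV: `participant_id`
#' plus one numeric column per test. RT is seconds on disk; milliseconds
#' appear only in human-readable summaries. Schema violations are reported
#' with row numbers by the cohort validator.
#'
#' @param trials_path,covariates_path CSV file paths.
#' @return A [cohort_data()] object.
#' @export
read_cohort_csv <- function(trials_path, covariates_path) {
  tr <- as.data.frame(data.table::fread(trials_path))
  cov <- as.data.frame(data.table::fread(covariates_path))
  cohort_data(tr, cov)
}

#' Write a cohort to CSV files
#'
#' @param cohort A [cohort_data()] object.
#' @param trials_path,covariates_path Output CSV paths.
#' @export
write_cohort_csv <- function(cohort, trials_path, covariates_path) {
  data.table::fwrite(cohort$trials, trials_path)
  data.table::fwrite(cohort$covariates, covariates_path)
  invisible(c(trials_path, covariates_path))
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

pipe_log <- function(verbose, fmt, ...) {
  if (verbose)
    message(format(Sys.time(), "%H:%M:%S "), sprintf(fmt, ...))
}

#' Simulate a cohort to disk
#'
#' Writes `trials.csv`, `covariates.csv` and `truth.json` (the exact
#' ground-truth record) under `out_dir`.
#'
#' @param config A [generator_config()] object.
#' @param out_dir Output directory (created if needed).
#' @param seed Seed passed to [generate_cohort()].
#' @param verbose Log progress messages.
#' @return Invisibly, the generated `list(cohort, truth)`.
#' @export
run_simulate <- function(config = generator_config(), out_dir,
                         seed = config$seed, verbose = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_cohort(config, seed = seed)
  write_cohort_csv(gen$cohort, file.path(out_dir, "trials.csv"),
                   file.path(out_dir, "covariates.csv"))
  truth <- gen$truth
  truth$subjects <- lapply(seq_len(nrow(truth$subjects)), function(r)
    as.list(truth$subjects[r, ]))
  write_json_report(truth, file.path(out_dir, "truth.json"))
  pipe_log(verbose, "simulated %d trials for %d participants (seed %d)",
           nrow(gen$cohort$trials), config$n_participants, seed)
  invisible(gen)
}

#' Run the classical behavioral pipeline
#'
#' Applies, in order: participant-level 3-SD exclusion, trial-level 3-SD
#' exclusion, censored-trial removal; then computes condition descriptives,
#' 2x2 repeated-measures ANOVAs for RT and accuracy, pairwise
#' Bonferroni-corrected comparisons, and the covariate-by-condition Pearson
#' correlation table. All artifacts are written to `out_dir` together with
#' the exclusion ledger.
#'
#' @param cohort A [cohort_data()] object.
#' @param out_dir Output directory.
#' @param verbose Log progress messages.
#' @return Invisibly, a list with the filtered cohort and all reports.
#' @export
run_behav <- function(cohort, out_dir, verbose = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- exclude_participants(cohort)
  pipe_log(verbose, "participant exclusion: %s",
           format_ledger_entry(cohort$ledger[[length(cohort$ledger)]]))
  cohort <- exclude_trials(cohort)
  pipe_log(verbose, "trial exclusion: %s",
           format_ledger_entry(cohort$ledger[[length(cohort$ledger)]]))
  cohort <- drop_censored(cohort)
  desc <- condition_summaries(cohort)
  anova_rt <- rm_anova_2x2(cell_means(cohort, "rt"))
  anova_acc <- rm_anova_2x2(cell_means(cohort, "accuracy"))
  pw_rt <- pairwise_bonferroni(cell_means(cohort, "rt"))
  cors <- correlation_table(cohort)
  data.table::fwrite(desc, file.path(out_dir, "descriptives.csv"))
  data.table::fwrite(cbind(dependent = rep(c("rt", "accuracy"), each = 3),
                           rbind(anova_rt, anova_acc)),
                     file.path(out_dir, "anova.csv"))
  data.table::fwrite(pw_rt, file.path(out_dir, "pairwise_rt.csv"))
  cor_df <- data.frame(test = rownames(cors$r), round(cors$r, 4),
                       check.names = FALSE)
  data.table::fwrite(cor_df, file.path(out_dir, "correlations.csv"))
  write_json_report(cohort$ledger, file.path(out_dir, "exclusions.json"))
  invisible(list(cohort = cohort, descriptives = desc, anova_rt = anova_rt,
                 anova_accuracy = anova_acc, pairwise_rt = pw_rt,
                 correlations = cors, ledger = cohort$ledger))
}

format_ledger_entry <- function(e) {
  sprintf("%s removed %d of %d (%.2f%%)", e$rule, e$n_removed, e$n_before,
          e$pct_removed)
}

#' Fit a model and write its reports
#'
#' Preprocesses (exclusions + censoring), fits the requested model, and
#' writes `fit_<label>.json` (DIC, Geweke table, effect summaries, PPC) and
#' a flat `posterior_<label>.csv` of draws (`iteration`, `parameter`,
#' `value`) to `out_dir`.
#'
#' @inheritParams fit_ddm
#' @param cohort A [cohort_data()] object (raw; exclusions applied here).
#' @param out_dir Output directory.
#' @param preprocess Apply the exclusion pipeline before fitting.
#' @param verbose Log progress messages.
#' @return Invisibly, the `ddm_fit`.
#' @export
run_fit <- function(cohort, kind = "fc", covariate = NULL, out_dir,
                    n_samples = 12000, n_burn = 2000, seed = 1,
                    n_rep_ppc = 0, preprocess = TRUE, verbose = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (preprocess) {
    cohort <- exclude_participants(cohort)
    cohort <- exclude_trials(cohort)
    cohort <- drop_censored(cohort)
  }
  fit <- fit_ddm(cohort, kind, covariate, n_samples, n_burn, seed,
                 n_rep_ppc = n_rep_ppc)
  label <- if (is.null(covariate)) kind else paste0(kind, "_", covariate)
  report <- list(
    model = list(kind = kind, covariate = covariate,
                 n_participants = fit$model$nsub,
                 n_trials = length(fit$model$rt),
                 n_samples = n_samples, n_burn = n_burn, seed = seed),
    dic = fit$dic, geweke = fit$geweke, effects = fit$effects,
    ppc = fit$ppc, ledger = cohort$ledger)
  write_json_report(report, file.path(out_dir, paste0("fit_", label, ".json")))
  dr <- fit$samples$draws
  flat <- data.table::data.table(
    iteration = rep(seq_len(nrow(dr)), ncol(dr)),
    parameter = rep(colnames(dr), each = nrow(dr)),
    value = as.numeric(dr))
  data.table::fwrite(flat, file.path(out_dir, paste0("posterior_", label, ".csv")))
  pipe_log(verbose, "fit '%s': DIC %.1f", label, fit$dic$dic)
  invisible(fit)
}

#' Fit and compare the model family by DIC
#'
#' Fits the two base models (null, fc) and one full model per covariate,
#' writes `dic_table.csv` ordered base models first then full models
#' alphabetically, and returns the table.
#'
#' @inheritParams compare_models
#' @param cohort A [cohort_data()] object (raw; exclusions applied here).
#' @param out_dir Output directory.
#' @param preprocess Apply the exclusion pipeline before fitting.
#' @param verbose Log progress messages.
#' @return The DIC table, invisibly.
#' @export
run_compare <- function(cohort, covariates = character(0), out_dir,
                        n_samples = 12000, n_burn = 2000, seed = 1,
                        preprocess = TRUE, verbose = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (preprocess) {
    cohort <- exclude_participants(cohort)
    cohort <- exclude_trials(cohort)
    cohort <- drop_censored(cohort)
  }
  tab <- compare_models(cohort, covariates, n_samples, n_burn, seed)
  data.table::fwrite(tab, file.path(out_dir, "dic_table.csv"))
  pipe_log(verbose, "compared %d models", nrow(tab))
  invisible(tab)
}

#' Parameter-recovery experiment
#'
#' Generates `n_replicates` cohorts from known truth, fits the requested
#' model to each, and reports per-replicate and pooled coverage of the
#' group-level 95% HDIs over the true values, plus the familiarity-effect
#' posterior summaries. Writes `recovery.csv` and `recovery_summary.json`.
#'
#' @param config A [generator_config()] object.
#' @param n_replicates Number of replicate cohorts.
#' @param kind,covariate Model fitted to each replicate.
#' @param n_samples,n_burn Sampler settings per fit.
#' @param seed Master seed (drives cohorts and fits).
#' @param out_dir Output directory (optional; no files written if missing).
#' @return data.frame of per-replicate, per-parameter recovery rows.
#' @export
run_recover <- function(config = generator_config(), n_replicates = 3,
                        kind = "fc", covariate = NULL,
                        n_samples = 3000, n_burn = 500, seed = 1,
                        out_dir = NULL) {
  suite <- make_recovery_suite(n_replicates, config, seed)
  rows <- list()
  for (r in seq_along(suite)) {
    gen <- suite[[r]]
    truth <- gen$truth$group
    model <- build_model(kind, drop_censored(gen$cohort), covariate)
    samples <- sample_posterior(model, n_samples, n_burn, seed = seed + r)
    for (p in group_nodes(model)) {
      tv <- truth_value_for(p, truth)
      if (is.na(tv)) next
      h <- hdi(samples$draws[, p])
      rows[[length(rows) + 1]] <- data.frame(
        replicate = r, parameter = p, truth = tv,
        post_mean = mean(samples$draws[, p]),
        hdi_low = h[1], hdi_high = h[2],
        covered = tv >= h[1] & tv <= h[2],
        prob_positive = mean(samples$draws[, p] > 0))
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    data.table::fwrite(out, file.path(out_dir, "recovery.csv"))
    write_json_report(list(coverage = mean(out$covered),
                           n_replicates = n_replicates),
                      file.path(out_dir, "recovery_summary.json"))
  }
  out
}

# Map a group-level node label to its ground-truth value.
truth_value_for <- function(param, truth) {
  map <- c(mu_v = "mu_v", sigma_v = "sigma_v", mu_a = "mu_a",
           sigma_a = "sigma_a", mu_t0 = "mu_t0", sigma_t0 = "sigma_t0",
           sv = "sv", st = "st", mu_bF = "mu_bF", sigma_bF = "sigma_bF",
           mu_bC = "mu_bC", sigma_bC = "sigma_bC", beta_v = "beta_v",
           beta_a = "beta_a", beta_t = "beta_t")
  if (!param %in% names(map)) return(NA_real_)
  as.numeric(truth[[map[[param]]]])
}
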