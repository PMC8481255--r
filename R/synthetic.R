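#' Synthetic cohort generator configuration
#'
#' Describes a cohort with the study design this pipeline targets: a 2x2
#' within-subject design (FAMILIARITY FM/NM crossed with CONTEXT SC/OC),
#' 38 participants x 31 trials per cell (124 per participant, 4712
#' responses), a 5 s response deadline, and seven between-subject
#' neuropsychological test scores of which one (COWAT_Semantic by default)
#' carries true covariate slopes; the other six have zero true effect so
#' specificity can be tested.
#'
#' The ground-truth population values default to: familiarity drift effect
#' `mu_bF = 0.76`, context effect `mu_bC = 0.06`, covariate slopes
#' 0.16 / -0.11 / -0.03 on drift, boundary and non-decision time (per unit
#' z-score). The base parameters (`mu_v = 2.75`, `mu_a = 2.6`,
#' `mu_t0 = 0.39` s, `sv = 1.9`) are tuned via the closed-form choice
#' probability and mean decision time so that simulated FM/NM accuracy is
#' about 93%/87% and the grand mean RT about 1.0 s, matching the
#' descriptive scale of the task being emulated; they are a modelling
#' choice, not measured population values.
#'
#' @param n_participants Number of participants.
#' @param trials_per_cell Trials per condition cell (x4 = trials per
#'   participant).
#' @param truth Named list of population ground-truth values; partial
#'   overrides are merged into the defaults.
#' @param covariate_dist data.frame (`test`, `mean`, `sd`) of score
#'   distributions.
#' @param active_covariate Which test carries the true slopes.
#' @param deadline Censoring deadline, seconds.
#' @param dt Euler step of the forward simulator, seconds.
#' @param seed Default seed used by [generate_cohort()].
#' @return List of class `generator_config`.
#' @export
generator_config <- function(n_participants = 38, trials_per_cell = 31,
                             truth = list(), covariate_dist = NULL,
                             active_covariate = "COWAT_Semantic",
                             deadline = 5, dt = 1e-4, seed = 1) {
  tdef <- list(mu_v = 2.75, sigma_v = 0.4,
               mu_a = 2.6, sigma_a = 0.25,
               mu_t0 = 0.39, sigma_t0 = 0.08,
               sv = 1.9, st = 0.15,
               mu_bF = 0.76, sigma_bF = 0.25,
               mu_bC = 0.06, sigma_bC = 0.15,
               beta_v = 0.16, beta_a = -0.11, beta_t = -0.03)
  truth <- modifyList(tdef, truth)
  if (is.null(covariate_dist))
    covariate_dist <- data.frame(
      test = c("ANT", "COWAT_Semantic", "COWAT_Phonemic", "GNG", "LNST",
               "Stroop", "WCST"),
      mean = c(0.20, 44.79, 52.71, 0.64, 13.00, 0.05, 5.92),
      sd = c(0.05, 10.00, 13.05, 0.16, 2.67, 0.02, 1.05))
  stopifnot(all(c("test", "mean", "sd") %in% names(covariate_dist)),
            active_covariate %in% covariate_dist$test,
            n_participants >= 2, trials_per_cell >= 1,
            all(unlist(truth[c("sigma_v", "sigma_a", "sigma_t0", "sv", "st",
                               "sigma_bF", "sigma_bC")]) >= 0))
  if (truth$mu_t0 - truth$st / 2 < 0)
    stop("config implies t0 - st/2 < 0")
  structure(list(n_participants = n_participants,
                 trials_per_cell = trials_per_cell, truth = truth,
                 covariate_dist = covariate_dist,
                 active_covariate = active_covariate,
                 deadline = deadline, dt = dt, seed = seed),
            class = "generator_config")
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws per-participant covariate scores, z-scores the active covariate,
#' draws subject-level diffusion parameters from the truth hierarchy
#' (boundary and minimal non-decision time kept in their support by
#' redrawing), and simulates every trial forward with the Euler-Maruyama
#' accumulator under condition-specific drift
#' `v_i + bF_i * F_j + bC_i * C_j + beta_v * score_i` (effect coding
#' FM/OC = +0.5, NM/SC = -0.5; accuracy coding: the upper boundary is the
#' correct response). Trials exceeding the deadline are emitted with a
#' censored flag.
#'
#' @param config A [generator_config()] object.
#' @param seed Seed (defaults to the one in the config).
#' @return List with `cohort` (a [cohort_data()]) and `truth` (the exact
#'   population and subject-level values used, for recovery scoring).
#' @export
generate_cohort <- function(config = generator_config(), seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(seed)
  tt <- config$truth
  n <- config$n_participants
  ids <- sprintf("P%03d", seq_len(n))

  cd <- config$covariate_dist
  scores <- as.data.frame(lapply(seq_len(nrow(cd)), function(k)
    rnorm(n, cd$mean[k], cd$sd[k])))
  names(scores) <- cd$test
  covariates <- cbind(data.frame(participant_id = ids), scores)
  z <- as.numeric(scale(scores[[config$active_covariate]]))

  rtrunc <- function(n, mean, sd, lower) {
    x <- rnorm(n, mean, sd)
    for (k in seq_len(1000)) {
      bad <- x <= lower
      if (!any(bad)) break
      x[bad] <- rnorm(sum(bad), mean, sd)
    }
    if (any(x <= lower)) stop("could not draw subject parameters in support")
    x
  }
  v_i <- rnorm(n, tt$mu_v, tt$sigma_v)
  bF_i <- rnorm(n, tt$mu_bF, tt$sigma_bF)
  bC_i <- rnorm(n, tt$mu_bC, tt$sigma_bC)
  # effective (covariate-shifted) a and t0 must stay in support per subject
  a_i <- rtrunc(n, tt$mu_a, tt$sigma_a, pmax(0.05 - tt$beta_a * z, 0.05))
  t0_i <- rtrunc(n, tt$mu_t0, tt$sigma_t0, tt$st / 2 - tt$beta_t * z)
  a_eff <- a_i + tt$beta_a * z
  t0_eff <- t0_i + tt$beta_t * z
  v_base <- v_i + tt$beta_v * z

  cell <- expand.grid(familiarity = c("FM", "NM"), context = c("SC", "OC"),
                      stringsAsFactors = FALSE)
  per <- config$trials_per_cell
  fam <- rep(cell$familiarity, each = per)
  ctx <- rep(cell$context, each = per)
  ntr <- length(fam)
  trials <- data.frame(
    participant_id = rep(ids, each = ntr),
    familiarity = rep(fam, n),
    context = rep(ctx, n))
  i <- rep(seq_len(n), each = ntr)
  Fc <- ifelse(trials$familiarity == "FM", 0.5, -0.5)
  Cc <- ifelse(trials$context == "OC", 0.5, -0.5)
  veff <- v_base[i] + bF_i[i] * Fc + bC_i[i] * Cc
  sim <- cpp_simulate_trials(veff, a_eff[i], rep(0.5, length(i)), t0_eff[i],
                             tt$sv, tt$st, config$dt, config$deadline)
  trials$rt_s <- sim$rt
  trials$response <- ifelse(is.na(sim$boundary), NA_integer_, sim$boundary)
  trials$censored <- sim$censored

  truth <- list(group = tt, active_covariate = config$active_covariate,
                subjects = data.frame(participant_id = ids, v = v_i,
                                      bF = bF_i, bC = bC_i, a = a_i,
                                      t0 = t0_i, score_z = z),
                seed = seed)
  list(cohort = cohort_data(trials, covariates), truth = truth)
}

#' Replicated cohorts for recovery experiments
#'
#' Deterministic per-replicate seeds derived from the master seed; the
#' ground truth is shared across replicates (only the random draws differ).
#'
#' @param n_replicates Number of cohorts (>= 1).
#' @param config A [generator_config()] object.
#' @param seed Master seed.
#' @return List of `list(cohort, truth)` pairs.
#' @export
make_recovery_suite <- function(n_replicates, config = generator_config(),
                                seed = 1) {
  stopifnot(n_replicates >= 1)
  lapply(seq_len(n_replicates),
         function(r) generate_cohort(config, seed = seed + 7919L * r))
}
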