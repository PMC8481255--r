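#' Highest density interval
#'
#' Shortest contiguous window over the sorted draws containing
#' `ceiling(mass * n)` draws; ties are broken by the leftmost window. For
#' skewed posteriors the HDI is not symmetric around the mean and need not
#' contain it.
#'
#' @param x Numeric draws (>= 20 unless `strict = FALSE` internally).
#' @param mass Probability mass, default 0.95.
#' @return Numeric vector `c(low, high)`.
#' @examples
#' hdi(rnorm(10000))
#' @export
hdi <- function(x, mass = 0.95) {
  x <- as.numeric(x)
  if (length(x) == 0) stop("empty input")
  if (length(x) < 20) stop("need >= 20 draws")
  stopifnot(mass > 0, mass <= 1)
  xs <- sort(x)
  n <- length(xs)
  m <- ceiling(mass * n)
  if (m >= n) return(c(xs[1], xs[n]))
  lo <- xs[1:(n - m + 1)]
  hi <- xs[m:n]
  i <- which.min(hi - lo)  # which.min returns the first (leftmost) minimum
  c(lo[i], hi[i])
}

#' Geweke convergence z-score
#'
#' Compares the mean of the first fraction of a chain against the mean of
#' the last fraction, standardized by batch-mean standard errors
#' (20 batches per segment): `z_raw = (m1 - m2) / sqrt(se1^2 + se2^2)`.
#' Because the batch-mean variance estimates carry their own sampling
#' error, the raw ratio has t-like tails; it is calibrated to a standard
#' normal through the Welch-Satterthwaite t distribution
#' (`z = qnorm(pt(z_raw, df))`), so that `|z| < 2` retains its nominal
#' two-sided level on stationary chains. `|z| < 2` is flagged as a pass.
#'
#' @param chain Numeric draws for one parameter (length >= 100, non-constant).
#' @param first_frac Fraction of the chain forming the early segment.
#' @param last_frac Fraction forming the late segment.
#' @param n_batches Batches used for the batch-mean standard errors.
#' @return List with `z` and logical `pass`.
#' @export
geweke_z <- function(chain, first_frac = 0.1, last_frac = 0.5, n_batches = 20) {
  chain <- as.numeric(chain)
  n <- length(chain)
  if (n < 100) stop("chain too short (need >= 100)")
  if (var(chain) == 0) stop("degenerate (constant) chain")
  seg_var <- function(x) {
    bs <- floor(length(x) / n_batches)
    bm <- colMeans(matrix(x[seq_len(bs * n_batches)], nrow = bs))
    var(bm) / n_batches
  }
  s1 <- chain[seq_len(floor(first_frac * n))]
  s2 <- chain[(n - floor(last_frac * n) + 1):n]
  v1 <- seg_var(s1); v2 <- seg_var(s2)
  z_raw <- (mean(s1) - mean(s2)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / ((v1^2 + v2^2) / (n_batches - 1))
  z <- if (abs(z_raw) < 8) qnorm(pt(z_raw, df)) else z_raw
  list(z = z, pass = is.finite(z) && abs(z) < 2)
}

# DIC arithmetic from a deviance trace and the deviance at the posterior
# mean; shared by dic() and usable with any model's deviance draws.
dic_components <- function(deviance_draws, deviance_at_mean) {
  d_bar <- mean(deviance_draws)
  p_d <- d_bar - deviance_at_mean
  list(d_bar = d_bar, p_d = p_d, dic = d_bar + p_d)
}

#' Deviance information criterion
#'
#' The focused (conditional) hierarchical DIC: the deviance is
#' `-2 x` the sum of trial log-likelihoods conditional on the
#' subject-level parameters (plus `sv`, `st` and any covariate slopes);
#' `d_bar` is its posterior mean, `p_d = d_bar - D(posterior mean of the
#' likelihood-relevant parameters)`, and `dic = d_bar + p_d`. Negative
#' `p_d` signals non-convergence and is flagged, not hidden. If the
#' posterior-mean parameters fall outside the support, `p_d` is reported
#' as undefined.
#'
#' @param samples A [sample_posterior()] object (>= 50 retained draws).
#' @param model The model the samples came from (defaults to the one
#'   attached to `samples`).
#' @return List with `d_bar`, `p_d`, `dic`, and `p_d_defined`.
#' @export
dic <- function(samples, model = samples$model) {
  stopifnot(inherits(samples, "ddm_posterior"))
  if (nrow(samples$draws) < 50) stop("need >= 50 retained draws")
  theta_bar <- colMeans(samples$draws)
  ll_bar <- state_log_lik(model, theta_bar)
  if (!is.finite(ll_bar)) {
    d_bar <- mean(samples$deviance)
    return(list(d_bar = d_bar, p_d = NA_real_, dic = NA_real_,
                p_d_defined = FALSE))
  }
  out <- dic_components(samples$deviance, -2 * ll_bar)
  out$p_d_defined <- TRUE
  out
}

#' Posterior effect summary
#'
#' Posterior mean, 95% HDI and the fraction of retained draws above zero
#' for one labelled parameter; the effect is flagged `credible` when the
#' 95% HDI excludes zero (the Bayesian decision rule used throughout this
#' pipeline).
#'
#' @param samples A [sample_posterior()] object.
#' @param label Parameter label, e.g. `"mu_bF"`, `"mu_bC"`, `"beta_v"`.
#' @param mass HDI mass.
#' @return data.frame row: `label`, `mean`, `hdi_low`, `hdi_high`,
#'   `prob_positive`, `credible`.
#' @export
effect_summary <- function(samples, label, mass = 0.95) {
  stopifnot(inherits(samples, "ddm_posterior"))
  if (!label %in% colnames(samples$draws)) stop("unknown label: ", label)
  x <- samples$draws[, label]
  h <- hdi(x, mass)
  data.frame(label = label, mean = mean(x), hdi_low = h[1], hdi_high = h[2],
             prob_positive = mean(x > 0),
             credible = h[1] > 0 | h[2] < 0)
}

# The group-level effect / slope labels a model reports on.
effect_labels <- function(model) {
  switch(model$kind,
         null = character(0),
         fc = c("mu_bF", "mu_bC"),
         full = c("mu_bF", "mu_bC", "beta_v", "beta_a", "beta_t"))
}

# Subject-level parameter values of one posterior draw, as effective
# per-subject (v intercept, bF, bC, a_eff, t0_eff) for simulation.
draw_subject_params <- function(model, draw) {
  ids <- model$participants
  v <- draw[paste0("v[", ids, "]")]
  a <- draw[paste0("a[", ids, "]")]
  t0 <- draw[paste0("t0[", ids, "]")]
  bF <- bC <- rep(0, model$nsub)
  if (model$kind != "null") {
    bF <- draw[paste0("bF[", ids, "]")]
    bC <- draw[paste0("bC[", ids, "]")]
  }
  bv <- ba <- bt <- 0
  if (model$kind == "full") {
    bv <- draw[["beta_v"]]; ba <- draw[["beta_a"]]; bt <- draw[["beta_t"]]
  }
  list(v = unname(v) + bv * model$score,
       bF = unname(bF), bC = unname(bC),
       a = unname(a) + ba * model$score,
       t0 = unname(t0) + bt * model$score,
       sv = draw[["sv"]], st = draw[["st"]])
}

#' Posterior predictive checks
#'
#' For each of `n_rep` (evenly spaced) posterior draws, a full replicate
#' dataset with the observed trial structure is simulated forward from the
#' drawn subject-level parameters; replicate trials censored at the
#' deadline are dropped as in the real pipeline. Per condition, observed
#' accuracy and correct-response RT deciles (0.1, 0.3, 0.5, 0.7, 0.9) are
#' compared with their replicate distributions via two-sided posterior
#' predictive p-values (twice the smaller tail fraction of replicates at or
#' beyond the observed statistic, capped at 1).
#'
#' @param model A [build_model()] object.
#' @param samples Posterior samples for that model.
#' @param n_rep Number of replicate datasets (>= 2).
#' @param seed Seed for the replicate simulation stream.
#' @param dt Euler step of the forward simulator, seconds.
#' @param deadline Censoring deadline, seconds.
#' @return data.frame: `condition`, `statistic`, `observed`,
#'   `predicted_mean`, `p_value`.
#' @export
posterior_predictive <- function(model, samples, n_rep = 50, seed = 1,
                                 dt = 1e-4, deadline = 5) {
  stopifnot(inherits(model, "ddm_model"), inherits(samples, "ddm_posterior"))
  if (n_rep < 2) stop("n_rep must be >= 2")
  set.seed(seed)
  qs <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  cond <- paste(ifelse(model$C > 0, "OC", "SC"),
                ifelse(model$F > 0, "FM", "NM"), sep = "-")
  stats_of <- function(upper, rt, keep = rep(TRUE, length(upper))) {
    out <- c()
    for (cc in conditions_2x2()) {
      sel <- keep & cond == cc
      acc <- if (any(sel)) mean(upper[sel]) * 100 else NA_real_
      crt <- rt[sel & upper == 1]
      dec <- if (length(crt)) quantile(crt, qs, names = FALSE) else rep(NA_real_, 5)
      out <- c(out, setNames(c(acc, dec),
                             paste0(cc, c("_accuracy", paste0("_rt_q", qs * 100)))))
    }
    out
  }
  obs <- stats_of(model$upper, model$rt)
  idx <- unique(round(seq(1, nrow(samples$draws), length.out = n_rep)))
  reps <- matrix(NA_real_, length(idx), length(obs),
                 dimnames = list(NULL, names(obs)))
  for (r in seq_along(idx)) {
    sp <- draw_subject_params(model, samples$draws[idx[r], ])
    i <- model$sub + 1L
    veff <- sp$v[i] + sp$bF[i] * model$F + sp$bC[i] * model$C
    sim <- cpp_simulate_trials(veff, sp$a[i], rep(0.5, length(i)), sp$t0[i],
                               sp$sv, sp$st, dt, deadline)
    keep <- sim$censored == 0
    reps[r, ] <- stats_of(ifelse(is.na(sim$boundary), 0L, sim$boundary),
                          sim$rt, keep)
  }
  pp_p <- function(o, r) {
    r <- r[!is.na(r)]
    if (!length(r) || is.na(o)) return(NA_real_)
    min(1, 2 * min(mean(r <= o), mean(r >= o)))
  }
  data.frame(
    condition = rep(conditions_2x2(), each = 6),
    statistic = rep(c("accuracy", paste0("rt_q", qs * 100)), 4),
    observed = unname(obs),
    predicted_mean = unname(colMeans(reps, na.rm = TRUE)),
    p_value = vapply(seq_along(obs), function(k) pp_p(obs[k], reps[, k]),
                     numeric(1)))
}

#' Fit one hierarchical diffusion model end to end
#'
#' Builds the model, samples the posterior, and assembles convergence
#' diagnostics (Geweke z per group-level parameter), the DIC decomposition,
#' effect/slope summaries and (optionally) posterior predictive checks.
#'
#' @param data A [cohort_data()] object.
#' @param kind Model family (`"null"`, `"fc"`, `"full"`).
#' @param covariate Covariate name for the full model.
#' @param n_samples,n_burn,seed Sampler settings, see [sample_posterior()].
#' @param priors See [default_priors()].
#' @param n_rep_ppc Number of posterior predictive replicates (0 = skip).
#' @param ppc_dt Euler step used for the PPC simulations.
#' @return An object of class `ddm_fit`.
#' @export
fit_ddm <- function(data, kind = model_kinds, covariate = NULL,
                    n_samples = 12000, n_burn = 2000, seed = 1,
                    priors = default_priors(), n_rep_ppc = 0, ppc_dt = 1e-4) {
  kind <- match.arg(kind)
  model <- build_model(kind, data, covariate, priors)
  samples <- sample_posterior(model, n_samples, n_burn, seed)
  gn <- group_nodes(model)
  gw <- do.call(rbind, lapply(gn, function(p) {
    g <- tryCatch(geweke_z(samples$draws[, p]),
                  error = function(e) list(z = NA_real_, pass = FALSE))
    data.frame(parameter = p, z = g$z, pass = g$pass)
  }))
  effects <- do.call(rbind, lapply(effect_labels(model),
                                   function(l) effect_summary(samples, l)))
  ppc <- NULL
  if (n_rep_ppc >= 2)
    ppc <- posterior_predictive(model, samples, n_rep_ppc, seed = seed + 1,
                                dt = ppc_dt)
  structure(list(model = model, samples = samples,
                 dic = dic(samples, model), geweke = gw,
                 effects = effects, ppc = ppc),
            class = "ddm_fit")
}

#' @export
print.ddm_fit <- function(x, ...) {
  cat(sprintf("ddm_fit '%s'%s  DIC %.1f (d_bar %.1f, p_d %.1f)\n",
              x$model$kind,
              if (is.null(x$model$covariate)) "" else paste0(" (", x$model$covariate, ")"),
              x$dic$dic, x$dic$d_bar, x$dic$p_d))
  if (!is.null(x$effects) && nrow(x$effects)) {
    cat("effects:\n")
    print(x$effects, row.names = FALSE)
  }
  cat(sprintf("Geweke pass: %d/%d group-level parameters\n",
              sum(x$geweke$pass), nrow(x$geweke)))
  invisible(x)
}

#' DIC model comparison table
#'
#' Fits the null and fc base models plus one full model per covariate, all
#' with shared sampler settings and the same seed, and tabulates their DIC
#' decompositions. Rows are ordered base models first, then full models
#' alphabetically by covariate. Individual fit failures are annotated per
#' row; the table is still emitted.
#'
#' @param data A [cohort_data()] object.
#' @param covariates Character vector of covariate names (may be empty,
#'   giving just the two base models).
#' @param n_samples,n_burn,seed Sampler settings shared across fits.
#' @param priors See [default_priors()].
#' @return data.frame: `model`, `covariate`, `dic`, `d_bar`, `p_d`, `note`.
#' @export
compare_models <- function(data, covariates = character(0),
                           n_samples = 12000, n_burn = 2000, seed = 1,
                           priors = default_priors()) {
  specs <- c(list(list(kind = "null", covariate = NA_character_),
                  list(kind = "fc", covariate = NA_character_)),
             lapply(sort(covariates),
                    function(cv) list(kind = "full", covariate = cv)))
  rows <- lapply(specs, function(sp) {
    lab <- if (sp$kind == "full") paste0("full:", sp$covariate) else sp$kind
    res <- tryCatch({
      m <- build_model(sp$kind, data,
                       if (sp$kind == "full") sp$covariate else NULL, priors)
      s <- sample_posterior(m, n_samples, n_burn, seed)
      d <- dic(s, m)
      data.frame(model = lab, covariate = sp$covariate, dic = d$dic,
                 d_bar = d$d_bar, p_d = d$p_d, note = "")
    }, error = function(e)
      data.frame(model = lab, covariate = sp$covariate, dic = NA_real_,
                 d_bar = NA_real_, p_d = NA_real_,
                 note = conditionMessage(e)))
    res
  })
  do.call(rbind, rows)
}
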