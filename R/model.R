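#' Default informed priors
#'
#' Group-level priors kept in a moderate range, following published surveys
#' of diffusion-model parameter values: the group drift intercept mean is
#' Normal(2, 3^2); the group boundary mean Gamma(shape 1.5, scale 1); the
#' group non-decision-time mean Normal(0.4, 0.2^2) truncated at 0;
#' condition-effect and covariate-slope means Normal(0, 1^2); group SDs
#' Half-Normal(1); inter-trial drift SD `sv` Half-Normal(2); inter-trial
#' non-decision-time range `st` Half-Normal(0.3). All scales are in evidence
#' units per second (drift), evidence units (boundary) or seconds.
#'
#' @param ... Named overrides of any element.
#' @return Named list of prior hyperparameters.
#' @export
default_priors <- function(...) {
  pr <- list(mu_v_mean = 2, mu_v_sd = 3,
             mu_a_shape = 1.5, mu_a_scale = 1,
             mu_t0_mean = 0.4, mu_t0_sd = 0.2,
             effect_sd = 1, group_sd_scale = 1,
             sv_scale = 2, st_scale = 0.3)
  modifyList(pr, list(...))
}

model_kinds <- c("null", "fc", "full")

#' Build a hierarchical diffusion model specification
#'
#' Declares which parameters vary and wires the cohort into the parameter
#' graph. Three families are supported:
#' \describe{
#'   \item{null}{all decision parameters fixed across conditions, no
#'     covariates;}
#'   \item{fc}{trial drift varies by FAMILIARITY and CONTEXT only:
#'     `v_ij = v_i + bF_i * F_j + bC_i * C_j` with effect coding
#'     FM = +0.5 / NM = -0.5 and OC = +0.5 / SC = -0.5 (so each
#'     population-level effect is the FM - NM or OC - SC difference);}
#'   \item{full}{fc plus one between-subject covariate entering drift rate,
#'     boundary separation and non-decision time through population-level
#'     slopes `beta_v`, `beta_a`, `beta_t` on the z-scored score.}
#' }
#' Boundary separation and non-decision time are per-participant and
#' condition-constant; the starting point is fixed at 0.5 (accuracy coding:
#' correct responses absorb at the upper boundary); `sv` and `st` are single
#' group-level values shared across participants. Drift intercepts, condition
#' effects, `a` and `t0` are per-participant draws from group Normal
#' distributions (`a`, `t0` with positivity enforced through the support).
#' Censored trials are dropped here, with a ledger-style count kept on the
#' model object.
#'
#' @param kind `"null"`, `"fc"` or `"full"`.
#' @param data A [cohort_data()] object; >= 2 participants, all four
#'   condition cells non-empty per participant.
#' @param covariate Covariate (test) name; required iff `kind = "full"`.
#' @param priors From [default_priors()].
#' @return An object of class `ddm_model`.
#' @export
build_model <- function(kind = model_kinds, data, covariate = NULL,
                        priors = default_priors()) {
  kind <- match.arg(kind)
  stopifnot(inherits(data, "cohort_data"))
  if (kind == "full") {
    if (is.null(covariate)) stop("the full model needs a covariate name")
    if (!covariate %in% covariate_names(data))
      stop("covariate not in the covariate table: ", covariate)
  } else covariate <- NULL

  tr <- data$trials
  n_censored <- sum(tr$censored == 1)
  tr <- tr[tr$censored != 1, , drop = FALSE]
  ids <- sort(unique(tr$participant_id))
  if (length(ids) < 2) stop("need >= 2 participants")
  cond_count <- table(tr$participant_id, condition_of(tr))
  if (ncol(cond_count) < 4 || any(cond_count == 0)) {
    bad <- if (ncol(cond_count) < 4) ids else
      rownames(cond_count)[rowSums(cond_count == 0) > 0]
    stop("participant(s) with an empty condition cell: ",
         paste(bad, collapse = ", "))
  }
  ord <- order(match(tr$participant_id, ids))
  tr <- tr[ord, , drop = FALSE]
  sub <- match(tr$participant_id, ids) - 1L
  Fc <- ifelse(tr$familiarity == "FM", 0.5, -0.5)
  Cc <- ifelse(tr$context == "OC", 0.5, -0.5)
  score <- rep(0, length(ids))
  if (kind == "full") {
    raw <- data$covariates[[covariate]][
      match(ids, data$covariates$participant_id)]
    if (anyNA(raw)) stop("missing covariate score(s)")
    score <- as.numeric(scale(raw))
  }

  nsub <- length(ids)
  kind_code <- match(kind, model_kinds) - 1L
  nm <- c("mu_v", "sigma_v", "mu_a", "sigma_a", "mu_t0", "sigma_t0", "sv", "st")
  if (kind != "null") nm <- c(nm, "mu_bF", "sigma_bF", "mu_bC", "sigma_bC")
  if (kind == "full") nm <- c(nm, "beta_v", "beta_a", "beta_t")
  nm <- c(nm,
          paste0("v[", ids, "]"), paste0("a[", ids, "]"),
          paste0("t0[", ids, "]"))
  if (kind != "null")
    nm <- c(nm, paste0("bF[", ids, "]"), paste0("bC[", ids, "]"))

  structure(list(kind = kind, kind_code = kind_code, covariate = covariate,
                 priors = priors, participants = ids, nsub = nsub,
                 sub = sub, rt = tr$rt_s, upper = as.integer(tr$response),
                 F = Fc, C = Cc, score = score,
                 n_censored_dropped = n_censored,
                 param_names = nm, npar = length(nm)),
            class = "ddm_model")
}

#' @export
print.ddm_model <- function(x, ...) {
  cat(sprintf("ddm_model '%s'%s: %d participants, %d trials, %d parameters\n",
              x$kind,
              if (is.null(x$covariate)) "" else paste0(" (", x$covariate, ")"),
              x$nsub, length(x$rt), x$npar))
  invisible(x)
}

# Named group-level parameter indices of a model.
group_nodes <- function(model) {
  nm <- model$param_names
  nm[!grepl("\\[", nm)]
}

#' Log posterior of a full parameter assignment
#'
#' Sum of all trial log-likelihoods, subject-level prior terms given the
#' group parameters, and group-level hyperprior terms (additive constants
#' that do not depend on any sampled parameter are dropped). Any support
#' violation (non-positive boundary, response faster than the minimal
#' non-decision time, non-positive group SD, ...) yields `-Inf` rather than
#' an error, so it can encode rejection inside a sampler.
#'
#' @param model A [build_model()] object.
#' @param state Numeric vector of length `model$npar`, ordered as
#'   `model$param_names` (names, if present, are checked).
#' @return Scalar log density (up to an additive constant).
#' @export
log_posterior <- function(model, state) {
  stopifnot(inherits(model, "ddm_model"), length(state) == model$npar)
  if (!is.null(names(state)) && !identical(names(state), model$param_names))
    state <- state[model$param_names]
  gl <- gl_rule()
  res <- cpp_log_posterior(model$kind_code, model$nsub, model$sub, model$rt,
                           model$upper, model$F, model$C, model$score,
                           model$priors, .WIENER_EPS, gl$nodes, gl$weights,
                           as.numeric(state))
  res$log_posterior
}

# Data log-likelihood conditional on subject-level parameters (and sv, st,
# covariate slopes): the deviance-relevant part of the model.
state_log_lik <- function(model, state) {
  stopifnot(length(state) == model$npar)
  gl <- gl_rule()
  res <- cpp_log_posterior(model$kind_code, model$nsub, model$sub, model$rt,
                           model$upper, model$F, model$C, model$score,
                           model$priors, .WIENER_EPS, gl$nodes, gl$weights,
                           as.numeric(state))
  res$log_lik
}

# Initial state: group locations at prior means, group scales at prior
# (half-normal) means, subjects at group locations; 1% jitter applied by
# the caller. The non-decision start is capped below the fastest response
# (minus the starting st window) so the initial log posterior stays finite
# for cohorts with fast responders.
initial_state <- function(model) {
  pr <- model$priors
  hn_mean <- function(s) s * sqrt(2 / pi)
  st0 <- min(hn_mean(pr$st_scale), 0.5 * min(model$rt))
  t00 <- min(pr$mu_t0_mean, 0.8 * min(model$rt))
  g <- c(mu_v = pr$mu_v_mean, sigma_v = hn_mean(pr$group_sd_scale),
         mu_a = pr$mu_a_shape * pr$mu_a_scale,
         sigma_a = hn_mean(pr$group_sd_scale),
         mu_t0 = t00, sigma_t0 = hn_mean(pr$group_sd_scale) / 4,
         sv = hn_mean(pr$sv_scale), st = st0)
  if (model$kind != "null")
    g <- c(g, mu_bF = 0, sigma_bF = hn_mean(pr$group_sd_scale) / 2,
           mu_bC = 0, sigma_bC = hn_mean(pr$group_sd_scale) / 2)
  if (model$kind == "full") g <- c(g, beta_v = 0, beta_a = 0, beta_t = 0)
  s <- c(g,
         rep(g[["mu_v"]], model$nsub), rep(g[["mu_a"]], model$nsub),
         rep(g[["mu_t0"]], model$nsub))
  if (model$kind != "null") s <- c(s, rep(0, 2 * model$nsub))
  setNames(as.numeric(s), model$param_names)
}

# Random-walk step-size starting points per node class; adapted during
# burn-in toward 0.3-0.5 acceptance.
initial_steps <- function(model) {
  nm <- model$param_names
  st <- rep(0.15, length(nm))
  st[nm == "st"] <- 0.03
  st[nm %in% c("sv", "beta_v", "beta_a")] <- 0.1
  st[nm %in% c("mu_t0", "sigma_t0", "beta_t")] <- 0.02
  st[grepl("^v\\[", nm)] <- 0.3
  st[grepl("^(bF|bC)\\[", nm)] <- 0.3
  st[grepl("^a\\[", nm)] <- 0.15
  st[grepl("^t0\\[", nm)] <- 0.03
  setNames(st, nm)
}

#' Draw posterior samples
#'
#' Metropolis-within-Gibbs: single-site Gaussian random-walk updates over
#' every node of the parameter graph, with per-node step sizes adapted
#' during burn-in toward 0.3-0.5 acceptance and frozen afterwards. A single
#' chain is run (multiple chains can be obtained by calling with different
#' seeds). Initialization places group locations at their prior means and
#' subject parameters at the group locations, jittered by 1% Gaussian
#' noise; up to 100 jittered restarts are attempted if the initial log
#' posterior is not finite.
#'
#' @param model A [build_model()] object.
#' @param n_samples Total MCMC iterations (including burn-in).
#' @param n_burn Burn-in iterations, discarded.
#' @param seed Integer seed; identical seeds give bitwise-identical draws.
#' @return An object of class `ddm_posterior`: retained draws (matrix,
#'   iterations x labelled parameters), the per-iteration deviance
#'   (-2 x data log-likelihood conditional on subject-level parameters),
#'   post-burn-in acceptance rates, and the sampler settings.
#' @export
sample_posterior <- function(model, n_samples = 12000, n_burn = 2000, seed = 1) {
  stopifnot(inherits(model, "ddm_model"), n_burn < n_samples, n_burn >= 0)
  set.seed(seed)
  gl <- gl_rule()
  base <- initial_state(model)
  # group-level nodes: 1% relative jitter; subject-level nodes: absolute
  # jitter at a fraction of the starting group scale, so subjects do not
  # all start identical (which would trap the group SDs near zero).
  nm <- model$param_names
  jsd <- ifelse(base != 0, abs(base) * 0.01, 0.01)
  jsd[grepl("^(v|bF|bC)\\[", nm)] <- 0.15
  jsd[grepl("^a\\[", nm)] <- 0.1
  jsd[grepl("^t0\\[", nm)] <- 0.02
  res <- NULL
  for (try in seq_len(100)) {
    init <- base + jsd * rnorm(length(base))
    res <- cpp_run_mcmc(model$kind_code, model$nsub, model$sub, model$rt,
                        model$upper, model$F, model$C, model$score,
                        model$priors, .WIENER_EPS, gl$nodes, gl$weights,
                        as.numeric(init), as.numeric(initial_steps(model)),
                        as.integer(n_samples), as.integer(n_burn))
    if (isTRUE(res$ok)) break
    res <- NULL
  }
  if (is.null(res))
    stop("initialization failed: log posterior not finite after 100 jittered restarts")
  draws <- res$draws
  colnames(draws) <- model$param_names
  structure(list(draws = draws, deviance = as.numeric(res$deviance),
                 n_total = n_samples, n_burn = n_burn, seed = seed,
                 accept_rate = setNames(as.numeric(res$accept_rate),
                                        model$param_names),
                 model = model),
            class = "ddm_posterior")
}

#' @export
print.ddm_posterior <- function(x, ...) {
  cat(sprintf("ddm_posterior: %d retained draws (of %d, burn-in %d), %d parameters, seed %d\n",
              nrow(x$draws), x$n_total, x$n_burn, ncol(x$draws), x$seed))
  invisible(x)
}
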