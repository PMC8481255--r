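#' Drift-diffusion trial parameterization
#'
#' Bundles one trial-level parameterization of the diffusion process. The
#' diffusion coefficient is fixed at 1 (so drift rates and boundary
#' separations are on the scale of the Python/HDDM ecosystem; under the
#' alternative 0.1 convention both `v` and `a` would be rescaled by 10).
#'
#' @param v Drift rate (evidence units per second).
#' @param a Boundary separation (> 0).
#' @param z Relative starting point, fraction of `a` in (0, 1).
#' @param t0 Non-decision time in seconds (>= 0).
#' @param sv Inter-trial drift-rate standard deviation (>= 0).
#' @param st Inter-trial non-decision-time range in seconds (>= 0);
#'   `t0 - st/2` must be non-negative.
#' @param sz Inter-trial starting-point range; fixed at 0 here (the starting
#'   point is not freed in this pipeline).
#' @return An object of class `ddm_params`.
#' @examples
#' p <- ddm_params(v = 1, a = 1.5, z = 0.5, t0 = 0.3)
#' choice_probability(p)
#' @export
ddm_params <- function(v, a, z = 0.5, t0 = 0, sv = 0, st = 0, sz = 0) {
  stopifnot(length(v) == 1, length(a) == 1, length(z) == 1, length(t0) == 1)
  if (!is.finite(a) || a <= 0) stop("boundary separation 'a' must be > 0")
  if (!is.finite(z) || z <= 0 || z >= 1) stop("starting point 'z' must lie in (0, 1)")
  if (t0 < 0) stop("non-decision time 't0' must be >= 0")
  if (sv < 0) stop("'sv' must be >= 0")
  if (st < 0) stop("'st' must be >= 0")
  if (t0 - st / 2 < 0) stop("'t0 - st/2' must be >= 0")
  if (sz != 0) stop("'sz' is fixed at 0 in this model family")
  structure(list(v = v, a = a, z = z, t0 = t0, sv = sv, st = st, sz = 0),
            class = "ddm_params")
}

#' @export
print.ddm_params <- function(x, ...) {
  cat(sprintf("ddm_params: v=%.4g a=%.4g z=%.4g t0=%.4g sv=%.4g st=%.4g\n",
              x$v, x$a, x$z, x$t0, x$sv, x$st))
  invisible(x)
}

#' Single trial outcome
#'
#' @param rt Response time in seconds.
#' @param boundary `"upper"` (correct, under accuracy coding) or `"lower"`.
#' @param censored Logical; `TRUE` when no response occurred within the
#'   deadline (then `rt` and `boundary` are meaningless).
#' @return An object of class `trial_outcome`.
#' @export
trial_outcome <- function(rt, boundary = c("upper", "lower"), censored = FALSE) {
  if (!censored) {
    boundary <- match.arg(boundary)
    if (!is.finite(rt) || rt <= 0) stop("'rt' must be > 0")
  } else {
    boundary <- NA_character_
    rt <- NA_real_
  }
  structure(list(rt = rt, boundary = boundary, censored = censored),
            class = "trial_outcome")
}

#' Wiener first-passage-time density
#'
#' Defective density of absorption at one boundary at decision time `t_dec`
#' (non-decision time plays no role here; the density integrates over time
#' to that boundary's absorption probability, not to 1). Evaluated with the
#' dual small-time/large-time series representation, switching to whichever
#' series needs fewer terms for truncation error at most 1e-7. Drift-rate
#' variability `sv` is marginalized in closed form; `st` must be zero (it is
#' handled at the trial-likelihood level).
#'
#' @param t_dec Decision time(s) in seconds; non-positive values give 0.
#' @param boundary `"upper"` or `"lower"`.
#' @param params A [ddm_params()] object with `st = 0`.
#' @return Vector of densities (per second), one per element of `t_dec`.
#' @examples
#' p <- ddm_params(v = 1, a = 1.5)
#' wiener_fpt_density(c(0.2, 0.5, 1), "upper", p)
#' @export
wiener_fpt_density <- function(t_dec, boundary = c("upper", "lower"), params) {
  boundary <- match.arg(boundary)
  stopifnot(inherits(params, "ddm_params"))
  if (params$st != 0) stop("'st' must be 0 for the plain FPT density")
  cpp_wfpt_density(as.numeric(t_dec), as.integer(boundary == "upper"),
                   params$v, params$a, params$z, params$sv, .WIENER_EPS)
}

#' Trial log-likelihood
#'
#' Log of the sv- and st-marginalized first-passage density at decision time
#' `rt - t0'`. With `sv = st = 0` this reduces to
#' `log(wiener_fpt_density(rt - t0, boundary, params))`. Responses faster
#' than the minimal non-decision time (`rt <= t0 - st/2`) give `-Inf`
#' (log-zero) rather than an error, so samplers can reject such states
#' gracefully. Censored outcomes are not supported: the pipeline drops them
#' before likelihood evaluation.
#'
#' @param outcome A [trial_outcome()] object.
#' @param params A [ddm_params()] object.
#' @return Scalar log density.
#' @export
trial_log_likelihood <- function(outcome, params) {
  stopifnot(inherits(outcome, "trial_outcome"), inherits(params, "ddm_params"))
  if (outcome$censored)
    stop("censored outcomes carry no likelihood; drop them upstream")
  gl <- gl_rule()
  cpp_trial_loglik(outcome$rt, as.integer(outcome$boundary == "upper"),
                   params$v, params$a, params$z, params$t0,
                   params$sv, params$st, .WIENER_EPS, gl$nodes, gl$weights)
}

# Vectorized trial log-likelihood over per-trial parameter vectors,
# used by the model-level code.
trial_loglik_vec <- function(rt, upper, v, a, z, t0, sv, st) {
  n <- length(rt)
  gl <- gl_rule()
  cpp_trial_loglik(rt, as.integer(upper),
                   rep_len(v, n), rep_len(a, n), rep_len(z, n),
                   rep_len(t0, n), sv, st, .WIENER_EPS, gl$nodes, gl$weights)
}

#' Closed-form choice probability
#'
#' Probability of absorption at the upper boundary for fixed drift
#' (diffusion coefficient 1): `(1 - exp(-2 v z a)) / (1 - exp(-2 v a))`,
#' and `z` when `v = 0`. Defined for `sv = 0` only; serves as the
#' closed-form oracle for the forward simulator.
#'
#' @param params A [ddm_params()] object with `sv = 0`.
#' @return Probability in (0, 1).
#' @export
choice_probability <- function(params) {
  stopifnot(inherits(params, "ddm_params"))
  if (params$sv > 0) stop("closed form defined for fixed drift only (sv = 0)")
  v <- params$v; a <- params$a; z <- params$z
  if (v == 0) return(z)
  if (v < 0) return(1 - choice_probability(ddm_params(-v, a, 1 - z, params$t0)))
  # v > 0: both expm1 arguments are negative, no overflow
  expm1(-2 * v * z * a) / expm1(-2 * v * a)
}

#' Closed-form mean decision time
#'
#' Mean first-passage time pooled over both boundaries, for an unbiased
#' start (`z = 0.5`), fixed drift and diffusion coefficient 1:
#' `(a / (2 v)) tanh(v a / 2)`, with limit `a^2 / 4` at `v = 0`. Excludes
#' non-decision time. Serves as the second closed-form simulator oracle.
#'
#' @param params A [ddm_params()] object with `z = 0.5` and `sv = 0`.
#' @return Mean decision time in seconds.
#' @export
mean_decision_time <- function(params) {
  stopifnot(inherits(params, "ddm_params"))
  if (params$z != 0.5) stop("closed form requires z = 0.5")
  if (params$sv > 0) stop("closed form defined for fixed drift only (sv = 0)")
  v <- params$v; a <- params$a
  if (abs(v) < 1e-10) return(a^2 / 4)
  (a / (2 * v)) * tanh(v * a / 2)
}

#' Simulate diffusion trials
#'
#' Euler-Maruyama forward simulation: accumulation starts at `z * a`, with
#' per-step increments `v' dt + sqrt(dt) * noise`, where `v'` is drawn once
#' per trial from `Normal(v, sv)` and the non-decision time once per trial
#' from `Uniform(t0 - st/2, t0 + st/2)`. Trials whose response time would
#' exceed the deadline are returned censored (mirroring a response deadline
#' of 5 s in the task being modelled). Uses R's RNG stream; seed with
#' [set.seed()] for reproducibility.
#'
#' @param n Number of trials.
#' @param params A [ddm_params()] object.
#' @param dt Euler step in seconds.
#' @param deadline Censoring deadline in seconds.
#' @return A data.frame with columns `rt`, `boundary` (`"upper"`/`"lower"`),
#'   `censored`.
#' @examples
#' set.seed(1)
#' head(simulate_trials(5, ddm_params(v = 2, a = 1.5, t0 = 0.3)))
#' @export
simulate_trials <- function(n, params, dt = 1e-4, deadline = 5) {
  stopifnot(inherits(params, "ddm_params"), dt > 0, deadline > 0)
  sim <- cpp_simulate_trials(rep(params$v, n), rep(params$a, n),
                             rep(params$z, n), rep(params$t0, n),
                             params$sv, params$st, dt, deadline)
  data.frame(rt = sim$rt,
             boundary = ifelse(is.na(sim$boundary), NA_character_,
                               ifelse(sim$boundary == 1, "upper", "lower")),
             censored = sim$censored == 1)
}

#' @rdname simulate_trials
#' @export
simulate_trial <- function(params, dt = 1e-4, deadline = 5) {
  out <- simulate_trials(1L, params, dt = dt, deadline = deadline)
  if (out$censored[1]) return(trial_outcome(NA, censored = TRUE))
  trial_outcome(out$rt[1], out$boundary[1])
}
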