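# Independent oracles, coded without reference to the package's C++ paths.

# Wiener FPT density at the lower boundary via the plain small-time series
# with a fixed large term count (converges for all tau at this K), fixed
# drift (no sv). Upper boundary by reflection.
oracle_wfpt <- function(t, boundary, v, a, z, K = 200) {
  if (boundary == "upper") { v <- -v; z <- 1 - z }
  if (t <= 0) return(0)
  tau <- t / a^2
  k <- -K:K
  s <- sum((z + 2 * k) * exp(-(z + 2 * k)^2 / (2 * tau)))
  s / sqrt(2 * pi * tau^3) / a^2 * exp(-v * a * z - v^2 * t / 2)
}

# Brute-force trial density: adaptive quadrature over t0' (uniform) and,
# when sv > 0, over the trial drift (Gaussian).
oracle_trial_density <- function(rt, boundary, v, a, z, t0, sv, st) {
  dens_v <- function(td) {
    if (sv == 0) return(sapply(td, oracle_wfpt, boundary = boundary,
                               v = v, a = a, z = z))
    sapply(td, function(tt) {
      if (tt <= 0) return(0)
      integrate(function(u) sapply(u, function(uu)
        oracle_wfpt(tt, boundary, uu, a, z)) * dnorm(u, v, sv),
        v - 8 * sv, v + 8 * sv, rel.tol = 1e-10)$value
    })
  }
  if (st == 0) return(dens_v(rt - t0))
  integrate(function(u) dens_v(rt - u), t0 - st / 2, t0 + st / 2,
            rel.tol = 1e-10)$value / st
}

# Exhaustive-search HDI: scan every contiguous window of the sorted draws.
oracle_hdi <- function(x, mass = 0.95) {
  xs <- sort(x)
  n <- length(xs)
  m <- ceiling(mass * n)
  best <- c(xs[1], xs[n]); bw <- Inf
  for (i in seq_len(n - m + 1)) {
    w <- xs[i + m - 1] - xs[i]
    if (w < bw) { bw <- w; best <- c(xs[i], xs[i + m - 1]) }
  }
  best
}

# Within-subject 2x2 ANOVA through base R's aov() with an Error stratum.
oracle_rm_anova <- function(cells) {
  df <- data.frame(
    y = as.numeric(cells),
    subj = factor(rep(rownames(cells), 4)),
    fam = factor(rep(ifelse(grepl("FM", colnames(cells)), "FM", "NM"),
                     each = nrow(cells))),
    ctx = factor(rep(ifelse(grepl("SC", colnames(cells)), "SC", "OC"),
                     each = nrow(cells))))
  fit <- summary(aov(y ~ fam * ctx + Error(subj / (fam * ctx)), data = df))
  getF <- function(stratum) fit[[stratum]][[1]][1, "F value"]
  c(FAMILIARITY = getF("Error: subj:fam"),
    CONTEXT = getF("Error: subj:ctx"),
    INTERACTION = getF("Error: subj:fam:ctx"))
}

# Pearson r straight from the covariance definition.
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Small synthetic cohort for model-level tests.
make_small_cohort <- function(n_sub = 6, per_cell = 6, seed = 1, ...) {
  cfg <- generator_config(n_participants = n_sub, trials_per_cell = per_cell,
                          ...)
  gen <- generate_cohort(cfg, seed = seed)
  list(cohort = drop_censored(gen$cohort), truth = gen$truth)
}

# Hand-built deterministic trial table (no simulation).
make_hand_trials <- function(ids, rts_by_cell) {
  rows <- list()
  for (i in seq_along(ids)) {
    for (cc in conditions_2x2()) {
      rt <- rts_by_cell[[i]][[cc]]
      rows[[length(rows) + 1]] <- data.frame(
        participant_id = ids[i],
        familiarity = sub(".*-", "", cc), context = sub("-.*", "", cc),
        rt_s = rt, response = 1L, censored = 0L)
    }
  }
  do.call(rbind, rows)
}

# Fixture reproducing the participant-level exclusion worked example:
# 40 participants x 124 trials, 2 planted extreme participants.
make_participant_outlier_fixture <- function(seed = 11) {
  set.seed(seed)
  ids <- sprintf("S%02d", 1:40)
  base_mean <- rep(1.0, 40)
  base_mean[c(7, 23)] <- 20  # extreme mean RT
  trials <- data.frame(
    participant_id = rep(ids, each = 124),
    familiarity = rep(rep(c("FM", "NM"), each = 31, times = 2), 40),
    context = rep(rep(c("SC", "OC"), each = 62), 40),
    rt_s = pmax(0.05, rnorm(40 * 124, rep(base_mean, each = 124), 0.05)),
    response = 1L, censored = 0L)
  covariates <- data.frame(participant_id = ids,
                           matrix(rnorm(40 * 7), 40, 7,
                                  dimnames = list(NULL, paste0("T", 1:7))))
  cohort_data(trials, covariates)
}

# Fixture reproducing the trial-level exclusion worked example:
# 38 participants x 124 trials with exactly 492 planted extreme RTs
# (balanced above/below each participant's baseline so the single-pass
# 3-SD rule flags all of them and nothing else).
make_trial_outlier_fixture <- function(seed = 13) {
  set.seed(seed)
  ids <- sprintf("S%02d", 1:38)
  n_out <- c(rep(13L, 36), 12L, 12L)  # 36*13 + 2*12 = 492
  rows <- lapply(seq_along(ids), function(i) {
    k <- n_out[i]
    k_hi <- ceiling(k / 2); k_lo <- k - k_hi
    rt <- c(2.5 + rnorm(124 - k, 0, 0.02),
            rep(4.5, k_hi), rep(0.5, k_lo))
    data.frame(participant_id = ids[i],
               familiarity = rep(rep(c("FM", "NM"), each = 31), 2),
               context = rep(c("SC", "OC"), each = 62),
               rt_s = rt, response = 1L, censored = 0L)
  })
  covariates <- data.frame(participant_id = ids,
                           matrix(rnorm(38 * 7), 38, 7,
                                  dimnames = list(NULL, paste0("T", 1:7))))
  cohort_data(do.call(rbind, rows), covariates)
}

# Minimal ddm_posterior wrapper for diagnostics that only need draws.
fake_posterior <- function(draws) {
  structure(list(draws = draws, deviance = rep(0, nrow(draws)),
                 n_total = nrow(draws), n_burn = 0, seed = 0,
                 accept_rate = NULL, model = NULL),
            class = "ddm_posterior")
}
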