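fit_small <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sc <- make_small_cohort(n_sub = 6, per_cell = 6, seed = 3)
      m <- build_model("fc", sc$cohort)
      s <- sample_posterior(m, n_samples = 700, n_burn = 200, seed = 2)
      cache <<- list(cohort = sc$cohort, model = m, samples = s)
    }
    cache
  }
})

test_that("model builder wires the three families correctly", {
  sc <- make_small_cohort(n_sub = 4, per_cell = 4, seed = 9)
  m0 <- build_model("null", sc$cohort)
  expect_false(any(grepl("bF|bC|beta", m0$param_names)))
  m1 <- build_model("fc", sc$cohort)
  expect_setequal(intersect(c("mu_bF", "mu_bC"), m1$param_names),
                  c("mu_bF", "mu_bC"))
  expect_false(any(grepl("beta_", m1$param_names)))
  m2 <- build_model("full", sc$cohort, covariate = "COWAT_Semantic")
  expect_true(all(c("beta_v", "beta_a", "beta_t") %in% m2$param_names))
  # covariate scores are z-scored across participants
  expect_equal(mean(m2$score), 0, tolerance = 1e-12)
  expect_equal(sd(m2$score), 1, tolerance = 1e-12)
  expect_error(build_model("full", sc$cohort), "covariate")
  expect_error(build_model("full", sc$cohort, covariate = "nope"),
               "not in the covariate table")
  # participant with an empty condition cell
  bad <- sc$cohort
  bad$trials <- bad$trials[!(bad$trials$participant_id == "P001" &
                               bad$trials$familiarity == "FM" &
                               bad$trials$context == "SC"), ]
  expect_error(build_model("fc", bad), "empty condition cell")
})

test_that("log posterior matches an independently coded sum-of-terms oracle", {
  # 2 participants x 8 trials, fixed by hand
  trials <- data.frame(
    participant_id = rep(c("A", "B"), each = 8),
    familiarity = rep(rep(c("FM", "NM"), each = 2), 4),
    context = rep(rep(c("SC", "OC"), each = 4), 2),
    rt_s = c(0.8, 1.1, 0.9, 1.4, 0.7, 1.0, 1.2, 0.95,
             1.05, 0.85, 1.3, 0.75, 0.9, 1.15, 1.0, 0.8),
    response = c(1L, 1L, 0L, 1L, 1L, 0L, 1L, 1L,
                 1L, 1L, 1L, 0L, 1L, 1L, 0L, 1L),
    censored = 0L)
  cov <- data.frame(participant_id = c("A", "B"), COWAT_Semantic = c(40, 50))
  coh <- cohort_data(trials, cov)
  m <- build_model("fc", coh)
  pr <- m$priors

  oracle_lp <- function(st) {
    # hyperpriors (same unnormalized form: constants drop in differences)
    hn <- function(x, s) if (x < 0) -Inf else -x^2 / (2 * s^2)
    dn <- function(x, mu, s) -0.5 * ((x - mu) / s)^2 - log(s)
    lp <- dn(st["mu_v"], pr$mu_v_mean, pr$mu_v_sd) +
      (pr$mu_a_shape - 1) * log(st["mu_a"]) - st["mu_a"] / pr$mu_a_scale +
      dn(st["mu_t0"], pr$mu_t0_mean, pr$mu_t0_sd) +
      hn(st["sigma_v"], pr$group_sd_scale) +
      hn(st["sigma_a"], pr$group_sd_scale) +
      hn(st["sigma_t0"], pr$group_sd_scale) +
      hn(st["sv"], pr$sv_scale) + hn(st["st"], pr$st_scale) +
      dn(st["mu_bF"], 0, pr$effect_sd) + dn(st["mu_bC"], 0, pr$effect_sd) +
      hn(st["sigma_bF"], pr$group_sd_scale) +
      hn(st["sigma_bC"], pr$group_sd_scale)
    for (id in c("A", "B")) {
      lp <- lp +
        dn(st[paste0("v[", id, "]")], st["mu_v"], st["sigma_v"]) +
        dn(st[paste0("a[", id, "]")], st["mu_a"], st["sigma_a"]) +
        dn(st[paste0("t0[", id, "]")], st["mu_t0"], st["sigma_t0"]) +
        dn(st[paste0("bF[", id, "]")], st["mu_bF"], st["sigma_bF"]) +
        dn(st[paste0("bC[", id, "]")], st["mu_bC"], st["sigma_bC"])
      sel <- trials$participant_id == id
      for (r in which(sel)) {
        veff <- st[paste0("v[", id, "]")] +
          st[paste0("bF[", id, "]")] * (if (trials$familiarity[r] == "FM") 0.5 else -0.5) +
          st[paste0("bC[", id, "]")] * (if (trials$context[r] == "OC") 0.5 else -0.5)
        b <- if (trials$response[r] == 1) "upper" else "lower"
        d <- oracle_trial_density(trials$rt_s[r], b, veff,
                                  st[paste0("a[", id, "]")], 0.5,
                                  st[paste0("t0[", id, "]")],
                                  st[["sv"]], st[["st"]])
        lp <- lp + log(d)
      }
    }
    unname(lp)
  }

  base <- ddmpipe:::initial_state(m)
  # sv = st = 0: pure series sums, no quadrature error in the oracle
  s1 <- base; s1["sv"] <- 0; s1["st"] <- 0
  s2 <- s1; s2["mu_v"] <- 1.4; s2["v[A]"] <- 2.4; s2["a[B]"] <- 1.7
  s2["bF[A]"] <- 0.4; s2["sigma_bF"] <- 0.3
  # log densities are defined up to one shared additive constant:
  # compare differences
  expect_equal(log_posterior(m, s1) - log_posterior(m, s2),
               oracle_lp(s1) - oracle_lp(s2), tolerance = 1e-10)
  # sv, st > 0 against the nested-quadrature oracle
  s3 <- s1; s3["sv"] <- 0.6; s3["st"] <- 0.15
  s4 <- s3; s4["t0[A]"] <- 0.35; s4["st"] <- 0.1; s4["sv"] <- 0.3
  expect_equal(log_posterior(m, s3) - log_posterior(m, s4),
               oracle_lp(s3) - oracle_lp(s4), tolerance = 1e-6)
  # support violations encode rejection, not errors
  s5 <- s1; s5[paste0("a[", "A", "]")] <- -0.2
  expect_identical(log_posterior(m, s5), -Inf)
  s6 <- s1; s6["sigma_v"] <- -1
  expect_identical(log_posterior(m, s6), -Inf)
  # perturbing a node with no data influence changes only its prior term
  s7 <- s1; s7["mu_bC"] <- 0.5
  expect_equal(log_posterior(m, s7) - log_posterior(m, s1),
               (-0.5 * (0.5 / pr$effect_sd)^2 -
                  0.5 * ((s1[["bC[A]"]] - 0.5) / s1[["sigma_bC"]])^2 -
                  0.5 * ((s1[["bC[B]"]] - 0.5) / s1[["sigma_bC"]])^2) -
                 (-0.5 * ((s1[["bC[A]"]] - 0) / s1[["sigma_bC"]])^2 +
                    -0.5 * ((s1[["bC[B]"]] - 0) / s1[["sigma_bC"]])^2),
               tolerance = 1e-10)
})

test_that("HDI: point mass, normal quantiles, and exhaustive-search equality", {
  expect_error(hdi(numeric(0)), "empty")
  expect_equal(hdi(rep(3.2, 50)), c(3.2, 3.2))
  set.seed(4)
  h <- hdi(rnorm(1e6))
  expect_lt(abs(h[1] + 1.959964), 0.03)
  expect_lt(abs(h[2] - 1.959964), 0.03)
  for (r in 1:20) {
    x <- switch(1 + r %% 3, rnorm(50), rexp(50), runif(50))
    expect_equal(hdi(x), oracle_hdi(x), label = paste("fixture", r))
  }
  # skewed draws: leftmost shortest window
  x <- c(rep(0, 30), seq(1, 5, length.out = 20))
  expect_equal(hdi(x, 0.5), oracle_hdi(x, 0.5))
})

test_that("Geweke statistic is calibrated and detects non-stationarity", {
  set.seed(88)
  pass <- vapply(1:200, function(i) geweke_z(rnorm(10000))$pass, logical(1))
  # nominal two-sided level ~95.4%; binomial 3 SE at n = 200 is ~4.4%
  expect_gte(mean(pass), 0.91)
  expect_gt(abs(geweke_z(seq(0, 10, length.out = 10000) +
                           rnorm(10000, 0, 0.1))$z), 2)
  expect_error(geweke_z(rep(1, 1000)), "constant")
  expect_error(geweke_z(rnorm(50)), "short")
})

test_that("DIC arithmetic: point posterior and the conjugate Gaussian toy", {
  d <- ddmpipe:::dic_components(rep(123.4, 100), 123.4)
  expect_equal(d$p_d, 0)
  expect_equal(d$dic, d$d_bar)
  # known-variance Gaussian mean estimation: p_d ~= 1 (one free parameter)
  set.seed(14)
  y <- rnorm(40, 2, 1)
  post_mean <- mean(y); post_sd <- 1 / sqrt(length(y))  # flat prior
  theta <- rnorm(10000, post_mean, post_sd)
  dev <- vapply(theta, function(th) -2 * sum(dnorm(y, th, 1, log = TRUE)),
                numeric(1))
  dev_at_mean <- -2 * sum(dnorm(y, mean(theta), 1, log = TRUE))
  toy <- ddmpipe:::dic_components(dev, dev_at_mean)
  expect_equal(toy$p_d, 1, tolerance = 0.1)
})

test_that("effect summaries implement the HDI decision rule", {
  dr <- cbind(pos = rexp(500) + 0.01, sym = rnorm(500))
  fp <- fake_posterior(dr)
  es <- effect_summary(fp, "pos")
  expect_equal(es$prob_positive, 1)
  expect_true(es$credible)
  es2 <- effect_summary(fp, "sym")
  expect_lt(abs(es2$prob_positive - 0.5), 0.1)
  expect_false(es2$credible)
  expect_error(effect_summary(fp, "nope"), "unknown label")
})

test_that("sampling is bitwise reproducible from the seed", {
  f <- fit_small()
  s2 <- sample_posterior(f$model, n_samples = 700, n_burn = 200, seed = 2)
  expect_identical(f$samples$draws, s2$draws)
  expect_identical(f$samples$deviance, s2$deviance)
  s3 <- sample_posterior(f$model, n_samples = 700, n_burn = 200, seed = 3)
  expect_false(identical(f$samples$draws, s3$draws))
})

test_that("posterior predictive checks are self-consistent and flag planted misfit", {
  f <- fit_small()
  ppc <- posterior_predictive(f$model, f$samples, n_rep = 30, seed = 4,
                              dt = 1e-3)
  expect_equal(nrow(ppc), 24)  # 4 conditions x (accuracy + 5 deciles)
  ok <- ppc$p_value > 0.01 & ppc$p_value < 0.99
  expect_gte(mean(ok, na.rm = TRUE), 0.75)
  # planted misfit: shift every observed RT by +0.5 s
  shifted <- f$cohort
  shifted$trials$rt_s <- shifted$trials$rt_s + 0.5
  m2 <- build_model("fc", shifted)
  ppc2 <- posterior_predictive(m2, f$samples, n_rep = 30, seed = 4, dt = 1e-3)
  med <- ppc2[ppc2$statistic == "rt_q50", "p_value"]
  expect_true(all(med < 0.01))
})

test_that("model comparison table shapes and ordering", {
  sc <- make_small_cohort(n_sub = 4, per_cell = 4, seed = 17)
  tab <- compare_models(sc$cohort, character(0), n_samples = 300,
                        n_burn = 100, seed = 1)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$model, c("null", "fc"))
  tab2 <- compare_models(sc$cohort, c("GNG", "ANT"), n_samples = 300,
                         n_burn = 100, seed = 1)
  expect_equal(tab2$model, c("null", "fc", "full:ANT", "full:GNG"))
  expect_true(all(is.finite(tab2$dic)))
})
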