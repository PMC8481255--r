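test_that("cohort validation reports schema violations with row numbers", {
  tr <- data.frame(participant_id = c("A", "A", "B", "B"),
                   familiarity = c("FM", "NM", "FM", "XX"),
                   context = c("SC", "OC", "SC", "OC"),
                   rt_s = c(1, 1, 1, 1), response = c(1L, 0L, 1L, 1L))
  cov <- data.frame(participant_id = c("A", "B"), T1 = c(1, 2))
  expect_error(cohort_data(tr, cov), "row\\(s\\): 4")
  tr$familiarity[4] <- "NM"; tr$rt_s[2] <- -1
  expect_error(cohort_data(tr, cov), "row\\(s\\): 2")
  tr$rt_s[2] <- 1
  expect_error(cohort_data(tr, cov[1, , drop = FALSE]), "missing from covariate table")
})

test_that("participant 3-SD exclusion: identity, planted singles and halting", {
  coh <- make_participant_outlier_fixture()
  out <- exclude_participants(coh)
  e <- out$ledger[[1]]
  expect_equal(e$n_removed, 248)
  expect_equal(e$pct_removed, 5.00)
  expect_equal(length(unique(out$trials$participant_id)), 38)
  # idempotent on its own output
  out2 <- exclude_participants(out)
  expect_equal(out2$ledger[[2]]$n_removed, 0)
  expect_equal(out2$ledger[[2]]$pct_removed, 0)
  # no outliers -> identity
  clean <- out
  clean$ledger <- list()
  expect_equal(nrow(exclude_participants(clean)$trials), nrow(clean$trials))
})

test_that("participant exclusion also screens averaged z-scored test scores", {
  set.seed(31)
  ids <- sprintf("S%02d", 1:20)
  trials <- make_hand_trials(ids, lapply(1:20, function(i)
    setNames(as.list(rnorm(4, 1, 0.05)), conditions_2x2())))
  sc <- matrix(rnorm(20 * 7), 20, 7, dimnames = list(NULL, paste0("T", 1:7)))
  sc[5, ] <- sc[5, ] + 25  # uniformly extreme across all tests
  coh <- cohort_data(trials, data.frame(participant_id = ids, sc))
  out <- exclude_participants(coh)
  expect_equal(out$ledger[[1]]$detail$participants_removed, list("S05"))
  expect_equal(out$ledger[[1]]$n_removed, 4)
})

test_that("trial 3-SD exclusion: planted worked example, boundary and zero spread", {
  coh <- make_trial_outlier_fixture()
  expect_equal(nrow(coh$trials), 4712)
  out <- exclude_trials(coh)
  e <- out$ledger[[1]]
  expect_equal(e$n_removed, 492)
  expect_equal(e$pct_removed, 10.44)
  # ledger conservation
  expect_equal(e$n_before, e$n_after + e$n_removed)
  expect_equal(e$pct_removed, round(100 * e$n_removed / e$n_before, 2))
  # outlier at +2.9 SD is retained
  set.seed(2)
  ids <- c("A", "B", "C")
  base <- rnorm(30, 1, 0.1)
  tr <- data.frame(participant_id = rep(ids, each = 31),
                   familiarity = "FM", context = "SC",
                   rt_s = c(base, mean(base) + 2.9 * sd(c(base, base[1])),
                            rnorm(31, 1, 0.1), rnorm(31, 1, 0.1))[1:93],
                   response = 1L, censored = 0L)
  # construct explicitly: participant A has 30 base + one at mean + 2.9 sd(all)
  rtA <- c(base, NA)
  for (iter in 1:20) rtA[31] <- mean(rtA, na.rm = TRUE) + 2.9 * sd(c(rtA[1:30], rtA[31]), na.rm = TRUE)
  tr$rt_s[1:31] <- rtA
  cov <- data.frame(participant_id = ids, T1 = c(1, 2, 3))
  out2 <- exclude_trials(cohort_data(tr, cov))
  expect_equal(sum(out2$trials$participant_id == "A"), 31)
  # zero spread: nothing removed
  tr$rt_s <- 1
  out3 <- exclude_trials(cohort_data(tr, cov))
  expect_equal(out3$ledger[[1]]$n_removed, 0)
})

test_that("condition summaries match a hand-computed two-participant fixture", {
  trials <- make_hand_trials(
    c("A", "B"),
    list(list(`SC-FM` = 0.8, `OC-FM` = 1.0, `SC-NM` = 1.2, `OC-NM` = 1.4),
         list(`SC-FM` = 0.9, `OC-FM` = 1.1, `SC-NM` = 1.3, `OC-NM` = 1.5)))
  cov <- data.frame(participant_id = c("A", "B"), T1 = c(1, 2))
  d <- condition_summaries(cohort_data(trials, cov))
  cell <- d[d$scope == "cell", ]
  expect_equal(cell$mean_rt_ms[cell$condition == "SC-FM"], 850)
  expect_equal(cell$sem_rt_ms[cell$condition == "SC-FM"],
               sd(c(800, 900)) / sqrt(2))
  expect_true(all(cell$accuracy_pct == 100))
  marg <- d[d$scope == "marginal", ]
  expect_equal(marg$mean_rt_ms[marg$condition == "FM"],
               mean(c((800 + 1000) / 2, (900 + 1100) / 2)))
  # marginal FM mean equals mean of the two constituent subject marginals
  expect_equal(marg$mean_rt_ms[marg$condition == "FM"],
               mean(cell$mean_rt_ms[cell$condition %in% c("SC-FM", "OC-FM")]))
  # identical RTs everywhere -> SEM 0
  trials2 <- make_hand_trials(
    c("A", "B"),
    rep(list(list(`SC-FM` = 1, `OC-FM` = 1, `SC-NM` = 1, `OC-NM` = 1)), 2))
  d2 <- condition_summaries(cohort_data(trials2, cov))
  expect_true(all(d2$sem_rt_ms == 0))
})

test_that("repeated-measures ANOVA matches the general-linear-model oracle", {
  set.seed(6)
  # textbook-sized fixture, frozen against the aov() oracle
  cells <- matrix(c(720, 810, 690, 850,
                    760, 890, 700, 900,
                    845, 930, 810, 960,
                    910, 990, 905, 1010),
                  nrow = 4, byrow = TRUE,
                  dimnames = list(paste0("S", 1:4), conditions_2x2()))
  res <- rm_anova_2x2(cells)
  orc <- oracle_rm_anova(cells)
  expect_equal(res$F, unname(orc[res$effect]), tolerance = 1e-10)
  expect_equal(res$df1, rep(1L, 3))
  expect_equal(res$df2, rep(3L, 3))
  # location invariance
  res2 <- rm_anova_2x2(cells + 500)
  expect_equal(res2$F, res$F, tolerance = 1e-10)
  # all cells equal per participant -> F = 0 throughout
  flat <- matrix(rep(c(700, 800, 900, 950), 4), 4, 4, byrow = FALSE,
                 dimnames = list(paste0("S", 1:4), conditions_2x2()))
  expect_equal(rm_anova_2x2(flat)$F, rep(0, 3))
  expect_error(rm_anova_2x2(replace(cells, 2, NA)), "missing")
})

test_that("pairwise Bonferroni comparisons", {
  cells <- matrix(rnorm(24, 1000, 50), 6, 4,
                  dimnames = list(paste0("S", 1:6), conditions_2x2()))
  pw <- pairwise_bonferroni(cells)
  expect_equal(nrow(pw), 4)
  expect_true(all(pw$p_adjusted >= pw$p_raw))
  expect_equal(pw$p_adjusted, pmin(1, pw$p_raw * 4))
  # identical conditions
  same <- cells; same[, "SC-NM"] <- same[, "SC-FM"]
  pw2 <- pairwise_bonferroni(same, pairs = list(c("SC-FM", "SC-NM")))
  expect_equal(pw2$t, 0)
  expect_equal(pw2$p_adjusted, 1)
})

test_that("correlation table matches the covariance-definition oracle", {
  set.seed(12)
  ids <- sprintf("S%02d", 1:10)
  rts <- lapply(1:10, function(i)
    setNames(as.list(rnorm(4, 1, 0.15)), conditions_2x2()))
  trials <- make_hand_trials(ids, rts)
  sc <- matrix(rnorm(10 * 7), 10, 7,
               dimnames = list(NULL, c("ANT", "COWAT_Semantic",
                                       "COWAT_Phonemic", "GNG", "LNST",
                                       "Stroop", "WCST")))
  coh <- cohort_data(trials, data.frame(participant_id = ids, sc))
  ct <- correlation_table(coh)
  expect_equal(dim(ct$r), c(7, 4))
  cm <- cell_means(coh, "rt")
  for (te in rownames(ct$r))
    for (cc in colnames(ct$r))
      expect_equal(ct$r[te, cc], oracle_pearson(sc[, te], cm[, cc]),
                   tolerance = 1e-12)
  # perfectly linear scores
  lin <- sc; lin[, "ANT"] <- 3 - 2 * cm[, "SC-FM"]
  ct2 <- correlation_table(cohort_data(trials,
                                       data.frame(participant_id = ids, lin)))
  expect_equal(ct2$r["ANT", "SC-FM"], -1, tolerance = 1e-12)
  expect_lt(ct2$p["ANT", "SC-FM"], 1e-12)
  # zero-variance score -> undefined cells
  zv <- sc; zv[, "GNG"] <- 0.5
  ct3 <- correlation_table(cohort_data(trials,
                                       data.frame(participant_id = ids, zv)))
  expect_true(all(is.na(ct3$r["GNG", ])))
})

test_that("summary-statistic Welch t-test", {
  expect_equal(welch_t_from_summary(3, 0.1, 30, 3, 0.2, 30)$t, 0)
  # norming-style summaries: frozen values from the formula itself
  w <- welch_t_from_summary(4.44, 0.11, 62, 2.51, 0.09, 62)
  expect_equal(w$t, 13.579, tolerance = 1e-3)
  expect_equal(w$df, 117.4, tolerance = 0.05)
  expect_lt(w$p, 0.001)
  # antisymmetry
  w2 <- welch_t_from_summary(2.51, 0.09, 62, 4.44, 0.11, 62)
  expect_equal(w2$t, -w$t)
  expect_equal(w2$df, w$df)
  expect_error(welch_t_from_summary(1, 0, 10, 2, 0.1, 10), "> 0")
})
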