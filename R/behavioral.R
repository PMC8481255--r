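#' Cohort container for two-choice behavioral data
#'
#' Holds per-trial records of a 2x2 within-subject metaphor-comprehension
#' style design (factors FAMILIARITY: FM/NM and CONTEXT: SC/OC), a
#' per-participant covariate table (neuropsychological test scores), and an
#' exclusion-accounting ledger that records every filtering step.
#'
#' @param trials data.frame with columns `participant_id`, `familiarity`
#'   (`"FM"`/`"NM"`), `context` (`"SC"`/`"OC"`), `rt_s` (response time in
#'   seconds), `response` (1 correct / 0 error), and optionally `censored`
#'   (0/1; censored trials carry `NA` rt and are dropped by the pipeline).
#' @param covariates data.frame with column `participant_id` plus one
#'   numeric column per test; every participant in `trials` must appear.
#' @param ledger List of exclusion-ledger entries (usually empty at
#'   construction).
#' @return An object of class `cohort_data`.
#' @export
cohort_data <- function(trials, covariates, ledger = list()) {
  need <- c("participant_id", "familiarity", "context", "rt_s", "response")
  miss <- setdiff(need, names(trials))
  if (length(miss))
    stop("trials is missing column(s): ", paste(miss, collapse = ", "))
  if (!"censored" %in% names(trials)) trials$censored <- 0L
  trials$participant_id <- as.character(trials$participant_id)
  covariates$participant_id <- as.character(covariates$participant_id)
  bad <- which(!trials$familiarity %in% c("FM", "NM"))
  if (length(bad))
    stop("invalid familiarity at trial row(s): ", paste(head(bad), collapse = ", "))
  bad <- which(!trials$context %in% c("SC", "OC"))
  if (length(bad))
    stop("invalid context at trial row(s): ", paste(head(bad), collapse = ", "))
  obs <- trials$censored != 1
  bad <- which(obs & (!is.finite(trials$rt_s) | trials$rt_s <= 0))
  if (length(bad))
    stop("non-positive rt_s at trial row(s): ", paste(head(bad), collapse = ", "))
  bad <- which(obs & !trials$response %in% c(0, 1))
  if (length(bad))
    stop("response must be 0/1 at trial row(s): ", paste(head(bad), collapse = ", "))
  orphan <- setdiff(unique(trials$participant_id), covariates$participant_id)
  if (length(orphan))
    stop("participants missing from covariate table: ",
         paste(orphan, collapse = ", "))
  structure(list(trials = trials, covariates = covariates, ledger = ledger),
            class = "cohort_data")
}

#' @export
print.cohort_data <- function(x, ...) {
  np <- length(unique(x$trials$participant_id))
  cat(sprintf("cohort_data: %d trials, %d participants, %d covariate(s), %d ledger entrie(s)\n",
              nrow(x$trials), np, ncol(x$covariates) - 1L, length(x$ledger)))
  invisible(x)
}

covariate_names <- function(cohort) {
  setdiff(names(cohort$covariates), "participant_id")
}

condition_of <- function(trials) paste(trials$context, trials$familiarity, sep = "-")

#' @rdname cohort_data
#' @export
conditions_2x2 <- function() c("SC-FM", "OC-FM", "SC-NM", "OC-NM")

ledger_entry <- function(rule, n_before, n_removed, detail = NULL) {
  e <- list(rule = rule, n_before = n_before, n_removed = n_removed,
            n_after = n_before - n_removed,
            pct_removed = round(100 * n_removed / n_before, 2))
  if (!is.null(detail)) e$detail <- detail
  e
}

#' Participant-level 3-SD exclusion
#'
#' Removes every participant whose mean response time, or whose mean across
#' the per-test z-scored covariate scores, lies more than three standard
#' deviations from the cohort mean (both statistics computed across all
#' participants, including the candidates). Scores are z-scored per test
#' before averaging so the seven scales are commensurable. All trials of an
#' excluded participant are removed and accounted for in the ledger.
#'
#' @param cohort A [cohort_data()] object with at least 3 participants.
#' @return The filtered `cohort_data`, with one ledger entry appended.
#' @export
exclude_participants <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_data"))
  tr <- cohort$trials
  ids <- unique(tr$participant_id)
  if (length(ids) < 3) stop("need at least 3 participants")
  obs <- tr[tr$censored != 1, ]
  mean_rt <- tapply(obs$rt_s, obs$participant_id, mean)[ids]
  cov <- cohort$covariates[match(ids, cohort$covariates$participant_id), , drop = FALSE]
  zsc <- scale(as.matrix(cov[, covariate_names(cohort), drop = FALSE]))
  mean_score <- rowMeans(zsc)
  out3 <- function(x) {
    s <- sd(x)
    if (!is.finite(s) || s == 0) return(rep(FALSE, length(x)))
    abs(x - mean(x)) > 3 * s
  }
  drop_ids <- ids[out3(mean_rt) | out3(mean_score)]
  if (length(drop_ids) == length(ids))
    stop("participant exclusion removed every participant; pipeline halted")
  keep <- !tr$participant_id %in% drop_ids
  entry <- ledger_entry("participant_3sd", nrow(tr), sum(!keep),
                        detail = list(participants_removed = as.list(drop_ids)))
  cohort$trials <- tr[keep, , drop = FALSE]
  cohort$covariates <- cohort$covariates[
    !cohort$covariates$participant_id %in% drop_ids, , drop = FALSE]
  cohort$ledger <- c(cohort$ledger, list(entry))
  cohort
}

#' Trial-level 3-SD exclusion
#'
#' Per participant, removes trials whose response time lies more than three
#' standard deviations from that participant's mean. A single pass is used,
#' with mean and SD computed on the participant's retained trials including
#' the candidate outliers (whether the original procedure iterated is
#' unknowable from its description; the single pass is the
#' least-assumption choice). Participants whose response times have zero
#' spread lose no trials: removal requires a strictly greater deviation.
#'
#' @param cohort A [cohort_data()] object; every participant needs >= 3
#'   trials.
#' @return The filtered `cohort_data`, with one ledger entry appended.
#' @export
exclude_trials <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_data"))
  tr <- cohort$trials
  cnt <- table(tr$participant_id)
  if (any(cnt < 3)) stop("every participant needs at least 3 trials")
  keep <- rep(TRUE, nrow(tr))
  for (id in unique(tr$participant_id)) {
    sel <- which(tr$participant_id == id & tr$censored != 1)
    x <- tr$rt_s[sel]
    s <- sd(x)
    if (is.finite(s) && s > 0)
      keep[sel[abs(x - mean(x)) > 3 * s]] <- FALSE
  }
  entry <- ledger_entry("trial_3sd", nrow(tr), sum(!keep))
  cohort$trials <- tr[keep, , drop = FALSE]
  cohort$ledger <- c(cohort$ledger, list(entry))
  cohort
}

# Drop censored trials (no response within the deadline) with a ledger entry.
#' @rdname exclude_trials
#' @export
drop_censored <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_data"))
  tr <- cohort$trials
  keep <- tr$censored != 1
  if (all(keep)) return(cohort)
  entry <- ledger_entry("censored", nrow(tr), sum(!keep))
  cohort$trials <- tr[keep, , drop = FALSE]
  cohort$ledger <- c(cohort$ledger, list(entry))
  cohort
}

# Per-participant cell means of one dependent variable.
# rt: correct, non-censored trials only, in ms. accuracy: % correct of
# non-censored trials. Returns participants x 4 matrix (may contain NA for
# empty rt cells).
#' Per-participant condition cell means
#'
#' @param cohort A [cohort_data()] object.
#' @param dependent `"rt"` (mean correct-response RT, ms) or `"accuracy"`
#'   (% correct).
#' @return Numeric matrix, participants in rows, the four conditions
#'   (`SC-FM`, `OC-FM`, `SC-NM`, `OC-NM`) in columns.
#' @export
cell_means <- function(cohort, dependent = c("rt", "accuracy")) {
  dependent <- match.arg(dependent)
  tr <- cohort$trials[cohort$trials$censored != 1, ]
  ids <- unique(tr$participant_id)
  cond <- condition_of(tr)
  m <- matrix(NA_real_, length(ids), 4,
              dimnames = list(ids, conditions_2x2()))
  for (cc in conditions_2x2()) {
    if (dependent == "rt") {
      sub <- tr[cond == cc & tr$response == 1, ]
      v <- tapply(sub$rt_s * 1000, sub$participant_id, mean)
    } else {
      sub <- tr[cond == cc, ]
      v <- tapply(sub$response * 100, sub$participant_id, mean)
    }
    m[names(v), cc] <- v
  }
  m
}

#' Condition descriptives
#'
#' Subject-level cell means are computed first (correct responses only for
#' RT, reported in ms), then averaged across subjects with the standard
#' error of the mean (SD / sqrt(n)). Marginal rows (FM, NM, SC, OC) are
#' means of the two constituent cell means per subject. Participants with
#' no correct trial in a cell are excluded from that cell's RT summary with
#' a warning.
#'
#' @param cohort A [cohort_data()] object.
#' @return data.frame with columns `condition`, `scope` (`cell`/`marginal`),
#'   `n`, `mean_rt_ms`, `sem_rt_ms`, `accuracy_pct`, `sem_accuracy_pct`.
#' @export
condition_summaries <- function(cohort) {
  rt <- cell_means(cohort, "rt")
  ac <- cell_means(cohort, "accuracy")
  if (anyNA(rt))
    warning("participant(s) with no correct trials in a cell excluded from that cell's RT summary")
  sem <- function(x) { x <- x[!is.na(x)]; sd(x) / sqrt(length(x)) }
  mn <- function(x) mean(x, na.rm = TRUE)
  marg <- list(FM = c("SC-FM", "OC-FM"), NM = c("SC-NM", "OC-NM"),
               SC = c("SC-FM", "SC-NM"), OC = c("OC-FM", "OC-NM"))
  rows <- lapply(conditions_2x2(), function(cc)
    data.frame(condition = cc, scope = "cell", n = sum(!is.na(rt[, cc])),
               mean_rt_ms = mn(rt[, cc]), sem_rt_ms = sem(rt[, cc]),
               accuracy_pct = mn(ac[, cc]), sem_accuracy_pct = sem(ac[, cc])))
  mrows <- lapply(names(marg), function(mm) {
    r <- rowMeans(rt[, marg[[mm]], drop = FALSE])
    a <- rowMeans(ac[, marg[[mm]], drop = FALSE])
    data.frame(condition = mm, scope = "marginal", n = sum(!is.na(r)),
               mean_rt_ms = mn(r), sem_rt_ms = sem(r),
               accuracy_pct = mn(a), sem_accuracy_pct = sem(a))
  })
  do.call(rbind, c(rows, mrows))
}

#' Two-way repeated-measures ANOVA (2 x 2 within-subject)
#'
#' Standard within-subject decomposition on one observation per
#' participant x condition cell: each effect's F is MS_effect divided by
#' MS_effect-by-subject, with df (1, n - 1). For a 2 x 2 design this equals
#' the squared paired t statistic on the corresponding within-subject
#' contrast, which is how it is computed here; the equivalence with the
#' sums-of-squares route is exercised against a general-linear-model oracle
#' in the test suite.
#'
#' @param cells Numeric matrix from [cell_means()]: participants x 4
#'   conditions, complete (no NA).
#' @return data.frame with one row per effect (`FAMILIARITY`, `CONTEXT`,
#'   `INTERACTION`): `F`, `df1`, `df2`, `p`.
#' @export
rm_anova_2x2 <- function(cells) {
  cells <- as.matrix(cells[, conditions_2x2(), drop = FALSE])
  if (anyNA(cells)) stop("missing participant x condition cell(s)")
  n <- nrow(cells)
  contrast_F <- function(d) {
    num <- n * mean(d)^2
    den <- var(d)
    if (den == 0) return(if (num == 0) 0 else Inf)
    num / den
  }
  dF <- rowMeans(cells[, c("SC-FM", "OC-FM")]) - rowMeans(cells[, c("SC-NM", "OC-NM")])
  dC <- rowMeans(cells[, c("SC-FM", "SC-NM")]) - rowMeans(cells[, c("OC-FM", "OC-NM")])
  dI <- (cells[, "SC-FM"] - cells[, "OC-FM"]) - (cells[, "SC-NM"] - cells[, "OC-NM"])
  Fv <- c(contrast_F(dF), contrast_F(dC), contrast_F(dI))
  data.frame(effect = c("FAMILIARITY", "CONTEXT", "INTERACTION"),
             F = Fv, df1 = 1L, df2 = n - 1L,
             p = pf(Fv, 1, n - 1, lower.tail = FALSE))
}

#' Pairwise Bonferroni-corrected comparisons
#'
#' Paired two-sided t-tests on the four comparisons displayed in the
#' condition bar plots (familiarity within each context, context within
#' each familiarity), Bonferroni-adjusted over the number of pairs.
#'
#' @param cells Matrix from [cell_means()].
#' @param pairs List of length-2 character vectors of condition names.
#' @return data.frame with `pair`, `t`, `df`, `p_raw`, `p_adjusted`.
#' @export
pairwise_bonferroni <- function(cells,
                                pairs = list(c("SC-FM", "SC-NM"),
                                             c("OC-FM", "OC-NM"),
                                             c("SC-FM", "OC-FM"),
                                             c("SC-NM", "OC-NM"))) {
  cells <- as.matrix(cells)
  k <- length(pairs)
  out <- lapply(pairs, function(pp) {
    d <- cells[, pp[1]] - cells[, pp[2]]
    if (sd(d) == 0) {
      if (all(d == 0))
        return(data.frame(pair = paste(pp, collapse = " vs "), t = 0,
                          df = length(d) - 1L, p_raw = 1, p_adjusted = 1))
      stop("zero-variance non-zero difference vector for pair ",
           paste(pp, collapse = " vs "))
    }
    tt <- t.test(cells[, pp[1]], cells[, pp[2]], paired = TRUE)
    data.frame(pair = paste(pp, collapse = " vs "),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_raw = tt$p.value, p_adjusted = min(1, tt$p.value * k))
  })
  do.call(rbind, out)
}

#' Covariate-by-condition Pearson correlation table
#'
#' For each test score and each condition: participants' mean
#' correct-response RTs and their scores are z-scored across participants,
#' then correlated (Pearson; the z-scoring leaves r unchanged and mirrors
#' how such tables are reported). Two-sided p-values come from the t
#' transform with df = n - 2; significance tiers are starred at
#' 0.05 / 0.01 / 0.001, uncorrected.
#'
#' @param cohort A [cohort_data()] object with >= 4 participants with
#'   complete scores.
#' @return An object of class `ddm_cor_table`: list of matrices `r`, `p`,
#'   `stars` (tests x conditions; `NA` cells where a score has zero
#'   variance).
#' @export
correlation_table <- function(cohort) {
  rt <- cell_means(cohort, "rt")
  ids <- rownames(rt)
  if (length(ids) < 4) stop("need >= 4 participants")
  cov <- cohort$covariates[match(ids, cohort$covariates$participant_id), , drop = FALSE]
  tests <- covariate_names(cohort)
  r <- p <- matrix(NA_real_, length(tests), 4,
                   dimnames = list(tests, conditions_2x2()))
  for (te in tests) {
    x <- cov[[te]]
    if (sd(x) == 0) next
    for (cc in conditions_2x2()) {
      y <- rt[, cc]
      ok <- !is.na(y)
      ct <- cor.test(as.numeric(scale(x[ok])), as.numeric(scale(y[ok])),
                     method = "pearson")
      r[te, cc] <- unname(ct$estimate)
      p[te, cc] <- ct$p.value
    }
  }
  stars <- matrix(ifelse(is.na(p), NA_character_,
                         ifelse(p < 0.001, "***",
                                ifelse(p < 0.01, "**",
                                       ifelse(p < 0.05, "*", "")))),
                  nrow(p), ncol(p), dimnames = dimnames(p))
  structure(list(r = r, p = p, stars = stars), class = "ddm_cor_table")
}

#' @export
print.ddm_cor_table <- function(x, digits = 2, ...) {
  m <- matrix(paste0(format(round(x$r, digits)), x$stars),
              nrow(x$r), ncol(x$r), dimnames = dimnames(x$r))
  m[is.na(x$r)] <- "NA"
  print(m, quote = FALSE)
  invisible(x)
}

#' Welch t-test from summary statistics
#'
#' Two-sample Welch t-test computed from group means, standard errors of
#' the mean and sample sizes (the form available when only summary
#' statistics are published, e.g. stimulus norming ratings):
#' `t = (m1 - m2) / sqrt(sem1^2 + sem2^2)` with Welch-Satterthwaite
#' degrees of freedom.
#'
#' @param m1,m2 Group means.
#' @param sem1,sem2 Standard errors of the mean (> 0).
#' @param n1,n2 Group sizes (>= 2).
#' @return List with `t`, `df`, `p` (two-sided).
#' @export
welch_t_from_summary <- function(m1, sem1, n1, m2, sem2, n2) {
  if (sem1 <= 0 || sem2 <= 0) stop("standard errors must be > 0")
  stopifnot(n1 >= 2, n2 >= 2)
  s2 <- sem1^2 + sem2^2
  t <- (m1 - m2) / sqrt(s2)
  df <- s2^2 / (sem1^4 / (n1 - 1) + sem2^4 / (n2 - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}
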