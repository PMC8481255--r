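# ddmpipe

Hierarchical drift-diffusion modelling of two-choice behavioral data from a
2×2 within-subject design with between-subject covariates.

## What problem this solves

In two-alternative forced-choice tasks (the motivating case is a
metaphor-comprehension judgement task crossing metaphor FAMILIARITY with
CONTEXT supportiveness), response times and accuracies mix several
processes: evidence quality, response caution, and time spent on encoding
and motor execution. The drift-diffusion model (DDM) decomposes each trial
into interpretable parameters — drift rate *v*, boundary separation *a*,
non-decision time *t0*, starting point *z*, with inter-trial variabilities
*sv* and *st* — and a hierarchical Bayesian treatment pools information
across participants so that individual parameters are estimable from ~124
trials each.

`ddmpipe` provides, as one tested pipeline:

* an exact Wiener first-passage-time density (dual-series evaluation,
  closed-form *sv* marginalization, Gauss–Legendre *st* marginalization)
  and an Euler–Maruyama forward simulator with deadline censoring;
* a Metropolis-within-Gibbs sampler for three hierarchical model families
  (`null`, `fc` with condition-dependent drift
  `v_ij = v_i + βF_i·F_j + βC_i·C_j`, and `full` adding one z-scored
  covariate into *v*, *a* and *t0*), with adapted per-node step sizes and
  bitwise seed reproducibility;
* DIC model comparison (focused hierarchical deviance), Geweke convergence
  z-scores, 95% highest-density-interval effect tests
  (`credible` ⇔ the 95% HDI excludes zero), posterior predictive checks;
* the classical companion pipeline: participant- and trial-level 3-SD
  exclusions with an accounting ledger, condition descriptives, 2×2
  repeated-measures ANOVA, Bonferroni pairwise tests, z-scored Pearson
  correlation tables, and a Welch t-test from summary statistics;
* a synthetic-cohort generator with known ground truth (38 participants ×
  124 trials, seven covariate batteries, one active covariate) for
  parameter-recovery and specificity experiments.

## Worked example

```r
library(ddmpipe)

# a synthetic cohort with known truth (familiarity drift effect 0.76)
gen <- generate_cohort(generator_config(n_participants = 20,
                                        trials_per_cell = 16), seed = 7)
coh <- drop_censored(gen$cohort)

# classical side
condition_summaries(coh)[1:4, c("condition", "mean_rt_ms", "accuracy_pct")]
rm_anova_2x2(cell_means(coh, "rt"))

# hierarchical DDM side
m <- build_model("fc", coh)
s <- sample_posterior(m, n_samples = 1500, n_burn = 400, seed = 3)
effect_summary(s, "mu_bF")
dic(s)
```

Output from this exact run:

```
  condition mean_rt_ms accuracy_pct
1     SC-FM   935.3362     93.12500
2     OC-FM   889.9123     95.93750
3     SC-NM   989.4750     87.70833
4     OC-NM  1004.1001     88.75000

       effect         F df1 df2          p
1 FAMILIARITY 5.9042115   1  19 0.02518777
2     CONTEXT 0.1776618   1  19 0.67812065
3 INTERACTION 0.7980921   1  19 0.38284076

  label     mean   hdi_low hdi_high prob_positive credible
1 mu_bF 0.818588 0.5212474 1.056995             1     TRUE

$d_bar 1516.5561  $p_d 51.27537  $dic 1567.8315
```

Reading it: familiar metaphors are answered faster and more accurately
(significant familiarity main effect, no interaction); the
population-level familiarity drift effect `mu_bF` has posterior mean 0.82
against a true value of 0.76, with all of its mass above zero
(`prob_positive = 1`) and a 95% HDI excluding zero, so the effect is
flagged `credible` under the HDI decision rule. `dic()` values are
comparable across model families via `compare_models()`, lower is better.

The command-line wrapper exposes the same stages:

```sh
Rscript inst/cli/ddmpipe.R simulate --out sim --seed 1
Rscript inst/cli/ddmpipe.R behav --trials sim/trials.csv --covariates sim/covariates.csv --out reports
Rscript inst/cli/ddmpipe.R fit --trials sim/trials.csv --covariates sim/covariates.csv \
    --kind full --covariate COWAT_Semantic --out fits
```

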