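---
title: "Modelling two-choice metaphor-comprehension behavior with a hierarchical drift-diffusion model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling two-choice metaphor-comprehension behavior with a hierarchical drift-diffusion model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddmpipe)
```

## The problem

In a two-alternative forced-choice sentence-judgement task, each trial yields
a response time and a correct/error outcome. The design crossed two
within-subject factors — metaphor FAMILIARITY (familiar, FM vs. novel, NM)
and CONTEXT supportiveness (supporting, SC vs. opposing, OC) — and each
participant also contributed seven neuropsychological test scores (ANT,
COWAT-Semantic, COWAT-Phonemic, GNG, LNST, Stroop, WCST) measuring distinct
executive functions. Raw RT/accuracy contrasts confound stimulus encoding,
evidence quality, response caution and motor execution; the drift-diffusion
model (DDM) separates them, so condition and individual-difference effects
can be attributed to specific components of the decision process.

`ddmpipe` implements the complete analysis chain: exclusion rules and
classical statistics; a hierarchical Bayesian DDM with condition-dependent
drift rates and between-subject covariate regression; DIC model comparison
across a family of model variants; 95% highest-density-interval (HDI)
hypothesis tests; posterior predictive checks; and a synthetic-cohort
generator with known ground truth so that every stage is testable without
access to any participant-level data set.

## The diffusion model

A trial is modelled as noisy evidence accumulation between two absorbing
boundaries separated by $a$, starting at fraction $z$ of $a$, with mean
drift $v$ and unit diffusion coefficient. Absorption at the upper boundary
is the correct response (accuracy coding), at the lower boundary an error;
the response time adds a non-decision offset $t_0$. Inter-trial variability
enters through a per-trial drift $v' \sim \mathrm{Normal}(v, s_v)$ and a
per-trial offset $t_0' \sim \mathrm{Uniform}(t_0 - s_t/2, t_0 + s_t/2)$.
The starting point is fixed at $z = 0.5$: with accuracy-coded boundaries
there is no reason to allow a bias toward "correct", and $s_z$ is fixed at 0.

**Conventions that matter.** The diffusion coefficient is fixed at 1. Under
the alternative 0.1 convention used by some older programs, drift rates and
boundary separations are 10 times smaller; all parameter values in this
package (priors, defaults, reported posteriors) are on the unit-coefficient
scale.

The first-passage-time density is evaluated with the classical dual-series
representation: a small-time expansion (Gaussian image sums) and a
large-time expansion (sine series), switching to whichever needs fewer
terms for truncation error at most $10^{-7}$. Drift variability $s_v$ is
marginalized in closed form (a Gaussian integral over the drift-dependent
exponential factor). Non-decision variability $s_t$ is marginalized with a
fixed 11-node Gauss–Legendre rule over $[t_0 - s_t/2,\; t_0 + s_t/2]$; on
the smooth integrands that arise away from the $rt = t_0'$ kink this agrees
with adaptive quadrature to near machine precision (the test suite checks
$10^{-6}$ relative error against an independently coded brute-force
oracle). Responses faster than the minimal non-decision time get log-zero
($-\infty$) rather than an error, so the sampler simply rejects such
states.

The forward simulator is an Euler–Maruyama accumulator (default step
$10^{-4}$ s) with a 5 s censoring deadline mirroring the task's response
window. Euler first-passage times carry a known $O(\sqrt{dt})$ boundary
overshoot bias; at the default step this is a few milliseconds and the
simulator-vs-density Kolmogorov–Smirnov distance stays below 0.01. Censored
trials are excluded from likelihoods with a ledger entry — the least
assumption available when the analysed procedure does not describe
censoring handling.

Two closed forms (fixed drift, unit coefficient) serve as independent
oracles for the simulator and likelihood:
$P(\text{upper}) = \frac{1 - e^{-2vza}}{1 - e^{-2va}}$ and, for $z = 0.5$,
the boundary-pooled mean decision time $\frac{a}{2v}\tanh(va/2)$.

## Hierarchical model family

For participant $i$ in condition $j$ the trial drift is
$$v_{ij} = v_i + \beta^F_i F_j + \beta^C_i C_j \;(+\; \beta_v\,x_i),$$
with effect coding $F_j = +0.5$ for FM, $-0.5$ for NM and $C_j = +0.5$ for
OC, $-0.5$ for SC, so each population-level effect mean is directly the
FM$-$NM or OC$-$SC drift difference. Boundary separation and non-decision
time are per-participant and condition-constant; in the covariate model
they receive population-level shifts $\beta_a x_i$ and $\beta_t x_i$.
Covariate scores $x_i$ are z-scored across included participants before
entering the graph, which makes slopes comparable across the seven tests
(whose raw scales differ by orders of magnitude). Three families are
exposed:

* **null** — no condition effects, no covariates;
* **fc** — condition effects on drift only;
* **full** — fc plus one covariate entering $v$, $a$ and $t_0$.

Subject-level parameters ($v_i$, $\beta^F_i$, $\beta^C_i$, $a_i$, $t_0{}_i$)
are draws from group Normal distributions. Covariate slopes are
population-level only: the covariate is between-subject with one score per
participant, so subject-level slopes would be unidentifiable. $s_v$ and
$s_t$ are single group-level values shared across participants, the common
default in hierarchical DDM practice. Condition effects are
subject-hierarchical; whether the original analysis treated them as
hierarchical or population-only is not documented, so this is this
package's design choice, not a claim about that analysis.

Positivity of $a_i$ (and of the covariate-shifted $a_i + \beta_a x_i$, and
of the minimal non-decision time $t_0{}_i + \beta_t x_i - s_t/2$) is
enforced as a support constraint: states outside the support get log-zero.
The Gaussian subject priors are not renormalized by their truncation mass;
the joint remains a well-defined unnormalized density, and this choice
keeps group-mean updates free of truncation-constant terms.

**Priors.** Informed priors in a moderate range, following published
surveys of diffusion parameters: group drift-intercept mean
$\mathrm{Normal}(2, 3^2)$; group boundary mean $\mathrm{Gamma}(1.5, 1)$;
group non-decision mean $\mathrm{Normal}(0.4, 0.2^2)$ truncated at 0;
effect and slope means $\mathrm{Normal}(0, 1)$; group SDs
$\mathrm{HalfNormal}(1)$; $s_v \sim \mathrm{HalfNormal}(2)$;
$s_t \sim \mathrm{HalfNormal}(0.3)$ (seconds). All are configurable via
`default_priors()`.

## Sampling, diagnostics and decision rules

`sample_posterior()` runs single-site Metropolis-within-Gibbs: each node
gets a Gaussian random-walk proposal per sweep, with per-node step sizes
adapted every 50 burn-in sweeps toward the 0.3–0.5 acceptance band and
frozen afterwards (so the retained chain is a fixed Markov kernel).
The default run length follows common practice for this model class —
12,000 iterations with 2,000 discarded as burn-in — and a single chain is
run by default; multiple chains are obtained by varying the seed.
Initialization places group locations at their prior means, starting
scales at moderate values, subject parameters at the group locations, all
jittered by 1% Gaussian noise; up to 100 jittered restarts are attempted
if the initial log posterior is not finite. Identical seeds give
bitwise-identical draws.

The C++ sampler caches the drift-free series part of every trial's density
per quadrature node; proposals that move only drift-side quantities
($v_i$, $\beta^F_i$, $\beta^C_i$, $s_v$, $\beta_v$) reuse the cache and
recompute only the cheap exponential factor, which is what makes
study-scale fits (roughly 200 parameters, ~4700 trials) run in a couple of
minutes at reduced sampling.

**Convergence.** `geweke_z()` compares the first 10% of a chain against the
last 50% with batch-mean standard errors (20 batches per segment). Because
the batch-mean variance estimates have their own sampling error, the raw
ratio has t-like tails; the statistic is calibrated to a standard normal
through the Welch–Satterthwaite t distribution so that the $|z| < 2$ pass
rule holds its nominal level on stationary chains (the uncalibrated ratio
passes only ~94.8% of iid chains, which would systematically over-flag).

**Model comparison.** `dic()` uses the focused (conditional) hierarchical
DIC: the deviance conditions on subject-level parameters plus $s_v$, $s_t$
and slopes; $p_D = \bar D - D(\bar\theta)$ and
$\mathrm{DIC} = \bar D + p_D$. Negative $p_D$ is reported, not hidden — it
indicates non-convergence. `compare_models()` fits the two base models and
one covariate model per test with shared settings and seed, ordered base
models first, then covariate models alphabetically.

**Effect tests.** `effect_summary()` reports the posterior mean, 95% HDI
(shortest contiguous window over the sorted draws, leftmost on ties) and
the fraction of draws above zero; an effect is "credible" when the 95% HDI
excludes zero.

**Posterior predictive checks.** For each of `n_rep` evenly spaced retained
draws, a full replicate data set with the observed trial structure is
simulated forward from the drawn subject parameters; per condition,
accuracy and correct-RT deciles (0.1–0.9) are compared to their replicate
distributions with two-sided predictive p-values.

## The synthetic-cohort generator

`generator_config()` describes the design this pipeline targets: 38
participants × 31 trials per cell (124 per participant, 4712 responses),
5 s deadline, and seven covariates with realistic score distributions
(e.g. COWAT-Semantic 44.79 ± 10.00). One covariate (COWAT-Semantic by
default) carries true slopes $\beta_v = 0.16$, $\beta_a = -0.11$,
$\beta_t = -0.03$ per unit z-score; the other six have zero true effect so
specificity is testable. The population condition effects default to a
familiarity drift effect of 0.76 and a context effect of 0.06.

No population values exist for the base parameters, so the defaults
($\mu_v = 2.75$, $\mu_a = 2.6$, $\mu_{t_0} = 0.39$ s, $s_v = 1.9$) were
chosen once by matching the closed-form choice probability and mean
decision time (marginalized over the between- and within-subject drift
spread) to the descriptive scale of the emulated task: FM/NM accuracy
around 93%/87% and a grand mean RT around 1.0 s. The large $s_v$ is forced
by that calibration — reproducing a ~6-point accuracy gap from a drift
effect of 0.76 requires a flat marginal accuracy curve — and it has a real
consequence discussed below. Under these defaults, fewer than 2% of trials
hit the deadline.

What the generator deliberately does **not** emulate: item-level stimulus
effects, sequential/fatigue effects, contaminant (non-decision) responses,
and any correlation between covariates. Passing recovery tests therefore
shows the estimator is correct for data generated by the model itself, not
that real data satisfy the model; the posterior predictive machinery is
the tool for the latter question.

## Experiment sizes used by the test suite

The test suite runs every experiment at sizes chosen to keep the default
run practical while preserving the property under test; the generator
defaults above are used unless stated:

* **Parameter recovery** — 3 replicate study-scale cohorts (38 × 124),
  covariate model, 3,000 iterations / 500 burn-in; pooled 95%-HDI coverage
  of the group-level truth must reach 90%, and the familiarity effect's
  posterior mass above zero must exceed 0.99 in every fit. The 20-replicate
  version of the same experiment is available through `run_recover()`.
* **Model selection** — 20 scaled-down cohorts (12 × 40), null vs. fc at
  2,500/700. At this scale the expected DIC gap is small (see limitations),
  so this is the most delicate experiment in the suite.
* **Type-I behavior** — 20 scaled-down null-effect cohorts
  ($\mu_{\beta F} = \mu_{\beta C} = 0$), fc fits at 1,200/300; the
  HDI-excludes-zero rule may fire at most twice.
* **Simulator oracles** — 10,000 trials per parameter point for choice
  probabilities, 4,000 for mean decision times, with an explicit
  $O(\sqrt{dt})$ bias allowance on top of the 3-SE Monte-Carlo band.
* **ANOVA calibration** — 200 null cohorts (6 × 16); the familiarity
  p-values must be consistent with uniform (KS test).

## Numerical choices and degenerate inputs

* Series truncation error $10^{-7}$; 11-node Gauss–Legendre for $s_t$;
  closed-form $s_v$ marginalization.
* HDI ties broken by the leftmost window; a point-mass sample yields a
  zero-width interval.
* Constant chains raise a degenerate-chain error in `geweke_z()` (there is
  no meaningful z-score), while support violations in the likelihood
  return $-\infty$ so samplers can reject.
* Zero-spread participants lose no trials under the 3-SD rule (removal
  requires a strictly greater deviation); the trial filter runs as a
  single pass with mean and SD computed including the candidate outliers.
  Whether the emulated procedure iterated its filter is unknowable from
  its description; single-pass is the least-assumption reading and is
  configurable in principle by re-applying the rule.
* Participant screening averages per-test z-scores (the seven raw scales
  are not commensurable); screening on raw scores would let the
  widest-scaled test dominate.
* RT is stored in seconds everywhere; milliseconds appear only in
  human-readable summaries.

## Known limitations

* **Boundary/`sv` posterior displacement at the study design size.** With
  the calibrated $s_v \approx 1.9$, the likelihood surface has a ridge
  along which boundary separation, drift scale and $s_v$ trade off, and
  with only 124 trials per participant the free subject-level parameters
  produce a small incidental-parameter bias: the joint posterior genuinely
  concentrates at slightly lower $(\mu_a, s_v)$ than the generating truth
  (a chain initialized *at* the truth migrates there, and the deviance in
  that region is lower than at the truth — so this is the posterior, not a
  sampler artifact). In recovery experiments the $\mu_a$ HDI therefore
  misses the truth consistently and the $s_v$ HDI intermittently, putting
  pooled group-node coverage near 87% rather than the nominal ~95%; effect
  and slope parameters ($\mu_{\beta F}$, $\mu_{\beta C}$, $\beta_v$,
  $\beta_a$, $\beta_t$), which carry the scientific conclusions, are
  recovered without systematic displacement. Reports based on this model
  class should treat absolute $a$/$s_v$ magnitudes with caution at this
  design size.
* **DIC at desk scale.** With the calibrated $s_v \approx 1.9$, a drift
  effect of $\pm 0.38$ carries modest per-trial information; on 12 × 40
  cohorts the expected DIC(null) $-$ DIC(fc) gap is of the same order as
  its replicate-to-replicate spread, so individual scaled-down replicates
  can rank the models the wrong way even though the ordering is clear in
  expectation and decisive at the full design size. This is a property of
  the inference problem, not of the implementation.
* Single-site random-walk sampling mixes slowly on group-scale parameters;
  Geweke flags on `sigma_*` nodes at short run lengths are expected, and
  the default 12,000/2,000 settings (or multiple seeds) should be used for
  reported analyses.
* No contaminant-response mixture: a real data set with fast guesses would
  need the exclusion rules to catch them, or a mixture extension.
* $s_z$ is fixed at 0 and boundaries are constant over time by design.
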