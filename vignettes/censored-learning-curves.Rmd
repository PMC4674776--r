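---
title: "Censored hierarchical learning curves for water-maze latencies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Censored hierarchical learning curves for water-maze latencies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mwmbayes)
```

## The problem

Hidden-platform Morris water maze training produces trial-level escape
latencies: several animals per genotype-by-treatment group, several
training days, several trials per day, with trials that hit the cutoff
(60 s) recorded at the cutoff, i.e. right-censored. Averaging the four
daily trials and running day-wise ANOVAs discards two things the raw data
clearly contain: the within-day structure (animals typically improve
across a day's trials and partially regress overnight) and the censoring
(early in training a substantial fraction of trials time out, so daily
means are biased toward the cutoff). `mwmbayes` models the trial-level
data directly.

## Model and priors

For animal $i$ in group $g$ on day $d$, trial-of-day $t$, the latent
(uncensored) latency is

$$y^*_{idt} = x_g(d,t)^\top\beta + u_i + v_i^\top B(d) + \varepsilon_{idt},
\qquad \varepsilon_{idt}\sim N(0,\sigma^2),$$

and the recorded latency is $\min(y^*_{idt}, 60)$ with a censoring flag.

**Mean structure.** $B(d)$ is a natural cubic spline in training day with
3 degrees of freedom: boundary knots at the first and last observed day,
internal knots at evenly spaced quantiles of the observed days (for 6 days
the terciles), linear tails beyond the boundaries. Three dummies mark
trials 2–4 of each day, each with a linear-in-day drift, so within-day
profiles can change as training proceeds. By default the full 10-parameter
block (intercept, 3 spline terms, 3 dummies, 3 drifts) is estimated
independently per group; a shared-dummy variant is available via
`model_spec(group_dummies = FALSE)`. The spline covariate is training day,
not cumulative trial index: the dummies already absorb within-day
structure, so the spline only has to carry the day-level trend.

**Random effects.** Each animal contributes a random intercept and three
random spline coefficients, giving four variance components — persistent
level differences and animal-specific curve shapes. Mice enter
exchangeably and are conditionally independent given the variance
components.

**Priors.** Fixed effects: flat. The four random-effect standard
deviations: flat on $(0,\infty)$ on the s.d. scale, which implies an
inverse-gamma full conditional for each variance with shape $(M-1)/2$ and
rate $\tfrac12\sum_i \text{effect}_i^2$ ($M$ = number of animals). The
residual s.d. uses the same flat-on-s.d. form by default
(`model_spec(residual_prior = "inv_gamma")` switches to a vague
inverse-gamma). Flat s.d. priors are improper; with fewer than 3 animals
the posterior propriety of a variance component is at risk, so the sampler
refuses to run below that bound (`scenario("tiny")` exists precisely to
exercise this guard).

## Sampling

Censoring is handled by data augmentation: conditional on everything else,
the latent latency of a censored trial is normal with mean equal to its
fitted value and s.d. $\sigma$, truncated to $[60,\infty)$. With the
latent responses in place every block is conjugate, so one sweep is pure
Gibbs:

1. latent censored responses (lower-truncated normal draws; inverse-CDF
   for moderate truncation, Robert's exponential rejection beyond 6 s.d.),
2. all fixed effects jointly (Gaussian, generalized-least-squares form),
3. per-animal random-effect 4-vectors jointly (Gaussian; vectorized across
   animals on balanced cohorts),
4. the five variances (inverse-gamma),
5. an interweaving rescale of each random-effect family: substituting
   $u_{k} = \sigma_k w_k$ turns $\sigma_k$ into a regression coefficient
   with a truncated-normal full conditional. This extra step is an exact
   Gibbs update in the non-centered parameterization and leaves the
   posterior invariant; it is included because the centered updates alone
   mix the spline-s.d. components very slowly when they approach zero (the
   usual variance-component "funnel"), with effective sample sizes in the
   tens per 2,500 sweeps, which would defeat the convergence protocol
   below.

**Protocol.** Three chains from overdispersed starts (least-squares fixed
effects and residual-scale s.d. heuristics, multiplied by 0.5, 1 and 2 per
chain), 2,500 burn-in and 2,500 retained sweeps each; the combined 7,500
draws are thinned deterministically (evenly spaced retention, i.e. every
third draw of the chain-concatenated sequence is dropped) to 5,000 draws
for inference. Each chain owns a deterministic RNG stream derived from the
base seed, so serial runs are bit-reproducible. Numerical guards: sums of
squares in variance draws are floored at $10^{-12}$ to survive all-zero
states early in burn-in; non-finite states abort with the sweep index;
`sampler_config(debug = TRUE)` asserts the censoring invariant
($y^* \ge 60$ for censored rows, $y^* = y$ otherwise) after every sweep.

**Diagnostics.** The original (non-split) Gelman-Rubin statistic per
parameter (split variant behind a flag) on the retained, pre-thinning
draws, and effective sample sizes by Geyer's initial-positive-sequence
truncation of the autocorrelation sum. Convergence is declared when every
PSRF is at or below 1.1; reports also round to one decimal.

## Posterior summaries

All reported curves are population curves: fixed effects only, random
effects at zero. From the thinned draws the package computes, per group:

* the fitted latency at every (day, trial) cell with 2.5–97.5 percentile
  bands;
* the **learning rate**: drop of the fitted curve from day 1 trial 1 to
  the last day's last trial, divided by the number of intervening trials
  (23 in a 6x4 design), in s/trial. This endpoint definition is the
  simplest one consistent with the unit "s per trial"; a regression-slope
  definition would weight interior cells and was deliberately not layered
  on top;
* **within-day improvement**: trial-4 minus trial-1 fitted value at a
  given day (equals the trial-4 dummy plus its drift times day);
* **inter-day setbacks**: the overnight rise from a day's last trial to
  the next day's first trial, averaged over the transitions in a chosen
  window (the "last 3 days" window means the two final transitions);
* **contrasts** of any two matched draw vectors, with
  $P = 2\min(\Pr(\Delta>0), \Pr(\Delta<0))$, the credible-interval
  inversion rule: $P < 0.05$ exactly when the 95% equal-tailed interval
  excludes zero. An empty tail reports the floor $2/N$.

## The synthetic cohort generator

No public trial-level MWM dataset accompanies this model, so the package
generates its own cohorts with known ground truth
(`true_parameters()` / `simulate_cohort()`). Group mean curves are
parameterized as a start latency with a constant per-trial improvement
(linear in cumulative trial index — exactly representable by the spline
plus constant dummies, so generator truths live inside the model family),
optionally with explicit trial offsets and drifts to inject within-day
structure or setbacks. Animals receive Gaussian random intercepts and
spline deviations, trials receive Gaussian noise, and latents at or above
60 s are recorded as censored at 60.

Default scales — residual 10 s, intercept 5 s, spline terms 2 s each —
are package choices producing realistic early-training censoring
(roughly 5–10% of records when starting at 45 s), not published
estimates. The packaged scenarios are `"fig4b-like"` (4 groups x 20 mice,
6 days x 4 trials, start 45 s, per-trial improvements 1.6, 0.9, 1.6 and
0.4 s/trial), `"null"` (all groups share one curve; used for P-value
calibration) and `"tiny"` (below the propriety guard; oracle math only).

**Known mismatch.** The Gaussian model has unbounded support, but a
latency must be positive, so simulated latents are clamped below at 0.1 s.
For steep curves whose late-training means approach zero (the 1.6 s/trial
groups end near 8 s with 10 s residual noise) this clamps a noticeable
fraction of late trials upward, flattening the tail of the realized curve
by roughly 0.05 s/trial relative to the nominal truth. Real escape
latencies have a physiological floor the model likewise ignores; passing
recovery tests on these cohorts therefore demonstrates correctness of the
inference machinery under the model's own assumptions, not robustness to
floor effects in real data.

## Problem sizes and calibration checks

The test suite verifies the sampler blocks against independent oracles
(grid-integration posteriors for the censored intercept model and the
flat-on-s.d. variance conditional, closed-form truncated-normal moments,
hand-evaluated PSRF on 4-point fixtures, AR(1) effective sample sizes),
and the pipeline end to end: the full three-chain protocol converges with
all Gelman-Rubin statistics rounding to 1.0 on the `fig4b-like` cohort;
null-scenario genotype contrasts give approximately uniform P values over
50 replicate cohorts (6 mice/group, shortened chains); and 95% credible
intervals for the learning rate cover the generating truth at a rate
compatible with 0.95 over 20 replicate one-group fits. Replicated
calibration runs use 6–10 mice per group and a few hundred sweeps per
chain — enough for these well-mixing reduced problems, as their own
diagnostics confirm — while single-fit checks use the full protocol.

Single-cohort recovery of a learning rate at one-decimal precision is
intrinsically noisy at 20 mice: the across-cohort standard deviation of
the posterior mean rate is about 0.12 s/trial under the default noise
scales, so the recovered rate rounds to the generating value in only
roughly a third to a half of cohorts even though the estimator is
unbiased. Averaging over replicate cohorts, not sharpening a single one,
is the appropriate way to verify unbiasedness.

## Limitations

* Population curves only; per-animal fitted curves can be reconstructed
  from stored random-effect draws (`sampler_config(store_ranef = TRUE)`)
  but no helper is provided.
* No probe-trial, swim-path, speed or strategy modelling; no covariates
  beyond group, day and trial-of-day.
* Variance components are shared across groups (a single joint model);
  per-group variances are not offered.
* No model comparison machinery (WAIC, Bayes factors) and no alternative
  samplers; the Gibbs scheme with interweaving is fast and mixes well for
  this model class, but models outside it require other tools.
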