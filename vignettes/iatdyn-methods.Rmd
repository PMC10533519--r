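---
title: "Modeling within-session dynamics of IAT response times"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling within-session dynamics of IAT response times}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iatdyn)
```

## The problem

The Implicit Association Test (IAT) summarizes a participant's
response-time difference between "compatible" and "incompatible"
stimulus pairings as a single aggregate score (the D-score). That
aggregation assumes response-time distributions are stationary within
the task. In practice RTs fall steeply across a block — through
learning, habituation, or self-regulation — and two participants with
identical aggregate scores can have very different trajectories: one
may start heavily biased and suppress the difference within a few
dozen trials, another may start mildly biased and stay there. `iatdyn`
implements a trial-level model that separates these possibilities, the
conventional scoring it generalizes, and the downstream analyses that
link trajectory components to external behavior.

## The model

Response times are ex-Gaussian: `RT = N(mu, sigma^2) + Exp(tau)`.
The Gaussian component absorbs additive sensorimotor noise and is
constant over trials (its mean may carry a stimulus-class contrast,
word vs. face); the exponential component `tau` carries the
decision-related mass, so effects placed on `tau` move mean and
variance together — matching the ubiquitous observation that RT
variance scales with the mean.

`tau` evolves across the trials `t = 1, 2, ...` of a run as a
saturating exponential with three parameters,

    tau(t) = asym + (start - asym) * 2^(-(t - 1) / rate),

so `tau(1) = start` exactly, `tau(t) -> asym` monotonically, and
`rate` is a *time constant in trials*: at `t = 1 + rate` exactly half
of the start-to-asymptote change is complete. Smaller rates mean
faster change. The base-2 form with the `(t - 1)` offset is the only
parameterization in which both anchoring properties hold literally;
a base-e form with a rescaled constant is observationally equivalent,
and we fix base 2 so the reported rate is directly interpretable as
"trials to 50% of change".

All four targets (`start`, `rate`, `asym`, and the Gaussian mean) get
log-link linear predictors. Fixed terms cover the incompatibility
contrast, run position, a zero-centered IAT-type code, stimulus
class, centered gender/age covariates, and treatment-coded learning
conditions; random deviations are allowed per participant (and per
experiment batch) for any subset of a target's fixed terms. The three
resulting participant-level indices have tentative interpretations:
the starting difference as *initial bias*, the rate as
*self-regulation speed*, and the asymptotic difference as *persistent
bias*.

## Estimation

The default backend (`method = "map"`) is penalized maximum
likelihood with a Laplace approximation of the random-effect
integrals, in two stages:

1. *Joint seed.* All parameters — fixed effects, random effects, and
   the log Gaussian SD — are optimized jointly by `nlminb` with a
   fully analytic gradient (chain rule through the trajectory and the
   log links; the pointwise kernel is compiled). Fixed-effect
   coefficients carry mild Gaussian shrinkage (SD 1.5 on log-scale
   effects, SD 10 on intercepts).
2. *Marginal refinement.* Joint ("profile") estimation is biased for
   weakly identified targets — above all the rate, whose trade-off
   with the asymptote creates a likelihood ridge — so the fixed
   effects and the random-effect SDs are then re-optimized on the
   Laplace *marginal* likelihood: the random effects are profiled out
   by an inner Newton solver built on exact analytic per-participant
   curvature blocks, and the objective carries the log-determinant
   correction of those blocks. The outer problem is low-dimensional,
   so a damped saddle-free Newton iteration with finite-difference
   gradients converges in a few dozen steps. Because the
   per-participant inner problems can be multimodal on the
   rate–asymptote ridge, participants whose curvature block turns
   near-singular are restarted from zero and the better mode is kept
   (the inner objective separates by participant, so modes may be
   mixed).

Intervals are Wald intervals from the curvature of the marginal
objective at the optimum. When the profiled optimum sits on an inner
mode boundary — where marginal curvature is ill-defined and its
variances collapse — the standard errors fall back to the fixed-effect
block of the inverse joint-objective Hessian at its own optimum, which
is positive definite by construction. Estimation is deterministic: the
same data give bit-identical results. Setting
`control = list(marginal = FALSE)` keeps the faster joint estimator
(with an empirical-Bayes update of the shrinkage SDs), which is
adequate for cross-validated model comparison where only held-out
log-likelihoods matter.

An optional MCMC backend (adaptive random-walk Metropolis started at
the penalized optimum, with the Laplace covariance as proposal shape)
is provided for interval checks on small models; split R-hat below
1.05 is accepted and values above 1.01 are flagged. It is not meant
for the full hierarchical models, whose posterior dimension makes
random-walk sampling inefficient.

### Numerical choices

The ex-Gaussian log-density is evaluated by two routes with a
crossover at `z = (x - mu)/sigma - sigma/tau = 0`: the direct
log-Gaussian-CDF form for `z >= 0`, and a scaled-complementary-error-
function form for `z < 0` where the direct form cancels
catastrophically. `erfcx` itself switches to its asymptotic series
above argument 25, where the library routine overflows. The density
is finite for all finite inputs, including near-Gaussian regimes
(`tau` a thousandth of `sigma`).

Parameters are box-bounded at ±30 on the log scale (a no-op for any
plausible optimum), random-effect SDs are floored at 1e-3, and the
K-fold assignment used for model comparison is deterministic
(round-robin within participant), so comparing a fit with itself
yields a difference of exactly zero.

## Model comparison

The static null has the identical parameterization except that `tau`
is constant over trials (the level keeps the union of the start/asym
terms; rate terms are structurally forbidden). Fits are compared on
approximate leave-one-out deviance: Pareto-smoothed importance
sampling over posterior draws for MCMC fits, and a 10-fold
cross-validated deviance for the default backend, with folds
stratified by participant so every refit retains all random effects.
The difference is reported as `LOOIC_diff = -2 * elpd_diff` (negative
favors the time-varying model) and is flagged *reliable* when its
absolute value exceeds 4 and is at least 2 standard errors — the
"several standard errors" multiplier is configurable because no single
value is canonical.

## Scoring and filters

The improved D-score computes one standardized difference from the
20-trial block pair and one from the 40-trial pair, then averages
them; with the standard 20/40 lengths this weights each early trial
twice as heavily as each later trial (`effective_trial_weights`).
Incorrect trials are excluded rather than replaced with penalty
latencies — matching the filtering dialect the rest of the package
assumes; the error-penalty variant is out of scope. Trial filters
(window 320–2000 ms), participant screens (80% accuracy, at most 9
responses outside the window), and block-level screens (70% accuracy,
1.5 s mean RT) ship as presets. The lower cutoff can also be
determined empirically: RTs are pooled across participants into 10-ms
bins and the cutoff is the lower edge of the first bin whose accuracy
beats chance by a one-sided binomial test at alpha 0.05 (pooling
across participants is an assumption; a per-participant variant would
need far more trials per bin).

## Robust linkage models

Participant indices are z-scored and entered into bootstrapped robust
regressions against behavioral measures (a "seeming racist" rating,
seating distance), with interviewer race and motivation scales
(IMS/EMS) as moderators. Before that, multivariate outliers are
removed by robust Mahalanobis distances from a minimum-covariance-
determinant estimate using at least 80% of cases, cut at the
chi-square 99th percentile. Regressions are Huber M-estimates (tuning
constant 1.345, 95% Gaussian efficiency) refit on 5,000 case
resamples; coefficients are summarized by percentile 2.5/97.5%
intervals and a term is *reliable* when 0 lies outside its interval.
Percentile rather than bias-corrected intervals are used — the simpler
convention, adequate at these sample sizes.

## The synthetic-data generator

`simulate_iat()` emulates the standard 7-block session: two
dual-stimulus runs of 60 trials (20-trial then 40-trial block),
counterbalanced condition order, ex-Gaussian RTs whose `tau` follows
the trajectory above, random per-trial stimulus class, and a logistic
accuracy model with a chance floor below 300 ms (present only so the
empirical-cutoff and accuracy filters can be exercised). Defaults are
anchored at realistic group-level magnitudes for an online race IAT:
Gaussian mean `exp(6.161) ≈ 473` ms, starting tau `exp(5.878) ≈ 357`
ms, asymptotic tau `exp(5.112) ≈ 166` ms, rate `exp(2.451) ≈ 11.6`
trials, with log-scale incompatibility effects 0.374 / 0.342 / 0.658
on start / asymptote / rate. Between-participant SDs (0.12–0.45 on
the log scale) and the carry-over shift on the second run's asymptote
(−0.1) are chosen once as plausible for such samples; the carry-over
is placed on the asymptote because that is where order effects
manifest in session-level data. External measures are generated from
stated linear links between z-scored true indices, IMS/EMS, and
interviewer race.

What the generator does *not* emulate: stimulus-level content and
item effects, response conflict processes, post-error slowing,
session-to-session variation, and non-exponential trajectory shapes.
Passing recovery tests therefore shows the estimator is correct when
the model family is right — not that real IAT data follow this family.

## Validation sizes

The test suite validates the pipeline at sizes chosen to keep a full
run in minutes: parameter-recovery coverage uses 20 replicates of 60
participants × 120 trials; model selection uses 20 time-varying and
20 static replicates of 10 participants × 120 trials; oracle checks
(numerical convolution for the density, exhaustive enumeration for
the signed-rank statistic and the MCD subset, hand-computed D-scores,
the OLS limit of the Huber fit) run at small n where exact answers
are available.

## Known limitations

* The default backend maximizes the joint penalized likelihood rather
  than the marginal likelihood; for weakly identified targets (the
  rate, above all) this can shift population-level estimates by a
  fraction of a standard error relative to full marginalization, and
  interval coverage for those terms is slightly conservative or
  anticonservative depending on heterogeneity. The MCMC backend
  avoids this at small scales.
* A single Gaussian SD is shared across trials and conditions by
  design; data with strongly condition-dependent additive noise will
  fold that misfit into `tau`.
* The two-IAT model assumes both tasks share one Gaussian mean
  structure per participant.
* Robust-regression reliability flags are percentile-bootstrap
  decisions; they inherit the usual caveats near the interval
  boundary.
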