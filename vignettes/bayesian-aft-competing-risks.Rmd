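---
title: "Bayesian AFT modelling of competing mortality causes with baftcr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian AFT modelling of competing mortality causes with baftcr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(baftcr)
```

## The modelling problem

Registry cohorts of heart-failure (HF) patients observe, for each subject,
a follow-up time in months since diagnosis and one of three outcomes:
death from HF-related causes, death from non-HF-related causes, or
censoring (administrative closeout or loss to follow-up). The two death
causes compete: only the first one is observed. `baftcr` analyses such
data with *cause-specific* parametric accelerated failure time (AFT)
models: one Bayesian regression per cause, in which deaths from the
competing cause are treated as censored. This is the cause-specific
analogue of cause-specific hazards modelling, and identifies the same
estimands as the classical latent-failure-time construction the
synthetic-data generator uses.

AFT models are attractive here because their coefficients act
multiplicatively on *time*: the reporting scale is the time ratio (TR),
the factor by which one unit of a covariate stretches (TR > 1) or
shrinks (TR < 1) survival time. Clinically, "chest pain at presentation
has TR 0.4 for HF-related death" reads directly as "survival time is 60%
shorter".

## Likelihood

For subjects $i = 1, \dots, N$ with time $t_i$ and cause-specific
indicator $d_i$ (1 = death from the modelled cause, 0 = censored or
competing death), the right-censored likelihood is

$$L(\beta \mid X, t) = \prod_{i=1}^N f(t_i)^{d_i}\, S(t_i)^{1 - d_i}.$$

Three families are supported, all with rate
$\lambda_i = \exp(x_i'\beta)$ unless noted:

* **Weibull**: $f(t) = \lambda p t^{p-1} e^{-\lambda t^p}$,
  $S(t) = e^{-\lambda t^p}$, shape $p > 0$. Monotone hazard;
  $p = 1$ is the exponential model.
* **Log-logistic**: $S(t) = 1/(1 + \lambda t^p)$,
  $f(t) = \lambda p t^{p-1} / (1 + \lambda t^p)^2$. Unimodal hazard for
  $p > 1$.
* **Log-normal**: $\log t_i \sim N(\mu_i = x_i'\beta,\ \delta)$,
  $S(t) = 1 - \Phi\!\big((\ln t - \mu)/\sqrt\delta\big)$.

On this parameterisation a coefficient converts to a time ratio as
$TR_j = \exp(-\beta_j / p)$ for the Weibull and log-logistic families and
$TR_j = \exp(\beta_j)$ for the log-normal (whose location is already on
the log-time scale). The conversion is applied *per posterior draw*,
using that draw's ancillary parameter — never by refitting.

All density and survival evaluations run in log space (`log1p`-style
guards on the log-logistic denominator) so that large $\lambda t^p$
cannot overflow; the test suite verifies by adaptive quadrature that every
family integrates to 1 and by central differences that $-S'(t) = f(t)$
across a parameter grid.

## Prior and posterior

Coefficients carry independent $N(0, \sigma_0^2)$ priors, with
$\sigma_0^2 = 10{,}000$ by default — effectively non-informative on the
linear-predictor scale — and the same prior is placed on the *log* of the
ancillary parameter. The posterior is the (unnormalised) product of this
prior and the censored likelihood. Because the prior variance is itself a
modelling choice, the pipeline includes a sensitivity layer that refits
over the grid $\{1, 10, 100, 1000, 10{,}000\}$ and flags covariates whose
posterior-median TR moves by more than 10% relative to the
reference-variance column. The flag compares point estimates; intervals
are reported alongside but do not enter the rule.

## Sampling

Posterior draws come from an adaptive random-walk Metropolis sampler with
a joint Gaussian proposal on $(\beta, \log p)$ (or $(\beta, \log\delta)$):

* **Initialisation** at the numerical MLE (BFGS on the censored
  log-likelihood; zeros as fallback), with the inverse Hessian as the
  initial proposal covariance.
* **Adaptation during burn-in only**: the proposal covariance tracks the
  running empirical covariance of the chain (updated every 50
  iterations) and a global scale is tuned by a Robbins–Monro rule toward
  the 0.234 acceptance target. Both are frozen when burn-in ends, so
  retained draws come from a fixed Markov kernel.
* **Defaults**: 2 chains of 20,000 iterations with 10,000 burn-in and no
  thinning. These are package defaults chosen so a single registry-scale
  fit mixes well; the validation suite uses shorter chains (typically
  1–2 chains of 1,500–8,000 iterations) because the fixtures are small
  and the checks have explicit Monte-Carlo allowances.
* **Reproducibility**: every chain's RNG stream derives deterministically
  from one integer seed; the same seed and configuration give
  bit-identical draws. Study pipelines expand one master seed into
  per-cause, per-stage substreams, which makes each cause's results
  independent of whether the other branch runs.
* **Diagnostics**: split-$\hat R$ per parameter (warning above 1.1, never
  an error) and per-chain post-burn-in acceptance rates.

Point estimates are posterior medians on the TR scale with equal-tailed
2.5–97.5% credible intervals; an effect is flagged "significant" when the
95% interval excludes 1. This is a reporting convention in the spirit of
a two-sided 0.05 level, not a frequentist test.

## Model comparison

`compare_families()` fits the candidate families to the same
cause-specific view and reports three criteria from the shared
pointwise log-likelihood matrix $\ell_{si}$ (draw $s$, subject $i$):

* **DIC** $= \bar D + p_D$ with $p_D = \bar D - D(\bar\theta)$, where
  $\bar\theta$ is the posterior mean taken on the sampling scale
  $(\beta, \log p)$ and back-transformed — this keeps $p_D$ invariant to
  the positivity reparameterisation. Negative $p_D$ attaches a warning.
* **WAIC** $= -2(\mathrm{lppd} - p_{\mathrm{WAIC}})$ with the variance
  form of the penalty, computed by log-sum-exp.
* **LPML** $= \sum_i \log \mathrm{CPO}_i$ with the harmonic-mean CPO
  estimator, chosen because it needs only $\ell_{si}$; a brute-force
  leave-one-out refit oracle in the test suite bounds its error on a
  20-subject fixture.

Ranking uses DIC alone; WAIC and LPML are reported alongside. The three
criteria can genuinely disagree, which is why a single declared ranking
rule matters. Ties resolve to the first family in the candidate order and
are flagged.

## The study pipeline

`run_study()` chains the stages the way registry analyses are reported:

1. **Family selection** by DIC with the full covariate set. By default
   the comparison runs once (on the first configured cause) and the
   selected family is applied to both causes, mirroring analyses that
   publish a single comparison table; `family_scope = "per_cause"`
   selects independently per cause.
2. **Univariable screening**: one single-covariate fit per declared
   covariate (multi-level covariates enter as their whole dummy or trend
   block); a covariate passes when any of its TR intervals excludes 1.
3. **Multivariable model** of the screened-in covariates, per cause.
   Covariates not selected for a cause appear as "NC" in the written
   report, so the two causes' tables stay aligned.
4. **Sensitivity analysis** over the prior-variance grid, as above.

Covariate coding is declared per cohort: binary (0/1), ordinal trend
(integer scores 0, 1, 2, …), categorical with a reference level
(indicator columns), or continuous. Age is continuous by default; an
ordinal banded coding is available and yields the same per-unit TR
interpretation. Records with missing covariate values are excluded at
load (with a count), never imputed.

## Descriptive layer

* **Person-time rates**: cause-specific failures per 1000 person-months
  with exact Poisson (gamma/chi-square quantile) 95% limits. Months are
  the native time unit throughout.
* **Kaplan–Meier**: product-limit estimate with Greenwood variance;
  deaths precede censorings at ties; competing-cause deaths are censored,
  so curves are cause-specific quantities (not complements of a
  cumulative incidence — Aalen–Johansen estimation is deliberately out of
  scope). Intervals are on the plain probability scale, truncated to
  [0, 1], with a log-log option.
* **Log-rank**: the standard observed-minus-expected chi-square with
  hypergeometric covariance, plus a 1-df trend variant with integer
  scores for ordinal covariates. The implementation is cross-checked in
  tests against `survival::survdiff` and against a permutation null.

## The synthetic cohort generator

Because registry data of this kind are not publicly deposited, validation
rests on a seeded generator with known truth. It draws covariates from
declared marginals, then one latent time per cause from that cause's AFT
family at $\lambda = \exp(x'\beta_{\text{cause}})$, and observes the
minimum of the latent times, an optional exponential dropout time, and an
administrative horizon (default 64 months, a five-year
enrolment-to-closeout span).

The registry preset (`rashf_config()`) emulates an acute systolic HF
registry: n = 435; covariate marginals matching the published baseline
table (61.1% male, 88.3% chest pain, 23% hyperlipidemia, heart-rate bands
11/63.6/25.2%, age mean 56.57 years truncated to 14–95 with SD 13 —
the SD is our choice, consistent with the published range); and
exponential cause rates solved analytically so that, marginally, ~36.8%
die of HF, ~22.3% of other causes, ~24.6% remain alive at closeout and
the remainder drop out. Mild true effects (chest pain TR 0.7, age TR
0.995/year) give the screening stage signal to find.

What the generator does *not* emulate: dependence between latent cause
times (no copulas), covariate interactions, non-proportional time
effects, measurement error, or informative censoring. Passing recovery
tests therefore demonstrates correctness of the inference machinery under
the model's own assumptions — not robustness to their violation in real
registries.

## Numerical and design choices

* The log-normal density/survival pair is the standard form with variance
  $\delta$; the log-logistic density carries the squared denominator
  required for $f = -S'$.
* Degenerate designs (collinear columns) are rejected at view
  construction with the offending columns named; a cause with zero events
  is an error, since its likelihood is degenerate.
* The shrinkage-monotonicity validation (posterior-median $|\beta|$
  non-increasing as the prior variance falls through the grid) is a
  statement about exact posteriors; its test compares MCMC medians and
  therefore allows a batch-means Monte-Carlo-error margin (3 combined
  MCSEs) between adjacent grid points, while requiring the
  strongest-shrinkage column to sit strictly below the diffuse one.
* Validation problem sizes: n = 800 cohorts for recovery and flat-prior
  agreement (posterior-median gap to the independent `survreg` MLE below
  0.05 per coordinate), n = 400 for family selection across 10 seeded
  replicates per truth, n = 20 for brute-force leave-one-out oracles,
  and 20 replicates for interval-coverage checks. These sizes were chosen
  so each check's Monte-Carlo error is small against its tolerance.
* Written reports render TRs and intervals to 2 decimals; all
  computations and returned objects keep full precision.

## Known limitations

* The harmonic-mean CPO estimator can be unstable when single
  observations are highly influential; the LOO oracle bounds this on
  test fixtures, but for publication-grade LPML on real data a
  Pareto-smoothed estimator would be preferable.
* Random-walk Metropolis mixes slowly for strongly correlated posteriors
  with many covariates; the covariance adaptation mitigates this, but
  very wide designs would warrant a gradient-based sampler, which is out
  of scope.
* Cause-specific KM curves answer "what if the competing cause were
  removed" style questions only under independence assumptions; marginal
  cumulative-incidence estimation is intentionally not provided.
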