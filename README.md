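# baftcr — Bayesian AFT models for competing mortality causes

`baftcr` is an R package for cause-specific **Bayesian accelerated
failure time (AFT)** analysis of right-censored survival data with
**competing event causes**, built for registry studies of heart-failure
(HF) mortality where deaths split into HF-related and non-HF-related
causes. It is aimed at biostatisticians and epidemiologists who want the
full study workflow — descriptive rates, model selection, screening,
multivariable modelling and prior sensitivity — as reproducible, seeded
code.

## The model

For each cause, subjects contribute a right-censored likelihood (deaths
from the competing cause count as censored):

    L(β | X, t) = ∏ᵢ f(tᵢ)^dᵢ · S(tᵢ)^(1−dᵢ)

with three AFT families in the rate parameterisation
λᵢ = exp(xᵢ'β):

| family       | S(t)                         | ancillary        |
|--------------|------------------------------|------------------|
| Weibull      | exp(−λtᵖ)                    | shape p          |
| log-logistic | 1 / (1 + λtᵖ)                | shape p          |
| log-normal   | 1 − Φ((ln t − μ)/√δ), μ = x'β | variance δ      |

Coefficients carry diffuse N(0, 10000) priors (and the same on the log
ancillary parameter); posteriors are sampled by an adaptive random-walk
Metropolis sampler that is bit-reproducible given a seed. Effects are
reported as **time ratios** — TR = exp(−βⱼ/p) (Weibull/log-logistic) or
exp(βⱼ) (log-normal), computed per posterior draw — with equal-tailed 95%
credible intervals; TR < 1 means shorter survival. Candidate families are
compared by DIC (with WAIC and LPML reported alongside), and a
prior-variance sensitivity layer refits over {1, 10, 100, 1000, 10000}
and flags covariates whose TR moves by more than 10%.

The package also ships a descriptive layer (person-time mortality rates
per 1000 person-months with exact Poisson intervals, Kaplan–Meier curves
with Greenwood variance, log-rank and trend tests) and a seeded synthetic
generator of registry-like cohorts with known cause-specific AFT
structure, which powers the validation suite.

## Worked example

Fit a cause-specific Weibull AFT model to a synthetic cohort whose true
time ratios are known (x1 = 0.5, x2 = 0.7, x3 = 1.0):

```r
library(baftcr)

fx  <- standard_fixtures(seed = 1)
v   <- cause_specific_view(fx$weibull_truth_n800$cohort, "hf")
fit <- baft(v, family = "weibull",
            control = mcmc_control(n_chains = 2, n_iter = 4000,
                                   n_burnin = 2000, seed = 1))
summary(fit)
#> Bayesian weibull AFT model (cause-specific: hf)
#>   800 subjects, 587 events | ancillary median 1.334 | max R-hat 1.015
#>   Time ratios (posterior median, 95% credible interval):
#>     x1                            0.49 (0.43-0.55) *
#>     x2                            0.70 (0.63-0.79) *
#>     x3                            1.11 (0.97-1.25)
```

The posterior medians recover the generating ratios: x1 halves survival
time (TR 0.49, interval excluding 1, starred as significant), x2
shortens it by 30%, and the null covariate x3 straddles 1. The ancillary
median 1.334 is the Weibull shape (truth 1.3); R-hat near 1 indicates
the chains agree.

```r
compare_families(v, control = mcmc_control(n_chains = 1, n_iter = 2500,
                                           n_burnin = 1000, seed = 2))
#> AFT family comparison (lower DIC/WAIC better, higher LPML better)
#>       family     waic      lpml      dic
#>      weibull 5598.281 -2799.137 5598.321
#>  loglogistic 5649.555 -2824.773 5649.428
#>    lognormal 5710.074 -2855.032 5708.773
#> Selected by DIC: weibull
```

DIC correctly prefers the generating Weibull family. The full study
pipeline — family selection, univariable screening, multivariable fit and
prior sensitivity for both causes — runs as
`run_study(cohort, study_config(seed = 1))`, and
`describe_cohort(cohort)` produces the person-time rate / Kaplan–Meier /
log-rank report. A registry-like cohort with the published baseline
margins is one call away: `simulate_cohort(rashf_config(seed = 1))`.

A thin command-line front end (`inst/cli/baftcr.R`) exposes
`simulate`, `describe` and `run-study` subcommands over the same
functions.

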