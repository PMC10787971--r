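test_that("prior and posterior densities follow their closed forms", {
  pr <- prior_spec(10000)
  # single coefficient at the prior mean
  expect_equal(log_prior(0, NULL, pr), -0.5 * log(2 * pi * 10000))
  # symmetry
  expect_equal(log_prior(c(3, -2), 0.5, pr), log_prior(c(-3, 2), -0.5, pr))
  # variance 1 vs 10000 at beta = 3: analytic normal log-density difference
  expect_equal(log_prior(3, NULL, prior_spec(1)) -
                 log_prior(3, NULL, pr),
               stats::dnorm(3, 0, 1, log = TRUE) -
                 stats::dnorm(3, 0, 100, log = TRUE))

  v <- cause_specific_view(small_gen$cohort, "hf")
  beta <- c(-3, 0.4, -0.2)
  # posterior = likelihood + prior, checked as a hand sum
  expect_equal(
    log_posterior("weibull", beta, 1.2, v, pr),
    censored_loglik("weibull", beta, 1.2, v$design, v$times, v$d) +
      log_prior(beta, log(1.2), pr))
  # with an essentially flat prior, posterior - likelihood is constant in beta
  flat <- prior_spec(1e12)
  offs <- vapply(seq(-1, 1, by = 0.5), function(b) {
    bb <- c(-3, b, -0.2)
    log_posterior("weibull", bb, 1.2, v, flat) -
      censored_loglik("weibull", bb, 1.2, v$design, v$times, v$d)
  }, numeric(1))
  expect_lt(diff(range(offs)), 1e-6)
  # shrinkage direction: tighter prior penalises large coefficients more
  big <- c(-5, 5, -5)
  expect_gt(log_posterior("weibull", big, 1.2, v, prior_spec(10000)),
            log_posterior("weibull", big, 1.2, v, prior_spec(1)))
})

test_that("the sampler is deterministic given a seed and mixes adequately", {
  v <- cause_specific_view(small_gen$cohort, "hf")
  d1 <- run_mcmc(v, "weibull", control = ctl_short)
  d2 <- run_mcmc(v, "weibull", control = ctl_short)
  expect_identical(d1$draws, d2$draws)
  d3 <- run_mcmc(v, "weibull",
                 control = mcmc_control(n_chains = 1, n_iter = 1500,
                                        n_burnin = 700, seed = 2))
  expect_false(identical(d1$draws, d3$draws))
  expect_equal(nrow(d1$draws), 800)  # (n_iter - n_burnin) / thin
  # post-adaptation acceptance in the tuned band
  d4 <- run_mcmc(v, "weibull", control = ctl_mid)
  expect_true(all(d4$acceptance_rate >= 0.15 & d4$acceptance_rate <= 0.5))
})

test_that("intercept-only exponential model matches the conjugate posterior", {
  # With shape fixed at 1 and a flat prior on beta0, the implied posterior
  # of lambda is Gamma(sum d, sum t): an independent closed form.
  df <- small_gen$cohort
  ch <- cohort(as.data.frame(df)[, c("id", "time_months", "event")], list())
  v <- cause_specific_view(ch, "hf")
  dr <- run_mcmc(v, "weibull", prior = prior_spec(1e12),
                 control = mcmc_control(n_chains = 2, n_iter = 6000,
                                        n_burnin = 2000, seed = 5),
                 fix_ancillary = 1)
  lam <- exp(dr$draws[, "(Intercept)"])
  a <- sum(v$d)
  b <- sum(v$times)
  # Monte-Carlo error bound: a few standard errors at a conservative ESS
  expect_lt(abs(mean(lam) - a / b), 5 * sqrt(a) / b / sqrt(200))
  expect_lt(abs(stats::var(lam) - a / b^2), 0.4 * a / b^2)
})

test_that("posterior summaries report time ratios with credible intervals", {
  v <- cause_specific_view(small_gen$cohort, "hf")
  fit <- baft(v, family = "weibull", control = ctl_mid)
  s <- summary(fit)
  expect_equal(s$time_ratios$term, c("x1", "z"))
  expect_true(all(s$time_ratios$ci_low <= s$time_ratios$tr))
  expect_true(all(s$time_ratios$tr <= s$time_ratios$ci_high))
  expect_equal(s$time_ratios$significant,
               s$time_ratios$ci_low > 1 | s$time_ratios$ci_high < 1)
  # the generating TR 0.5 on x1 is detected
  expect_true(s$time_ratios$significant[s$time_ratios$term == "x1"])
  expect_lt(s$time_ratios$tr[1], 1)

  # degenerate draws: all-zero coefficients give TR exactly 1
  fit0 <- fit
  fit0$draws <- matrix(0, 50, ncol(fit$draws),
                       dimnames = dimnames(fit$draws))
  s0 <- summary(fit0)
  expect_equal(s0$time_ratios$tr, c(1, 1))
  expect_equal(s0$time_ratios$ci_low, c(1, 1))
  expect_false(any(s0$time_ratios$significant))
})

test_that("the significance flag is the interval-excludes-1 rule", {
  v <- cause_specific_view(small_gen$cohort, "hf")
  fit <- baft(v, family = "weibull", control = ctl_short)
  fab <- fit
  set.seed(9)
  n_d <- nrow(fit$draws)
  # fabricate coefficient draws whose TR interval clearly excludes 1
  # (protective, like a 0.10-0.96 interval) and one that straddles 1
  fab$draws[, "x1"] <- -log(exp(stats::rnorm(n_d, log(0.4), 0.25)))
  fab$draws[, "z"] <- -log(exp(stats::rnorm(n_d, log(0.95), 0.25)))
  fab$draws[, "log_shape"] <- 0
  s <- summary(fab)
  expect_true(s$time_ratios$significant[s$time_ratios$term == "x1"])
  expect_false(s$time_ratios$significant[s$time_ratios$term == "z"])
})

test_that("chain-merge order does not change summaries", {
  v <- cause_specific_view(small_gen$cohort, "hf")
  fit <- baft(v, family = "weibull", control = ctl_mid)
  fit_swapped <- fit
  ch <- fit$draws_obj$chain_id
  fit_swapped$draws <- rbind(fit$draws[ch == 2, ], fit$draws[ch == 1, ])
  expect_equal(summary(fit_swapped)$time_ratios, summary(fit)$time_ratios)
})

test_that("model methods are coherent", {
  v <- cause_specific_view(small_gen$cohort, "hf")
  fit <- baft(v, family = "weibull", control = ctl_mid)
  cf <- coef(fit)
  expect_named(cf, c("(Intercept)", "x1", "z", "shape"))
  expect_gt(cf[["shape"]], 0)
  expect_s3_class(logLik(fit), "logLik")

  # survival predictions are proper curves
  S <- predict(fit, newdata = matrix(c(1, 0, 0), 1), times = c(1, 10, 30))
  expect_true(all(diff(drop(S)) < 0))
  expect_true(all(S > 0 & S < 1))
  # a protective covariate (TR 0.5 coded on x1) shortens median survival
  med <- predict(fit, newdata = rbind(c(1, 0, 0), c(1, 1, 0)),
                 type = "median")
  expect_lt(med[2], med[1])
  expect_equal(med[2] / med[1],
               summary(fit)$time_ratios$tr[1], tolerance = 0.05)

  # Cox-Snell residuals of a correct model look unit-exponential
  r <- residuals(fit)
  expect_length(r, 120)
  expect_true(all(r > 0))

  sim <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sim), c(120, 3))
  expect_true(all(sim > 0))
})

test_that("formula interface mirrors the view interface", {
  df <- as.data.frame(small_gen$cohort)
  df$d_hf <- as.numeric(df$event == "hf_death")
  df$x1n <- as.numeric(df$x1 == "yes")
  fit_f <- baft(survival::Surv(time_months, d_hf) ~ x1n + z, data = df,
                family = "weibull", control = ctl_mid)
  fit_v <- baft(cause_specific_view(small_gen$cohort, "hf"),
                family = "weibull", control = ctl_mid)
  # identical design matrices and seeds -> identical draws
  expect_equal(unname(fit_f$draws), unname(fit_v$draws))
})
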