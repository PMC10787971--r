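fit_small <- baft(cause_specific_view(small_gen$cohort, "hf"),
                  family = "weibull", control = ctl_mid)

test_that("pointwise log-likelihood matrix is consistent with the total", {
  pw <- pointwise_loglik(fit_small)
  expect_equal(dim(pw), c(nrow(fit_small$draws), 120))
  # row sums equal the censored log-likelihood at each draw
  v <- fit_small$view
  for (s in c(1, 17, nrow(pw))) {
    beta <- fit_small$draws[s, 1:3]
    anc <- exp(fit_small$draws[s, 4])
    expect_equal(sum(pw[s, ]),
                 censored_loglik("weibull", beta, anc, v$design, v$times,
                                 v$d),
                 tolerance = 1e-10)
  }
})

test_that("degenerate posteriors give the zero-spread identities", {
  fit0 <- fit_small
  theta <- fit_small$draws[1, ]
  fit0$draws <- matrix(rep(theta, each = 40), 40,
                       dimnames = list(NULL, colnames(fit_small$draws)))
  pw <- pointwise_loglik(fit0)
  ll <- pw[1, ]
  # pD = 0 and DIC = D(theta); pWAIC = 0 and WAIC = -2 sum l_i; LPML = sum l_i
  d0 <- dic(fit0, pw)
  expect_equal(attr(d0, "pD"), 0, tolerance = 1e-8)
  expect_equal(as.numeric(d0), -2 * sum(ll), tolerance = 1e-8)
  w0 <- waic(pw)
  expect_equal(attr(w0, "pwaic"), 0)
  expect_equal(as.numeric(w0), -2 * sum(ll))
  expect_equal(lpml(pw), sum(ll))
})

test_that("DIC matches a brute-force recomputation from raw draws", {
  g <- simulate_cohort(generator_config(
    n = 20, covariates = list(
      covariate_def(covariate_spec("x1", "binary", c("no", "yes")),
                    prob = 0.5)),
    intercept = c(hf = -3, non_hf = -4), horizon = 64, seed = 11))
  v <- cause_specific_view(g$cohort, "hf")
  fit <- baft(v, family = "weibull", control = ctl_short)
  pw <- pointwise_loglik(fit)
  got <- dic(fit, pw)
  # independent recomputation straight from the draw matrix
  devs <- apply(fit$draws, 1, function(th)
    -2 * censored_loglik("weibull", th[1:2], exp(th[3]), v$design,
                         v$times, v$d))
  Dbar <- mean(devs)
  th_bar <- colMeans(fit$draws)
  Dhat <- -2 * censored_loglik("weibull", th_bar[1:2], exp(th_bar[3]),
                               v$design, v$times, v$d)
  expect_equal(as.numeric(got), Dbar + (Dbar - Dhat), tolerance = 1e-10)
  expect_equal(attr(got, "pD"), Dbar - Dhat, tolerance = 1e-10)
})

test_that("WAIC follows its spreadsheet arithmetic and shift identity", {
  # 3 draws x 2 subjects, hand-listed values
  l <- matrix(c(-1.0, -1.2, -0.8,
                -2.0, -2.1, -1.9), nrow = 3)
  lppd <- log(mean(exp(l[, 1]))) + log(mean(exp(l[, 2])))
  pwaic <- stats::var(l[, 1]) + stats::var(l[, 2])
  expect_equal(as.numeric(waic(l)), -2 * (lppd - pwaic))
  expect_equal(pwaic, 0.05)  # hand value: var(c(-1,-1.2,-.8)) + var(...)

  # adding a constant c to every entry shifts WAIC by -2 n c
  cc <- 0.37
  expect_equal(as.numeric(waic(l + cc)), as.numeric(waic(l)) - 2 * 2 * cc,
               tolerance = 1e-12)
})

test_that("LPML is bounded above by the log pointwise predictive density", {
  set.seed(3)
  for (r in 1:5) {
    l <- matrix(stats::rnorm(60, -2, 0.6), nrow = 10)
    lppd <- sum(apply(l, 2, function(x) log(mean(exp(x)))))
    expect_lte(lpml(l), lppd + 1e-12)   # Jensen
  }
})

test_that("family comparison tabulates all criteria and ranks by DIC", {
  v <- cause_specific_view(small_gen$cohort, "hf")
  cmp <- suppressWarnings(compare_families(v, control = ctl_short))
  expect_s3_class(cmp, "baft_comparison")
  expect_equal(cmp$family, c("weibull", "loglogistic", "lognormal"))
  expect_true(all(is.finite(cmp$waic) & is.finite(cmp$lpml) &
                  is.finite(cmp$dic)))
  expect_equal(attr(cmp, "best_family"), cmp$family[which.min(cmp$dic)])

  # published-style criterion table: the DIC minimiser wins even when
  # WAIC would prefer another family
  tab <- data.frame(family = c("weibull", "lognormal", "loglogistic"),
                    waic = c(1730.922, 1728.042, 1728.594),
                    dic = c(1717.717, 1722.320, 1723.892))
  expect_equal(tab$family[which.min(tab$dic)], "weibull")
  expect_false(tab$family[which.min(tab$waic)] == "weibull")

  # single-candidate comparison degenerates to that family
  cmp1 <- suppressWarnings(
    compare_families(v, families = "lognormal", control = ctl_short))
  expect_equal(nrow(cmp1), 1)
  expect_equal(attr(cmp1, "best_family"), "lognormal")
})

test_that("criteria are invariant to subject order", {
  g <- small_gen
  v <- cause_specific_view(g$cohort, "hf")
  fit <- baft(v, family = "weibull", control = ctl_short)
  pw <- pointwise_loglik(fit)
  set.seed(4)
  perm <- sample(ncol(pw))
  expect_equal(as.numeric(waic(pw[, perm])), as.numeric(waic(pw)))
  expect_equal(lpml(pw[, perm]), lpml(pw))
  v_perm <- v
  v_perm$times <- v$times[perm]
  v_perm$d <- v$d[perm]
  v_perm$design <- v$design[perm, ]
  expect_equal(as.numeric(dic(fit, pointwise_loglik(fit, v_perm))),
               as.numeric(dic(fit, pw)), tolerance = 1e-10)
})
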