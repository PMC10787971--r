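# minimal view builder for hand fixtures
mk_view <- function(t, d) {
  structure(list(times = t, d = d,
                 design = matrix(1, length(t), 1,
                                 dimnames = list(NULL, "(Intercept)")),
                 column_names = "(Intercept)", cause = "hf",
                 n_events = sum(d)),
            class = "baft_view")
}

test_that("person-time rates use exact Poisson limits", {
  # 2 failures in 1000 person-months -> 2.00 per 1000; chi-square-quantile
  # oracle for the exact limits
  v <- mk_view(t = rep(100, 10), d = c(1, 1, rep(0, 8)))
  r <- person_time_rate(v)
  expect_equal(r$failures, 2)
  expect_equal(r$person_time, 1000)
  expect_equal(r$rate, 2)
  expect_equal(r$ci_low, 1000 * stats::qchisq(0.025, 2 * 2) / 2 / 1000,
               tolerance = 1e-10)
  expect_equal(r$ci_high, 1000 * stats::qchisq(0.975, 2 * (2 + 1)) / 2 / 1000,
               tolerance = 1e-10)

  # zero failures: rate 0 with lower bound 0
  r0 <- person_time_rate(mk_view(rep(50, 4), rep(0, 4)))
  expect_equal(r0$rate, 0)
  expect_equal(r0$ci_low, 0)
  expect_gt(r0$ci_high, 0)

  # splitting follow-up into two records with the same total changes nothing
  v1 <- mk_view(c(60, 40, 100), c(1, 0, 0))
  v2 <- mk_view(c(60, 20, 20, 100), c(1, 0, 0, 0))
  expect_equal(person_time_rate(v1)[c("rate", "ci_low", "ci_high")],
               person_time_rate(v2)[c("rate", "ci_low", "ci_high")])
  expect_error(person_time_rate(v1, stratum = rep(FALSE, 3)), "empty")
})

test_that("Kaplan-Meier matches the hand-computed product limit", {
  # worked fixture: times 2,4,4,6,8 with d = 1,1,0,1,0
  #  t=2: 5 at risk, 1 event -> S = 4/5 = 0.8
  #  t=4: 4 at risk, 1 event -> S = 0.8 * 3/4 = 0.6
  #  t=6: 2 at risk, 1 event -> S = 0.6 * 1/2 = 0.3
  v <- mk_view(c(2, 4, 4, 6, 8), c(1, 1, 0, 1, 0))
  km <- km_curve(v)
  expect_equal(km$time, c(2, 4, 6))
  expect_equal(km$n_risk, c(5, 4, 2))
  expect_equal(km$surv, c(0.8, 0.6, 0.3))
  # Greenwood: S^2 * cumsum(d / (n (n - d)))
  expect_equal(km$var, c(0.8^2 * (1 / 20),
                         0.6^2 * (1 / 20 + 1 / 12),
                         0.3^2 * (1 / 20 + 1 / 12 + 1 / 2)))
  # independent oracle: survival::survfit with plain intervals
  sf <- survival::survfit(survival::Surv(v$times, v$d) ~ 1,
                          conf.type = "plain")
  ss <- summary(sf, times = km$time)
  expect_equal(km$surv, ss$surv)
  expect_equal(sqrt(km$var), ss$std.err, tolerance = 1e-12)
  expect_equal(km$ci_low, pmax(0, ss$lower), tolerance = 1e-12)

  # step convention: value at t is the step at the largest event time <= t
  at <- km_at(km, c(1, 2, 5, 6, 100))
  expect_equal(at$surv, c(1, 0.8, 0.6, 0.3, 0.3))
})

test_that("Kaplan-Meier equals the empirical survival without censoring", {
  set.seed(8)
  t <- stats::rexp(60, 0.1)
  v <- mk_view(t, rep(1, 60))
  km <- km_curve(v)
  emp <- vapply(km$time, function(u) mean(t > u), numeric(1))
  expect_equal(km$surv, emp)
  # no events at all: flat curve at 1
  km0 <- km_curve(mk_view(t, rep(0, 60)))
  expect_equal(km_at(km0, c(1, 10, 50))$surv, c(1, 1, 1))
})

test_that("stratified failures and person-time add up to the totals", {
  v <- cause_specific_view(small_gen$cohort, "hf")
  grp <- small_gen$cohort$x1
  f <- pt <- 0
  for (l in c("no", "yes")) {
    r <- person_time_rate(v, stratum = grp == l)
    f <- f + r$failures
    pt <- pt + r$person_time
  }
  expect_equal(f, sum(v$d))
  expect_equal(pt, sum(v$times))
})

test_that("log-rank agrees with survdiff and is exactly null on duplicates", {
  v <- cause_specific_view(small_gen$cohort, "hf")
  grp <- small_gen$cohort$x1
  lr <- log_rank(v, grp)
  sd <- survival::survdiff(survival::Surv(v$times, v$d) ~ grp)
  expect_equal(lr$chi_square, sd$chisq, tolerance = 1e-10)
  expect_equal(lr$df, 1L)
  expect_equal(lr$p_value,
               stats::pchisq(sd$chisq, 1, lower.tail = FALSE),
               tolerance = 1e-10)

  # duplicated data split into two identical groups: chi-square exactly 0
  t2 <- c(v$times, v$times)
  d2 <- c(v$d, v$d)
  v2 <- mk_view(t2, d2)
  lr0 <- log_rank(v2, rep(c("a", "b"), each = length(v$times)))
  expect_equal(lr0$chi_square, 0)
  expect_equal(lr0$p_value, 1)

  # time-unit rescaling leaves the statistic unchanged
  v_days <- mk_view(v$times * 30.44, v$d)
  expect_equal(log_rank(v_days, grp)$chi_square, lr$chi_square)

  expect_error(log_rank(v, rep("a", length(v$times))), "two nonempty")
})

test_that("trend log-rank reduces to the two-group test when levels merge", {
  set.seed(21)
  n <- 90
  g3 <- sample(c("low", "mid", "high"), n, replace = TRUE)
  t <- stats::rexp(n, ifelse(g3 == "high", 0.08, 0.04))
  d <- as.numeric(t < 25)
  t <- pmin(t, 25)
  v <- mk_view(t, d)
  # scores 0,1,1 collapse mid and high: identical to the merged 2-group test
  g3f <- factor(g3, levels = c("low", "mid", "high"))
  tr <- log_rank(v, g3f, trend = TRUE, scores = c(0, 1, 1))
  g2 <- ifelse(g3 == "low", "low", "rest")
  two <- log_rank(v, g2)
  expect_equal(tr$chi_square, two$chi_square, tolerance = 1e-10)
  expect_equal(tr$df, 1L)

  # default integer scores give a 1-df monotone-trend statistic
  tr_def <- log_rank(v, g3f, trend = TRUE)
  expect_equal(tr_def$df, 1L)
  expect_gte(tr_def$chi_square, 0)
})

test_that("log-rank p agrees with a permutation null", {
  set.seed(31)
  n <- 40
  grp <- rep(c("a", "b"), each = n / 2)
  t <- stats::rexp(n, ifelse(grp == "a", 0.05, 0.08))
  d <- as.numeric(t < 20)
  t <- pmin(t, 20)
  v <- mk_view(t, d)
  obs <- log_rank(v, grp)
  perm_p <- local({
    B <- 5000
    hits <- 0
    for (b in seq_len(B)) {
      gb <- sample(grp)
      if (log_rank(v, gb)$chi_square >= obs$chi_square) hits <- hits + 1
    }
    hits / B
  })
  expect_lt(abs(obs$p_value - perm_p), 0.02)
})

test_that("the descriptive report assembles rates, KM and log-rank", {
  desc <- describe_cohort(small_gen$cohort, km_times = c(12, 36, 60))
  expect_named(desc$causes, c("hf", "non_hf"))
  hf <- desc$causes$hf
  expect_equal(nrow(hf$km_at), 3)
  expect_true(all(diff(hf$km_at$surv) <= 0))
  expect_true(all(hf$rates$rate >= 0))
  # bookkeeping: stratified failures of each covariate sum to the total
  v <- cause_specific_view(small_gen$cohort, "hf")
  x1_rows <- hf$rates[hf$rates$covariate == "x1", ]
  expect_equal(sum(x1_rows$failures), sum(v$d))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_description(desc, path)
  expect_true(file.exists(path))
  expect_gt(length(readLines(path)), 10)
})
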