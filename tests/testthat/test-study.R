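# a compact study configuration used throughout
ctl_study <- mcmc_control(n_chains = 1, n_iter = 1500, n_burnin = 700)
cfg_study <- study_config(control = ctl_study, seed = 5,
                          prior_variance_grid = c(1, 100, 10000))

test_that("family selection returns the criterion table and a winner", {
  sel <- select_family(fx$weibull_truth_n800$cohort, "hf", cfg_study)
  expect_true(sel$family %in% c("weibull", "loglogistic", "lognormal"))
  expect_equal(nrow(sel$comparison), 3)
  expect_true(all(c("waic", "lpml", "dic") %in% names(sel$comparison)))
  # generating family is Weibull on this fixture
  expect_equal(sel$family, "weibull")
})

test_that("univariable screening keeps the strong covariate, drops the null", {
  cfg <- generator_config(
    n = 600,
    covariates = list(
      covariate_def(covariate_spec("strong", "binary", c("no", "yes")),
                    prob = 0.5),
      covariate_def(covariate_spec("null", "binary", c("no", "yes")),
                    prob = 0.5)),
    intercept = c(hf = -3.8, non_hf = -5.5),
    ancillary = c(hf = 1, non_hf = 1),
    true_tr = list(hf = list(strong = 0.4, null = 1.0)),
    horizon = 64, seed = 23)
  g <- simulate_cohort(cfg)
  scr <- suppressWarnings(
    univariable_screen(g$cohort, "hf", "weibull", cfg_study))
  expect_true("strong" %in% scr$significant)
  expect_false("null" %in% scr$significant)
  expect_equal(sort(names(scr$fits)), c("null", "strong"))
  expect_true(all(c("covariate", "term", "tr") %in% names(scr$table)))
})

test_that("a single-covariate multivariable fit equals the univariable fit", {
  ch <- small_gen$cohort
  scr_fit <- univariable_screen(ch, "hf", "weibull", cfg_study)
  m <- multivariable_fit(ch, "hf", "weibull", "x1", cfg_study)
  ms <- summary(m)$time_ratios
  us <- scr_fit$fits$x1$time_ratios
  # same model, different seed substreams: agree within MC tolerance
  expect_lt(abs(ms$tr - us$tr), 0.08)
  expect_error(multivariable_fit(ch, "hf", "weibull", character(0)),
               "at least one")
})

test_that("sensitivity analysis flags prior-dependent terms only", {
  # constructed from published-style values: reference TR 0.41 at the
  # diffuse prior vs 0.46 at variance 1000 is a 12.2% change -> flagged
  tab <- data.frame(variance = c(10000, 1000, 1000),
                    term = c("chest_pain", "chest_pain", "age"),
                    tr = c(0.41, 0.46, NA))
  tab <- rbind(tab[1:2, ], data.frame(variance = 10000, term = "age",
                                      tr = 0.98),
               data.frame(variance = 1000, term = "age", tr = 0.99))
  fl <- sensitivity_flags(tab, 10000, threshold = 0.10)
  expect_equal(unname(fl$max_change[["chest_pain"]]), 0.05 / 0.41)
  expect_gt(fl$max_change[["chest_pain"]], 0.10)
  expect_true("chest_pain" %in% fl$flagged)
  expect_false("age" %in% fl$flagged)

  # identical TRs across the grid: nothing flagged
  tab2 <- expand.grid(variance = c(1, 100, 10000), term = "x")
  tab2$tr <- 0.5
  expect_length(sensitivity_flags(tab2, 10000)$flagged, 0)

  # degenerate grid (reference only): empty change columns
  tab3 <- data.frame(variance = 10000, term = "x", tr = 0.5)
  fl3 <- sensitivity_flags(tab3, 10000)
  expect_length(fl3$flagged, 0)
  expect_true(is.na(fl3$max_change[["x"]]))
})

test_that("sensitivity refits share the reference column with the fit", {
  ch <- small_gen$cohort
  sens <- sensitivity_analysis(ch, "hf", "weibull", c("x1", "z"), cfg_study)
  ref_rows <- sens$table[sens$table$variance == 10000, ]
  m <- multivariable_fit(ch, "hf", "weibull", c("x1", "z"), cfg_study)
  expect_equal(ref_rows$tr, summary(m)$time_ratios$tr, tolerance = 1e-12)
  expect_true(all(c("x1", "z") %in% names(sens$max_change)))
})

test_that("the full study runs per cause, deterministically", {
  cfg <- study_config(causes = c("hf", "non_hf"),
                      families = c("weibull", "lognormal"),
                      prior_variance_grid = c(100, 10000),
                      control = ctl_study, seed = 5)
  st <- run_study(small_gen$cohort, cfg)
  expect_s3_class(st, "baft_study")
  expect_named(st$causes, c("hf", "non_hf"))
  for (cause in names(st$causes)) {
    cc <- st$causes[[cause]]
    expect_null(cc$error)
    expect_s3_class(cc$comparison, "baft_comparison")
    expect_true(is.list(cc$univariable))
  }
  # rerun: identical numbers
  st2 <- run_study(small_gen$cohort, cfg)
  expect_equal(st2$causes$hf$univariable$table,
               st$causes$hf$univariable$table)

  # cause independence: the HF branch alone reproduces the joint run
  cfg_hf <- cfg
  cfg_hf$causes <- "hf"
  st_hf <- run_study(small_gen$cohort, cfg_hf)
  expect_equal(st_hf$causes$hf$univariable$table,
               st$causes$hf$univariable$table)
  if (!is.null(st$causes$hf$multivariable))
    expect_equal(st_hf$causes$hf$multivariable$time_ratios,
                 st$causes$hf$multivariable$time_ratios)

  # report files
  dir <- withr::local_tempdir()
  files <- write_study_report(st, dir)
  expect_true(any(grepl("comparison_hf", files)))
  expect_true(any(grepl("univariable_non_hf", files)))
})
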