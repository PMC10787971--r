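# Shared fixtures, computed once per test run.

fx <- standard_fixtures(seed = 1)

# short sampler settings for unit tests (studies and oracles use their own)
ctl_short <- mcmc_control(n_chains = 1, n_iter = 1500, n_burnin = 700, seed = 1)
ctl_mid <- mcmc_control(n_chains = 2, n_iter = 3000, n_burnin = 1500, seed = 1)

# A cohort whose event counts reproduce a registry baseline table:
# 435 subjects, 160 HF deaths, 97 non-HF deaths, 266 male, 384 with chest
# pain (deaths and covariates assigned independently; only the margins
# matter for bookkeeping checks).
table1_cohort <- local({
  n <- 435
  event <- c(rep("hf_death", 160), rep("non_hf_death", 97),
             rep("censored", n - 160 - 97))
  sex <- c(rep("male", 266), rep("female", n - 266))
  chest <- c(rep("yes", 384), rep("no", n - 384))
  df <- data.frame(id = paste0("P", seq_len(n)), time_months = 50,
                   event = event, sex = sex, chest_pain = chest)
  cohort(df, list(
    covariate_spec("sex", "binary", c("female", "male")),
    covariate_spec("chest_pain", "binary", c("no", "yes"))))
})

# Small two-covariate cohort for fit-level tests
small_gen <- simulate_cohort(generator_config(
  n = 120,
  covariates = list(
    covariate_def(covariate_spec("x1", "binary", c("no", "yes")), prob = 0.5),
    covariate_def(covariate_spec("z", "continuous"), mean = 0, sd = 1)),
  family = c(hf = "weibull", non_hf = "weibull"),
  intercept = c(hf = -3.5, non_hf = -4.5),
  ancillary = c(hf = 1.2, non_hf = 1),
  true_tr = list(hf = list(x1 = 0.5)),
  horizon = 64, seed = 42))
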