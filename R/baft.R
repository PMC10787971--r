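#' Fit a Bayesian accelerated failure time model
#'
#' `baft()` fits a parametric AFT regression to right-censored survival
#' data by MCMC under diffuse normal priors, and is the building block of
#' the competing-risks pipeline: fitting one `baft` model per event cause,
#' with competing-cause deaths coded as censored, gives the cause-specific
#' analysis.
#'
#' The model for subject \eqn{i} with covariate row \eqn{x_i} is an AFT
#' regression in the rate parameterisation \eqn{\lambda_i = \exp(x_i'\beta)}
#' (Weibull, log-logistic) or log-time location \eqn{\mu_i = x_i'\beta}
#' (log-normal); see [aft_families]. Coefficients carry independent
#' N(0, `prior_variance`) priors, as does the log ancillary parameter.
#' Covariate effects are reported as time ratios: posterior median and
#' equal-tailed 95% credible interval of \eqn{TR_j} computed draw by draw
#' (see [to_time_ratio()]); an effect is flagged significant when the 95%
#' interval excludes 1.
#'
#' @param x a [cause_specific_view], a `baft_cohort`, or a model formula
#'   with a `survival::Surv(time, status)` left-hand side.
#' @param ... passed between methods.
#' @return an object of class `baft` with `print`, `summary`, `coef`,
#'   `predict`, `plot`, `simulate`, `residuals` and `logLik` methods.
#' @examples
#' cohorts <- standard_fixtures(seed = 1)
#' v <- cause_specific_view(cohorts$tiny_n20, "hf")
#' fit <- baft(v, family = "weibull",
#'             control = mcmc_control(n_chains = 1, n_iter = 600,
#'                                    n_burnin = 300, seed = 1))
#' summary(fit)
#' @export
baft <- function(x, ...) UseMethod("baft")

#' @rdname baft
#' @param family `"weibull"`, `"loglogistic"` or `"lognormal"`.
#' @param prior_variance prior variance for coefficients and log ancillary.
#' @param control a [mcmc_control].
#' @param fix_ancillary optional value at which the shape/variance
#'   parameter is fixed.
#' @export
baft.baft_view <- function(x, family = "weibull", prior_variance = 10000,
                           control = mcmc_control(), fix_ancillary = NULL,
                           ...) {
  family <- check_family(family)
  prior <- prior_spec(prior_variance)
  draws <- run_mcmc(x, family, prior, control, fix_ancillary)
  structure(list(call = match.call(), family = family, cause = x$cause,
                 view = x, prior = prior, control = control,
                 draws_obj = draws, draws = draws$draws,
                 par_names = draws$par_names,
                 fix_ancillary = fix_ancillary, terms = NULL),
            class = "baft")
}

#' @rdname baft
#' @param cause event cause to model (`"hf"` or `"non_hf"`); competing
#'   deaths are treated as censored.
#' @param covariates optional subset of declared covariates.
#' @export
baft.baft_cohort <- function(x, cause = "hf", covariates = NULL,
                             family = "weibull", prior_variance = 10000,
                             control = mcmc_control(), ...) {
  v <- cause_specific_view(x, cause, covariates)
  out <- baft(v, family = family, prior_variance = prior_variance,
              control = control, ...)
  out$call <- match.call()
  out
}

#' @rdname baft
#' @param data data frame for the formula method.
#' @export
baft.formula <- function(x, data, family = "weibull", prior_variance = 10000,
                         control = mcmc_control(), ...) {
  mf <- stats::model.frame(x, data)
  y <- stats::model.response(mf)
  if (!inherits(y, "Surv")) stopf("left-hand side must be a survival::Surv object")
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  t <- as.numeric(y[, 1])
  d <- as.numeric(y[, 2])
  view <- structure(list(times = t, d = d, design = X,
                         column_names = colnames(X), cause = NULL,
                         n_events = sum(d)),
                    class = "baft_view")
  if (view$n_events == 0) stopf("no events in the data")
  out <- baft(view, family = family, prior_variance = prior_variance,
              control = control, ...)
  out$call <- match.call()
  out$terms <- attr(mf, "terms")
  out
}

# beta draws / ancillary draws helpers
beta_draws <- function(fit) {
  p <- ncol(fit$view$design)
  fit$draws[, seq_len(p), drop = FALSE]
}

ancillary_draws <- function(fit) {
  p <- ncol(fit$view$design)
  if (!is.null(fit$fix_ancillary))
    rep(fit$fix_ancillary, nrow(fit$draws))
  else exp(fit$draws[, p + 1L])
}

#' @export
print.baft <- function(x, ...) {
  cat(sprintf("Bayesian %s AFT model%s (%d subjects, %d events)\n",
              x$family,
              if (!is.null(x$cause)) paste0(", cause: ", x$cause) else "",
              length(x$view$times), x$view$n_events))
  s <- summary(x)
  print(s$time_ratios, digits = 3)
  invisible(x)
}

#' Posterior time-ratio summary of a fitted AFT model
#'
#' For every non-intercept design column the coefficient draws are
#' transformed to the time-ratio scale draw by draw (using that draw's
#' ancillary parameter) and summarised by the posterior median and the
#' equal-tailed 2.5-97.5 percentile interval. `significant` flags
#' intervals that exclude 1.
#'
#' @param object a fitted `baft` model.
#' @param prob credible level (default 0.95).
#' @param ... unused.
#' @return a `summary.baft` list; `$time_ratios` is a data frame with
#'   columns `term`, `tr`, `ci_low`, `ci_high`, `significant`.
#' @export
summary.baft <- function(object, prob = 0.95, ...) {
  B <- beta_draws(object)
  anc <- ancillary_draws(object)
  a <- (1 - prob) / 2
  terms <- object$par_names[seq_len(ncol(B))]
  keep <- which(terms != "(Intercept)")
  rows <- lapply(keep, function(j) {
    # to_time_ratio applied draw by draw with that draw's ancillary value
    tr <- if (object$family == "lognormal") exp(B[, j]) else exp(-B[, j] / anc)
    q <- unname(stats::quantile(tr, c(0.5, a, 1 - a), type = 7))
    data.frame(term = terms[j], tr = q[1], ci_low = q[2], ci_high = q[3],
               significant = q[2] > 1 | q[3] < 1,
               stringsAsFactors = FALSE)
  })
  tr_tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(term = character(), tr = numeric(), ci_low = numeric(),
               ci_high = numeric(), significant = logical())
  rownames(tr_tab) <- NULL
  structure(list(
    family = object$family, cause = object$cause,
    time_ratios = tr_tab,
    ancillary_median = stats::median(anc),
    intercept_median = stats::median(B[, 1]),
    n = length(object$view$times), n_events = object$view$n_events,
    acceptance_rate = object$draws_obj$acceptance_rate,
    rhat = object$draws_obj$rhat,
    prob = prob
  ), class = "summary.baft")
}

#' @export
print.summary.baft <- function(x, ...) {
  cat(sprintf("Bayesian %s AFT model%s\n", x$family,
              if (!is.null(x$cause)) paste0(" (cause-specific: ", x$cause, ")")
              else ""))
  cat(sprintf("  %d subjects, %d events | ancillary median %.3f | max R-hat %.3f\n",
              x$n, x$n_events, x$ancillary_median,
              max(x$rhat, na.rm = TRUE)))
  cat(sprintf("  Time ratios (posterior median, %.0f%% credible interval):\n",
              100 * x$prob))
  tab <- x$time_ratios
  for (i in seq_len(nrow(tab)))
    cat(sprintf("    %-28s %5.2f (%.2f-%.2f)%s\n", tab$term[i], tab$tr[i],
                tab$ci_low[i], tab$ci_high[i],
                if (tab$significant[i]) " *" else ""))
  invisible(x)
}

#' Posterior time ratios as a data frame
#'
#' @inheritParams summary.baft
#' @param fit a fitted `baft` model.
#' @return data frame `term`, `tr`, `ci_low`, `ci_high`, `significant`.
#' @export
time_ratios <- function(fit, prob = 0.95) {
  summary(fit, prob = prob)$time_ratios
}

#' @export
coef.baft <- function(object, ...) {
  B <- beta_draws(object)
  out <- apply(B, 2, stats::median)
  names(out) <- object$par_names[seq_len(ncol(B))]
  anc <- stats::median(ancillary_draws(object))
  out <- c(out, anc)
  names(out)[length(out)] <-
    if (object$family == "lognormal") "delta" else "shape"
  out
}

#' @export
logLik.baft <- function(object, ...) {
  cf <- coef.baft(object)
  k <- length(cf)
  val <- censored_loglik(object$family, cf[-k], cf[k], object$view$design,
                         object$view$times, object$view$d)
  structure(val, df = k, class = "logLik")
}

# Resolve newdata into design rows matching the fit
design_rows <- function(object, newdata) {
  if (is.null(newdata)) return(object$view$design)
  if (is.matrix(newdata)) {
    if (ncol(newdata) != ncol(object$view$design))
      stopf("newdata matrix must have %d columns (including intercept)",
            ncol(object$view$design))
    return(newdata)
  }
  if (!is.null(object$terms)) {
    tt <- stats::delete.response(object$terms)
    return(stats::model.matrix(tt, stats::model.frame(tt, newdata)))
  }
  stopf("supply newdata as a design matrix (with intercept) for view-based fits")
}

#' Posterior predictive survival and median survival time
#'
#' @param object a fitted `baft` model.
#' @param newdata covariate values: a design matrix with intercept, a data
#'   frame (formula fits), or `NULL` for the training rows.
#' @param times evaluation times in months (type `"survival"`).
#' @param type `"survival"` for posterior median survival probabilities
#'   S(t | x) on a time grid, `"median"` for the posterior median of the
#'   median survival time.
#' @param ... unused.
#' @return type `"survival"`: matrix (rows = newdata rows, columns =
#'   `times`); type `"median"`: vector of median survival times.
#' @export
predict.baft <- function(object, newdata = NULL, times = NULL,
                         type = c("survival", "median"), ...) {
  type <- match.arg(type)
  X <- design_rows(object, newdata)
  B <- beta_draws(object)
  anc <- ancillary_draws(object)
  LP <- X %*% t(B)                       # rows x draws
  if (type == "median") {
    med <- switch(object$family,
      weibull = (log(2) * exp(-LP))^(1 / matrix(anc, nrow(LP), length(anc),
                                                byrow = TRUE)),
      loglogistic = exp(-LP / matrix(anc, nrow(LP), length(anc), byrow = TRUE)),
      lognormal = exp(LP))
    return(apply(med, 1, stats::median))
  }
  if (is.null(times)) times <- pretty(c(0.1, max(object$view$times)), 25)
  times <- times[times > 0]
  out <- matrix(NA_real_, nrow(X), length(times),
                dimnames = list(NULL, signif(times, 6)))
  for (j in seq_along(times)) {
    # S(t) per draw, then posterior median across draws
    lS <- vapply(seq_along(anc), function(s)
      aft_logS(object$family, times[j], LP[, s], anc[s]), numeric(nrow(X)))
    if (nrow(X) == 1L) lS <- matrix(lS, nrow = 1L)
    out[, j] <- apply(exp(lS), 1, stats::median)
  }
  out
}

#' Simulate posterior predictive event times
#'
#' Draws one posterior parameter set per replicate and simulates an event
#' time for every training row from the fitted family.
#'
#' @param object a fitted `baft` model.
#' @param nsim number of replicate datasets.
#' @param seed integer seed.
#' @param ... unused.
#' @return data frame with `nsim` columns of simulated times.
#' @export
simulate.baft <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  B <- beta_draws(object)
  anc <- ancillary_draws(object)
  X <- object$view$design
  n <- nrow(X)
  idx <- sample.int(nrow(B), nsim, replace = TRUE)
  out <- vapply(idx, function(s) {
    lp <- drop(X %*% B[s, ])
    raft(n, object$family, lp, anc[s])
  }, numeric(n))
  as.data.frame(matrix(out, nrow = n,
                       dimnames = list(NULL, paste0("sim_", seq_len(nsim)))))
}

#' Cox-Snell residuals of a fitted AFT model
#'
#' \eqn{r_i = -\log S(t_i | x_i)} at the posterior median parameters; if
#' the model fits, the uncensored residuals behave like a unit-exponential
#' censored sample.
#'
#' @param object a fitted `baft` model.
#' @param ... unused.
#' @return numeric vector with attribute `d` (the event indicators).
#' @export
residuals.baft <- function(object, ...) {
  cf <- coef.baft(object)
  k <- length(cf)
  lp <- drop(object$view$design %*% cf[-k])
  r <- -aft_logS(object$family, object$view$times, lp, cf[k])
  attr(r, "d") <- object$view$d
  r
}

#' Plot a fitted AFT model
#'
#' `type = "fit"` overlays the posterior median survival curve at the
#' covariate means on the Kaplan-Meier estimate of the modelled cause;
#' `type = "trace"` draws one trace per parameter.
#'
#' @param x a fitted `baft` model.
#' @param type `"fit"` or `"trace"`.
#' @param ... passed to the underlying plotting calls.
#' @export
plot.baft <- function(x, type = c("fit", "trace"), ...) {
  type <- match.arg(type)
  if (type == "trace") {
    k <- ncol(x$draws)
    op <- graphics::par(mfrow = c(min(k, 3), ceiling(k / min(k, 3))),
                        mar = c(3, 4, 2, 1))
    on.exit(graphics::par(op))
    per <- nrow(x$draws) / x$draws_obj$n_chains
    for (j in seq_len(k)) {
      graphics::plot(NA, xlim = c(1, per), ylim = range(x$draws[, j]),
                     xlab = "iteration", ylab = x$par_names[j], main = "")
      for (ch in seq_len(x$draws_obj$n_chains))
        graphics::lines(seq_len(per),
                        x$draws[x$draws_obj$chain_id == ch, j], col = ch)
    }
    return(invisible(x))
  }
  km <- km_curve(x$view)
  xbar <- matrix(colMeans(x$view$design), 1)
  grid <- seq(0.01, max(x$view$times), length.out = 100)
  S <- drop(predict(x, newdata = xbar, times = grid))
  graphics::plot(stats::stepfun(km$time, c(1, km$surv)), do.points = FALSE,
                 xlab = "months", ylab = "S(t)", main = "", ylim = c(0, 1),
                 ...)
  graphics::lines(grid, S, col = 2, lwd = 2)
  graphics::legend("topright", c("Kaplan-Meier", "posterior median"),
                   col = c(1, 2), lty = 1, bty = "n")
  invisible(x)
}
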