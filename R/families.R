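#' Parametric AFT families
#'
#' Three accelerated failure time (AFT) families for right-censored event
#' times, in the rate parameterisation \eqn{\lambda = \exp(x'\beta)}:
#' \describe{
#'   \item{weibull}{\eqn{f(t) = \lambda p t^{p-1} \exp(-\lambda t^p)},
#'     \eqn{S(t) = \exp(-\lambda t^p)}; shape \eqn{p > 0}.}
#'   \item{loglogistic}{\eqn{f(t) = \lambda p t^{p-1} / (1 + \lambda t^p)^2},
#'     \eqn{S(t) = 1 / (1 + \lambda t^p)}; shape \eqn{p > 0}.}
#'   \item{lognormal}{location \eqn{\mu = x'\beta} on the log-time scale and
#'     variance \eqn{\delta}: \eqn{S(t) = 1 - \Phi((\ln t - \mu)/\sqrt\delta)}.}
#' }
#' For the Weibull and log-logistic families a positive coefficient shortens
#' survival (it raises the rate \eqn{\lambda}); the reporting scale is the
#' time ratio, see [to_time_ratio()].
#'
#' @param family one of `"weibull"`, `"loglogistic"`, `"lognormal"`.
#' @param t positive event or censoring times.
#' @param lp linear predictor \eqn{x'\beta} per observation (recycled).
#' @param ancillary shape `p` (weibull, loglogistic) or variance `delta`
#'   (lognormal); a single positive number.
#' @return `aft_logf` and `aft_logS` return vectors of log-density and
#'   log-survival values.
#' @examples
#' aft_logf("weibull", t = 1, lp = 0, ancillary = 1)   # exponential: -1
#' exp(aft_logS("loglogistic", t = 1, lp = 0, ancillary = 1)) # 1/2
#' @name aft_families
NULL

aft_families <- c("weibull", "loglogistic", "lognormal")

check_family <- function(family) {
  match.arg(tolower(family), aft_families)
}

check_ancillary <- function(ancillary) {
  if (!is.numeric(ancillary) || length(ancillary) != 1L ||
      !is.finite(ancillary) || ancillary <= 0)
    stopf("'ancillary' must be a single positive number, got %s",
          deparse(ancillary))
  ancillary
}

#' @rdname aft_families
#' @export
aft_logf <- function(family, t, lp, ancillary) {
  family <- check_family(family)
  check_ancillary(ancillary)
  if (any(t <= 0)) stopf("times must be positive")
  switch(family,
    weibull = {
      p <- ancillary
      lp + log(p) + (p - 1) * log(t) - exp(lp + p * log(t))
    },
    loglogistic = {
      p <- ancillary
      # log f = log(lambda p t^(p-1)) - 2 log(1 + lambda t^p)
      u <- lp + p * log(t)
      lp + log(p) + (p - 1) * log(t) - 2 * log1pexp(u)
    },
    lognormal = {
      delta <- ancillary
      stats::dnorm(log(t), mean = lp, sd = sqrt(delta), log = TRUE) - log(t)
    })
}

#' @rdname aft_families
#' @export
aft_logS <- function(family, t, lp, ancillary) {
  family <- check_family(family)
  check_ancillary(ancillary)
  if (any(t <= 0)) stopf("times must be positive")
  switch(family,
    weibull = -exp(lp + ancillary * log(t)),
    loglogistic = -log1pexp(lp + ancillary * log(t)),
    lognormal = stats::pnorm(log(t), mean = lp, sd = sqrt(ancillary),
                             lower.tail = FALSE, log.p = TRUE))
}

# log(1 + exp(u)) without overflow (u can be very large)
log1pexp <- function(u) ifelse(u > 35, u, log1p(exp(pmin(u, 35))))

#' Censored log-likelihood of an AFT model
#'
#' The right-censored likelihood
#' \eqn{L = \prod_i f(t_i)^{d_i} S(t_i)^{1-d_i}}, with \eqn{d_i = 1} for an
#' observed event and \eqn{d_i = 0} for a censored time (including
#' competing-cause events in a cause-specific analysis).
#'
#' @param beta coefficient vector, intercept first, conformable with the
#'   columns of `X`.
#' @param ancillary family shape/variance parameter, see [aft_families].
#' @param X design matrix with leading intercept column.
#' @param t positive follow-up times.
#' @param d event indicators in \{0, 1\}.
#' @inheritParams aft_families
#' @return the log-likelihood (a single number).
#' @export
censored_loglik <- function(family, beta, ancillary, X, t, d) {
  lp <- drop(X %*% beta)
  ll <- ifelse(d == 1,
               aft_logf(family, t, lp, ancillary),
               aft_logS(family, t, lp, ancillary))
  if (any(!is.finite(ll)))
    stopf("non-finite log-likelihood contribution for subject(s) %s",
          paste(which(!is.finite(ll)), collapse = ", "))
  sum(ll)
}

# Same kernel without the error (used inside MCMC where -Inf is a rejection)
censored_loglik_safe <- function(family, beta, ancillary, X, t, d) {
  lp <- drop(X %*% beta)
  ll <- ifelse(d == 1,
               aft_logf(family, t, lp, ancillary),
               aft_logS(family, t, lp, ancillary))
  sum(ll)
}

#' Convert an AFT coefficient to a time ratio
#'
#' In the rate parameterisation \eqn{\lambda = \exp(x'\beta)} a coefficient
#' \eqn{\beta_j} acts on the time scale as the multiplicative factor
#' \eqn{TR = \exp(-\beta_j/p)} (Weibull, log-logistic). For the log-normal
#' family \eqn{\mu = x'\beta} is already the log-time location, so
#' \eqn{TR = \exp(\beta_j)}. A TR below 1 shortens survival.
#'
#' @param beta_j coefficient value(s) on the model's linear-predictor scale.
#' @inheritParams aft_families
#' @return positive time ratio(s), same length as `beta_j`.
#' @export
to_time_ratio <- function(family, beta_j, ancillary) {
  family <- check_family(family)
  if (family == "lognormal") return(exp(beta_j))
  check_ancillary(ancillary)
  exp(-beta_j / ancillary)
}
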