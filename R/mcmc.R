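#' Diffuse normal prior for AFT parameters
#'
#' Independent normal priors with mean 0 and a common (large) variance on
#' every regression coefficient and on the log of the ancillary parameter
#' (log shape for Weibull/log-logistic, log variance for log-normal). The
#' default variance 10000 is effectively non-informative on the
#' linear-predictor scale; the sensitivity layer refits over a grid of
#' smaller variances.
#'
#' @param variance prior variance (> 0), default `10000`.
#' @return a `baft_prior` object.
#' @export
prior_spec <- function(variance = 10000) {
  stopifnot(is.numeric(variance), length(variance) == 1L, variance > 0)
  structure(list(mean = 0, variance = variance), class = "baft_prior")
}

#' Log prior density
#'
#' Sum of normal log densities of the coefficients and of the log ancillary
#' parameter under a [prior_spec].
#'
#' @param beta coefficient vector.
#' @param log_ancillary log of the shape/variance parameter; `NULL` when
#'   the ancillary parameter is held fixed.
#' @param prior a `baft_prior`.
#' @return the log prior density (unnormalised posterior building block).
#' @export
log_prior <- function(beta, log_ancillary = NULL, prior = prior_spec()) {
  stopifnot(inherits(prior, "baft_prior"))
  sd <- sqrt(prior$variance)
  out <- sum(stats::dnorm(beta, prior$mean, sd, log = TRUE))
  if (!is.null(log_ancillary))
    out <- out + stats::dnorm(log_ancillary, prior$mean, sd, log = TRUE)
  out
}

#' Unnormalised log posterior
#'
#' Censored AFT log-likelihood plus log prior; the target density of the
#' Metropolis sampler.
#'
#' @inheritParams censored_loglik
#' @param view a [cause_specific_view] (alternative to `X`, `t`, `d`).
#' @inheritParams log_prior
#' @return the unnormalised log posterior.
#' @export
log_posterior <- function(family, beta, ancillary, view, prior = prior_spec()) {
  stopifnot(inherits(view, "baft_view"))
  censored_loglik(family, beta, ancillary, view$design, view$times, view$d) +
    log_prior(beta, log(ancillary), prior)
}

#' MCMC sampler settings
#'
#' Defaults (2 chains, 20000 iterations, 10000 burn-in, no thinning) are
#' sized so that a single registry-scale fit mixes well; study pipelines
#' and tests typically pass shorter chains.
#'
#' @param n_chains number of independent chains.
#' @param n_iter iterations per chain (including burn-in).
#' @param n_burnin burn-in iterations discarded per chain; proposal
#'   adaptation stops here.
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param seed integer seed; every chain derives its own substream.
#' @return a `baft_mcmc_control` list.
#' @export
mcmc_control <- function(n_chains = 2L, n_iter = 20000L, n_burnin = 10000L,
                         thin = 1L, seed = 1L) {
  stopifnot(n_chains >= 1, n_iter > n_burnin, n_burnin >= 0, thin >= 1)
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 n_burnin = as.integer(n_burnin), thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "baft_mcmc_control")
}

# Fast censored log-likelihood closure for a fixed view/family.
# theta = c(beta, log_ancillary) unless ancillary is fixed.
make_logpost <- function(view, family, prior, fix_ancillary = NULL) {
  e <- view$d == 1
  Xe <- view$design[e, , drop = FALSE]
  Xc <- view$design[!e, , drop = FALSE]
  te <- view$times[e]
  tc <- view$times[!e]
  p <- ncol(view$design)
  sd0 <- sqrt(prior$variance)
  fixed <- !is.null(fix_ancillary)
  function(theta) {
    beta <- theta[seq_len(p)]
    anc <- if (fixed) fix_ancillary else exp(theta[p + 1L])
    if (!is.finite(anc) || anc <= 0) return(-Inf)
    ll <- sum(aft_logf(family, te, drop(Xe %*% beta), anc)) +
      (if (length(tc)) sum(aft_logS(family, tc, drop(Xc %*% beta), anc)) else 0)
    lp <- sum(stats::dnorm(beta, 0, sd0, log = TRUE))
    if (!fixed) lp <- lp + stats::dnorm(theta[p + 1L], 0, sd0, log = TRUE)
    val <- ll + lp
    if (!is.finite(val)) -Inf else val
  }
}

# Short numerical MLE for initialisation (and flat-prior oracle tests use
# survreg instead, independently).
aft_mle <- function(view, family, fix_ancillary = NULL) {
  p <- ncol(view$design)
  flat <- prior_spec(1e12)
  lp <- make_logpost(view, family, flat, fix_ancillary)
  init <- if (is.null(fix_ancillary)) rep(0, p + 1L) else rep(0, p)
  fit <- try(stats::optim(init, function(th) -lp(th), method = "BFGS",
                          control = list(maxit = 500), hessian = TRUE),
             silent = TRUE)
  if (inherits(fit, "try-error") || !is.finite(fit$value)) return(NULL)
  vc <- try(solve(fit$hessian), silent = TRUE)
  if (inherits(vc, "try-error") || any(!is.finite(vc)) ||
      any(diag(vc) <= 0)) vc <- NULL
  list(par = fit$par, vcov = vc)
}

#' Run the adaptive Metropolis sampler for one cause-specific AFT model
#'
#' Joint Gaussian random-walk Metropolis on (coefficients, log ancillary).
#' During burn-in the proposal covariance tracks the empirical covariance
#' of the chain and a global step-size scale is tuned toward an acceptance
#' rate of 0.234; both are frozen when burn-in ends, so the retained draws
#' come from a fixed-kernel chain. Chains are initialised at the numerical
#' MLE (zeros as fallback) with log ancillary 0, and each chain uses a seed
#' derived deterministically from `control$seed`, making the draws
#' bit-reproducible.
#'
#' @param view a [cause_specific_view].
#' @inheritParams aft_families
#' @param prior a [prior_spec].
#' @param control a [mcmc_control].
#' @param fix_ancillary optional positive value at which the ancillary
#'   parameter is held fixed (e.g. shape 1 for an exponential model).
#' @return a `baft_draws` object: retained draws (rows =
#'   `n_chains * (n_iter - n_burnin) / thin`), parameter names, chain ids,
#'   per-chain acceptance rates and split-R-hat diagnostics. A warning is
#'   issued (not an error) if any R-hat exceeds 1.1.
#' @export
run_mcmc <- function(view, family, prior = prior_spec(),
                     control = mcmc_control(), fix_ancillary = NULL) {
  stopifnot(inherits(view, "baft_view"))
  family <- check_family(family)
  if (!is.null(fix_ancillary)) check_ancillary(fix_ancillary)
  if (view$n_events == 0) stopf("view has zero events")
  p <- ncol(view$design)
  k <- if (is.null(fix_ancillary)) p + 1L else p
  par_names <- c(view$column_names,
                 if (is.null(fix_ancillary))
                   switch(family, lognormal = "log_delta", "log_shape"))

  logpost <- make_logpost(view, family, prior, fix_ancillary)
  mle <- aft_mle(view, family, fix_ancillary)
  init <- rep(0, k)
  prop0 <- diag(0.01, k)
  if (!is.null(mle)) {
    init <- mle$par
    if (is.null(fix_ancillary)) init[k] <- mle$par[k]
    if (!is.null(mle$vcov)) prop0 <- mle$vcov
  }
  if (!is.finite(logpost(init))) {
    init <- rep(0, k)
    if (!is.finite(logpost(init)))
      stopf(paste("log posterior is non-finite at the initial value;",
                  "consider rescaling covariates"))
  }

  n_keep <- (control$n_iter - control$n_burnin) %/% control$thin
  chains <- vector("list", control$n_chains)
  accept <- numeric(control$n_chains)

  for (ch in seq_len(control$n_chains)) {
    set.seed(derive_seed(control$seed, "chain", ch))
    res <- rwm_chain(logpost, init, prop0, control$n_iter, control$n_burnin,
                     control$thin)
    chains[[ch]] <- res$draws
    accept[ch] <- res$accept_rate
  }

  draws <- do.call(rbind, chains)
  colnames(draws) <- par_names
  chain_id <- rep(seq_len(control$n_chains), each = n_keep)
  rhat <- split_rhat(chains)
  names(rhat) <- par_names
  if (any(rhat > 1.1, na.rm = TRUE))
    warnf("R-hat > 1.1 for: %s (consider longer chains)",
          paste(par_names[which(rhat > 1.1)], collapse = ", "))

  structure(list(draws = draws, par_names = par_names, chain_id = chain_id,
                 n_chains = control$n_chains, n_iter = control$n_iter,
                 n_burnin = control$n_burnin, thin = control$thin,
                 seed = control$seed, acceptance_rate = accept, rhat = rhat,
                 family = family, cause = view$cause,
                 fix_ancillary = fix_ancillary, mle = mle),
            class = "baft_draws")
}

# One adaptive random-walk Metropolis chain. Adaptation (empirical
# covariance + Robbins-Monro scale toward 0.234) runs during burn-in only.
rwm_chain <- function(logpost, init, prop0, n_iter, n_burnin, thin) {
  k <- length(init)
  theta <- init
  lp <- logpost(theta)
  L <- chol(prop0 + diag(1e-10, k))
  log_scale <- log(2.38 / sqrt(k))
  target <- 0.234

  # running moments for covariance adaptation
  run_mean <- theta
  run_cov <- prop0
  n_keep <- (n_iter - n_burnin) %/% thin
  out <- matrix(NA_real_, n_keep, k)
  kept <- 0L
  acc_post <- 0L
  n_post <- 0L
  acc_win <- 0L

  for (i in seq_len(n_iter)) {
    prop <- theta + exp(log_scale) * drop(crossprod(L, stats::rnorm(k)))
    lp_prop <- logpost(prop)
    if (is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp) {
      theta <- prop
      lp <- lp_prop
      acc_win <- acc_win + 1L
      if (i > n_burnin) acc_post <- acc_post + 1L
    }
    if (i > n_burnin) n_post <- n_post + 1L

    if (i <= n_burnin) {
      # running covariance (Welford)
      w <- 1 / (i + 1)
      dtheta <- theta - run_mean
      run_mean <- run_mean + w * dtheta
      run_cov <- (1 - w) * (run_cov + w * tcrossprod(dtheta))
      if (i %% 50L == 0L) {
        log_scale <- log_scale + (acc_win / 50 - target) / sqrt(i / 50)
        acc_win <- 0L
        if (i >= 200L)
          L <- chol(run_cov + diag(1e-8, k))
      }
    } else if ((i - n_burnin) %% thin == 0L && kept < n_keep) {
      kept <- kept + 1L
      out[kept, ] <- theta
    }
  }
  list(draws = out, accept_rate = if (n_post > 0) acc_post / n_post else NA_real_)
}

# Split R-hat (each chain halved), standard between/within variance ratio
split_rhat <- function(chains) {
  halves <- list()
  for (m in chains) {
    n <- nrow(m)
    if (n < 4) return(rep(NA_real_, ncol(chains[[1]])))
    h <- n %/% 2
    halves <- c(halves, list(m[seq_len(h), , drop = FALSE],
                             m[(h + 1):(2 * h), , drop = FALSE]))
  }
  vapply(seq_len(ncol(chains[[1]])), function(j) {
    x <- vapply(halves, function(m) c(mean(m[, j]), stats::var(m[, j])),
                numeric(2))
    W <- mean(x[2, ])
    B <- stats::var(x[1, ]) * nrow(halves[[1]])
    if (W <= 0) return(NA_real_)
    n <- nrow(halves[[1]])
    sqrt(((n - 1) / n * W + B / n) / W)
  }, numeric(1))
}

#' @export
print.baft_draws <- function(x, ...) {
  cat(sprintf(
    "<baft_draws> %s AFT, cause=%s | %d chains x %d kept (burn-in %d)\n",
    x$family, x$cause %||% "?", x$n_chains, nrow(x$draws) / x$n_chains,
    x$n_burnin))
  cat(sprintf("  acceptance: %s | max R-hat: %.3f\n",
              paste(sprintf("%.2f", x$acceptance_rate), collapse = ", "),
              max(x$rhat, na.rm = TRUE)))
  invisible(x)
}

#' Export posterior draws as delimited text
#'
#' Writes one row per retained iteration with chain id and one column per
#' parameter, for external diagnostics.
#'
#' @param draws a `baft_draws` object (or a fitted [baft] model).
#' @param path output path.
#' @export
write_draws <- function(draws, path) {
  if (inherits(draws, "baft")) draws <- draws$draws_obj
  stopifnot(inherits(draws, "baft_draws"))
  df <- data.frame(iteration = ave(draws$chain_id, draws$chain_id,
                                   FUN = seq_along),
                   chain = draws$chain_id)
  df <- cbind(df, as.data.frame(draws$draws))
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
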