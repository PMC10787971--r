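#' Pointwise log-likelihood matrix over posterior draws
#'
#' Entry (s, i) is subject i's censored log-likelihood contribution
#' \eqn{d_i \log f(t_i) + (1-d_i)\log S(t_i)} evaluated at draw s: the
#' shared kernel of WAIC, LPML and DIC.
#'
#' @param fit a fitted [baft] model (or a `baft_draws` plus `view`/`family`).
#' @param view a [cause_specific_view]; defaults to the fit's own view.
#' @return matrix (retained draws x subjects).
#' @export
pointwise_loglik <- function(fit, view = NULL) {
  stopifnot(inherits(fit, "baft"))
  view <- view %||% fit$view
  B <- beta_draws(fit)
  anc <- ancillary_draws(fit)
  S <- nrow(B)
  n <- length(view$times)
  LP <- B %*% t(view$design)             # draws x subjects
  e <- view$d == 1
  out <- matrix(NA_real_, S, n)
  for (s in seq_len(S)) {
    out[s, e] <- aft_logf(fit$family, view$times[e], LP[s, e], anc[s])
    if (any(!e))
      out[s, !e] <- aft_logS(fit$family, view$times[!e], LP[s, !e], anc[s])
  }
  if (any(!is.finite(out))) {
    bad <- which(!is.finite(out), arr.ind = TRUE)[1, ]
    stopf("non-finite pointwise log-likelihood at draw %d, subject %d",
          bad[1], bad[2])
  }
  out
}

#' Deviance information criterion
#'
#' \eqn{DIC = \bar D + p_D} with deviance \eqn{D(\theta) = -2\,\ell(\theta)},
#' \eqn{\bar D} the posterior mean deviance, and
#' \eqn{p_D = \bar D - D(\bar\theta)} evaluated at the posterior mean of
#' the sampling-scale parameters (coefficients and log ancillary, then
#' back-transformed), which keeps \eqn{p_D} invariant to the positivity
#' reparameterisation. Lower is better.
#'
#' @param fit a fitted [baft] model.
#' @param pointwise optional precomputed [pointwise_loglik] matrix.
#' @return the DIC value, with attributes `pD` and `Dbar`; a warning is
#'   attached when `pD < 0` (poorly identified posterior).
#' @export
dic <- function(fit, pointwise = NULL) {
  stopifnot(inherits(fit, "baft"))
  pointwise <- pointwise %||% pointwise_loglik(fit)
  Dbar <- mean(-2 * rowSums(pointwise))
  theta_bar <- colMeans(fit$draws)
  p <- ncol(fit$view$design)
  anc_bar <- if (!is.null(fit$fix_ancillary)) fit$fix_ancillary
             else exp(theta_bar[p + 1L])
  D_at_mean <- -2 * censored_loglik(fit$family, theta_bar[seq_len(p)],
                                    anc_bar, fit$view$design,
                                    fit$view$times, fit$view$d)
  pD <- Dbar - D_at_mean
  if (pD < 0) warnf("negative effective parameter count (pD = %.3f)", pD)
  structure(Dbar + pD, pD = pD, Dbar = Dbar)
}

#' Watanabe-Akaike information criterion
#'
#' \eqn{WAIC = -2(\mathrm{lppd} - p_{WAIC})} with
#' \eqn{\mathrm{lppd} = \sum_i \log \mathrm{mean}_s \exp(\ell_{si})}
#' (computed by log-sum-exp) and
#' \eqn{p_{WAIC} = \sum_i \mathrm{var}_s(\ell_{si})}. Lower is better.
#'
#' @param pointwise a [pointwise_loglik] matrix (>= 2 draws).
#' @return the WAIC value with attributes `lppd` and `pwaic`.
#' @export
waic <- function(pointwise) {
  stopifnot(is.matrix(pointwise), nrow(pointwise) >= 2)
  lppd <- sum(apply(pointwise, 2, logmeanexp))
  pwaic <- sum(apply(pointwise, 2, stats::var))
  structure(-2 * (lppd - pwaic), lppd = lppd, pwaic = pwaic)
}

#' Log pseudo-marginal likelihood
#'
#' \eqn{LPML = \sum_i \log CPO_i} with the conditional predictive ordinate
#' estimated by the harmonic mean over draws,
#' \eqn{CPO_i = [\mathrm{mean}_s \exp(-\ell_{si})]^{-1}}, computed in log
#' space. Higher is better.
#'
#' @inheritParams waic
#' @return the LPML value.
#' @export
lpml <- function(pointwise) {
  stopifnot(is.matrix(pointwise), nrow(pointwise) >= 2)
  sum(-apply(-pointwise, 2, logmeanexp))
}

#' Compare candidate AFT families by DIC, WAIC and LPML
#'
#' Fits each family to the same cause-specific view with the same prior
#' and sampler settings and tabulates the three criteria. The selected
#' family minimises DIC (ties resolve to the first family in the supplied
#' order and are flagged); WAIC and LPML are reported alongside.
#'
#' @param view a [cause_specific_view].
#' @param families candidate families, default all three.
#' @param prior_variance prior variance.
#' @param control a [mcmc_control].
#' @return a `baft_comparison`: data frame (`family`, `waic`, `lpml`,
#'   `dic`) with attributes `best_family` and the fitted models in
#'   `attr(, "fits")`. A family whose fit fails is dropped with a warning
#'   provided at least one succeeds.
#' @export
compare_families <- function(view, families = aft_families,
                             prior_variance = 10000,
                             control = mcmc_control()) {
  stopifnot(length(families) >= 1)
  fits <- list()
  rows <- list()
  for (fam in families) {
    fit <- try(baft(view, family = fam, prior_variance = prior_variance,
                    control = control), silent = TRUE)
    if (inherits(fit, "try-error")) {
      warnf("family '%s' failed to fit: %s", fam,
            attr(fit, "condition")$message)
      next
    }
    pw <- pointwise_loglik(fit)
    rows[[fam]] <- data.frame(family = fam,
                              waic = as.numeric(waic(pw)),
                              lpml = lpml(pw),
                              dic = as.numeric(suppressWarnings(dic(fit, pw))),
                              stringsAsFactors = FALSE)
    fits[[fam]] <- fit
  }
  if (!length(rows)) stopf("every candidate family failed to fit")
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  best <- tab$family[which.min(tab$dic)]
  tied <- sum(tab$dic == min(tab$dic)) > 1
  structure(tab, best_family = best, tie = tied, fits = fits,
            class = c("baft_comparison", "data.frame"))
}

#' @export
print.baft_comparison <- function(x, ...) {
  cat("AFT family comparison (lower DIC/WAIC better, higher LPML better)\n")
  df <- as.data.frame(x)
  df$waic <- sprintf("%.3f", df$waic)
  df$lpml <- sprintf("%.3f", df$lpml)
  df$dic <- sprintf("%.3f", df$dic)
  print(df, row.names = FALSE)
  cat(sprintf("Selected by DIC: %s%s\n", attr(x, "best_family"),
              if (isTRUE(attr(x, "tie"))) " (tie, first in order)" else ""))
  invisible(x)
}

#' Write a family-comparison table as delimited text
#'
#' @param comparison a `baft_comparison`.
#' @param path output path.
#' @export
write_comparison <- function(comparison, path) {
  df <- as.data.frame(comparison)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
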