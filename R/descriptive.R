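#' Person-time mortality rate with exact Poisson interval
#'
#' Cause-specific failures divided by total follow-up, reported per 1000
#' person-months. The 95% interval treats the failure count as Poisson and
#' uses the exact (gamma / chi-square quantile) limits; the lower limit is
#' 0 when no failures occur.
#'
#' @param view a [cause_specific_view].
#' @param stratum optional logical or integer index selecting a subject
#'   subset (default: everyone).
#' @param per rate denominator (default 1000 person-months).
#' @param conf confidence level.
#' @return a `baft_rate` list: `failures`, `person_time`, `rate`,
#'   `ci_low`, `ci_high`.
#' @export
person_time_rate <- function(view, stratum = NULL, per = 1000, conf = 0.95) {
  stopifnot(inherits(view, "baft_view"))
  d <- view$d
  t <- view$times
  if (!is.null(stratum)) {
    d <- d[stratum]
    t <- t[stratum]
  }
  if (!length(t)) stopf("empty stratum")
  f <- sum(d)
  pt <- sum(t)
  if (pt <= 0) stopf("nonpositive person-time")
  a <- (1 - conf) / 2
  lo <- if (f == 0) 0 else stats::qgamma(a, f) / pt
  hi <- stats::qgamma(1 - a, f + 1) / pt
  structure(list(failures = f, person_time = pt, rate = per * f / pt,
                 ci_low = per * lo, ci_high = per * hi, per = per),
            class = "baft_rate")
}

#' @export
print.baft_rate <- function(x, ...) {
  cat(sprintf("%d failures / %.1f person-months: %.2f per %g (%.2f-%.2f)\n",
              x$failures, x$person_time, x$rate, x$per, x$ci_low, x$ci_high))
  invisible(x)
}

#' Kaplan-Meier product-limit estimate
#'
#' Cause-specific product-limit survival curve: competing-cause deaths
#' enter as censored, matching the likelihood's indicator coding, so the
#' curve is a cause-specific quantity, not a marginal cumulative-incidence
#' complement. Deaths precede censorings at tied times. The variance is
#' Greenwood's; intervals are on the plain probability scale by default
#' (truncated to [0, 1]), with a log-log option.
#'
#' @param view a [cause_specific_view].
#' @param stratum optional subject subset as in [person_time_rate].
#' @param conf confidence level.
#' @param conf_type `"plain"` or `"log-log"`.
#' @return a `baft_km` list with `time` (event times), `n_risk`,
#'   `n_event`, `surv`, `var` (Greenwood), `ci_low`, `ci_high`.
#' @export
km_curve <- function(view, stratum = NULL, conf = 0.95,
                     conf_type = c("plain", "log-log")) {
  stopifnot(inherits(view, "baft_view"))
  conf_type <- match.arg(conf_type)
  d <- view$d
  t <- view$times
  if (!is.null(stratum)) {
    d <- d[stratum]
    t <- t[stratum]
  }
  if (!length(t)) stopf("empty stratum")
  et <- sort(unique(t[d == 1]))
  n_risk <- vapply(et, function(u) sum(t >= u), numeric(1))
  n_event <- vapply(et, function(u) sum(t == u & d == 1), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  gw <- surv^2 * cumsum(n_event / (n_risk * (n_risk - n_event)))
  gw[n_risk == n_event] <- 0  # curve hits zero; variance degenerates
  z <- stats::qnorm(1 - (1 - conf) / 2)
  if (conf_type == "plain") {
    lo <- pmax(0, surv - z * sqrt(gw))
    hi <- pmin(1, surv + z * sqrt(gw))
  } else {
    se_cll <- sqrt(gw) / (surv * abs(log(surv)))
    lo <- surv^exp(z * se_cll)
    hi <- surv^exp(-z * se_cll)
    lo[!is.finite(lo)] <- 0
    hi[!is.finite(hi)] <- 1
  }
  structure(list(time = et, n_risk = n_risk, n_event = n_event, surv = surv,
                 var = gw, ci_low = lo, ci_high = hi, conf = conf,
                 conf_type = conf_type, n = length(t)),
            class = "baft_km")
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' Step-function convention: the estimate at `t` is the value at the
#' largest event time not exceeding `t` (1 before the first event).
#'
#' @param km a `baft_km`.
#' @param times evaluation times.
#' @return data frame `time`, `surv`, `ci_low`, `ci_high`.
#' @export
km_at <- function(km, times) {
  stopifnot(inherits(km, "baft_km"))
  idx <- findInterval(times, km$time)
  surv <- ifelse(idx == 0, 1, km$surv[pmax(idx, 1)])
  lo <- ifelse(idx == 0, 1, km$ci_low[pmax(idx, 1)])
  hi <- ifelse(idx == 0, 1, km$ci_high[pmax(idx, 1)])
  data.frame(time = times, surv = surv, ci_low = lo, ci_high = hi)
}

#' @export
print.baft_km <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d subjects, %d event times, S(max) = %.3f\n",
              x$n, length(x$time),
              if (length(x$surv)) x$surv[length(x$surv)] else 1))
  invisible(x)
}

#' Log-rank test across covariate groups
#'
#' Standard observed-minus-expected log-rank statistic over the pooled
#' event times, with the hypergeometric covariance. With
#' `trend = TRUE` the groups receive integer scores 0, 1, 2, ... in level
#' order and the 1-df trend statistic is returned instead of the
#' (k-1)-df heterogeneity statistic.
#'
#' @param view a [cause_specific_view].
#' @param group a factor/vector of group labels (one per subject) or the
#'   name of a declared covariate when `cohort` is supplied.
#' @param trend use the ordered 1-df trend variant.
#' @param scores optional numeric scores for the trend test (defaults to
#'   0, 1, 2, ... in level order).
#' @return a `baft_logrank` list: `chi_square`, `df`, `p_value`, `groups`,
#'   per-group observed and expected counts.
#' @export
log_rank <- function(view, group, trend = FALSE, scores = NULL) {
  stopifnot(inherits(view, "baft_view"))
  g <- factor(group)
  if (length(g) != length(view$times))
    stopf("'group' must have one label per subject")
  if (any(table(g) == 0) || nlevels(g) < 2)
    stopf("need at least two nonempty groups")
  k <- nlevels(g)
  t <- view$times
  d <- view$d
  et <- sort(unique(t[d == 1]))
  O <- E <- numeric(k)
  V <- matrix(0, k, k)
  for (u in et) {
    at <- t >= u
    n_j <- sum(at)
    d_j <- sum(t == u & d == 1)
    n_gj <- vapply(levels(g), function(l) sum(at & g == l), numeric(1))
    d_gj <- vapply(levels(g), function(l) sum(t == u & d == 1 & g == l),
                   numeric(1))
    O <- O + d_gj
    E <- E + d_j * n_gj / n_j
    if (n_j > 1) {
      c_j <- d_j * (n_j - d_j) / (n_j - 1)
      V <- V + c_j * (diag(n_gj / n_j, k) - tcrossprod(n_gj / n_j))
    }
  }
  if (trend) {
    sc <- scores %||% (seq_len(k) - 1)
    if (length(sc) != k) stopf("need one score per group")
    num <- sum(sc * (O - E))^2
    den <- drop(t(sc) %*% V %*% sc)
    chi <- if (den > 0) num / den else 0
    df <- 1L
  } else {
    z <- (O - E)[-k]
    Vs <- V[-k, -k, drop = FALSE]
    chi <- tryCatch(drop(t(z) %*% solve(Vs, z)), error = function(e) 0)
    df <- k - 1L
  }
  structure(list(chi_square = chi, df = df,
                 p_value = stats::pchisq(chi, df, lower.tail = FALSE),
                 groups = levels(g), observed = O, expected = E,
                 trend = trend),
            class = "baft_logrank")
}

#' @export
print.baft_logrank <- function(x, ...) {
  cat(sprintf("%s test: chi-square = %.3f on %d df, p = %.4g\n",
              if (x$trend) "Log-rank trend" else "Log-rank",
              x$chi_square, x$df, x$p_value))
  invisible(x)
}

#' Descriptive mortality report for a competing-risks cohort
#'
#' For each cause: overall and per-covariate-level person-time mortality
#' rates (per 1000 person-months, exact Poisson intervals) with a
#' log-rank p-value per covariate (trend variant for ordinal covariates),
#' plus Kaplan-Meier survival at chosen horizons. Continuous covariates
#' get the trend log-rank on their cohort values split at the median
#' unless declared ordinal.
#'
#' @param cohort a `baft_cohort`.
#' @param causes causes to report.
#' @param km_times horizons (months) for the survival estimates; the
#'   default is 1, 3 and 5 years.
#' @return a `baft_description` list.
#' @export
describe_cohort <- function(cohort, causes = c("hf", "non_hf"),
                            km_times = c(12, 36, 60)) {
  stopifnot(inherits(cohort, "baft_cohort"))
  specs <- attr(cohort, "specs")
  out <- list()
  for (cause in causes) {
    v <- cause_specific_view(cohort, cause)
    overall <- person_time_rate(v)
    km <- km_curve(v)
    km_tab <- km_at(km, km_times)
    rows <- list()
    for (s in specs) {
      if (s$kind == "continuous") {
        vals <- as.numeric(cohort[[s$name]])
        grp <- factor(ifelse(vals <= stats::median(vals), "low", "high"),
                      levels = c("low", "high"))
        lr <- log_rank(v, grp, trend = TRUE)
        levels_used <- levels(grp)
      } else {
        grp <- factor(as.character(cohort[[s$name]]), levels = s$levels)
        lr <- log_rank(v, grp, trend = (s$kind == "ordinal"))
        levels_used <- s$levels
      }
      for (l in levels_used) {
        r <- person_time_rate(v, stratum = grp == l)
        rows[[paste(s$name, l)]] <- data.frame(
          covariate = s$name, level = l, failures = r$failures,
          person_time = r$person_time, rate = r$rate,
          ci_low = r$ci_low, ci_high = r$ci_high,
          logrank_p = lr$p_value, stringsAsFactors = FALSE)
      }
    }
    out[[cause]] <- list(overall = overall, km = km, km_at = km_tab,
                         rates = if (length(rows)) do.call(rbind, rows)
                                 else NULL)
    if (!is.null(out[[cause]]$rates)) rownames(out[[cause]]$rates) <- NULL
  }
  structure(list(causes = out, summary = summary(cohort),
                 km_times = km_times),
            class = "baft_description")
}

#' @export
print.baft_description <- function(x, digits = 2, ...) {
  print(x$summary)
  for (cause in names(x$causes)) {
    cc <- x$causes[[cause]]
    cat(sprintf("\n-- %s-related mortality --\n",
                if (cause == "hf") "HF" else "non-HF"))
    cat(sprintf("  overall rate: %.2f per 1000 person-months (%.2f-%.2f)\n",
                cc$overall$rate, cc$overall$ci_low, cc$overall$ci_high))
    for (i in seq_len(nrow(cc$km_at)))
      cat(sprintf("  S(%g months) = %.2f%% (%.2f-%.2f)\n",
                  cc$km_at$time[i], 100 * cc$km_at$surv[i],
                  cc$km_at$ci_low[i], cc$km_at$ci_high[i]))
    if (!is.null(cc$rates)) {
      cat("  per-level rates (per 1000 person-months):\n")
      for (i in seq_len(nrow(cc$rates)))
        cat(sprintf("    %-18s %-10s %5.2f (%.2f-%.2f)  p=%.3f\n",
                    cc$rates$covariate[i], cc$rates$level[i],
                    cc$rates$rate[i], cc$rates$ci_low[i],
                    cc$rates$ci_high[i], cc$rates$logrank_p[i]))
    }
  }
  invisible(x)
}

#' Write the descriptive report as delimited text
#'
#' @param description a `baft_description`.
#' @param path output path (one file, sections separated by cause).
#' @export
write_description <- function(description, path) {
  stopifnot(inherits(description, "baft_description"))
  con <- file(path, "w")
  on.exit(close(con))
  s <- description$summary
  writeLines(sprintf("n\t%d", s$n), con)
  writeLines(sprintf("hf_deaths\t%d\t%.1f", s$n_hf, s$pct_hf), con)
  writeLines(sprintf("non_hf_deaths\t%d\t%.1f", s$n_non_hf, s$pct_non_hf), con)
  writeLines(sprintf("censored\t%d\t%.1f", s$n_censored, s$pct_censored), con)
  for (cause in names(description$causes)) {
    cc <- description$causes[[cause]]
    writeLines(sprintf("## cause\t%s", cause), con)
    writeLines(sprintf("overall_rate\t%.4f\t%.4f\t%.4f", cc$overall$rate,
                       cc$overall$ci_low, cc$overall$ci_high), con)
    for (i in seq_len(nrow(cc$km_at)))
      writeLines(sprintf("km\t%g\t%.4f\t%.4f\t%.4f", cc$km_at$time[i],
                         cc$km_at$surv[i], cc$km_at$ci_low[i],
                         cc$km_at$ci_high[i]), con)
    if (!is.null(cc$rates)) {
      writeLines(paste(colnames(cc$rates), collapse = "\t"), con)
      utils::write.table(cc$rates, con, sep = "\t", row.names = FALSE,
                         col.names = FALSE, quote = FALSE)
    }
  }
  invisible(path)
}
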