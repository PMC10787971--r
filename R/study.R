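#' Configuration of the full competing-risks study pipeline
#'
#' Bundles every tunable of [run_study]: which causes to analyse, the
#' candidate AFT families, the prior-variance grid of the sensitivity
#' layer, the univariable screening rule, and the shared MCMC settings.
#' All randomness flows from `seed`, expanded deterministically into
#' per-cause, per-stage substreams, so the two causes' results are
#' independent of whether the other branch runs.
#'
#' @param causes causes to analyse.
#' @param families candidate families for model selection.
#' @param prior_variance_grid ascending positive variances for the
#'   sensitivity analysis.
#' @param reference_variance the variance used for the headline fits and
#'   as the sensitivity reference column.
#' @param sensitivity_threshold flag a covariate when its time ratio moves
#'   by more than this relative fraction (default 0.10) at any grid value.
#' @param family_scope `"pooled"`: one family comparison on the first
#'   cause, applied to every cause (a single comparison table);
#'   `"per_cause"`: one comparison per cause.
#' @param control a [mcmc_control] template (its seed is overridden by the
#'   derived substreams).
#' @param seed master seed.
#' @return a `study_config`.
#' @export
study_config <- function(causes = c("hf", "non_hf"),
                         families = aft_families,
                         prior_variance_grid = c(1, 10, 100, 1000, 10000),
                         reference_variance = 10000,
                         sensitivity_threshold = 0.10,
                         family_scope = c("pooled", "per_cause"),
                         control = mcmc_control(), seed = 1) {
  stopifnot(all(causes %in% c("hf", "non_hf")),
            all(prior_variance_grid > 0),
            !is.unsorted(prior_variance_grid),
            sensitivity_threshold > 0, sensitivity_threshold < 1,
            reference_variance > 0)
  family_scope <- match.arg(family_scope)
  structure(list(causes = causes, families = families,
                 prior_variance_grid = prior_variance_grid,
                 reference_variance = reference_variance,
                 sensitivity_threshold = sensitivity_threshold,
                 family_scope = family_scope, control = control,
                 seed = as.integer(seed)),
            class = "study_config")
}

ctl_with_seed <- function(control, seed) {
  control$seed <- seed
  control
}

#' Select the best-fitting AFT family for one cause
#'
#' Fits every candidate family to the cause-specific view with the full
#' covariate set and returns the DIC-minimising family together with the
#' criterion table (see [compare_families]).
#'
#' @param cohort a `baft_cohort`.
#' @param cause event cause.
#' @param config a [study_config].
#' @return list `family`, `comparison`.
#' @export
select_family <- function(cohort, cause, config = study_config()) {
  v <- cause_specific_view(cohort, cause)
  cmp <- compare_families(
    v, families = config$families,
    prior_variance = config$reference_variance,
    control = ctl_with_seed(config$control,
                            derive_seed(config$seed, cause, "select")))
  list(family = attr(cmp, "best_family"), comparison = cmp)
}

#' Univariable screening of covariates
#'
#' One single-covariate Bayesian AFT fit per declared covariate
#' (multi-level covariates enter as their whole dummy or trend block). A
#' covariate passes the screen when any of its time-ratio intervals
#' excludes 1. A covariate whose fit fails is dropped with a warning.
#'
#' @inheritParams select_family
#' @param family AFT family to use.
#' @return list `fits` (named [summary.baft] list), `significant`
#'   (character vector of screened-in covariates), `table` (stacked
#'   time-ratio rows with a `covariate` column).
#' @export
univariable_screen <- function(cohort, cause, family,
                               config = study_config()) {
  specs <- attr(cohort, "specs")
  covnames <- vapply(specs, `[[`, "", "name")
  if (!length(covnames)) stopf("cohort declares no covariates")
  fits <- list()
  rows <- list()
  sig <- character(0)
  for (nm in covnames) {
    fit <- try(baft(cohort, cause = cause, covariates = nm, family = family,
                    prior_variance = config$reference_variance,
                    control = ctl_with_seed(
                      config$control,
                      derive_seed(config$seed, cause, "uni", nm))),
               silent = TRUE)
    if (inherits(fit, "try-error")) {
      warnf("univariable fit for '%s' (%s) failed; covariate dropped",
            nm, cause)
      next
    }
    s <- summary(fit)
    fits[[nm]] <- s
    tab <- s$time_ratios
    tab <- cbind(covariate = nm, tab)
    rows[[nm]] <- tab
    if (any(tab$significant)) sig <- c(sig, nm)
  }
  if (!length(fits)) stopf("every univariable fit failed for cause '%s'", cause)
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(fits = fits, significant = sig, table = tab)
}

#' Multivariable Bayesian AFT fit of the screened-in covariates
#'
#' @inheritParams univariable_screen
#' @param selected covariate names to include jointly (normally the
#'   screen's significant set).
#' @param prior_variance prior variance (defaults to the config
#'   reference).
#' @return the fitted [baft] model.
#' @export
multivariable_fit <- function(cohort, cause, family, selected,
                              config = study_config(),
                              prior_variance = config$reference_variance) {
  if (!length(selected)) stopf("'selected' must name at least one covariate")
  baft(cohort, cause = cause, covariates = selected, family = family,
       prior_variance = prior_variance,
       control = ctl_with_seed(config$control,
                               derive_seed(config$seed, cause, "multi")))
}

#' Prior-variance sensitivity analysis
#'
#' Refits the multivariable model at every prior variance in the grid
#' (same derived seed at each level, so only the prior changes) and
#' compares each level's posterior-median time ratios with the
#' reference-variance column. A covariate column is flagged when its
#' relative change `|TR_v - TR_ref| / TR_ref` exceeds the configured
#' threshold at any grid value. Point estimates drive the flag; intervals
#' are reported alongside.
#'
#' @inheritParams multivariable_fit
#' @return a `baft_sensitivity`: `$table` (term x variance TRs with CIs),
#'   `$max_change` (per term), `$flagged` (term names), `$threshold`.
#' @export
sensitivity_analysis <- function(cohort, cause, family, selected,
                                 config = study_config()) {
  grid <- config$prior_variance_grid
  if (!length(grid)) stopf("empty prior-variance grid")
  ref_v <- config$reference_variance
  all_v <- unique(c(grid, ref_v))
  fits <- list()
  for (v in all_v) {
    fit <- try(multivariable_fit(cohort, cause, family, selected, config,
                                 prior_variance = v), silent = TRUE)
    if (inherits(fit, "try-error")) {
      warnf("sensitivity refit at variance %g failed", v)
      next
    }
    fits[[as.character(v)]] <- summary(fit)$time_ratios
  }
  if (is.null(fits[[as.character(ref_v)]]))
    stopf("reference-variance fit failed; sensitivity table undefined")
  ref <- fits[[as.character(ref_v)]]
  terms <- ref$term
  tab <- do.call(rbind, lapply(names(fits), function(v) {
    cbind(variance = as.numeric(v), fits[[v]])
  }))
  rownames(tab) <- NULL
  fl <- sensitivity_flags(tab, ref_v, config$sensitivity_threshold,
                          grid = grid)
  rel_change <- fl$max_change
  flagged <- fl$flagged
  structure(list(table = tab, max_change = rel_change, flagged = flagged,
                 threshold = config$sensitivity_threshold,
                 reference_variance = ref_v, cause = cause),
            class = "baft_sensitivity")
}

#' @export
print.baft_sensitivity <- function(x, ...) {
  cat(sprintf(
    "Prior-variance sensitivity (reference %g, flag at >%.0f%% TR change)\n",
    x$reference_variance, 100 * x$threshold))
  for (tm in names(x$max_change))
    cat(sprintf("  %-28s max change %5.1f%%%s\n", tm,
                100 * x$max_change[[tm]],
                if (tm %in% x$flagged) "  *" else ""))
  invisible(x)
}

#' Apply the prior-sensitivity flag rule to a time-ratio table
#'
#' The rule compares posterior-median time ratios at each prior variance
#' with the reference-variance column: the relative change is
#' `|TR_v - TR_ref| / TR_ref`, and a term is flagged when its largest
#' change over the grid exceeds `threshold`. A degenerate grid (only the
#' reference) flags nothing.
#'
#' @param table long data frame with columns `variance`, `term`, `tr`.
#' @param reference_variance the reference column's variance.
#' @param threshold relative-change threshold (default 0.10).
#' @param grid variances to scan (default: all non-reference values in
#'   `table`).
#' @return list `max_change` (named per term) and `flagged`.
#' @examples
#' tab <- data.frame(variance = c(10000, 1000), term = "chest_pain",
#'                   tr = c(0.41, 0.46))
#' sensitivity_flags(tab, 10000)   # 12.2% change -> flagged
#' @export
sensitivity_flags <- function(table, reference_variance, threshold = 0.10,
                              grid = NULL) {
  stopifnot(all(c("variance", "term", "tr") %in% names(table)))
  ref <- table[table$variance == reference_variance, , drop = FALSE]
  if (!nrow(ref)) stopf("reference variance %g not present", reference_variance)
  grid <- grid %||% setdiff(unique(table$variance), reference_variance)
  grid <- setdiff(grid, reference_variance)
  terms <- unique(ref$term)
  max_change <- vapply(terms, function(tm) {
    tr_ref <- ref$tr[ref$term == tm][1]
    ch <- vapply(grid, function(v) {
      tr_v <- table$tr[table$variance == v & table$term == tm]
      if (!length(tr_v)) return(NA_real_)
      abs(tr_v[1] - tr_ref) / tr_ref
    }, numeric(1))
    if (all(is.na(ch)) || !length(ch)) NA_real_ else max(ch, na.rm = TRUE)
  }, numeric(1))
  names(max_change) <- terms
  list(max_change = max_change,
       flagged = terms[!is.na(max_change) & max_change > threshold])
}

#' Run the full competing-risks study
#'
#' Per cause: DIC family selection, univariable screening, multivariable
#' modelling of the screened-in covariates, and prior-variance
#' sensitivity analysis. With the default pooled family scope the
#' comparison is run once (on the first cause) and the selected family is
#' used for both causes. A stage failure aborts that cause's branch;
#' the other cause still runs. Deterministic given `config$seed`.
#'
#' @param cohort a `baft_cohort`.
#' @param config a [study_config].
#' @return a `baft_study`: per cause a list with `family`, `comparison`,
#'   `univariable`, `multivariable` (a [summary.baft]; `NULL` with an
#'   `error` field if the screen selected nothing), `sensitivity`; plus
#'   the config echo.
#' @export
run_study <- function(cohort, config = study_config()) {
  stopifnot(inherits(cohort, "baft_cohort"))
  pooled <- NULL
  if (config$family_scope == "pooled")
    pooled <- select_family(cohort, config$causes[1], config)
  res <- list()
  for (cause in config$causes) {
    res[[cause]] <- tryCatch({
      sel <- if (!is.null(pooled)) pooled
             else select_family(cohort, cause, config)
      uni <- univariable_screen(cohort, cause, sel$family, config)
      if (length(uni$significant)) {
        mfit <- multivariable_fit(cohort, cause, sel$family,
                                  uni$significant, config)
        msum <- summary(mfit)
        sens <- sensitivity_analysis(cohort, cause, sel$family,
                                     uni$significant, config)
      } else {
        msum <- NULL
        sens <- NULL
      }
      list(family = sel$family, comparison = sel$comparison,
           univariable = uni, multivariable = msum, sensitivity = sens,
           error = NULL)
    }, error = function(e) list(error = conditionMessage(e)))
  }
  structure(list(causes = res, config = config, seed = config$seed,
                 n = nrow(cohort)),
            class = "baft_study")
}

#' @export
print.baft_study <- function(x, ...) {
  cat(sprintf("Competing-risks Bayesian AFT study (n = %d, seed %d)\n",
              x$n, x$seed))
  for (cause in names(x$causes)) {
    cc <- x$causes[[cause]]
    cat(sprintf("\n== cause: %s ==\n", cause))
    if (!is.null(cc$error)) {
      cat("  FAILED:", cc$error, "\n")
      next
    }
    cat(sprintf("  selected family: %s\n", cc$family))
    cat(sprintf("  screened-in covariates: %s\n",
                if (length(cc$univariable$significant))
                  paste(cc$univariable$significant, collapse = ", ")
                else "(none)"))
    if (!is.null(cc$multivariable)) {
      cat("  multivariable time ratios:\n")
      tab <- cc$multivariable$time_ratios
      for (i in seq_len(nrow(tab)))
        cat(sprintf("    %-28s %5.2f (%.2f-%.2f)%s\n", tab$term[i],
                    tab$tr[i], tab$ci_low[i], tab$ci_high[i],
                    if (tab$significant[i]) " *" else ""))
      if (length(cc$sensitivity$flagged))
        cat(sprintf("  prior-sensitive terms (>%.0f%%): %s\n",
                    100 * cc$sensitivity$threshold,
                    paste(cc$sensitivity$flagged, collapse = ", ")))
    }
  }
  invisible(x)
}

#' Write a study report as per-table delimited files
#'
#' Emits `comparison_<cause>.tsv`, `univariable_<cause>.tsv`,
#' `multivariable_<cause>.tsv` and `sensitivity_<cause>.tsv` per analysed
#' cause. Multivariable tables list every screened covariate; rows for
#' covariates outside the cause's selected set carry `NC` (not computed).
#' Time ratios are rendered to 2 decimals; full precision stays in the
#' returned objects.
#'
#' @param study a `baft_study`.
#' @param dir output directory (created if missing).
#' @return character vector of written file paths.
#' @export
write_study_report <- function(study, dir) {
  stopifnot(inherits(study, "baft_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fmt <- function(x) sprintf("%.2f", x)
  files <- character(0)
  emit <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", row.names = FALSE, quote = FALSE)
    files <<- c(files, p)
  }
  for (cause in names(study$causes)) {
    cc <- study$causes[[cause]]
    if (!is.null(cc$error)) next
    emit(as.data.frame(cc$comparison), paste0("comparison_", cause, ".tsv"))
    ut <- cc$univariable$table
    emit(data.frame(covariate = ut$covariate, term = ut$term,
                    tr = fmt(ut$tr),
                    ci = paste0(fmt(ut$ci_low), "-", fmt(ut$ci_high)),
                    significant = ut$significant),
         paste0("univariable_", cause, ".tsv"))
    if (!is.null(cc$multivariable)) {
      mt <- cc$multivariable$time_ratios
      all_cov <- unique(ut$covariate)
      rows <- do.call(rbind, lapply(all_cov, function(cv) {
        hit <- mt[vapply(mt$term, function(tm)
          tm == cv | startsWith(tm, paste0(cv, ":")), logical(1)), ,
          drop = FALSE]
        if (nrow(hit))
          data.frame(covariate = cv, term = hit$term, tr = fmt(hit$tr),
                     ci = paste0(fmt(hit$ci_low), "-", fmt(hit$ci_high)),
                     significant = as.character(hit$significant))
        else
          data.frame(covariate = cv, term = cv, tr = "NC", ci = "NC",
                     significant = "NC")
      }))
      emit(rows, paste0("multivariable_", cause, ".tsv"))
      st <- cc$sensitivity$table
      emit(data.frame(variance = st$variance, term = st$term,
                      tr = fmt(st$tr),
                      ci = paste0(fmt(st$ci_low), "-", fmt(st$ci_high))),
           paste0("sensitivity_", cause, ".tsv"))
    }
  }
  invisible(files)
}
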