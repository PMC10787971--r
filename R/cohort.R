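event_levels <- c("censored", "hf_death", "non_hf_death")

normalize_event <- function(x) {
  x <- trimws(tolower(as.character(x)))
  map <- c("0" = "censored", "1" = "hf_death", "2" = "non_hf_death",
           "censored" = "censored", "hf_death" = "hf_death",
           "hf" = "hf_death", "non_hf_death" = "non_hf_death",
           "non_hf" = "non_hf_death", "nonhf" = "non_hf_death")
  out <- unname(map[x])
  if (any(is.na(out) & !is.na(x)))
    stopf("unknown event code '%s' (row %d); expected 0/1/2 or %s",
          x[which(is.na(out) & !is.na(x))[1L]],
          which(is.na(out) & !is.na(x))[1L],
          paste(event_levels, collapse = "/"))
  factor(out, levels = event_levels)
}

#' Construct a survival cohort with competing event causes
#'
#' A cohort couples subject-level follow-up records (time in months since
#' diagnosis, an event code, covariate values) with the covariate
#' specifications that fix how covariates are coded. Records with a missing
#' value in any declared covariate are rejected rather than imputed; the
#' number of exclusions is kept in the `n_excluded` attribute.
#'
#' @param data data frame with columns `id`, `time_months`, `event`
#'   (`0`/`1`/`2` or `censored`/`hf_death`/`non_hf_death`) and one column
#'   per declared covariate.
#' @param specs list of [covariate_spec] objects.
#' @param time_unit unit of the time column; values are stored in months
#'   (`"years"` multiplies by 12).
#' @return a `baft_cohort`: the validated data frame (row order preserved)
#'   with the specs attached.
#' @seealso [read_cohort()], [cause_specific_view()], [encode_design()]
#' @export
cohort <- function(data, specs, time_unit = c("months", "years")) {
  time_unit <- match.arg(time_unit)
  stopifnot(is.data.frame(data), is.list(specs))
  specs <- lapply(specs, function(s) {
    if (!inherits(s, "covariate_spec")) stopf("specs must be covariate_spec objects")
    s
  })
  need <- c("id", "time_months", "event", vapply(specs, `[[`, "", "name"))
  miss <- setdiff(need, names(data))
  if (length(miss)) stopf("missing column(s): %s", paste(miss, collapse = ", "))

  tm <- suppressWarnings(as.numeric(data$time_months))
  bad <- which(is.na(tm) | tm <= 0)
  if (length(bad))
    stopf("nonpositive or unparseable time in row(s) %s",
          paste(utils::head(bad, 5L), collapse = ", "))
  if (time_unit == "years") tm <- tm * 12

  ev <- normalize_event(data$event)
  if (anyNA(ev)) stopf("missing event code in row(s) %s",
                       paste(utils::head(which(is.na(ev)), 5L), collapse = ", "))

  covnames <- vapply(specs, `[[`, "", "name")
  df <- data.frame(id = as.character(data$id), time_months = tm, event = ev,
                   stringsAsFactors = FALSE)
  for (nm in covnames) df[[nm]] <- data[[nm]]

  # reject rows with any missing covariate value (no imputation)
  has_na <- if (length(covnames))
    Reduce(`|`, lapply(covnames, function(nm) is.na(df[[nm]])))
  else rep(FALSE, nrow(df))
  n_excluded <- sum(has_na)
  df <- df[!has_na, , drop = FALSE]
  rownames(df) <- NULL
  # validate levels now so bad values fail at load, not at fit
  for (s in specs) encode_column(s, df[[s$name]])

  structure(df, specs = specs, n_excluded = n_excluded,
            class = c("baft_cohort", "data.frame"))
}

#' Read a cohort from delimited text
#'
#' Expects a header row with columns `id`, `time_months` (or `time`),
#' `event`, and the declared covariates; comma- or tab-separated
#' (auto-detected from the header line).
#'
#' @param path file path.
#' @inheritParams cohort
#' @return a `baft_cohort`; excluded-row count in `attr(, "n_excluded")`.
#' @export
read_cohort <- function(path, specs, time_unit = "months") {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""))
  if (!"time_months" %in% names(df) && "time" %in% names(df))
    names(df)[names(df) == "time"] <- "time_months"
  cohort(df, specs, time_unit = time_unit)
}

#' Write a cohort back to delimited text
#'
#' @param cohort a `baft_cohort`.
#' @param path output file path.
#' @param sep field separator.
#' @export
write_cohort <- function(cohort, path, sep = ",") {
  stopifnot(inherits(cohort, "baft_cohort"))
  df <- as.data.frame(cohort)
  df$event <- as.character(df$event)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.baft_cohort <- function(x, ...) {
  ev <- table(x$event)
  cat(sprintf(
    "<baft_cohort> %d subjects | %d HF deaths, %d non-HF deaths, %d censored\n",
    nrow(x), ev[["hf_death"]], ev[["non_hf_death"]], ev[["censored"]]))
  cat(sprintf("  follow-up (months): median %.1f, max %.1f\n",
              stats::median(x$time_months), max(x$time_months)))
  cat(sprintf("  covariates: %s\n",
              paste(vapply(attr(x, "specs"), `[[`, "", "name"),
                    collapse = ", ")))
  invisible(x)
}

#' Cohort bookkeeping summary
#'
#' Counts and percentages in the shape of a registry baseline table:
#' overall mortality split by cause, plus per-covariate level counts.
#' Percentages are of the cohort total, rounded to one decimal.
#'
#' @param object a `baft_cohort`.
#' @param ... unused.
#' @return a `summary.baft_cohort` list with `n`, per-cause counts and
#'   percentages, and a per-covariate level count table.
#' @export
summary.baft_cohort <- function(object, ...) {
  n <- nrow(object)
  ev <- table(object$event)
  pct <- function(k) round(100 * k / n, 1)
  covs <- lapply(attr(object, "specs"), function(s) {
    if (s$kind == "continuous") {
      c(mean = mean(as.numeric(object[[s$name]])),
        median = stats::median(as.numeric(object[[s$name]])))
    } else {
      tab <- table(factor(as.character(object[[s$name]]), levels = s$levels))
      data.frame(level = names(tab), n = as.integer(tab),
                 pct = pct(as.integer(tab)), row.names = NULL)
    }
  })
  names(covs) <- vapply(attr(object, "specs"), `[[`, "", "name")
  structure(list(
    n = n,
    n_hf = as.integer(ev[["hf_death"]]),
    n_non_hf = as.integer(ev[["non_hf_death"]]),
    n_censored = as.integer(ev[["censored"]]),
    pct_hf = pct(ev[["hf_death"]]),
    pct_non_hf = pct(ev[["non_hf_death"]]),
    pct_censored = pct(ev[["censored"]]),
    covariates = covs
  ), class = "summary.baft_cohort")
}

#' @export
print.summary.baft_cohort <- function(x, ...) {
  cat(sprintf("Cohort of %d subjects\n", x$n))
  cat(sprintf("  HF-related deaths:     %4d (%.1f%%)\n", x$n_hf, x$pct_hf))
  cat(sprintf("  non-HF-related deaths: %4d (%.1f%%)\n", x$n_non_hf, x$pct_non_hf))
  cat(sprintf("  censored:              %4d (%.1f%%)\n", x$n_censored, x$pct_censored))
  for (nm in names(x$covariates)) {
    v <- x$covariates[[nm]]
    if (is.data.frame(v)) {
      cat(sprintf("  %s: %s\n", nm,
                  paste(sprintf("%s %d (%.1f%%)", v$level, v$n, v$pct),
                        collapse = ", ")))
    } else {
      cat(sprintf("  %s: mean %.2f, median %.2f\n", nm, v[["mean"]], v[["median"]]))
    }
  }
  invisible(x)
}

#' Cause-specific view of a competing-risks cohort
#'
#' Recodes the cohort for a single event cause: the indicator is 1 only for
#' deaths from the requested cause; competing-cause deaths and censored
#' subjects are both coded 0 (the cause-specific convention shared by the
#' likelihood, Kaplan-Meier and log-rank layers). The design matrix is
#' expanded per the cohort's covariate specs with a leading intercept.
#'
#' @param cohort a `baft_cohort`.
#' @param cause `"hf"` or `"non_hf"`.
#' @param covariates optional character vector restricting the design to a
#'   subset of declared covariates (default: all).
#' @return a `baft_view`: list with `times`, `d`, `design`, `column_names`,
#'   `cause`, `n_events`.
#' @export
cause_specific_view <- function(cohort, cause = c("hf", "non_hf"),
                                covariates = NULL) {
  stopifnot(inherits(cohort, "baft_cohort"))
  cause <- match.arg(cause)
  target <- if (cause == "hf") "hf_death" else "non_hf_death"
  d <- as.numeric(cohort$event == target)
  if (sum(d) == 0)
    stopf("no '%s' events in the cohort: cause-specific likelihood is degenerate",
          cause)
  specs <- attr(cohort, "specs")
  if (!is.null(covariates)) {
    unknown <- setdiff(covariates, vapply(specs, `[[`, "", "name"))
    if (length(unknown))
      stopf("unknown covariate(s): %s", paste(unknown, collapse = ", "))
    specs <- specs[vapply(specs, `[[`, "", "name") %in% covariates]
    # keep requested order
    specs <- specs[order(match(vapply(specs, `[[`, "", "name"), covariates))]
  }
  sub <- cohort
  attr(sub, "specs") <- specs
  X <- encode_design(sub)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dep <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stopf("design matrix is rank deficient; collinear column(s): %s",
          paste(dep, collapse = ", "))
  }
  structure(list(times = cohort$time_months, d = d, design = X,
                 column_names = colnames(X), cause = cause,
                 n_events = sum(d)),
            class = "baft_view")
}

#' @export
print.baft_view <- function(x, ...) {
  cat(sprintf("<baft_view> cause=%s | %d subjects, %d events, %d design columns\n",
              x$cause, length(x$times), x$n_events, ncol(x$design)))
  invisible(x)
}
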