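#' Declare how a covariate enters the design matrix
#'
#' A covariate specification fixes, once per cohort, how a raw column is
#' coded into regression columns:
#' \describe{
#'   \item{binary}{two levels; a single 0/1 indicator of the second level.}
#'   \item{ordinal}{ordered levels scored 0, 1, 2, ... in level order
#'     (a trend effect); one column.}
#'   \item{categorical}{indicator columns for every level except the
#'     reference.}
#'   \item{continuous}{the numeric value, unchanged.}
#' }
#' The expansion is deterministic: columns follow the order of the spec
#' list, and within a categorical spec the order of `levels`.
#'
#' @param name column name in the cohort file.
#' @param kind one of `"binary"`, `"ordinal"`, `"categorical"`,
#'   `"continuous"`.
#' @param levels ordered character vector of levels (required unless
#'   continuous). For `binary` the second level is coded 1.
#' @param reference reference level (categorical only; defaults to the
#'   first level).
#' @return an object of class `covariate_spec`.
#' @examples
#' covariate_spec("chest_pain", "binary", levels = c("no", "yes"))
#' covariate_spec("heart_rate", "categorical",
#'                levels = c("lt60", "60-100", "gt100"),
#'                reference = "60-100")
#' @export
covariate_spec <- function(name,
                           kind = c("continuous", "binary", "ordinal",
                                    "categorical"),
                           levels = NULL, reference = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (kind == "continuous") {
    if (!is.null(levels)) stopf("'levels' is not used for continuous '%s'", name)
  } else {
    if (is.null(levels) || length(levels) < 2L)
      stopf("'%s' (%s) needs at least two levels", name, kind)
    if (kind == "binary" && length(levels) != 2L)
      stopf("binary '%s' needs exactly two levels", name)
    if (anyDuplicated(levels)) stopf("duplicate levels in '%s'", name)
  }
  if (kind == "categorical") {
    reference <- reference %||% levels[1L]
    if (!reference %in% levels)
      stopf("reference '%s' is not a level of '%s'", reference, name)
  } else if (!is.null(reference)) {
    stopf("'reference' only applies to categorical specs ('%s')", name)
  }
  structure(list(name = name, kind = kind,
                 levels = as.character(levels), reference = reference),
            class = "covariate_spec")
}

#' @export
print.covariate_spec <- function(x, ...) {
  lv <- if (x$kind == "continuous") "" else
    paste0(" [", paste(x$levels, collapse = ", "),
           if (!is.null(x$reference)) paste0("; ref=", x$reference), "]")
  cat(sprintf("<covariate_spec> %s: %s%s\n", x$name, x$kind, lv))
  invisible(x)
}

# Number of design columns a spec expands to
spec_ncol <- function(spec) {
  switch(spec$kind,
         categorical = length(spec$levels) - 1L,
         1L)
}

# Column names a spec expands to
spec_colnames <- function(spec) {
  switch(spec$kind,
    categorical = paste0(spec$name, ":",
                         setdiff(spec$levels, spec$reference)),
    spec$name)
}

# Encode one raw column under its spec -> numeric matrix (n x spec_ncol)
encode_column <- function(spec, values) {
  n <- length(values)
  if (spec$kind == "continuous") {
    v <- suppressWarnings(as.numeric(values))
    if (any(is.na(v) & !is.na(values)))
      stopf("non-numeric value in continuous covariate '%s'", spec$name)
    return(matrix(v, ncol = 1, dimnames = list(NULL, spec$name)))
  }
  values <- as.character(values)
  bad <- !is.na(values) & !values %in% spec$levels
  if (any(bad))
    stopf("value '%s' of covariate '%s' is not a declared level",
          values[which(bad)[1L]], spec$name)
  out <- switch(spec$kind,
    binary = matrix(as.numeric(values == spec$levels[2L]), ncol = 1),
    ordinal = matrix(as.numeric(match(values, spec$levels) - 1L), ncol = 1),
    categorical = {
      keep <- setdiff(spec$levels, spec$reference)
      m <- vapply(keep, function(l) as.numeric(values == l), numeric(n))
      matrix(m, nrow = n)
    })
  out[is.na(values), ] <- NA_real_
  dimnames(out) <- list(NULL, spec_colnames(spec))
  out
}

#' Expand a cohort's covariates into a design matrix
#'
#' Builds the regression design matrix from a cohort's covariate
#' specifications, with an intercept column prepended. The expansion is
#' order-stable: identical specs and rows give a byte-identical matrix.
#'
#' @param cohort a [cohort] object.
#' @param intercept prepend an intercept column (default `TRUE`).
#' @return numeric matrix with named columns.
#' @export
encode_design <- function(cohort, intercept = TRUE) {
  stopifnot(inherits(cohort, "baft_cohort"))
  specs <- attr(cohort, "specs")
  blocks <- lapply(specs, function(s) encode_column(s, cohort[[s$name]]))
  X <- do.call(cbind, blocks)
  if (intercept)
    X <- cbind("(Intercept)" = rep(1, nrow(cohort)), X)
  X
}
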