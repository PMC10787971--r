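#' @keywords internal
#' @importFrom survival Surv survfit survdiff survreg
#' @importFrom stats median quantile qgamma qnorm pchisq
#' @importFrom graphics lines legend par
"_PACKAGE"

# log(sum(exp(x))) without overflow
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(mean(exp(x)))
logmeanexp <- function(x) logsumexp(x) - log(length(x))

# Deterministic sub-seed derivation: keeps every derived seed a valid
# 32-bit integer whatever the user supplies.
derive_seed <- function(seed, ...) {
  parts <- c(seed, unlist(lapply(list(...), function(p) {
    if (is.character(p)) sum(utf8ToInt(p)) else as.numeric(p)
  })))
  s <- 0
  for (p in parts) s <- (s * 69069 + as.numeric(p) %% 2^31) %% (2^31 - 1)
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
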