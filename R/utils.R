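#' @keywords internal
"_PACKAGE"

#' @useDynLib oralmia, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Closed vocabularies used throughout
GROUPS   <- c("ASD", "control")
HABITATS <- c("saliva", "plaque")
RANKS    <- c("phylum", "class", "order", "family", "genus", "species")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded package functions never clobber the session RNG.
#'
#' @param seed integer seed, or NULL to use the current RNG stream.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' One structured log line per pipeline stage
#' @keywords internal
log_stage <- function(stage, ...) {
  kv <- list(...)
  msg <- paste(sprintf("%s=%s", names(kv), vapply(kv, function(x)
    paste(format(x), collapse = ","), character(1))), collapse = " ")
  message(sprintf("[oralmia] stage=%s %s", stage, msg))
}

# Derive a reproducible 32-bit sub-seed from a base seed and a stage tag.
# Keeps every stream independent while remaining a pure function of (seed, tag).
derive_seed <- function(seed, tag) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647L)
}
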