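#' @useDynLib thymoquant, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm rpois runif rnbinom rbinom rlnorm rbeta quantile
#'   median pnorm p.adjust aggregate setNames complete.cases
#' @importFrom utils head write.csv read.csv
NULL

# Run `code` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Derive a child seed from a base seed and a stage label, staying within
# 32-bit integer range (stable across platforms).
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483587L)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

check_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0))
    stopf("'%s' must be strictly positive", name)
  invisible(x)
}
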