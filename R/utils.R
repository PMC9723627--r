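#' @importFrom methods new validObject is slot
#' @importFrom stats rnorm runif rbinom rpois rnbinom plogis uniroot
#'   pnorm pchisq phyper glm poisson t.test quantile sd var
#'   hclust cutree dist setNames complete.cases
#' @importFrom utils head tail write.table read.table
NULL

# numerically stable log(sum(exp(x)))
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

.assert_fraction <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("'%s' must be a fraction in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

.assert_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("'%s' must be positive", name), call. = FALSE)
  }
  invisible(x)
}

.assert_count <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) ||
      any(x != floor(x))) {
    stop(sprintf("'%s' must be a non-negative integer", name), call. = FALSE)
  }
  invisible(x)
}

# deterministic child seeds below 2^31, derived from one user seed
.derive_seed <- function(seed, k) {
  (as.integer(seed) + 48271L * as.integer(k)) %% 2147483L + 1L
}
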