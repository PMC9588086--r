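# Internal numerical helpers shared across modules.

# Gauss error function and its inverse via the normal CDF.
erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

erfinv <- function(y) stats::qnorm((1 + y) / 2) / sqrt(2)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Scalar validation: finite numeric of length 1, optionally strictly positive
# or non-negative. `name` is used verbatim in the error message.
check_scalar <- function(x, name, positive = FALSE, non_negative = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be > 0 (got %g)", name, x), call. = FALSE)
  }
  if (non_negative && x < 0) {
    stop(sprintf("`%s` must be >= 0 (got %g)", name, x), call. = FALSE)
  }
  invisible(x)
}

check_numeric_vector <- function(x, name, non_negative = FALSE) {
  if (!is.numeric(x) || length(x) == 0L || any(!is.finite(x))) {
    stop(sprintf("`%s` must be a non-empty finite numeric vector", name),
         call. = FALSE)
  }
  if (non_negative && any(x < 0)) {
    stop(sprintf("`%s` must be non-negative", name), call. = FALSE)
  }
  invisible(x)
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# state; seed = NULL leaves the current stream untouched.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}
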