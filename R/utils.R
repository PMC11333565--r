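# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Geometric mean with zero replacement
#'
#' Zeros (and negative values, which should not occur in count data) are
#' replaced by `zero_floor` before taking logs, the package-wide convention
#' for count data.
#' @noRd
geomean <- function(x, zero_floor = 0.5) {
  x <- ifelse(x <= 0, zero_floor, x)
  exp(mean(log(x)))
}

# log2 with the package-wide pseudo-count for possibly-zero counts
log2p <- function(x, pseudo = 0.5) log2(x + pseudo)

# Sample SD (denominator n - 1), returning 0 for length-1 input
sample_sd <- function(x) {
  if (length(x) < 2L) return(0)
  stats::sd(x)
}

# Coefficient of variation across lanes; 0/0 treated as 0
coef_var <- function(x) {
  m <- mean(x)
  if (m == 0) return(0)
  sample_sd(x) / m
}

# Deterministic ordering by (value, name): returns an index permutation
order_by_value_then_name <- function(value, name) {
  order(value, name, method = "radix")
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
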