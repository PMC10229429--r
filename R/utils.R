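#' @importFrom rlang %||% .data
#' @importFrom stats rnorm rpois runif sd setNames
NULL

# Scalar validation helpers. All raise with the offending field name so
# configuration errors are self-explanatory.
assert_number <- function(x, name, lower = -Inf, upper = Inf,
                          strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  ok_low <- if (strict_lower) x > lower else x >= lower
  if (!ok_low || x > upper) {
    stop(sprintf("`%s` = %g out of range [%g, %g]", name, x, lower, upper),
         call. = FALSE)
  }
  invisible(x)
}

assert_window <- function(w, name = "window") {
  if (!is.numeric(w) || length(w) != 2 || any(!is.finite(w)) || w[2] <= w[1]) {
    stop(sprintf("`%s` must be c(start, end) with end > start", name),
         call. = FALSE)
  }
  invisible(w)
}

# Half-open window membership [start, end): the package-wide convention.
in_window <- function(time_s, window) {
  time_s >= window[1] & time_s < window[2]
}

# One seed per independent stream, derived reproducibly and kept < 2^31.
derive_seed <- function(seed, offset = 0L) {
  (as.integer(seed) * 1009L + as.integer(offset)) %% .Machine$integer.max
}
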