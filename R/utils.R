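#' Truncate (not round) to a fixed number of decimal places
#'
#' Report formatting used throughout: printed FDR values and percentages are
#' truncated, so 0.5190 prints as 0.51 and 3.898% prints as 3.8%.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places to keep.
#' @return Numeric vector truncated towards zero at `digits` decimals.
#' @export
#' @examples
#' truncate_decimals(0.5190069, 2)
truncate_decimals <- function(x, digits = 2) {
  trunc(x * 10^digits) / 10^digits
}

# positive integer scalar check
assert_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != floor(x)) {
    abort(sprintf("`%s` must be a single positive integer, got %s", name,
                  paste(format(x), collapse = ", ")))
  }
  invisible(as.integer(x))
}

assert_prob <- function(x, name, lo = 0, hi = 1, lo_open = FALSE, hi_open = FALSE) {
  ok <- is.numeric(x) && all(!is.na(x)) &&
    all(if (lo_open) x > lo else x >= lo) &&
    all(if (hi_open) x < hi else x <= hi)
  if (!ok) abort(sprintf("`%s` must lie in %s%g, %g%s", name,
                         if (lo_open) "(" else "[", lo, hi,
                         if (hi_open) ")" else "]"))
  invisible(x)
}

# fold an allele frequency to minor-allele frequency
fold_maf <- function(p) pmin(p, 1 - p)

# derive a deterministic sub-seed (kept below 2^31) from a base seed
sub_seed <- function(seed, offset) {
  (as.integer(seed) + 1000003L * as.integer(offset)) %% 2147483629L
}

`%||%` <- rlang::`%||%`
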