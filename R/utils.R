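# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Commercial rounding: ties go away from zero, so 2.5 -> 3 and -2.5 -> -3.
#' Used when converting expected undiagnosed counts to integers, where base R's
#' banker's rounding would make the tie behaviour depend on parity.
#'
#' @param x Numeric vector.
#' @return Integer-valued numeric vector.
#' @export
#' @examples
#' round_half_away(c(2.5, 3.5, -2.5))
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Cosine similarity between the rows of A and the rows of B (matrices with the
# same number of columns). Returns an nrow(A) x nrow(B) matrix.
row_cosine <- function(A, B) {
  num <- A %*% t(B)
  na <- sqrt(rowSums(A^2))
  nb <- sqrt(rowSums(B^2))
  out <- num / outer(na, nb)
  out[!is.finite(out)] <- 0
  out
}

# Validate that `x` is a single non-missing number in [lo, hi].
check_prob <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
    stop(sprintf("`%s` must be a single number in [%s, %s]", name, lo, hi),
         call. = FALSE)
  }
  invisible(x)
}

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != as.integer(x)) {
    stop(sprintf("`%s` must be a single integer >= %s", name, min),
         call. = FALSE)
  }
  invisible(as.integer(x))
}

# Deterministic child seeds for pipeline stages, kept within 32-bit range.
child_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset)) %% .Machine$integer.max
}
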