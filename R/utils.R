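#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going away from zero, the
#' convention used in the reported tables (base [round()] rounds ties to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector of the same length.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  # nudge by an ulp-scale epsilon so values like 2.675 that are stored just
  # below the tie still round up
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# row-wise log-sum-exp of a matrix, numerically stable
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# derive a per-task seed from a base seed, kept inside 32-bit integer range
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k) %% 2147483647L)
}
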