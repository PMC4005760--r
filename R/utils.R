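## Shared small helpers: half-up rounding and printed percentages.

#' Round half-up
#'
#' Deterministic half-up rounding (0.005 -> 0.01 at 2 digits), unlike base
#' [round()] which rounds half to even.
#'
#' @param x numeric vector.
#' @param digits number of decimal digits.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage rounded half-up
#'
#' `100 * numerator / denominator` rounded half-up to `digits` decimals.
#' This is the rounding used in all reported overlap and category shares;
#' one-decimal figures reproduce by re-rounding the two-decimal value.
#'
#' @param numerator integer vector, `0 <= numerator <= denominator`.
#' @param denominator positive integer vector.
#' @param digits decimal digits (default 2).
#' @return numeric vector of percentages in \[0, 100\].
#' @examples
#' percentage(165, 529)      # 31.19
#' percentage(17700, 23409)  # 75.61
#' @export
percentage <- function(numerator, denominator, digits = 2) {
  if (any(denominator <= 0)) stop("denominator must be > 0")
  if (any(numerator < 0) || any(numerator > denominator))
    stop("numerator must lie in [0, denominator]")
  round_half_up(100 * numerator / denominator, digits)
}

## reverse complement of a plain character string over A/C/G/T/N
.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

.sanitize_dna <- function(x) {
  x <- toupper(x)
  gsub("[^ACGT]", "N", x)
}
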