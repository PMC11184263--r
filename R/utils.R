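#' Round half away from zero
#'
#' Decimal rounding where a trailing 5 always rounds up in magnitude
#' (2.345 -> 2.35), unlike [base::round()]'s round-half-even. Used for all
#' reported percentages and throughputs so that printed values are
#' reproducible independent of the platform's banker's rounding.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` decimals.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Reverse complement of nucleotide strings
#'
#' @param x character vector of DNA strings (A/C/G/T/N, case-insensitive;
#'   output is uppercase).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ck <- function(...) stop(..., call. = FALSE)
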