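# Phred+33 string <-> integer quality helpers. Qualities live as compact
# phred+33 strings in data frames and are expanded on demand.

#' Decode a phred+33 quality string to integer qualities
#' @param x character scalar (one quality string)
#' @return integer vector of per-base qualities
#' @keywords internal
phred_to_int <- function(x) {
  as.integer(charToRaw(x)) - 33L
}

#' Encode integer qualities as a phred+33 string
#' @param q integer vector of qualities (0..93)
#' @return character scalar
#' @keywords internal
int_to_phred <- function(q) {
  rawToChar(as.raw(as.integer(q) + 33L))
}

#' Reverse-complement a DNA string
#'
#' Base-R implementation (chartr + byte reversal) kept free of S4
#' dispatch because it sits in the per-read hot path; agreement with
#' [Biostrings::reverseComplement()] is asserted in the test suite.
#' @param x character scalar over {A,C,G,T,N}
#' @return character scalar
#' @keywords internal
revcomp <- function(x) {
  rawToChar(rev(charToRaw(chartr("ACGTNacgtn", "TGCANtgcan", x))))
}

#' Reverse-complement many DNA strings
#' @param x character vector over {A,C,G,T,N}
#' @return character vector
#' @keywords internal
revcomp_many <- function(x) {
  vapply(x, revcomp, "", USE.NAMES = FALSE)
}

#' Reverse many phred+33 quality strings
#' @keywords internal
reverse_quals <- function(x) {
  vapply(x, function(q) rawToChar(rev(charToRaw(q))), "", USE.NAMES = FALSE)
}

#' Draw from a truncated normal by rejection
#' @param n number of draws
#' @param mean,sd normal parameters
#' @param lower,upper truncation bounds (inclusive)
#' @keywords internal
rtruncnorm <- function(n, mean, sd, lower, upper) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  while (length(bad) > 0L) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower | out[bad] > upper]
  }
  out
}

#' Parse a comma-separated position list stored in a truth table
#' @param x character scalar ("" for none)
#' @return integer vector
#' @keywords internal
parse_pos_list <- function(x) {
  if (is.na(x) || !nzchar(x)) return(integer(0))
  as.integer(strsplit(x, ",", fixed = TRUE)[[1L]])
}

#' Serialise a position vector for a truth table
#' @keywords internal
format_pos_list <- function(p) {
  if (length(p) == 0L) "" else paste(p, collapse = ",")
}
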