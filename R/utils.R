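#' Percentage with fixed one-decimal rounding
#'
#' All summary tables in this package print percentages to one decimal with
#' round-half-up semantics (so 42.55 prints as 42.6, never 42.5), matching the
#' convention of the founder summary tables the pipeline mirrors.
#'
#' @param x Numerator (count or vector of counts).
#' @param total Denominator. A zero total yields `NA`.
#' @param digits Decimal places (default 1).
#' @return Numeric percentage(s), rounded half-up to `digits` decimals.
#' @examples
#' percent_of(16154580, 24178653)  # 66.8
#' @export
percent_of <- function(x, total, digits = 1) {
  out <- 100 * x / total              # keeps dim/dimnames of x
  out[rep_len(total == 0, length(out))] <- NA_real_
  round_half_up(out, digits)
}

#' @rdname percent_of
#' @export
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# random DNA as a single string
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# lexicographically least rotation of a motif (canonical STR motif label)
canonical_rotation <- function(motif) {
  vapply(motif, function(m) {
    k <- nchar(m)
    rots <- vapply(seq_len(k), function(i) {
      paste0(substr(m, i, k), substr(m, 1, i - 1))
    }, character(1))
    min(rots)
  }, character(1), USE.NAMES = FALSE)
}

# bounded hamming distance between two equal-length strings (-1 if exceeded)
hamming_bounded <- function(a, b, maxmm) {
  hamming_bounded_cpp(a, b, as.integer(maxmm))
}
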