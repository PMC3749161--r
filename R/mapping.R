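#' Map read pairs to consensus references with bounded mismatches
#'
#' Mates are anchored end-to-end at fixed offsets (the insert size is pinned
#' to the consensus length, so no positional search is performed): the
#' forward mate is compared against the reference forward consensus and the
#' reverse mate against the reverse consensus in sequencing orientation.
#' A pair maps to the reference with the minimum total mismatch count over
#' both mates, provided it does not exceed `max_mismatch`; ties break
#' deterministically to the lowest locus id. Candidate references come from
#' an exact-seed index on a fixed-length prefix of each mate, with a full
#' scan as fallback when no seeded candidate is acceptable.
#'
#' @param pairs Read-pair table (`fwd_seq`, `rev_seq`, `founder`, ...).
#' @param refs Reference locus table from [select_references()] (needs
#'   `locus_id`, `fwd_cons`, `rev_cons`).
#' @param max_mismatch Mismatch bound over both mates; default 3.
#' @param seed_len Exact-seed prefix length; default 16.
#' @return `pairs` with `locus_id`, `locus_index`, and `mismatches` columns
#'   added (`NA` for unmapped pairs).
#' @export
map_read_pairs <- function(pairs, refs, max_mismatch = 3, seed_len = 16) {
  stopifnot(nrow(refs) > 0 || nrow(pairs) == 0)
  if (nrow(pairs) == 0) {
    pairs$locus_id <- character(0)
    pairs$locus_index <- integer(0)
    pairs$mismatches <- integer(0)
    return(pairs)
  }
  res <- map_pairs_cpp(pairs$fwd_seq, pairs$rev_seq,
                       refs$fwd_cons, refs$rev_cons,
                       as.integer(max_mismatch), as.integer(seed_len))
  pairs$locus_id <- ifelse(is.na(res$locus), NA_character_,
                           refs$locus_id[res$locus])
  pairs$locus_index <- res$locus
  pairs$mismatches <- res$mismatches
  pairs
}

#' Tabulate per-position allele depths from mapped pairs
#'
#' Every mapped pair contributes one count per informative offset: offsets
#' 0-100 are forward-mate positions (consensus positions 1-101), offsets
#' 101-201 are reverse-mate positions in sequencing orientation (offset
#' `101 + j` corresponds to consensus position `300 - j`, with the base
#' complemented relative to the consensus strand). The depth unit is the
#' read pair throughout.
#'
#' @param mapped Mapped pair table from [map_read_pairs()].
#' @param refs The reference table used for mapping.
#' @param founders Founder labels fixing the founder dimension order;
#'   defaults to the sorted labels present.
#' @return An `allele_depth_table`: an integer array with dimensions
#'   (base A/C/G/T, offset 0-201, founder, locus), with dimnames.
#' @export
tally_alleles <- function(mapped, refs, founders = NULL) {
  if (is.null(founders)) founders <- sort(unique(mapped$founder))
  rl <- if (nrow(refs) > 0) nchar(refs$fwd_cons[1]) else 101L
  keep <- !is.na(mapped$locus_index)
  m <- mapped[keep, , drop = FALSE]
  arr <- tally_alleles_cpp(m$locus_index,
                           match(m$founder, founders),
                           m$fwd_seq, m$rev_seq,
                           nrow(refs), length(founders), as.integer(rl))
  dimnames(arr) <- list(c("A", "C", "G", "T"),
                        as.character(seq_len(2L * rl) - 1L),
                        founders, refs$locus_id)
  class(arr) <- c("allele_depth_table", class(arr))
  arr
}

#' Per-founder mapping rates
#'
#' @param mapped Mapped pair table from [map_read_pairs()].
#' @return A data frame per founder: `n_pairs`, `n_mapped`, `pct_mapped`
#'   (percent, one decimal; `NA` when a founder has no pairs).
#' @export
mapping_report <- function(mapped) {
  founders <- sort(unique(mapped$founder))
  rows <- lapply(founders, function(f) {
    m <- mapped[mapped$founder == f, , drop = FALSE]
    n <- nrow(m)
    nm <- sum(!is.na(m$locus_index))
    data.frame(founder = f, n_pairs = n, n_mapped = nm,
               pct_mapped = percent_of(nm, n), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
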