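#' Load mate-synchronised paired FASTQ files
#'
#' Reads a pair of FASTQ files into a read-pair table. Mate record
#' identifiers must match after stripping a trailing `/1`//`/2` suffix or
#' anything after the first whitespace; a desynchronised pair raises an error
#' naming the first offending record.
#'
#' @param fastq_r1,fastq_r2 Paths to the forward and reverse FASTQ files.
#' @param founder_id Label attached to every pair.
#' @return A data frame with `read_id`, `founder`, `fwd_seq`, `rev_seq`,
#'   `fwd_qual`, `rev_qual`, in file order.
#' @export
load_pairs <- function(fastq_r1, fastq_r2, founder_id) {
  r1 <- Biostrings::readDNAStringSet(fastq_r1, format = "fastq",
                                     with.qualities = TRUE)
  r2 <- Biostrings::readDNAStringSet(fastq_r2, format = "fastq",
                                     with.qualities = TRUE)
  id1 <- mate_core_id(names(r1))
  id2 <- mate_core_id(names(r2))
  if (length(id1) != length(id2)) {
    stop("mate files desynchronised: record ", min(length(id1), length(id2)) + 1,
         " present in only one file")
  }
  bad <- which(id1 != id2)
  if (length(bad) > 0) {
    stop("mate identifiers disagree at record ", bad[1], ": '",
         id1[bad[1]], "' vs '", id2[bad[1]], "'")
  }
  data.frame(read_id = id1, founder = founder_id,
             fwd_seq = as.character(r1), rev_seq = as.character(r2),
             fwd_qual = as.character(S4Vectors::mcols(r1)$qualities),
             rev_qual = as.character(S4Vectors::mcols(r2)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}

mate_core_id <- function(x) {
  x <- sub("\\s.*$", "", x)
  sub("/[12]$", "", x)
}

#' Discard read pairs containing N bases
#'
#' A pair is discarded when either mate contains at least one `N`.
#'
#' @param pairs Read-pair table from [load_pairs()].
#' @return A list with `pairs` (the kept rows) and `n_discarded`.
#' @export
filter_pairs <- function(pairs) {
  has_n <- grepl("N", pairs$fwd_seq, fixed = TRUE) |
    grepl("N", pairs$rev_seq, fixed = TRUE)
  list(pairs = pairs[!has_n, , drop = FALSE],
       n_discarded = sum(has_n))
}

#' Classify read pairs by their 5'-terminal sequences
#'
#' The cut chemistry leaves a fixed signature at each fragment end: HaeIII
#' (GG^CC) fragments start with `CC` and end with `GG`, so both mates of a
#' both-end-HaeIII fragment begin with `CC`; MboI (^GATC) fragments start
#' with `GATC` at both ends. Pairs are labelled `HAEIII_BOTH`, `MBOI_BOTH`,
#' or `OTHER` (mixed or error-bearing termini); the three labels partition
#' the input.
#'
#' @param pairs Read-pair table (N-filtered).
#' @return The table with a `group` column added.
#' @export
classify_terminal <- function(pairs) {
  fwd2 <- substr(pairs$fwd_seq, 1, 2)
  rev2 <- substr(pairs$rev_seq, 1, 2)
  fwd4 <- substr(pairs$fwd_seq, 1, 4)
  rev4 <- substr(pairs$rev_seq, 1, 4)
  group <- rep("OTHER", nrow(pairs))
  group[fwd2 == "CC" & rev2 == "CC"] <- "HAEIII_BOTH"
  group[fwd4 == "GATC" & rev4 == "GATC"] <- "MBOI_BOTH"
  pairs$group <- group
  pairs
}

#' Per-founder read and base accounting
#'
#' Mirrors the lane-level bookkeeping of the sequencing summary: reads and
#' bases per founder, discarded pairs, and the terminal-group split when
#' available.
#'
#' @param pairs Read-pair table (optionally with a `group` column).
#' @param n_discarded Named vector of discarded pair counts per founder, or a
#'   single number applied to a single-founder table.
#' @return A data frame with one row per founder: `founder`, `n_pairs`,
#'   `n_reads`, `n_bases`, `n_discarded`, and group counts.
#' @export
quality_summary <- function(pairs, n_discarded = 0) {
  if (nrow(pairs) == 0) {
    return(data.frame(founder = character(0), n_pairs = integer(0),
                      n_reads = integer(0), n_bases = numeric(0),
                      n_discarded = integer(0), n_haeiii_both = integer(0),
                      n_mboi_both = integer(0), n_other = integer(0),
                      stringsAsFactors = FALSE))
  }
  founders <- sort(unique(pairs$founder))
  disc <- if (length(n_discarded) == 1 && is.null(names(n_discarded))) {
    stats::setNames(rep(n_discarded, length(founders)), founders)
  } else n_discarded
  rows <- lapply(founders, function(f) {
    p <- pairs[pairs$founder == f, , drop = FALSE]
    grp <- if ("group" %in% names(p)) p$group else rep(NA_character_, nrow(p))
    data.frame(founder = f, n_pairs = nrow(p), n_reads = 2L * nrow(p),
               n_bases = sum(nchar(p$fwd_seq)) + sum(nchar(p$rev_seq)),
               n_discarded = if (f %in% names(disc)) unname(disc[f]) else 0L,
               n_haeiii_both = sum(grp == "HAEIII_BOTH", na.rm = TRUE),
               n_mboi_both = sum(grp == "MBOI_BOTH", na.rm = TRUE),
               n_other = sum(grp == "OTHER", na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
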