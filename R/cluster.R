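#' Cluster read pairs of one terminal group into loci
#'
#' Greedy seed-and-extend clustering with no positional shifts: distinct
#' (forward, reverse) sequence pairs are processed in decreasing multiplicity
#' (ties by lexicographic order, for determinism and so that high-copy true
#' sequences become representatives); each joins the first existing cluster
#' whose representative differs by at most `max_mismatch` substitutions
#' summed over both mates, else founds a new cluster.
#'
#' @param pairs Read-pair table of a single terminal group.
#' @param max_mismatch Maximum substitutions (both mates pooled) to a cluster
#'   representative; default 3.
#' @return A list with `assignment` (cluster id per input row, 1-based in
#'   cluster-creation order), `n_clusters`, and `clusters` (id, size,
#'   representative fwd/rev sequences).
#' @export
cluster_pairs <- function(pairs, max_mismatch = 3) {
  if (max_mismatch < 0) stop("max_mismatch must be non-negative")
  if ("group" %in% names(pairs) && length(unique(pairs$group)) > 1) {
    stop("cluster_pairs expects pairs of a single terminal group")
  }
  n <- nrow(pairs)
  if (n == 0) {
    return(list(assignment = integer(0), n_clusters = 0L,
                clusters = data.frame(cluster_id = integer(0),
                                      size = integer(0),
                                      rep_fwd = character(0),
                                      rep_rev = character(0),
                                      stringsAsFactors = FALSE)))
  }
  rl <- nchar(pairs$fwd_seq[1])
  key <- paste0(pairs$fwd_seq, pairs$rev_seq)
  u <- unique(key)
  mult <- tabulate(match(key, u), nbins = length(u))
  ord <- order(-mult, u, method = "radix")
  useq <- u[ord]
  ucl <- greedy_cluster_cpp(useq, as.integer(max_mismatch))
  assignment <- ucl[match(key, useq)]
  n_clusters <- max(ucl)
  first <- match(seq_len(n_clusters), ucl)
  reps <- useq[first]
  list(assignment = assignment, n_clusters = n_clusters,
       clusters = data.frame(cluster_id = seq_len(n_clusters),
                             size = tabulate(assignment, nbins = n_clusters),
                             rep_fwd = substr(reps, 1L, rl),
                             rep_rev = substr(reps, rl + 1L, nchar(reps)),
                             stringsAsFactors = FALSE))
}

#' Per-column majority consensus of a cluster
#'
#' Votes independently per offset of each mate; ties break by the fixed base
#' order A < C < G < T. The stored 300-character locus sequence is the
#' forward consensus, a 98-base N spacer, then the reverse complement of the
#' reverse consensus, so positions 1-101 and 200-300 (1-based) carry the 202
#' informative bases in fragment orientation.
#'
#' @param fwd_seqs,rev_seqs Member mate sequences (parallel vectors).
#' @param counts Optional multiplicities (default all 1).
#' @return A list: `fwd_cons`, `rev_cons` (sequencing orientation),
#'   `sequence` (the 300-bp locus string), `depth` (sum of counts).
#' @export
build_consensus <- function(fwd_seqs, rev_seqs, counts = NULL) {
  stopifnot(length(fwd_seqs) == length(rev_seqs), length(fwd_seqs) > 0)
  if (is.null(counts)) counts <- rep(1L, length(fwd_seqs))
  fwd <- as.character(consensus_vote_cpp(fwd_seqs, as.integer(counts)))
  rev <- as.character(consensus_vote_cpp(rev_seqs, as.integer(counts)))
  spacer_len <- 300L - 2L * nchar(fwd)
  spacer <- if (spacer_len > 0) strrep("N", spacer_len) else ""
  list(fwd_cons = fwd, rev_cons = rev,
       sequence = paste0(fwd, spacer, revcomp(rev)),
       depth = sum(counts))
}

#' Build consensus loci for every cluster of a group
#'
#' @param pairs Read-pair table of one terminal group.
#' @param assignment Cluster ids from [cluster_pairs()].
#' @param group Group label recorded on every locus.
#' @return A data frame of consensus loci: `locus_id`, `group`, `depth`,
#'   `fwd_cons`, `rev_cons`, `sequence`.
#' @export
consensus_loci <- function(pairs, assignment, group = "GROUP") {
  stopifnot(nrow(pairs) == length(assignment))
  if (nrow(pairs) == 0) {
    return(data.frame(locus_id = character(0), group = character(0),
                      depth = integer(0), fwd_cons = character(0),
                      rev_cons = character(0), sequence = character(0),
                      stringsAsFactors = FALSE))
  }
  key <- paste0(pairs$fwd_seq, "\r", pairs$rev_seq)
  uk <- !duplicated(key)
  mult <- tabulate(match(key, key[uk]), nbins = sum(uk))
  ufwd <- pairs$fwd_seq[uk]
  urev <- pairs$rev_seq[uk]
  ucl <- assignment[uk]
  n_clusters <- max(assignment)
  members <- split(seq_along(ucl), ucl)
  rows <- vector("list", n_clusters)
  for (ci in seq_len(n_clusters)) {
    m <- members[[as.character(ci)]]
    cons <- build_consensus(ufwd[m], urev[m], mult[m])
    rows[[ci]] <- data.frame(
      locus_id = sprintf("%s_%06d", group, ci), group = group,
      depth = cons$depth, fwd_cons = cons$fwd_cons,
      rev_cons = cons$rev_cons, sequence = cons$sequence,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Retain consensus loci deep enough to serve as references
#'
#' @param loci Consensus locus table.
#' @param min_depth Minimum pooled depth (read pairs); default 10.
#' @return The retained loci.
#' @export
select_references <- function(loci, min_depth = 10) {
  loci[loci$depth >= min_depth, , drop = FALSE]
}

#' Per-group consensus accounting
#'
#' @param loci All consensus loci (any number of groups).
#' @param min_depth Reference depth threshold.
#' @return Per-group counts of consensus sequences and of those at or above
#'   `min_depth`.
#' @export
consensus_summary <- function(loci, min_depth = 10) {
  groups <- unique(loci$group)
  rows <- lapply(groups, function(g) {
    l <- loci[loci$group == g, , drop = FALSE]
    data.frame(group = g, n_consensus = nrow(l),
               n_reference = sum(l$depth >= min_depth),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write reference consensus sequences as FASTA
#'
#' @param loci Reference locus table.
#' @param path Output FASTA path.
#' @return Invisibly, `path`.
#' @export
write_reference_fasta <- function(loci, path) {
  x <- Biostrings::DNAStringSet(loci$sequence)
  names(x) <- loci$locus_id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
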