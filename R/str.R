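#' Detect short tandem repeats in consensus loci
#'
#' Scans the two 101-base informative segments of each consensus (the
#' forward consensus, "head", and the genome-oriented tail, i.e. the reverse
#' complement of the reverse consensus) for maximal pure tandem runs of 2-4
#' base motifs. Detection thresholds are at least 8 units for
#' di-nucleotide, 5 for tri-nucleotide and 4 for tetra-nucleotide motifs.
#' Motifs that are repeats of a shorter unit (homopolymers, `ATAT`, ...) are
#' excluded; reported motifs are canonicalised to their lexicographically
#' least rotation, and phase-shifted duplicates of one physical run are
#' collapsed to the longest.
#'
#' @param loci Consensus locus table (needs `locus_id`, `fwd_cons`,
#'   `rev_cons`).
#' @param min_units Named or positional thresholds for motif lengths 2, 3, 4;
#'   default `c(8, 5, 4)`.
#' @return Candidate table: `locus_id`, `segment` ("head"/"tail"), `start`
#'   (1-based within the segment), `motif` (as present), `motif_canon`,
#'   `motif_len`, `n_units`.
#' @export
detect_strs <- function(loci, min_units = c(8, 5, 4)) {
  empty <- data.frame(locus_id = character(0), segment = character(0),
                      start = integer(0), motif = character(0),
                      motif_canon = character(0), motif_len = integer(0),
                      n_units = integer(0), stringsAsFactors = FALSE)
  if (nrow(loci) == 0) return(empty)
  segs <- list(head = loci$fwd_cons, tail = revcomp(loci$rev_cons))
  out <- list()
  for (sg in names(segs)) {
    hits <- find_strs_cpp(segs[[sg]], as.integer(min_units))
    if (nrow(hits) == 0) next
    out[[sg]] <- data.frame(
      locus_id = loci$locus_id[hits$seq_index], segment = sg,
      start = hits$start, motif = hits$motif,
      motif_canon = canonical_rotation(hits$motif),
      motif_len = hits$motif_len, n_units = hits$n_units,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) return(empty)
  cand <- do.call(rbind, out)
  rownames(cand) <- NULL
  # collapse phase-shifted reports of the same physical run
  key <- paste(cand$locus_id, cand$segment, cand$motif_canon)
  keep <- rep(TRUE, nrow(cand))
  for (k in unique(key[duplicated(key)])) {
    rows <- which(key == k)
    rows <- rows[order(-cand$n_units[rows], cand$start[rows])]
    taken <- integer(0)
    for (r in rows) {
      iv <- c(cand$start[r], cand$start[r] +
                cand$n_units[r] * cand$motif_len[r] - 1L)
      overlaps <- any(vapply(taken, function(t) {
        jv <- c(cand$start[t], cand$start[t] +
                  cand$n_units[t] * cand$motif_len[t] - 1L)
        iv[1] <= jv[2] && jv[1] <= iv[2]
      }, logical(1)))
      if (overlaps) keep[r] <- FALSE else taken <- c(taken, r)
    }
  }
  cand <- cand[keep, , drop = FALSE]
  cand <- cand[order(cand$locus_id, cand$segment, cand$start), , drop = FALSE]
  rownames(cand) <- NULL
  cand
}

#' Group STR candidates whose consensus sequences differ only in the run
#'
#' Two candidates merge when they share the motif and segment, their runs
#' are anchored at the same flank position — head-segment runs start at the
#' fragment-anchored offset, tail-segment runs end at it (the tail is the
#' last 101 fragment bases, so a longer allele shifts the run start, not
#' its end) — and their sequences outside the repeat run (anchored flank
#' compared directly, free flank over the common length, plus the full
#' other segment) differ by at most `max_mismatch` substitutions in total.
#' Each merged locus's alleles are the distinct repeat counts of its
#' members.
#'
#' @param cand Candidate table from [detect_strs()].
#' @param loci The consensus locus table the candidates refer to.
#' @param max_mismatch Flank mismatch bound (the mapping bound); default 3.
#' @return A list of STR loci: each has `str_id`, `motif`, `segment`,
#'   `members` (locus_id, n_units) and `alleles` (sorted distinct repeat
#'   counts).
#' @export
group_str_loci <- function(cand, loci, max_mismatch = 3) {
  if (nrow(cand) == 0) return(list())
  heads <- stats::setNames(loci$fwd_cons, loci$locus_id)
  tails <- stats::setNames(revcomp(loci$rev_cons), loci$locus_id)
  seg_of <- function(i) {
    if (cand$segment[i] == "head") heads[[cand$locus_id[i]]]
    else tails[[cand$locus_id[i]]]
  }
  other_of <- function(i) {
    if (cand$segment[i] == "head") tails[[cand$locus_id[i]]]
    else heads[[cand$locus_id[i]]]
  }
  n <- nrow(cand)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  run_end <- cand$start + cand$n_units * cand$motif_len  # one past the run
  anchor <- ifelse(cand$segment == "head", cand$start, run_end)
  key <- paste(cand$segment, cand$motif_canon, cand$motif_len, anchor)
  for (k in unique(key)) {
    rows <- which(key == k)
    if (length(rows) < 2) next
    for (a in seq_along(rows)) {
      for (b in seq_len(a - 1L)) {
        i <- rows[a]; j <- rows[b]
        si <- seg_of(i); sj <- seg_of(j)
        pre_i <- substr(si, 1L, cand$start[i] - 1L)
        pre_j <- substr(sj, 1L, cand$start[j] - 1L)
        suf_i <- substr(si, run_end[i], nchar(si))
        suf_j <- substr(sj, run_end[j], nchar(sj))
        if (cand$segment[i] == "head") {
          # prefixes share the anchored start; suffixes compared left-aligned
          ln <- min(nchar(suf_i), nchar(suf_j))
          suf_i <- substr(suf_i, 1L, ln)
          suf_j <- substr(suf_j, 1L, ln)
        } else {
          # suffixes share the anchored end; prefixes compared right-aligned
          ln <- min(nchar(pre_i), nchar(pre_j))
          pre_i <- substr(pre_i, nchar(pre_i) - ln + 1L, nchar(pre_i))
          pre_j <- substr(pre_j, nchar(pre_j) - ln + 1L, nchar(pre_j))
        }
        mm <- hamming_bounded(pre_i, pre_j, max_mismatch)
        if (mm < 0) next
        mm2 <- hamming_bounded(suf_i, suf_j, max_mismatch - mm)
        if (mm2 < 0) next
        mm3 <- hamming_bounded(other_of(i), other_of(j),
                               max_mismatch - mm - mm2)
        if (mm3 < 0) next
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), roots)
  out <- vector("list", length(groups))
  for (g in seq_along(groups)) {
    rows <- groups[[g]]
    out[[g]] <- list(
      str_id = sprintf("STR_%04d", g),
      motif = cand$motif_canon[rows[1]],
      segment = cand$segment[rows[1]],
      members = data.frame(locus_id = cand$locus_id[rows],
                           n_units = cand$n_units[rows],
                           stringsAsFactors = FALSE),
      alleles = sort(unique(cand$n_units[rows])))
  }
  out
}

#' Genotype STR loci from mapping results
#'
#' Per founder, the depth of an STR allele is the number of read pairs
#' mapped to the member consensus loci carrying that repeat count. An
#' allele is present under the same strict presence rule as SNPs (depth
#' above `presence_frac` of the founder's total locus depth); a founder is
#' genotyped only when its total locus depth reaches `min_founder_depth`.
#'
#' @param strs STR loci from [group_str_loci()].
#' @param mapped Mapped pair table from [map_read_pairs()].
#' @param founders Founder labels; defaults to those present in `mapped`.
#' @param min_founder_depth Minimum depth to call a founder; default 20.
#' @param presence_frac Presence threshold; default 0.05.
#' @return A list with `loci` (per-locus allele depth matrices, presence,
#'   genotypes) and `summary` (per-locus allele number, polymorphism flag,
#'   whether every founder was genotyped, per-founder specific-allele
#'   counts in `specific`).
#' @export
genotype_strs <- function(strs, mapped, founders = NULL,
                          min_founder_depth = 20, presence_frac = 0.05) {
  if (is.null(founders)) founders <- sort(unique(mapped$founder))
  ok <- !is.na(mapped$locus_id)
  tab <- table(factor(mapped$locus_id[ok]),
               factor(mapped$founder[ok], levels = founders))
  depth_of <- function(lid, f) {
    if (lid %in% rownames(tab)) tab[lid, f] else 0L
  }
  loci_out <- vector("list", length(strs))
  spec <- stats::setNames(rep(0L, length(founders)), founders)
  srows <- vector("list", length(strs))
  for (si in seq_along(strs)) {
    s <- strs[[si]]
    alleles <- s$alleles
    dep <- matrix(0, length(founders), length(alleles),
                  dimnames = list(founders, as.character(alleles)))
    for (mi in seq_len(nrow(s$members))) {
      a <- as.character(s$members$n_units[mi])
      for (f in founders) {
        dep[f, a] <- dep[f, a] + depth_of(s$members$locus_id[mi], f)
      }
    }
    tot <- rowSums(dep)
    callable <- tot >= min_founder_depth
    present <- dep > presence_frac * tot & callable
    genotype <- rep(NA_character_, length(founders))
    names(genotype) <- founders
    for (f in which(callable)) {
      pa <- alleles[present[f, ]]
      if (length(pa) == 1) genotype[f] <- paste(pa, pa, sep = "/")
      if (length(pa) >= 2) genotype[f] <- paste(pa[1], pa[2], sep = "/")
    }
    n_obs_alleles <- sum(colSums(present) > 0)
    one_founder <- colSums(present) == 1
    for (a in which(one_founder)) {
      f <- founders[which(present[, a])]
      spec[f] <- spec[f] + 1L
    }
    loci_out[[si]] <- list(str_id = s$str_id, motif = s$motif,
                           alleles = alleles, depth = dep,
                           present = present, genotype = genotype)
    srows[[si]] <- data.frame(str_id = s$str_id, motif = s$motif,
                              n_alleles = n_obs_alleles,
                              polymorphic = n_obs_alleles >= 2,
                              genotyped_in_all = all(callable),
                              stringsAsFactors = FALSE)
  }
  list(loci = loci_out,
       summary = if (length(srows)) do.call(rbind, srows)
                 else data.frame(str_id = character(0), motif = character(0),
                                 n_alleles = integer(0),
                                 polymorphic = logical(0),
                                 genotyped_in_all = logical(0)),
       specific = spec)
}
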