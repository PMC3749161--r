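#' Evaluate SNP calls against simulation truth
#'
#' Scores putative SNPs from a pipeline run on simulated reads against the
#' planted truth table. Recall is measured on the *detectable* truth set:
#' planted SNPs lying within the informative 101-base head or tail of at
#' least one size-selected fragment (an RRL interrogates only those bases,
#' so genome-wide recall is bounded by the representation, not by the
#' caller) and whose realised pooled read-pair depth over those fragments
#' reaches the prediction threshold (a site sequenced below `depth >= 100`
#' — e.g. a variant that destroys the restriction site in most founders —
#' is structurally invisible to the method). A call matches when its genome
#' position and unordered allele pair equal the truth record's. Calls are
#' placed on the genome through each consensus locus's majority source
#' fragment.
#'
#' @param result A pipeline result from [run_rrl_pipeline()] on simulated
#'   reads (SNP-only simulations, i.e. `str_count = 0`, have stable
#'   coordinates).
#' @param min_pooled_depth Realised-depth requirement entering the
#'   detectability definition; default 100, the prediction threshold.
#' @return List: `recall`, `precision`, `n_truth_detectable`, `n_called`,
#'   `n_matched`.
#' @export
evaluate_snp_recovery <- function(result, min_pooled_depth = 100) {
  sim <- result$sim
  stopifnot(!is.null(sim), sim$config$str_count == 0)
  sel <- sim$selected
  refs <- result$refs
  put <- result$putative
  rl <- sim$config$read_length
  truth <- sim$genomes$truth_snps
  # Realised read-pair coverage of each truth position, split by the allele
  # carried on the covering haplotype. Tail windows shift right by the
  # end-repair fill (sequenced tail = genomic tail + fill bases, which
  # duplicate the next genomic bases). A variant that creates or destroys a
  # restriction site changes the carriers' fragmentation, so the carrier
  # haplotypes may contribute no reads at the position at all — that allele
  # then has zero realised coverage and the site is undetectable as a base
  # call (RRL allele dropout), however deep the non-carrier locus is.
  per_frag <- sim$reads$per_fragment
  realised_ref <- realised_alt <- rep(0, nrow(truth))
  qpos <- IRanges::IRanges(truth$pos, truth$pos)
  for (f in unique(sel$founder)) {
    for (h in 1:2) {
      sf <- sel[sel$founder == f & sel$hap == h, , drop = FALSE]
      if (nrow(sf) == 0) next
      cover <- c(IRanges::IRanges(sf$start + 1L, sf$start + rl),
                 IRanges::IRanges(sf$end + sf$fill - rl + 1L,
                                  sf$end + sf$fill))
      wt <- rep(per_frag$n_pairs[match(sf$frag_id, per_frag$frag_id)], 2L)
      hits <- IRanges::findOverlaps(qpos, cover)
      if (length(hits) == 0) next
      agg <- tapply(wt[S4Vectors::subjectHits(hits)],
                    S4Vectors::queryHits(hits), sum)
      idx <- as.integer(names(agg))
      is_alt <- truth[[paste0("h", h, "_", f)]][idx] == truth$alt[idx]
      realised_ref[idx[!is_alt]] <- realised_ref[idx[!is_alt]] +
        agg[!is_alt]
      realised_alt[idx[is_alt]] <- realised_alt[idx[is_alt]] + agg[is_alt]
    }
  }
  # both alleles must be observable (singletons are ignored by rule 1) and
  # the site must clear the prediction depth
  detectable <- realised_ref + realised_alt >= min_pooled_depth &
    realised_ref >= 2 & realised_alt >= 2
  truth_key <- paste0(truth$pos, ":",
                      pmin(truth$ref, truth$alt), "/",
                      pmax(truth$ref, truth$alt))
  s <- put$sites
  frag <- refs$frag_id[match(s$locus_id, refs$locus_id)]
  fs <- sel$start[match(frag, sel$frag_id)]
  fe <- sel$end[match(frag, sel$frag_id)]
  ff <- sel$fill[match(frag, sel$frag_id)]
  on_rev <- s$offset >= rl
  pos <- ifelse(on_rev, fe + ff - (s$offset - rl), fs + s$offset + 1L)
  a1 <- ifelse(on_rev, chartr("ACGT", "TGCA", s$major), s$major)
  a2 <- ifelse(on_rev, chartr("ACGT", "TGCA", s$minor), s$minor)
  called_key <- paste0(pos, ":", pmin(a1, a2), "/", pmax(a1, a2))
  called_key <- called_key[!is.na(frag)]
  n_det <- sum(detectable)
  n_called <- length(called_key)
  matched_truth <- truth_key[detectable] %in% called_key
  matched_called <- called_key %in% truth_key
  list(recall = if (n_det) mean(matched_truth) else NA_real_,
       precision = if (n_called) mean(matched_called) else NA_real_,
       n_truth_detectable = n_det, n_called = n_called,
       n_matched = sum(matched_called))
}

#' Evaluate STR recovery against simulation truth
#'
#' A planted STR allele is detectable when its tandem run is fully
#' contained in the informative head or tail of at least one size-selected
#' fragment carrying that allele, and the read pairs realised for such
#' fragments (pooled over founders) reach the reference depth threshold.
#' Loci whose alleles are not mutually separable — the error-free read
#' pairs of two alleles differ at no more than `max_mismatch` positions,
#' which happens when the run reaches the edge of the informative window so
#' the length difference is absorbed by the repeat — are flagged
#' `confounded` and excluded: the read data carry no signal to resolve
#' them. A truth locus is recovered when some called STR locus has the same
#' canonical motif, at least one member consensus whose source fragment
#' covers the truth run, and exactly the detectable allele set.
#'
#' @param result A pipeline result from [run_rrl_pipeline()] on simulated
#'   reads with planted STRs.
#' @param min_ref_depth Reference depth threshold used by the run;
#'   default 10.
#' @param max_mismatch Clustering mismatch bound used by the run; default 3.
#' @return List: per-locus detail plus `n_loci`, `n_detectable` (loci with
#'   at least one detectable allele, excluding confounded loci),
#'   `n_recovered`.
#' @export
evaluate_str_recovery <- function(result, min_ref_depth = 10,
                                  max_mismatch = 3) {
  sim <- result$sim
  stopifnot(!is.null(sim))
  sel <- sim$selected
  per_frag <- sim$reads$per_fragment
  npairs <- stats::setNames(per_frag$n_pairs, per_frag$frag_id)
  truth <- sim$genomes$truth_strs
  ta <- sim$genomes$truth_str_alleles
  refs <- result$refs
  strs <- result$strs
  member_frag <- function(str) {
    refs$frag_id[match(str$members$locus_id, refs$locus_id)]
  }
  detail <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    sid <- truth$str_id[i]
    k <- truth$motif_len[i]
    canon <- canonical_rotation(truth$motif[i])
    rows <- ta[ta$str_id == sid, , drop = FALSE]
    alleles <- sort(unique(rows$units))
    det <- logical(length(alleles))
    covering <- list()      # windows fully containing the run (detectable)
    touching <- list()      # windows merely overlapping it (read evidence)
    for (ai in seq_along(alleles)) {
      a <- alleles[ai]
      ar <- rows[rows$units == a, , drop = FALSE]
      frs <- integer(0)
      frs_any <- integer(0)
      for (j in seq_len(nrow(ar))) {
        run_lo <- ar$hap_start[j]
        run_hi <- run_lo + a * k - 1L
        fsel <- sel[sel$founder == ar$founder[j] & sel$hap == ar$hap[j], ,
                    drop = FALSE]
        rlz <- sim$config$read_length
        inhead <- run_lo >= fsel$start + 1L & run_hi <= fsel$start + rlz
        intail <- run_lo >= fsel$end + fsel$fill - rlz + 1L &
          run_hi <= fsel$end + fsel$fill
        ovhead <- run_lo <= fsel$start + rlz & run_hi >= fsel$start + 1L
        ovtail <- run_lo <= fsel$end + fsel$fill &
          run_hi >= fsel$end + fsel$fill - rlz + 1L
        frs <- c(frs, fsel$frag_id[inhead | intail])
        frs_any <- c(frs_any, fsel$frag_id[ovhead | ovtail])
      }
      pooled <- sum(npairs[as.character(frs)], na.rm = TRUE)
      det[ai] <- length(frs) > 0 && pooled >= min_ref_depth
      covering[[ai]] <- frs
      touching[[ai]] <- frs_any
    }
    # alleles must be mutually separable at the clustering mismatch bound
    rlz <- sim$config$read_length
    read_pair_of <- function(frag_id) {
      fseq <- sel$sequence[match(frag_id, sel$frag_id)]
      c(substr(fseq, 1L, rlz),
        revcomp(substring(fseq, nchar(fseq) - rlz + 1L, nchar(fseq))))
    }
    # a detectable allele can be confounded by ANY other allele whose reads
    # (possibly window-truncated) fall within the mismatch bound — compare
    # against every allele with read evidence, detectable or not
    confounded <- FALSE
    rep_frag <- vapply(seq_along(alleles), function(ai) {
      if (length(covering[[ai]]) > 0) covering[[ai]][1]
      else if (length(touching[[ai]]) > 0) touching[[ai]][1]
      else NA_integer_
    }, integer(1))
    for (x in seq_along(alleles)) {
      for (y in seq_len(x - 1L)) {
        if (!(det[x] || det[y])) next
        if (is.na(rep_frag[x]) || is.na(rep_frag[y])) next
        rp1 <- read_pair_of(rep_frag[x])
        rp2 <- read_pair_of(rep_frag[y])
        if (nchar(rp1[1]) != nchar(rp2[1]) ||
            nchar(rp1[2]) != nchar(rp2[2])) next
        mm <- hamming_bounded(rp1[1], rp2[1], max_mismatch)
        if (mm >= 0 &&
            hamming_bounded(rp1[2], rp2[2], max_mismatch - mm) >= 0) {
          confounded <- TRUE
        }
      }
    }
    a_det <- alleles[det]
    if (confounded) a_det <- integer(0)
    recovered <- FALSE
    if (length(a_det) > 0) {
      # an undetectable allele's reads can still merge into the called
      # cluster (window-truncated run), so the member match accepts any
      # run-overlapping fragment of the locus
      truth_frags <- unique(unlist(touching))
      for (s in strs) {
        if (s$motif != canon) next
        mf <- member_frag(s)
        if (!any(mf %in% truth_frags, na.rm = TRUE)) next
        if (identical(sort(unique(s$alleles)), sort(unique(a_det)))) {
          recovered <- TRUE
          break
        }
      }
    }
    detail[[i]] <- data.frame(str_id = sid, motif = canon,
                              n_alleles = length(alleles),
                              n_detectable = length(a_det),
                              confounded = confounded,
                              recovered = recovered)
  }
  detail <- if (length(detail)) do.call(rbind, detail) else
    data.frame(str_id = integer(0), motif = character(0),
               n_alleles = integer(0), n_detectable = integer(0),
               confounded = logical(0), recovered = logical(0))
  list(detail = detail, n_loci = nrow(truth),
       n_detectable = sum(detail$n_detectable > 0),
       n_recovered = sum(detail$recovered))
}
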