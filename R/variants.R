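#' Predict SNPs from an allele depth table
#'
#' A predicted SNP is any (locus, offset) with at least two observed bases
#' and a pooled depth (all founders, all bases) at or above
#' `min_pooled_depth`.
#'
#' @param adt An `allele_depth_table` from [tally_alleles()].
#' @param min_pooled_depth Pooled depth threshold; default 100.
#' @return An object of class `predicted_snps`: `sites` (locus_id,
#'   locus_index, offset 0-based, pooled_depth), `counts` (sites x founders
#'   x bases integer array) and `founders`.
#' @export
predict_snps <- function(adt, min_pooled_depth = 100) {
  d <- dim(adt)
  n_off <- d[2]; n_f <- d[3]; n_loci <- d[4]
  founders <- dimnames(adt)[[3]]
  locus_ids <- dimnames(adt)[[4]]
  arr <- as.integer(adt)
  dim(arr) <- d
  empty <- function() {
    structure(list(
      sites = data.frame(locus_id = character(0), locus_index = integer(0),
                         offset = integer(0), pooled_depth = integer(0),
                         stringsAsFactors = FALSE),
      counts = array(0L, dim = c(0, n_f, 4)),
      founders = founders), class = "predicted_snps")
  }
  if (n_loci == 0) return(empty())
  pooled <- array(0L, dim = c(4, n_off, n_loci))
  for (f in seq_len(n_f)) {
    sl <- arr[, , f, , drop = FALSE]
    dim(sl) <- c(4, n_off, n_loci)
    pooled <- pooled + sl
  }
  nbase <- colSums(pooled > 0)           # n_off x n_loci
  depth <- colSums(pooled)               # n_off x n_loci
  dim(nbase) <- dim(depth) <- c(n_off, n_loci)
  sel <- which(nbase >= 2 & depth >= min_pooled_depth, arr.ind = TRUE)
  n <- nrow(sel)
  if (n == 0) return(empty())
  off <- sel[, 1]; loc <- sel[, 2]
  i_idx <- rep(seq_len(n), n_f * 4L)
  f_idx <- rep(rep(seq_len(n_f), each = n), 4L)
  b_idx <- rep(1:4, each = n * n_f)
  lin <- b_idx + 4L * (off[i_idx] - 1L) + 4L * n_off * (f_idx - 1L) +
    4L * n_off * n_f * (loc[i_idx] - 1L)
  counts <- array(arr[lin], dim = c(n, n_f, 4),
                  dimnames = list(NULL, founders, c("A", "C", "G", "T")))
  ord <- order(loc, off)
  structure(list(
    sites = data.frame(locus_id = locus_ids[loc[ord]],
                       locus_index = loc[ord], offset = off[ord] - 1L,
                       pooled_depth = depth[cbind(off, loc)][ord],
                       stringsAsFactors = FALSE),
    counts = counts[ord, , , drop = FALSE],
    founders = founders), class = "predicted_snps")
}

#' Depth-based SNP filter cascade
#'
#' Applies, in order, on per-founder base depths: (1) alleles with depth
#' exactly 1 in a founder are zeroed in that founder; (2) sites where any
#' founder's total depth exceeds `max_founder_depth` are removed; (3) an
#' allele is "present" in a founder when its depth exceeds
#' `presence_frac` of that founder's total site depth — sites with three or
#' more present alleles in any founder, or whose presence-qualified allele
#' set (alleles present in at least one founder) is not exactly two, are
#' removed; (4) for founders with exactly
#' two present alleles, sites where the depth ratio between those alleles
#' exceeds `max_ratio` are removed. All comparisons are strict, matching the
#' "more than" phrasing of each rule. Survivors carry major/minor labels
#' (major = larger pooled depth; ties to the lexicographically smaller
#' base).
#'
#' @param pred A `predicted_snps` object.
#' @param max_founder_depth Per-founder depth cap (strict); default 300.
#' @param presence_frac Presence threshold as a fraction of founder depth
#'   (strict); default 0.05.
#' @param max_ratio Allele depth ratio cap (strict); default 3.
#' @return An object of class `putative_snps`: `sites` (locus_id,
#'   locus_index, offset, major, minor, pooled depths per allele), `d_major`
#'   / `d_minor` (site x founder post-rule-1 depth matrices), `founders`,
#'   `n_predicted`, `n_putative`.
#' @export
filter_snps <- function(pred, max_founder_depth = 300, presence_frac = 0.05,
                        max_ratio = 3) {
  stopifnot(inherits(pred, "predicted_snps"))
  cnt <- pred$counts
  n <- dim(cnt)[1]; n_f <- dim(cnt)[2]
  if (n == 0) {
    return(structure(list(sites = cbind(pred$sites[0, ],
                                        data.frame(major = character(0),
                                                   minor = character(0),
                                                   pooled_major = integer(0),
                                                   pooled_minor = integer(0))),
                          d_major = matrix(0L, 0, n_f),
                          d_minor = matrix(0L, 0, n_f),
                          founders = pred$founders,
                          n_predicted = 0L, n_putative = 0L),
                     class = "putative_snps"))
  }
  bases <- c("A", "C", "G", "T")
  cnt[cnt == 1L] <- 0L                                     # rule 1
  slice <- function(b) matrix(cnt[, , b], nrow = n)
  ftot <- slice(1) + slice(2) + slice(3) + slice(4)        # n x F
  keep2 <- rowSums(ftot > max_founder_depth) == 0          # rule 2
  pooled <- vapply(1:4, function(b) rowSums(slice(b)), numeric(n))
  pooled <- matrix(pooled, nrow = n)                       # n x 4
  thr <- presence_frac * ftot
  pres_by_base <- lapply(1:4, function(b) slice(b) > thr)
  npres <- Reduce(`+`, pres_by_base)
  # allele qualifies when present in at least one founder; a site is a SNP
  # only when exactly two alleles qualify
  pres_any <- vapply(pres_by_base, function(p) rowSums(p) > 0, logical(n))
  pres_any <- matrix(pres_any, nrow = n)                   # n x 4
  keep_biallelic <- rowSums(pres_any) == 2
  keep3 <- rowSums(npres >= 3) == 0                        # rule 3
  b1 <- max.col(pres_any, ties.method = "first")
  b2 <- max.col(pres_any, ties.method = "last")
  i_idx <- rep(seq_len(n), n_f)
  f_idx <- rep(seq_len(n_f), each = n)
  d1 <- matrix(cnt[cbind(i_idx, f_idx, b1[i_idx])], n, n_f)
  d2 <- matrix(cnt[cbind(i_idx, f_idx, b2[i_idx])], n, n_f)
  both <- (d1 > thr) & (d2 > thr)
  bad_ratio <- both & (pmax(d1, d2) > max_ratio * pmin(d1, d2))
  keep4 <- rowSums(bad_ratio) == 0                         # rule 4
  keep <- keep2 & keep_biallelic & keep3 & keep4
  p1 <- pooled[cbind(seq_len(n), b1)]
  p2 <- pooled[cbind(seq_len(n), b2)]
  maj_is_b1 <- p1 >= p2   # tie: b1 has the lexicographically smaller base
  maj <- ifelse(maj_is_b1, b1, b2)
  mino <- ifelse(maj_is_b1, b2, b1)
  dmaj <- ifelse(matrix(maj_is_b1, n, n_f), d1, d2)
  dmin <- ifelse(matrix(maj_is_b1, n, n_f), d2, d1)
  sites <- cbind(pred$sites,
                 data.frame(major = bases[maj], minor = bases[mino],
                            pooled_major = pmax(p1, p2),
                            pooled_minor = pmin(p1, p2),
                            stringsAsFactors = FALSE))
  out <- list(sites = sites[keep, , drop = FALSE],
              d_major = matrix(dmaj[keep, ], ncol = n_f,
                               dimnames = list(NULL, pred$founders)),
              d_minor = matrix(dmin[keep, ], ncol = n_f,
                               dimnames = list(NULL, pred$founders)),
              founders = pred$founders,
              n_predicted = n, n_putative = sum(keep))
  rownames(out$sites) <- NULL
  structure(out, class = "putative_snps")
}

#' Recast putative SNPs as a predicted-SNP object
#'
#' Rebuilds the counts array from the stored per-allele depths so that the
#' filter cascade can be re-applied (it is idempotent on its own output).
#'
#' @param put A `putative_snps` object.
#' @return A `predicted_snps` object.
#' @export
putative_to_predicted <- function(put) {
  stopifnot(inherits(put, "putative_snps"))
  n <- nrow(put$sites); n_f <- length(put$founders)
  counts <- array(0L, dim = c(n, n_f, 4))
  bases <- c("A", "C", "G", "T")
  if (n > 0) {
    bj <- match(put$sites$major, bases)
    bn <- match(put$sites$minor, bases)
    i_idx <- rep(seq_len(n), n_f)
    f_idx <- rep(seq_len(n_f), each = n)
    counts[cbind(i_idx, f_idx, bj[i_idx])] <- as.integer(put$d_major)
    counts[cbind(i_idx, f_idx, bn[i_idx])] <- as.integer(put$d_minor)
  }
  structure(list(sites = put$sites[, c("locus_id", "locus_index", "offset",
                                       "pooled_depth")],
                 counts = counts, founders = put$founders),
            class = "predicted_snps")
}

#' Call per-founder genotypes for the analysis SNP set
#'
#' A SNP enters the genotype matrix only when every founder's total depth
#' at the site reaches `min_founder_depth`. Per founder, the genotype is
#' heterozygous when both alleles are present under the presence rule
#' (depth strictly above `presence_frac` of the founder total), else
#' homozygous for the present allele.
#'
#' @param put A `putative_snps` object.
#' @param min_founder_depth Minimum per-founder depth; default 20.
#' @param presence_frac Presence threshold; default 0.05.
#' @return An object of class `genotype_matrix`: `geno` (site x founder
#'   matrix of "hom_major"/"het"/"hom_minor"), `m` (major-allele dosage
#'   0/1/2), `sites` (the retained site table).
#' @export
call_genotypes <- function(put, min_founder_depth = 20, presence_frac = 0.05) {
  stopifnot(inherits(put, "putative_snps"))
  tot <- put$d_major + put$d_minor
  keep <- rowSums(tot < min_founder_depth) == 0
  dmaj <- put$d_major[keep, , drop = FALSE]
  dmin <- put$d_minor[keep, , drop = FALSE]
  tot <- tot[keep, , drop = FALSE]
  pm <- dmaj > presence_frac * tot
  pn <- dmin > presence_frac * tot
  geno <- matrix("hom_major", nrow(tot), ncol(tot),
                 dimnames = list(NULL, put$founders))
  geno[pm & pn] <- "het"
  geno[!pm & pn] <- "hom_minor"
  sites <- put$sites[keep, , drop = FALSE]
  rownames(sites) <- NULL
  rn <- paste0(sites$locus_id, ":", sites$offset)
  rownames(geno) <- rn
  m <- (geno == "hom_major") * 2L + (geno == "het") * 1L
  structure(list(geno = geno, m = m, sites = sites,
                 founders = put$founders),
            class = "genotype_matrix")
}

#' Construct a genotype matrix directly from genotype codes
#'
#' For analyses that start from an existing loci-by-founder genotype table
#' (e.g. published summary tables or synthetic cohorts) rather than from the
#' mapping pipeline.
#'
#' @param geno Character matrix (loci x founders) of
#'   "hom_major"/"het"/"hom_minor" codes; column names are founder labels.
#' @return A `genotype_matrix`.
#' @export
genotype_matrix <- function(geno) {
  stopifnot(is.matrix(geno),
            all(geno %in% c("hom_major", "het", "hom_minor")))
  if (is.null(colnames(geno))) {
    colnames(geno) <- make.unique(rep(LETTERS, length.out = ncol(geno)),
                                  sep = "")[seq_len(ncol(geno))]
  }
  m <- (geno == "hom_major") * 2L + (geno == "het") * 1L
  structure(list(geno = geno, m = m, sites = NULL,
                 founders = colnames(geno)),
            class = "genotype_matrix")
}

#' Construct a haplotype set
#'
#' @param locus_id Locus identifier.
#' @param haplotypes List of haplotypes, each a list with `alleles` (named
#'   by offset) and `depth`.
#' @param status "determined" or "undetermined".
#' @param offsets The SNP offsets of the locus.
#' @return An object of class `haplotype_set`.
#' @export
haplotype_set <- function(locus_id, haplotypes, status,
                          offsets = integer(0)) {
  stopifnot(status %in% c("determined", "undetermined"))
  structure(list(locus_id = locus_id, offsets = offsets,
                 haplotypes = haplotypes, status = status),
            class = "haplotype_set")
}

#' Phase multi-SNP loci by depth matching
#'
#' Within a consensus locus carrying two or more putative SNPs, alleles at
#' different offsets that are supported by (nearly) the same pooled read
#' depth are taken to ride on the same haplotype. All (offset, allele,
#' pooled depth) records are sorted by depth, descending; each record joins
#' the first group whose running mean depth is within `tolerance`
#' (strictly) and which has no allele at that offset yet, else founds a new
#' group. The locus is `determined` only when every group covers every
#' offset exactly once and no record could have joined two different groups
#' (the grouping is unique); otherwise `undetermined`.
#'
#' @param put A `putative_snps` object.
#' @param tolerance Depth difference treated as sequencing noise (strict
#'   upper bound); default 4.
#' @return A list of [haplotype_set()] objects, one per locus with at least
#'   two putative SNPs.
#' @export
deduce_haplotypes <- function(put, tolerance = 4) {
  stopifnot(inherits(put, "putative_snps"))
  s <- put$sites
  pooled_maj <- rowSums(put$d_major)
  pooled_min <- rowSums(put$d_minor)
  loci <- unique(s$locus_id[duplicated(s$locus_id)])
  out <- vector("list", length(loci))
  for (li in seq_along(loci)) {
    rows <- which(s$locus_id == loci[li])
    rec <- data.frame(
      offset = rep(s$offset[rows], 2L),
      allele = c(s$major[rows], s$minor[rows]),
      depth = c(pooled_maj[rows], pooled_min[rows]),
      stringsAsFactors = FALSE)
    rec <- rec[order(-rec$depth, rec$offset, rec$allele), ]
    groups <- list()
    ambiguous <- FALSE
    for (r in seq_len(nrow(rec))) {
      depth_ok <- vapply(groups, function(grp) {
        abs(rec$depth[r] - mean(grp$depths)) < tolerance
      }, logical(1))
      # two depth-compatible groups means the assignment is not unique,
      # whether or not an offset slot happens to block one of them
      if (sum(depth_ok) >= 2) ambiguous <- TRUE
      elig <- which(depth_ok & vapply(groups, function(grp) {
        !(rec$offset[r] %in% grp$offsets)
      }, logical(1)))
      if (length(elig) >= 1) {
        g <- elig[1]
        groups[[g]]$offsets <- c(groups[[g]]$offsets, rec$offset[r])
        groups[[g]]$alleles <- c(groups[[g]]$alleles, rec$allele[r])
        groups[[g]]$depths <- c(groups[[g]]$depths, rec$depth[r])
      } else {
        groups[[length(groups) + 1L]] <- list(offsets = rec$offset[r],
                                              alleles = rec$allele[r],
                                              depths = rec$depth[r])
      }
    }
    offs <- sort(unique(rec$offset))
    complete <- all(vapply(groups, function(g) {
      length(g$offsets) == length(offs)
    }, logical(1)))
    status <- if (complete && !ambiguous) "determined" else "undetermined"
    haps <- lapply(groups, function(g) {
      ord <- order(g$offsets)
      list(alleles = stats::setNames(g$alleles[ord],
                                     as.character(g$offsets[ord])),
           depth = mean(g$depths))
    })
    out[[li]] <- haplotype_set(loci[li], haps, status, offs)
  }
  out
}

#' Summarise phased loci
#'
#' @param hapsets List of [haplotype_set()] objects.
#' @return A list: `n_determined`, `n_undetermined`, `pct_determined`
#'   (percent, one decimal; `NA` when there are no loci), and `histogram`
#'   (determined loci tabulated by haplotype number).
#' @export
summarize_haplotypes <- function(hapsets) {
  status <- vapply(hapsets, function(h) h$status, character(1))
  nhap <- vapply(hapsets, function(h) length(h$haplotypes), integer(1))
  n_det <- sum(status == "determined")
  n_undet <- sum(status == "undetermined")
  hist <- table(nhap[status == "determined"])
  list(n_determined = n_det, n_undetermined = n_undet,
       pct_determined = if (n_det + n_undet == 0) NA_real_
                        else percent_of(n_det, n_det + n_undet),
       histogram = hist)
}

#' Write putative SNPs as VCF
#'
#' One contig per consensus locus; positions are 1-based consensus
#' coordinates (forward offsets map to positions 1-101, reverse offsets to
#' positions 300-200 with alleles complemented onto the consensus strand).
#' REF is the major allele, ALT the minor; per-founder fields carry
#' GT (presence-rule genotype) and AD (major,minor depths).
#'
#' @param put A `putative_snps` object.
#' @param path Output path.
#' @param read_length Mate length used for the offset/position conversion.
#' @param presence_frac Presence threshold for the GT field; default 0.05.
#' @return Invisibly, `path`.
#' @export
write_snp_vcf <- function(put, path, read_length = 101,
                          presence_frac = 0.05) {
  s <- put$sites
  n <- nrow(s)
  on_rev <- s$offset >= read_length
  pos <- ifelse(on_rev, 300L - (s$offset - read_length), s$offset + 1L)
  ref <- ifelse(on_rev, chartr("ACGT", "TGCA", s$major), s$major)
  alt <- ifelse(on_rev, chartr("ACGT", "TGCA", s$minor), s$minor)
  tot <- put$d_major + put$d_minor
  pm <- put$d_major > presence_frac * tot
  pn <- put$d_minor > presence_frac * tot
  gt <- matrix("0/0", n, length(put$founders))
  gt[pm & pn] <- "0/1"
  gt[!pm & pn] <- "1/1"
  gt[tot == 0] <- "./."
  fields <- matrix(paste0(gt, ":", put$d_major, ",", put$d_minor),
                   n, length(put$founders))
  header <- c("##fileformat=VCFv4.2",
              "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Pooled depth\">",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              "##FORMAT=<ID=AD,Number=2,Type=Integer,Description=\"Major,minor depth\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", put$founders), collapse = "\t"))
  body <- if (n == 0) character(0) else {
    paste(s$locus_id, pos, ".", ref, alt, ".", "PASS",
          paste0("DP=", s$pooled_major + s$pooled_minor), "GT:AD",
          apply(fields, 1, paste, collapse = "\t"), sep = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}
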