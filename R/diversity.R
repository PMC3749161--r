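#' Per-founder zygosity summary
#'
#' @param gm A `genotype_matrix`.
#' @return Data frame per founder: counts of major-homozygous,
#'   minor-homozygous and heterozygous loci (a partition of the locus set)
#'   and the heterozygous percentage (one decimal).
#' @export
zygosity_summary <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  g <- gm$geno
  rows <- lapply(colnames(g), function(f) {
    data.frame(founder = f,
               n_hom_major = sum(g[, f] == "hom_major"),
               n_hom_minor = sum(g[, f] == "hom_minor"),
               n_het = sum(g[, f] == "het"),
               pct_het = percent_of(sum(g[, f] == "het"), nrow(g)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Count single-founder-specific alleles
#'
#' An allele is founder-specific when it is present (carried on at least one
#' haplotype) in exactly one founder. Both alleles of every locus are
#' examined: the minor allele is present unless the founder is
#' major-homozygous, the major allele unless minor-homozygous.
#'
#' @param gm A `genotype_matrix`.
#' @return Named integer vector of specific-allele counts per founder.
#' @export
count_specific_alleles <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  g <- gm$geno
  pres_min <- g != "hom_major"
  pres_maj <- g != "hom_minor"
  spec <- stats::setNames(rep(0L, ncol(g)), colnames(g))
  for (pres in list(pres_min, pres_maj)) {
    one <- rowSums(pres) == 1
    if (any(one)) {
      idx <- max.col(pres[one, , drop = FALSE], ties.method = "first")
      tab <- tabulate(idx, nbins = ncol(g))
      spec <- spec + tab
    }
  }
  spec
}

#' Pairwise shared-genotype counts and frequencies
#'
#' For each founder pair, the number of loci with an identical genotype
#' call, and that number as a percentage of all loci.
#'
#' @param gm A `genotype_matrix`.
#' @return A list with `counts` and `percent` (symmetric matrices, `NA`
#'   diagonal) and `table`: the conventional layout with counts above and
#'   percentages below the diagonal.
#' @export
pairwise_shared_genotypes <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  g <- gm$geno
  nf <- ncol(g)
  counts <- matrix(NA_real_, nf, nf, dimnames = list(colnames(g), colnames(g)))
  for (i in seq_len(nf)) {
    for (j in seq_len(nf)) {
      if (i != j) counts[i, j] <- sum(g[, i] == g[, j])
    }
  }
  percent <- percent_of(counts, nrow(g))
  tbl <- counts
  tbl[lower.tri(tbl)] <- percent[lower.tri(percent)]
  list(counts = counts, percent = percent, table = tbl)
}

#' Correlation matrix of founder major-allele dosages
#'
#' Pearson correlation between the founders' major-allele count vectors
#' (0/1/2 per locus), the similarity measure feeding PCA, MDS and the
#' bootstrapped dendrogram.
#'
#' @param gm A `genotype_matrix` (or a plain dosage matrix, loci x founders).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
founder_correlation <- function(gm) {
  m <- if (inherits(gm, "genotype_matrix")) gm$m else gm
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    stop("zero-variance founder(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  }
  cor(m)
}

# eigenvectors flipped so each one's largest-magnitude entry is positive
fix_signs <- function(v) {
  for (j in seq_len(ncol(v))) {
    k <- which.max(abs(v[, j]))
    if (v[k, j] < 0) v[, j] <- -v[, j]
  }
  v
}

#' PCA of founders on the dosage correlation matrix
#'
#' Eigendecomposition of the founder-by-founder correlation matrix:
#' component variance proportions are eigenvalues over the founder count,
#' and founder coordinates on component i are the i-th eigenvector scaled by
#' the square root of its eigenvalue (i.e. correlation-PCA variable
#' loadings, one point per founder). Eigenvector signs are fixed so the
#' largest-magnitude entry of each is positive.
#'
#' @param x A `genotype_matrix` or a correlation matrix.
#' @return List: `coordinates` (founders x components), `proportions`
#'   (variance proportions, summing to 1), `eigenvalues`.
#' @export
pca_founders <- function(x) {
  C <- if (inherits(x, "genotype_matrix")) founder_correlation(x) else x
  if (any(!is.finite(C))) stop("non-finite correlations")
  e <- eigen(C, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  vec <- fix_signs(e$vectors)
  coords <- sweep(vec, 2, sqrt(vals), `*`)
  dimnames(coords) <- list(rownames(C), paste0("PC", seq_along(vals)))
  list(coordinates = coords, proportions = vals / ncol(C),
       eigenvalues = vals)
}

#' Classical (Torgerson) MDS of founders
#'
#' Uses one minus the dosage correlation as the distance: the squared
#' distance matrix is double-centred, eigendecomposed, and the top-`k`
#' coordinates (positive eigenvalues only) returned, with the PCA sign
#' convention.
#'
#' @param x A `genotype_matrix` or a correlation matrix.
#' @param k Number of dimensions requested; default 2.
#' @return List: `coordinates` (founders x available dimensions, with a
#'   warning when fewer than `k` positive eigenvalues exist) and
#'   `eigenvalues`.
#' @export
mds_founders <- function(x, k = 2) {
  C <- if (inherits(x, "genotype_matrix")) founder_correlation(x) else x
  D <- 1 - C
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D^2) %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  pos <- which(e$values > sqrt(.Machine$double.eps))
  if (length(pos) < k) {
    warning("only ", length(pos), " positive eigenvalue(s); returning ",
            length(pos), " dimension(s)")
  }
  use <- pos[seq_len(min(k, length(pos)))]
  vec <- fix_signs(e$vectors[, use, drop = FALSE])
  coords <- sweep(vec, 2, sqrt(e$values[use]), `*`)
  dimnames(coords) <- list(rownames(C), paste0("Dim", seq_along(use)))
  list(coordinates = coords, eigenvalues = e$values)
}

# sorted-member signature for every internal node of an hclust tree
hclust_node_patterns <- function(hc) {
  labs <- hc$labels
  n <- length(labs)
  members <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    m <- hc$merge[i, ]
    grab <- function(x) if (x < 0) labs[-x] else members[[x]]
    members[[i]] <- sort(c(grab(m[1]), grab(m[2])))
  }
  vapply(members, paste, character(1), collapse = ",")
}

# AU p-value from per-scale recovery frequencies: weighted least squares of
# the normal quantiles z(r) = qnorm(1 - bp(r)) on (sqrt(r), 1/sqrt(r));
# AU = 1 - pnorm(v - c). Degenerate nodes (recovered always/never at nearly
# every scale) collapse to 1/0.
au_fit <- function(bp, scales, nboot) {
  eps <- 0.5 / nboot
  use <- bp > 0 & bp < 1
  if (sum(use) < 2) {
    return(if (mean(bp) > 0.5) 1 else 0)
  }
  b <- pmin(pmax(bp[use], eps), 1 - eps)
  r <- scales[use]
  z <- qnorm(1 - b)
  X <- cbind(sqrt(r), 1 / sqrt(r))
  w <- nboot * dnorm(qnorm(b))^2 / (b * (1 - b))
  XtW <- t(X * w)
  coef <- tryCatch(solve(XtW %*% X, XtW %*% z),
                   error = function(e) NULL)
  if (is.null(coef)) return(if (mean(bp) > 0.5) 1 else 0)
  unname(1 - pnorm(coef[1] - coef[2]))
}

#' Average-linkage founder dendrogram with multiscale-bootstrap support
#'
#' Clusters founders by average linkage on one minus the dosage
#' correlation, then assesses each internal node by multiscale bootstrap:
#' for scale factors r (default 0.5-1.4 in steps of 0.1), `nboot` replicates
#' resample `floor(n_loci * r)` loci with replacement, the tree is rebuilt,
#' and the node's recovery frequency recorded. BP is the recovery frequency
#' at r = 1; the approximately unbiased p-value (AU) comes from a
#' normal-quantile regression of the per-scale frequencies on sqrt(r) and
#' 1/sqrt(r). Deterministic given `seed`.
#'
#' @param gm A `genotype_matrix` (or dosage matrix) with at least 3
#'   founders.
#' @param nboot Bootstrap replicates per scale; default 10000. Below 100 a
#'   warning is issued (the AU fit is unstable).
#' @param seed Optional RNG seed.
#' @param scales Scale factors; must include 1.
#' @return Object of class `founder_hclust`: the `hclust` tree and a
#'   `nodes` table (members, `bp`, `au` per internal node).
#' @export
hclust_founders <- function(gm, nboot = 10000, seed = NULL,
                            scales = seq(0.5, 1.4, by = 0.1)) {
  m <- if (inherits(gm, "genotype_matrix")) gm$m else gm
  stopifnot(ncol(m) >= 3, any(abs(scales - 1) < 1e-9))
  if (nboot < 100) warning("nboot < 100: AU estimates are unstable")
  if (!is.null(seed)) set.seed(seed)
  C <- founder_correlation(m)
  hc <- hclust(as.dist(1 - C), method = "average")
  hc$labels <- colnames(m)
  pats <- hclust_node_patterns(hc)
  n <- nrow(m)
  counts <- matrix(0L, length(pats), length(scales))
  for (si in seq_along(scales)) {
    bn <- max(3L, floor(n * scales[si]))
    for (b in seq_len(nboot)) {
      idx <- sample.int(n, bn, replace = TRUE)
      mb <- m[idx, , drop = FALSE]
      sds <- apply(mb, 2, sd)
      if (any(sds == 0)) next
      hb <- hclust(as.dist(1 - cor(mb)), method = "average")
      hb$labels <- colnames(m)
      counts[, si] <- counts[, si] + (pats %in% hclust_node_patterns(hb))
    }
  }
  bp_mat <- counts / nboot
  r1 <- which(abs(scales - 1) < 1e-9)[1]
  au <- vapply(seq_along(pats), function(i) {
    au_fit(bp_mat[i, ], scales, nboot)
  }, numeric(1))
  structure(list(
    hclust = hc,
    nodes = data.frame(node = seq_along(pats), members = pats,
                       bp = bp_mat[, r1], au = au, stringsAsFactors = FALSE),
    bp_by_scale = bp_mat, scales = scales, nboot = nboot),
    class = "founder_hclust")
}

#' Newick export of a supported dendrogram
#'
#' Internal nodes are labelled `AU|BP` (both as probabilities to 3
#' decimals); branch lengths come from the merge heights.
#'
#' @param fh A `founder_hclust`.
#' @param path Optional output file.
#' @return The Newick string (invisibly when written to `path`).
#' @export
as_newick <- function(fh, path = NULL) {
  hc <- fh$hclust
  au <- fh$nodes$au
  bp <- fh$nodes$bp
  labs <- hc$labels
  render <- function(x, parent_h) {
    if (x < 0) {
      return(sprintf("%s:%.6f", labs[-x], parent_h))
    }
    h <- hc$height[x]
    kids <- paste(render(hc$merge[x, 1], h), render(hc$merge[x, 2], h),
                  sep = ",")
    sprintf("(%s)%.3f|%.3f:%.6f", kids, au[x], bp[x], parent_h - h)
  }
  root <- nrow(hc$merge)
  h <- hc$height[root]
  nwk <- sprintf("(%s,%s)%.3f|%.3f;",
                 render(hc$merge[root, 1], h), render(hc$merge[root, 2], h),
                 au[root], bp[root])
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}

#' Genome-wide SNP extrapolation and sequence representation
#'
#' `extrapolate_genome()` scales the observed SNP density (SNPs per
#' informative consensus base) up to the genome:
#' `snp_count / (consensus_count * informative_len) * genome_size`.
#' `genome_representation()` reports how much of the genome the consensus set
#' covers: `consensus_count * informative_len`, both as bases/Gb and as a
#' genome fraction.
#'
#' @param snp_count Putative SNPs observed.
#' @param consensus_count Consensus sequences screened.
#' @param informative_len Informative bases per consensus; default 202.
#' @param genome_size Assumed genome size in bases; default 1.5e9.
#' @return `extrapolate_genome()`: the genome-wide SNP estimate.
#'   `genome_representation()`: list with `bases`, `gb`, `fraction`.
#' @export
extrapolate_genome <- function(snp_count, consensus_count,
                               informative_len = 202, genome_size = 1.5e9) {
  if (consensus_count <= 0) stop("consensus_count must be positive")
  stopifnot(snp_count >= 0, informative_len > 0, genome_size > 0)
  snp_count / (consensus_count * informative_len) * genome_size
}

#' @rdname extrapolate_genome
#' @export
genome_representation <- function(consensus_count, informative_len = 202,
                           genome_size = 1.5e9) {
  stopifnot(consensus_count >= 0, informative_len > 0, genome_size > 0)
  bases <- consensus_count * informative_len
  list(bases = bases, gb = bases / 1e9, fraction = bases / genome_size)
}
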