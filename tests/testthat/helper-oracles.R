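# Independent brute-force oracles. These deliberately re-derive each
# contract with the plainest possible R code (loops, table()) and never call
# into the package's own compiled paths.

oracle_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# all-pairs single-link-to-representative clustering, same processing order
oracle_cluster <- function(seqs, max_mismatch) {
  reps <- character(0)
  out <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    hit <- 0L
    for (j in seq_along(reps)) {
      if (oracle_hamming(reps[j], seqs[i]) <= max_mismatch) {
        hit <- j
        break
      }
    }
    if (hit == 0L) {
      reps <- c(reps, seqs[i])
      hit <- length(reps)
    }
    out[i] <- hit
  }
  out
}

# exhaustive scan over every reference, minimum mismatches, lowest-id ties
oracle_map <- function(qf, qr, rf, rr, max_mismatch) {
  n <- length(qf)
  locus <- rep(NA_integer_, n)
  mism <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    best <- NA_integer_
    bestmm <- max_mismatch + 1L
    for (j in seq_along(rf)) {
      mm <- oracle_hamming(qf[i], rf[j]) + oracle_hamming(qr[i], rr[j])
      if (mm < bestmm) {
        bestmm <- mm
        best <- j
      }
    }
    if (!is.na(best)) {
      locus[i] <- best
      mism[i] <- bestmm
    }
  }
  list(locus = locus, mismatches = mism)
}

# per-column vote with A<C<G<T tie-break
oracle_consensus <- function(seqs) {
  mat <- do.call(rbind, strsplit(seqs, ""))
  paste(apply(mat, 2, function(col) {
    tab <- table(factor(col, levels = c("A", "C", "G", "T")))
    names(tab)[which.max(tab)]
  }), collapse = "")
}

# straight-line reimplementation of the four filtering rules on one site:
# counts is a founders x 4 matrix (A,C,G,T). Returns NULL when the site is
# removed, else list(major, minor).
oracle_filter_site <- function(counts, cap = 300, frac = 0.05, ratio = 3) {
  bases <- c("A", "C", "G", "T")
  counts[counts == 1] <- 0                         # rule 1
  ftot <- rowSums(counts)
  if (any(ftot > cap)) return(NULL)                # rule 2
  present <- counts > frac * ftot                  # rule 3 presence
  if (any(rowSums(present) >= 3)) return(NULL)
  allele_set <- which(colSums(present) > 0)
  if (length(allele_set) != 2) return(NULL)
  for (f in seq_len(nrow(counts))) {               # rule 4
    pf <- which(present[f, ])
    if (length(pf) == 2) {
      d <- counts[f, pf]
      if (max(d) > ratio * min(d)) return(NULL)
    }
  }
  pooled <- colSums(counts)[allele_set]
  ord <- order(-pooled, allele_set)
  list(major = bases[allele_set[ord[1]]], minor = bases[allele_set[ord[2]]])
}

# a predicted_snps object from a site x founder x base counts array
make_predicted <- function(counts, founders = NULL) {
  n <- dim(counts)[1]
  if (is.null(founders)) {
    founders <- LETTERS[seq_len(dim(counts)[2])]
  }
  pooled <- apply(counts, 1, sum)
  structure(list(
    sites = data.frame(locus_id = sprintf("L%05d", seq_len(n)),
                       locus_index = seq_len(n),
                       offset = rep(0L, n), pooled_depth = pooled,
                       stringsAsFactors = FALSE),
    counts = counts, founders = founders), class = "predicted_snps")
}

# a putative_snps object straight from allele depth matrices
make_putative <- function(locus_id, offset, major, minor, d_major, d_minor,
                          founders = colnames(d_major)) {
  if (is.null(founders)) founders <- LETTERS[seq_len(ncol(d_major))]
  structure(list(
    sites = data.frame(locus_id = locus_id, locus_index = seq_along(locus_id),
                       offset = offset,
                       pooled_depth = rowSums(d_major) + rowSums(d_minor),
                       major = major, minor = minor,
                       pooled_major = rowSums(d_major),
                       pooled_minor = rowSums(d_minor),
                       stringsAsFactors = FALSE),
    d_major = d_major, d_minor = d_minor, founders = founders,
    n_predicted = length(locus_id), n_putative = length(locus_id)),
    class = "putative_snps")
}

# genotype matrix with given per-founder code vectors
make_gm <- function(...) {
  genotype_matrix(cbind(...))
}

random_seq <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

mutate_seq <- function(s, k) {
  ch <- strsplit(s, "")[[1]]
  pos <- sample(length(ch), k)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

# enumerate every (start, motif-length) tandem run at or above threshold;
# reports canonical motifs of maximal runs, for comparison with detect_strs
oracle_strs <- function(seq, thr = c(8, 5, 4)) {
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  canonical <- function(m) {
    k <- nchar(m)
    min(vapply(seq_len(k), function(i) {
      paste0(substr(m, i, k), substr(m, 1, i - 1))
    }, character(1)))
  }
  subperiodic <- function(m) {
    k <- nchar(m)
    any(vapply(seq_len(k - 1), function(d) {
      k %% d == 0 && strrep(substr(m, 1, d), k / d) == m
    }, logical(1)))
  }
  hits <- list()
  for (k in 2:4) {
    for (i in seq_len(L - 2 * k + 1)) {
      motif <- paste(ch[i:(i + k - 1)], collapse = "")
      if (subperiodic(motif)) next
      u <- 1L
      while (i + (u + 1) * k - 1 <= L &&
             all(ch[(i + u * k):(i + (u + 1) * k - 1)] ==
                   ch[i:(i + k - 1)])) {
        u <- u + 1L
      }
      if (u >= thr[k - 1]) {
        hits[[length(hits) + 1]] <- data.frame(
          start = i, end = i + u * k - 1, k = k,
          motif_canon = canonical(motif), n_units = u,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(start = integer(0), end = integer(0), k = integer(0),
                      motif_canon = character(0), n_units = integer(0)))
  }
  h <- do.call(rbind, hits)
  # keep, per canonical motif, maximal non-nested runs
  keep <- rep(TRUE, nrow(h))
  for (i in seq_len(nrow(h))) {
    for (j in seq_len(nrow(h))) {
      if (i != j && h$motif_canon[i] == h$motif_canon[j] &&
          h$start[j] <= h$start[i] && h$end[i] <= h$end[j] &&
          h$n_units[j] > h$n_units[i]) {
        keep[i] <- FALSE
      }
    }
  }
  unique(h[keep, , drop = FALSE])
}
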