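#' Restriction enzyme specification
#'
#' A recognition site plus the 0-based offset of the cut within the site.
#' `haeiii()` (GG^CC, blunt) and `mboi()` (^GATC, 5' overhang filled during
#' library prep) are the two enzymes used to build the reduced-representation
#' libraries; fragments are taken as the sequence between successive cut
#' points, so a HaeIII fragment starts with `CC` and ends with `GG` while an
#' MboI fragment starts with `GATC`.
#'
#' @param name Display name.
#' @param site Recognition sequence (A/C/G/T).
#' @param cut_offset 0-based cut position within the site.
#' @return An object of class `restriction_enzyme`.
#' @export
restriction_enzyme <- function(name, site, cut_offset) {
  stopifnot(is.character(site), nchar(site) > 0,
            cut_offset >= 0, cut_offset <= nchar(site))
  structure(list(name = name, site = site, cut_offset = as.integer(cut_offset)),
            class = "restriction_enzyme")
}

#' @rdname restriction_enzyme
#' @export
haeiii <- function() restriction_enzyme("HaeIII", "GGCC", 2L)

#' @rdname restriction_enzyme
#' @export
mboi <- function() restriction_enzyme("MboI", "GATC", 0L)

#' Simulation configuration for the RRL sequencing experiment
#'
#' Defines the study conditions the simulator emulates: a small diploid
#' founder cohort derived from a shared ancestral sequence, complete digestion
#' with HaeIII and MboI, 250-350 bp size selection (chosen so 101-bp mates
#' never overlap), and indexed paired-end 101-cycle sequencing at a mean
#' per-founder locus depth of about 30 read pairs with a uniform per-base
#' substitution error rate.
#'
#' Founder relatedness follows a shared-ancestry model: each planted SNP draws
#' an alternate-allele frequency from `Beta(beta_shape1, beta_shape2)` and
#' every founder haplotype samples its allele from that shared frequency, so
#' founders are related but non-identical.
#'
#' @param n_founders Number of diploid founders (default 5).
#' @param ancestral_length Ancestral sequence length in bases.
#' @param snp_rate Per-base probability that a segregating SNP is planted.
#' @param str_count Number of planted STR loci.
#' @param enzymes List of [restriction_enzyme()] specs.
#' @param size_min,size_max Size-selection window in bases (inclusive).
#' @param read_length Read length in bases (must not exceed `size_min`).
#' @param target_depth Mean read pairs per retained fragment: each fragment
#'   (one haplotype copy of a locus) draws Poisson(`target_depth`) pairs, so
#'   a diploid founder's locus depth averages twice this value.
#' @param error_rate Per-base substitution probability in `[0, 1)`.
#' @param beta_shape1,beta_shape2 Shape parameters of the shared allele
#'   frequency distribution.
#' @param seed Integer RNG seed; every simulator draw derives from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_founders = 5, ancestral_length = 2e6,
                       snp_rate = 5e-4, str_count = 0,
                       enzymes = list(haeiii(), mboi()),
                       size_min = 250, size_max = 350,
                       read_length = 101, target_depth = 30,
                       error_rate = 0.002,
                       beta_shape1 = 1, beta_shape2 = 1,
                       seed = 1L) {
  stopifnot(n_founders >= 1, ancestral_length >= 1000,
            snp_rate >= 0, snp_rate < 1, str_count >= 0,
            length(enzymes) >= 1,
            size_min <= size_max, read_length <= size_min,
            error_rate >= 0, error_rate < 1,
            beta_shape1 > 0, beta_shape2 > 0)
  for (e in enzymes) stopifnot(inherits(e, "restriction_enzyme"))
  structure(list(
    n_founders = as.integer(n_founders),
    ancestral_length = as.integer(ancestral_length),
    snp_rate = snp_rate, str_count = as.integer(str_count),
    enzymes = enzymes,
    size_min = as.integer(size_min), size_max = as.integer(size_max),
    read_length = as.integer(read_length), target_depth = target_depth,
    error_rate = error_rate,
    beta_shape1 = beta_shape1, beta_shape2 = beta_shape2,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# motifs whose tandem repetition would embed a restriction site cannot be
# planted cleanly (the digest would cut inside the run)
motif_ok <- function(motif, enzymes) {
  doubled <- strrep(motif, 3)
  for (e in enzymes) {
    if (grepl(e$site, doubled, fixed = TRUE)) return(FALSE)
  }
  k <- nchar(motif)
  for (d in seq_len(k - 1)) {
    if (k %% d == 0 &&
        strrep(substr(motif, 1, d), k / d) == motif) return(FALSE)
  }
  TRUE
}

#' Generate diploid founder genomes with planted variants
#'
#' Builds an ancestral sequence, plants segregating biallelic SNPs at density
#' `snp_rate` (allele frequency drawn per locus from the configured Beta;
#' haplotype alleles are resampled until the site segregates among the
#' `2 * n_founders` haplotypes) and `str_count` STR loci (pure tandem runs of
#' a 2-4 base motif with two repeat-count alleles segregating at a shared
#' frequency), then assembles two haplotype sequences per founder. The truth
#' tables exactly describe all planted differences.
#'
#' @param config A [sim_config()].
#' @return An object of class `founder_sim`: a list with `founders` (each a
#'   `founder_genome` with `founder_id`, `hap1`, `hap2`), `truth_snps`
#'   (position, ref, alt, per-founder alt-allele dosage `g_<id>` and
#'   per-haplotype alleles `h1_<id>`/`h2_<id>`), `truth_strs` (locus, motif,
#'   ancestral run start and unit count), `truth_str_alleles` (per haplotype:
#'   repeat units and run start in haplotype coordinates), and the `config`.
#' @export
generate_founders <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$ancestral_length
  nf <- config$n_founders
  ids <- make.unique(rep(LETTERS, length.out = nf), sep = "")[seq_len(nf)]
  anc <- sample(c("A", "C", "G", "T"), L, replace = TRUE)

  ## --- STR planting -------------------------------------------------------
  n_str <- config$str_count
  str_tbl <- data.frame(str_id = integer(0), pos = integer(0),
                        motif = character(0), motif_len = integer(0),
                        n0 = integer(0), stringsAsFactors = FALSE)
  str_alleles <- NULL
  str_units <- NULL  # matrix n_str x (2 * nf): planted units per haplotype
  if (n_str > 0) {
    margin <- 300L; spacing <- 400L
    slots <- seq.int(margin, L - margin, by = spacing)
    if (length(slots) < n_str) {
      stop("ancestral_length too small to host ", n_str,
           " STR loci without overlap")
    }
    pos <- sort(sample(slots, n_str))
    motif <- character(n_str); mlen <- integer(n_str); n0 <- integer(n_str)
    for (s in seq_len(n_str)) {
      repeat {
        k <- sample(2:4, 1)
        m <- paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
                   collapse = "")
        if (motif_ok(m, config$enzymes)) break
      }
      mlen[s] <- nchar(m); motif[s] <- m
      n0[s] <- switch(as.character(mlen[s]),
                      "2" = sample(8:12, 1),
                      "3" = sample(5:8, 1),
                      "4" = sample(4:6, 1))
      run <- strsplit(strrep(m, n0[s]), "")[[1]]
      anc[pos[s]:(pos[s] + length(run) - 1L)] <- run
      # break the run at both flanks so the planted unit count is exact
      last <- substr(m, mlen[s], mlen[s]); first <- substr(m, 1, 1)
      anc[pos[s] - 1L] <- sample(setdiff(c("A", "C", "G", "T"), last), 1)
      anc[pos[s] + length(run)] <- sample(setdiff(c("A", "C", "G", "T"), first), 1)
    }
    str_tbl <- data.frame(str_id = seq_len(n_str), pos = pos, motif = motif,
                          motif_len = mlen, n0 = n0, stringsAsFactors = FALSE)
    # two repeat-count alleles per locus, segregating at a Beta frequency
    alt_units <- n0 + sample(1:2, n_str, replace = TRUE)
    p <- rbeta(n_str, config$beta_shape1, config$beta_shape2)
    str_units <- matrix(0L, n_str, 2L * nf)
    for (s in seq_len(n_str)) {
      repeat {
        take_alt <- runif(2L * nf) < p[s]
        if (any(take_alt) && !all(take_alt)) break
      }
      str_units[s, ] <- ifelse(take_alt, alt_units[s], n0[s])
    }
  }

  ## --- SNP planting -------------------------------------------------------
  excluded <- rep(FALSE, L)
  if (n_str > 0) {
    for (s in seq_len(n_str)) {
      lo <- max(1L, str_tbl$pos[s] - 1L)
      hi <- min(L, str_tbl$pos[s] + str_tbl$motif_len[s] * str_tbl$n0[s])
      excluded[lo:hi] <- TRUE
    }
  }
  snp_pos <- integer(0)
  if (config$snp_rate > 0) {
    snp_pos <- which(runif(L) < config$snp_rate & !excluded)
  }
  n_snp <- length(snp_pos)
  bases <- c("A", "C", "G", "T")
  ref <- anc[snp_pos]
  alt <- character(n_snp)
  hap_alt <- matrix(FALSE, n_snp, 2L * nf)  # columns: f1.h1, f1.h2, f2.h1, ...
  if (n_snp > 0) {
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
    p <- rbeta(n_snp, config$beta_shape1, config$beta_shape2)
    for (i in seq_len(n_snp)) {
      repeat {
        draw <- runif(2L * nf) < p[i]
        if (any(draw) && !all(draw)) break
      }
      hap_alt[i, ] <- draw
    }
  }

  ## --- haplotype assembly -------------------------------------------------
  build_hap <- function(col) {
    h <- anc
    if (n_snp > 0) {
      swap <- hap_alt[, col]
      h[snp_pos[swap]] <- alt[swap]
    }
    if (n_str == 0) return(paste(h, collapse = ""))
    pieces <- character(2L * n_str + 1L)
    prev <- 1L
    for (s in seq_len(n_str)) {
      run_start <- str_tbl$pos[s]
      run_len0 <- str_tbl$motif_len[s] * str_tbl$n0[s]
      pieces[2L * s - 1L] <- paste(h[prev:(run_start - 1L)], collapse = "")
      pieces[2L * s] <- strrep(str_tbl$motif[s], str_units[s, col])
      prev <- run_start + run_len0
    }
    pieces[2L * n_str + 1L] <- paste(h[prev:L], collapse = "")
    paste(pieces, collapse = "")
  }

  founders <- vector("list", nf)
  for (f in seq_len(nf)) {
    founders[[f]] <- structure(list(
      founder_id = ids[f],
      hap1 = build_hap(2L * f - 1L),
      hap2 = build_hap(2L * f)
    ), class = "founder_genome")
  }

  ## --- truth tables -------------------------------------------------------
  truth_snps <- data.frame(pos = snp_pos, ref = ref, alt = alt,
                           stringsAsFactors = FALSE)
  for (f in seq_len(nf)) {
    h1 <- hap_alt[, 2L * f - 1L]; h2 <- hap_alt[, 2L * f]
    truth_snps[[paste0("g_", ids[f])]] <- as.integer(h1) + as.integer(h2)
    truth_snps[[paste0("h1_", ids[f])]] <- ifelse(h1, alt, ref)
    truth_snps[[paste0("h2_", ids[f])]] <- ifelse(h2, alt, ref)
  }

  truth_str_alleles <- NULL
  if (n_str > 0) {
    rows <- vector("list", 2L * nf)
    for (f in seq_len(nf)) {
      for (h in 1:2) {
        col <- 2L * (f - 1L) + h
        shift <- c(0L, cumsum((str_units[, col] - str_tbl$n0) *
                                str_tbl$motif_len))
        rows[[col]] <- data.frame(
          str_id = str_tbl$str_id, founder = ids[f], hap = h,
          units = str_units[, col],
          hap_start = str_tbl$pos + shift[seq_len(n_str)],
          stringsAsFactors = FALSE)
      }
    }
    truth_str_alleles <- do.call(rbind, rows)
  } else {
    truth_str_alleles <- data.frame(str_id = integer(0), founder = character(0),
                                    hap = integer(0), units = integer(0),
                                    hap_start = integer(0),
                                    stringsAsFactors = FALSE)
  }

  structure(list(founders = founders, ancestral = paste(anc, collapse = ""),
                 truth_snps = truth_snps, truth_strs = str_tbl,
                 truth_str_alleles = truth_str_alleles, config = config),
            class = "founder_sim")
}

#' Complete restriction digestion of a sequence
#'
#' Cuts at every occurrence of the enzyme's recognition site at its cut
#' offset (HaeIII GG^CC, MboI ^GATC). Fragments partition the input: their
#' concatenation reproduces the sequence exactly.
#'
#' @param sequence A single DNA string.
#' @param enzyme A [restriction_enzyme()].
#' @return A data frame with 0-based half-open `start`/`end` coordinates and
#'   the fragment `sequence`, in genomic order. An empty sequence yields an
#'   empty data frame.
#' @examples
#' digest("AAGGCCTT", haeiii())$sequence  # "AAGG" "CCTT"
#' digest("AAGATCTT", mboi())$sequence    # "AA" "GATCTT"
#' @export
digest <- function(sequence, enzyme) {
  stopifnot(inherits(enzyme, "restriction_enzyme"), length(sequence) == 1)
  L <- nchar(sequence)
  if (L == 0) {
    return(data.frame(start = integer(0), end = integer(0),
                      sequence = character(0), stringsAsFactors = FALSE))
  }
  hits <- gregexpr(enzyme$site, sequence, fixed = TRUE)[[1]]
  cuts <- integer(0)
  if (hits[1] != -1) {
    cuts <- as.integer(hits) - 1L + enzyme$cut_offset
    cuts <- cuts[cuts > 0 & cuts < L]
  }
  bounds <- unique(c(0L, sort(cuts), L))
  start <- bounds[-length(bounds)]
  end <- bounds[-1]
  data.frame(start = start, end = end,
             sequence = substring(sequence, start + 1L, end),
             stringsAsFactors = FALSE)
}

# 5' overhang filled in during end repair: for a palindromic site cut at
# offset c the overhang spans the central len - 2c bases (MboI ^GATC -> a
# 4-base GATC fill; HaeIII GG^CC is blunt -> none)
enzyme_end_fill <- function(enzyme) {
  len <- nchar(enzyme$site)
  ov <- len - 2L * enzyme$cut_offset
  if (ov > 0) substr(enzyme$site, enzyme$cut_offset + 1L, len - enzyme$cut_offset)
  else ""
}

#' Digest every founder haplotype with every configured enzyme
#'
#' Each enzyme digests each haplotype independently (the two digests are
#' pooled into one library per founder, as in the modelled protocol). End
#' repair is modelled at the terminal-base level: an enzyme leaving a 5'
#' overhang (MboI) has the overhang bases appended to every fragment whose
#' right boundary is a cut, so both sequenced ends of a both-end MboI
#' fragment read `GATC` — the fill duplicates the next genomic bases, so
#' error-free reads remain exact substrings of the haplotype. `start`/`end`
#' stay genomic; `fill` records the appended length and `length` is the
#' sequenced (repaired) fragment length.
#'
#' @param sim A `founder_sim` from [generate_founders()].
#' @param config A [sim_config()]; defaults to the one stored in `sim`.
#' @return A fragment table: `frag_id`, `founder`, `hap`, `enzyme`,
#'   0-based half-open `start`/`end` (haplotype coordinates), `fill`,
#'   `length`, `sequence`.
#' @export
digest_founders <- function(sim, config = sim$config) {
  stopifnot(inherits(sim, "founder_sim"))
  out <- vector("list", length(sim$founders) * length(config$enzymes) * 2L)
  i <- 0L
  for (fg in sim$founders) {
    for (h in 1:2) {
      hseq <- if (h == 1) fg$hap1 else fg$hap2
      for (e in config$enzymes) {
        d <- digest(hseq, e)
        if (nrow(d) == 0) next
        fill <- enzyme_end_fill(e)
        fill_len <- rep(0L, nrow(d))
        if (nzchar(fill) && nrow(d) > 1) {
          inner <- seq_len(nrow(d) - 1L)   # right boundary is a cut
          d$sequence[inner] <- paste0(d$sequence[inner], fill)
          fill_len[inner] <- nchar(fill)
        }
        i <- i + 1L
        out[[i]] <- data.frame(founder = fg$founder_id, hap = h,
                               enzyme = e$name, start = d$start, end = d$end,
                               fill = fill_len,
                               length = nchar(d$sequence),
                               sequence = d$sequence, stringsAsFactors = FALSE)
      }
    }
  }
  frags <- do.call(rbind, out[seq_len(i)])
  frags <- cbind(frag_id = seq_len(nrow(frags)), frags)
  rownames(frags) <- NULL
  frags
}

#' Size-select fragments
#'
#' Retains exactly the fragments whose length lies in `[min, max]`
#' (inclusive), preserving order — the in-silico counterpart of gel
#' purification of 250-350 bp digestion products.
#'
#' @param fragments Fragment table with a `length` column (or `sequence`).
#' @param min,max Bounds in bases.
#' @return The filtered fragment table.
#' @export
size_select <- function(fragments, min, max) {
  stopifnot(min <= max)
  len <- if ("length" %in% names(fragments)) fragments$length
         else nchar(fragments$sequence)
  fragments[len >= min & len <= max, , drop = FALSE]
}

# substitution errors at a uniform per-base rate
apply_errors <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0) return(seqs)
  bases <- c("A", "C", "G", "T")
  n_err <- rbinom(length(seqs), nchar(seqs), rate)
  for (i in which(n_err > 0)) {
    ch <- strsplit(seqs[i], "")[[1]]
    pos <- sample.int(length(ch), n_err[i])
    for (p in pos) ch[p] <- sample(setdiff(bases, ch[p]), 1)
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

#' Simulate indexed paired-end sequencing of size-selected fragments
#'
#' For each fragment, draws Poisson(`target_depth`) read pairs (each
#' haplotype copy of a locus is one fragment). The forward read is the first `read_length`
#' bases of the fragment and the reverse read is the reverse complement of
#' its last `read_length` bases; substitution errors are applied at
#' `error_rate` and qualities are a constant placeholder ('I').
#' Demultiplexing is modelled as per-founder files: index sequences are not
#' simulated.
#'
#' @param fragments Size-selected fragment table from [digest_founders()].
#' @param config A [sim_config()].
#' @param outdir Directory for `<founder>_R1.fastq` / `<founder>_R2.fastq`
#'   files, or `NULL` to keep reads in memory only.
#' @return A list: `pairs` (read_id, founder, frag_id, fwd/rev sequence),
#'   `per_fragment` (frag_id, n_pairs), `files` (per-founder FASTQ paths, if
#'   written).
#' @export
simulate_read_pairs <- function(fragments, config, outdir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  rl <- config$read_length
  if (nrow(fragments) > 0 && any(fragments$length < rl)) {
    stop("fragment shorter than read_length cannot be sequenced; ",
         "size-select first")
  }
  set.seed(config$seed + 1L)
  n_pairs <- rpois(nrow(fragments), config$target_depth)
  idx <- rep(seq_len(nrow(fragments)), n_pairs)
  seqs <- fragments$sequence[idx]
  lens <- fragments$length[idx]
  fwd <- substr(seqs, 1L, rl)
  rev <- revcomp(substring(seqs, lens - rl + 1L, lens))
  fwd <- apply_errors(fwd, config$error_rate)
  rev <- apply_errors(rev, config$error_rate)
  serial <- sequence(n_pairs)
  pairs <- data.frame(
    read_id = sprintf("%s:%d:%d", fragments$founder[idx],
                      fragments$frag_id[idx], serial),
    founder = fragments$founder[idx],
    frag_id = fragments$frag_id[idx],
    fwd_seq = fwd, rev_seq = rev, stringsAsFactors = FALSE)
  files <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    founders <- unique(fragments$founder)
    files <- data.frame(founder = founders,
                        r1 = file.path(outdir, paste0(founders, "_R1.fastq")),
                        r2 = file.path(outdir, paste0(founders, "_R2.fastq")),
                        stringsAsFactors = FALSE)
    for (j in seq_len(nrow(files))) {
      sel <- pairs$founder == files$founder[j]
      write_fastq(pairs$read_id[sel], pairs$fwd_seq[sel], files$r1[j])
      write_fastq(pairs$read_id[sel], pairs$rev_seq[sel], files$r2[j])
    }
  }
  list(pairs = pairs,
       per_fragment = data.frame(frag_id = fragments$frag_id,
                                 n_pairs = n_pairs),
       files = files)
}

# constant placeholder qualities ('I', Phred+33 = Q40)
write_fastq <- function(ids, seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  q <- Biostrings::BStringSet(strrep("I", nchar(seqs)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Run the full RRL simulation
#'
#' Convenience wrapper: generate founders, digest, size-select, sequence.
#'
#' @param config A [sim_config()].
#' @param outdir Optional FASTQ output directory (see
#'   [simulate_read_pairs()]).
#' @return An object of class `rrl_sim` bundling the `founder_sim`, the full
#'   and size-selected fragment tables, and the read simulation result.
#' @export
simulate_rrl <- function(config, outdir = NULL) {
  sim <- generate_founders(config)
  frags <- digest_founders(sim, config)
  sel <- size_select(frags, config$size_min, config$size_max)
  reads <- simulate_read_pairs(sel, config, outdir)
  structure(list(config = config, genomes = sim, fragments = frags,
                 selected = sel, reads = reads),
            class = "rrl_sim")
}

#' Write simulation truth tables as TSV
#'
#' @param sim An `rrl_sim` or `founder_sim`.
#' @param dir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_truth_tables <- function(sim, dir) {
  g <- if (inherits(sim, "rrl_sim")) sim$genomes else sim
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(dir, "truth_snps.tsv")
  p2 <- file.path(dir, "truth_strs.tsv")
  p3 <- file.path(dir, "truth_str_alleles.tsv")
  write.table(g$truth_snps, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(g$truth_strs, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(g$truth_str_alleles, p3, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(p1, p2, p3))
}
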