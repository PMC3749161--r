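loci_with_segments <- function(heads, tails = NULL) {
  n <- length(heads)
  if (is.null(tails)) {
    set.seed(99)
    tails <- random_seq(n, 101)
  }
  data.frame(locus_id = sprintf("S_%03d", seq_len(n)), group = "G",
             depth = 30L, fwd_cons = heads, rev_cons = revcomp(tails),
             stringsAsFactors = FALSE)
}

embed_run <- function(motif, units, flank_seed = 1, len = 101, at = 30) {
  set.seed(flank_seed)
  s <- random_seq(1, len)
  run <- strrep(motif, units)
  # break both flanks so the run is exactly `units` long
  before <- setdiff(c("A", "C", "G", "T"),
                    substr(motif, nchar(motif), nchar(motif)))[1]
  after <- setdiff(c("A", "C", "G", "T"), substr(motif, 1, 1))[1]
  paste0(substr(s, 1, at - 2), before, run, after,
         substr(s, at + nchar(run) + 1, len))
}

test_that("detection thresholds are 8/5/4 units for di/tri/tetra motifs", {
  heads <- c(embed_run("AC", 8), embed_run("AC", 7), embed_run("AGG", 5),
             embed_run("AGG", 4), embed_run("AGAT", 4), embed_run("AGAT", 3))
  cand <- detect_strs(loci_with_segments(heads))
  hits <- cand[cand$segment == "head", ]
  expect_equal(hits$locus_id, c("S_001", "S_003", "S_005"))
  expect_equal(hits$n_units, c(8L, 5L, 4L))
  expect_equal(hits$motif_canon, c("AC", "AGG", "AGAT"))
})

test_that("sub-period motifs are excluded and motifs canonicalised", {
  heads <- c(embed_run("A", 20, at = 40),      # homopolymer
             embed_run("ATAT", 5, at = 40),    # = (AT)x10, a di run
             embed_run("GA", 9, at = 40))
  cand <- detect_strs(loci_with_segments(heads))
  expect_false(any(cand$motif_len == 4 & cand$locus_id == "S_002"))
  expect_true(any(cand$locus_id == "S_002" & cand$motif_canon == "AT"))
  expect_false(any(cand$locus_id == "S_001"))
  expect_equal(cand$motif_canon[cand$locus_id == "S_003"], "AG")
})

test_that("runs in the reverse segment are found in genome orientation", {
  tail <- embed_run("CTG", 6, flank_seed = 3)
  loci <- loci_with_segments(random_seq(1, 101), tail)
  cand <- detect_strs(loci)
  expect_equal(cand$segment, "tail")
  expect_equal(cand$motif_canon, "CTG")
  expect_equal(cand$n_units, 6L)
})

test_that("detection agrees with a brute-force run enumerator", {
  set.seed(51)
  heads <- character(30)
  for (i in 1:30) {
    if (i <= 20) {
      k <- sample(2:4, 1)
      motif <- random_seq(1, k)
      units <- sample(3:12, 1)
      heads[i] <- embed_run(motif, units, flank_seed = i,
                            at = sample(10:40, 1))
    } else {
      heads[i] <- random_seq(1, 101)
    }
  }
  cand <- detect_strs(loci_with_segments(heads))
  cand <- cand[cand$segment == "head", ]
  for (i in 1:30) {
    want <- oracle_strs(heads[i])
    got <- cand[cand$locus_id == sprintf("S_%03d", i), ]
    expect_equal(sort(got$motif_canon), sort(unique(want$motif_canon)),
                 info = paste("locus", i))
    if (nrow(want)) {
      expect_setequal(paste(got$motif_canon, got$n_units),
                      unique(paste(want$motif_canon, want$n_units)))
    }
  }
})

# an allelic pair shares its flanks: the head window truncates the same
# pre + run + post construct at 101 bases
allelic_head <- function(motif, units, pre, post) {
  substr(paste0(pre, strrep(motif, units), post), 1, 101)
}

test_that("loci identical outside the run merge into one STR locus", {
  set.seed(52)
  shared_tail <- random_seq(1, 101)
  pre <- paste0(random_seq(1, 29), "T")   # break the AC run on the left
  post <- paste0("G", random_seq(1, 100)) # and on the right
  h8 <- allelic_head("AC", 8, pre, post)
  h10 <- allelic_head("AC", 10, pre, post)
  loci <- loci_with_segments(c(h8, h10), rep(shared_tail, 2))
  cand <- detect_strs(loci)
  strs <- group_str_loci(cand, loci)
  expect_length(strs, 1)
  expect_equal(strs[[1]]$alleles, c(8L, 10L))
  expect_equal(nrow(strs[[1]]$members), 2)
})

test_that("diverged flanks prevent merging", {
  set.seed(53)
  pre <- paste0(random_seq(1, 29), "T")
  post <- paste0("G", random_seq(1, 100))
  h1 <- allelic_head("AC", 8, pre, post)
  h2 <- allelic_head("AC", 10, pre, post)
  # mutate ten flank positions of the second head
  flank <- substr(h2, 1, 20)
  for (p in sample(5:20, 10)) {
    substr(flank, p, p) <- setdiff(c("A", "C", "G", "T"),
                                   substr(flank, p, p))[1]
  }
  h2 <- paste0(flank, substr(h2, 21, 101))
  shared_tail <- random_seq(1, 101)
  loci <- loci_with_segments(c(h1, h2), rep(shared_tail, 2))
  strs <- group_str_loci(detect_strs(loci), loci)
  expect_length(strs, 2)
})

test_that("tail-segment alleles anchor at the run end when merging", {
  set.seed(54)
  shared_head <- random_seq(1, 101)
  # same fragment end: longer allele pushes the run start left
  base <- random_seq(1, 130)
  mk_tail <- function(units) {
    run <- strrep("CAG", units)
    before <- "T"; after <- "A"   # break the run on both sides
    s <- paste0(substr(base, 1, 40), before, run, after,
                substr(base, 60, 130))
    substr(s, nchar(s) - 100, nchar(s))  # last 101 bases, end-anchored
  }
  t6 <- mk_tail(6)
  t8 <- mk_tail(8)
  loci <- loci_with_segments(rep(shared_head, 2), c(t6, t8))
  cand <- detect_strs(loci)
  expect_equal(nrow(cand), 2)
  expect_true(all(cand$segment == "tail"))
  strs <- group_str_loci(cand, loci)
  expect_length(strs, 1)
  expect_equal(strs[[1]]$alleles, c(6L, 8L))
})

test_that("STR genotyping applies depth and presence rules per founder", {
  strs <- list(list(str_id = "STR_0001", motif = "AC", segment = "head",
                    members = data.frame(locus_id = c("S_001", "S_002"),
                                         n_units = c(8L, 10L),
                                         stringsAsFactors = FALSE),
                    alleles = c(8L, 10L)))
  mapped <- data.frame(
    founder = c(rep("A", 29), rep("B", 30), rep("C", 10)),
    locus_id = c(rep("S_001", 15), rep("S_002", 14),   # A: het 8/10
                 rep("S_001", 30),                     # B: hom 8
                 rep("S_002", 10)),                    # C: below depth 20
    stringsAsFactors = FALSE)
  g <- genotype_strs(strs, mapped, founders = c("A", "B", "C"))
  geno <- g$loci[[1]]$genotype
  expect_equal(unname(geno["A"]), "8/10")
  expect_equal(unname(geno["B"]), "8/8")
  expect_true(is.na(geno["C"]))
  expect_equal(g$summary$n_alleles, 2L)
  expect_true(g$summary$polymorphic)
  expect_false(g$summary$genotyped_in_all)
  # allele 10 is present only in founder A among genotyped founders
  expect_equal(unname(g$specific["A"]), 1L)
  expect_equal(unname(g$specific["B"]), 0L)
})

test_that("a monomorphic locus is flagged non-polymorphic", {
  strs <- list(list(str_id = "STR_0001", motif = "AG", segment = "head",
                    members = data.frame(locus_id = "S_001", n_units = 9L,
                                         stringsAsFactors = FALSE),
                    alleles = 9L))
  mapped <- data.frame(founder = rep(c("A", "B"), each = 25),
                       locus_id = "S_001", stringsAsFactors = FALSE)
  g <- genotype_strs(strs, mapped, founders = c("A", "B"))
  expect_false(g$summary$polymorphic)
  expect_equal(unname(g$loci[[1]]$genotype), c("9/9", "9/9"))
})
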