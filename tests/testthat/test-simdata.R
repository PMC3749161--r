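test_that("digestion cuts at the documented offsets", {
  expect_equal(digest("AAGGCCTT", haeiii())$sequence, c("AAGG", "CCTT"))
  expect_equal(digest("AAGATCTT", mboi())$sequence, c("AA", "GATCTT"))
  expect_equal(nrow(digest("", haeiii())), 0)
  # no site -> single fragment spanning the input
  d <- digest("AAAATTTT", haeiii())
  expect_equal(d$sequence, "AAAATTTT")
  expect_equal(c(d$start, d$end), c(0L, 8L))
})

test_that("digestion partitions the input sequence", {
  set.seed(42)
  seq <- paste(sample(c("A", "C", "G", "T"), 1e5, replace = TRUE),
               collapse = "")
  for (enz in list(haeiii(), mboi())) {
    d <- digest(seq, enz)
    expect_identical(paste(d$sequence, collapse = ""), seq)
    expect_identical(d$end - d$start, nchar(d$sequence))
    expect_identical(d$start[-1], d$end[-nrow(d)])
  }
  # interior fragments carry the enzyme-determined termini
  d <- digest(seq, haeiii())
  inner <- d$sequence[-c(1, nrow(d))]
  expect_true(all(startsWith(inner, "CC")))
  expect_true(all(endsWith(inner, "GG")))
  d <- digest(seq, mboi())
  expect_true(all(startsWith(d$sequence[-1], "GATC")))
})

test_that("size selection keeps exactly the in-range fragments", {
  fr <- data.frame(length = c(100, 250, 300, 350, 400),
                   sequence = strrep("A", c(100, 250, 300, 350, 400)))
  expect_equal(size_select(fr, 250, 350)$length, c(250, 300, 350))
  expect_equal(nrow(size_select(fr[0, ], 250, 350)), 0)
  set.seed(7)
  seq <- paste(sample(c("A", "C", "G", "T"), 2e6, replace = TRUE),
               collapse = "")
  d <- digest(seq, haeiii())
  sel <- size_select(d, 250, 350)
  lens <- nchar(d$sequence)
  expect_equal(nrow(sel), sum(lens >= 250 & lens <= 350))
  expect_true(all(nchar(sel$sequence) >= 250 & nchar(sel$sequence) <= 350))
})

test_that("founder generation is deterministic and truth-complete", {
  cfg <- sim_config(ancestral_length = 3e4, snp_rate = 2e-3, str_count = 0,
                    seed = 5)
  g1 <- generate_founders(cfg)
  g2 <- generate_founders(cfg)
  expect_identical(g1, g2)
  # truth table describes exactly the differences between haplotypes
  anc <- strsplit(g1$ancestral, "")[[1]]
  for (fg in g1$founders) {
    for (h in 1:2) {
      hap <- strsplit(if (h == 1) fg$hap1 else fg$hap2, "")[[1]]
      diffs <- which(hap != anc)
      tcol <- g1$truth_snps[[paste0("h", h, "_", fg$founder_id)]]
      expected <- g1$truth_snps$pos[tcol != g1$truth_snps$ref]
      expect_identical(diffs, expected)
      expect_identical(hap[expected], tcol[tcol != g1$truth_snps$ref])
    }
  }
})

test_that("no-variation configuration yields identical founders", {
  cfg <- sim_config(ancestral_length = 2e4, snp_rate = 0, str_count = 0,
                    seed = 3)
  g <- generate_founders(cfg)
  expect_equal(nrow(g$truth_snps), 0)
  haps <- unlist(lapply(g$founders, function(f) c(f$hap1, f$hap2)))
  expect_length(unique(haps), 1)
  expect_identical(haps[1], g$ancestral)
})

test_that("planted SNP count follows the binomial planting density", {
  cfg <- sim_config(ancestral_length = 2e6, snp_rate = 5e-4, str_count = 0,
                    seed = 9)
  g <- generate_founders(cfg)
  expected <- 2e6 * 5e-4
  expect_lt(abs(nrow(g$truth_snps) - expected), 3 * sqrt(expected))
})

test_that("STR planting honours thresholds and records per-haplotype truth", {
  cfg <- sim_config(ancestral_length = 1e5, snp_rate = 0, str_count = 20,
                    seed = 13)
  g <- generate_founders(cfg)
  expect_equal(nrow(g$truth_strs), 20)
  thr <- c(`2` = 8, `3` = 5, `4` = 4)
  expect_true(all(g$truth_strs$n0 >= thr[as.character(g$truth_strs$motif_len)]))
  # every haplotype's sequence carries the recorded run at the recorded spot
  ta <- g$truth_str_alleles
  for (i in sample(nrow(ta), 25)) {
    fg <- g$founders[[match(ta$founder[i],
                            vapply(g$founders, `[[`, "", "founder_id"))]]
    hap <- if (ta$hap[i] == 1) fg$hap1 else fg$hap2
    s <- g$truth_strs[g$truth_strs$str_id == ta$str_id[i], ]
    run <- substr(hap, ta$hap_start[i],
                  ta$hap_start[i] + ta$units[i] * s$motif_len - 1)
    expect_identical(run, strrep(s$motif, ta$units[i]))
  }
  expect_error(generate_founders(
    sim_config(ancestral_length = 2000, str_count = 50)), "host")
})

test_that("read simulation draws Poisson depth and exact terminal bases", {
  mid <- paste(sample(c("A", "C", "G", "T"), 296, replace = TRUE),
               collapse = "")
  frag <- data.frame(frag_id = 1L, founder = "A", hap = 1L,
                     enzyme = "HaeIII", start = 0L, end = 300L,
                     length = 300L,
                     sequence = paste0("CC", mid, "GG"),
                     stringsAsFactors = FALSE)
  cfg <- sim_config(ancestral_length = 1e4, error_rate = 0, seed = 2)
  rp <- simulate_read_pairs(frag, cfg)
  expect_gt(nrow(rp$pairs), 0)
  expect_true(all(startsWith(rp$pairs$fwd_seq, "CC")))
  expect_true(all(startsWith(rp$pairs$rev_seq, "CC")))  # revcomp of "GG"
  expect_identical(rp$pairs$fwd_seq[1], substr(frag$sequence, 1, 101))
  expect_identical(rp$pairs$rev_seq[1],
                   revcomp(substr(frag$sequence, 200, 300)))
})

test_that("total pair count concentrates around depth times fragments", {
  set.seed(1)
  n <- 1000
  frags <- data.frame(frag_id = seq_len(n), founder = "A", hap = 1L,
                      enzyme = "HaeIII", start = 0L, end = 300L,
                      length = 300L,
                      sequence = random_seq(n, 300),
                      stringsAsFactors = FALSE)
  cfg <- sim_config(ancestral_length = 1e4, error_rate = 0,
                    target_depth = 30, seed = 4)
  rp <- simulate_read_pairs(frags, cfg)
  expect_lt(abs(nrow(rp$pairs) - 30000), 3 * sqrt(30000))
  expect_error(simulate_read_pairs(
    data.frame(frag_id = 1, founder = "A", hap = 1, enzyme = "x",
               start = 0, end = 50, length = 50,
               sequence = strrep("A", 50)), cfg), "read_length")
})

test_that("simulation is byte-deterministic under a fixed seed", {
  cfg <- sim_config(ancestral_length = 5e4, snp_rate = 1e-3,
                    error_rate = 0.002, seed = 6)
  d1 <- file.path(tempdir(), "sim_a")
  d2 <- file.path(tempdir(), "sim_b")
  s1 <- simulate_rrl(cfg, d1)
  s2 <- simulate_rrl(cfg, d2)
  expect_identical(s1$reads$pairs, s2$reads$pairs)
  for (i in seq_len(nrow(s1$reads$files))) {
    expect_identical(readLines(s1$reads$files$r1[i]),
                     readLines(s2$reads$files$r1[i]))
    expect_identical(readLines(s1$reads$files$r2[i]),
                     readLines(s2$reads$files$r2[i]))
  }
})

test_that("error-free reads are substrings of their source haplotype", {
  cfg <- sim_config(ancestral_length = 5e4, snp_rate = 1e-3, error_rate = 0,
                    seed = 8)
  sim <- simulate_rrl(cfg)
  g <- sim$genomes
  hapseq <- list()
  for (fg in g$founders) {
    hapseq[[paste0(fg$founder_id, ".1")]] <- fg$hap1
    hapseq[[paste0(fg$founder_id, ".2")]] <- fg$hap2
  }
  idx <- sample(nrow(sim$reads$pairs), 50)
  for (i in idx) {
    p <- sim$reads$pairs[i, ]
    fr <- sim$selected[sim$selected$frag_id == p$frag_id, ]
    hap <- hapseq[[paste0(fr$founder, ".", fr$hap)]]
    expect_true(grepl(p$fwd_seq, hap, fixed = TRUE))
    expect_true(grepl(revcomp(p$rev_seq), hap, fixed = TRUE))
  }
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(size_min = 400, size_max = 350))
  expect_error(sim_config(read_length = 300, size_min = 250))
  expect_error(sim_config(error_rate = 1))
  expect_silent(sim_config(error_rate = 0))
})
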