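adt_of <- function(counts_list, founders = c("A", "B")) {
  # counts_list: per locus, list of offset -> named base counts per founder
  n_loci <- length(counts_list)
  arr <- array(0L, dim = c(4, 202, length(founders), n_loci),
               dimnames = list(c("A", "C", "G", "T"),
                               as.character(0:201), founders,
                               sprintf("L%03d", seq_len(n_loci))))
  for (li in seq_along(counts_list)) {
    for (off in names(counts_list[[li]])) {
      per_f <- counts_list[[li]][[off]]
      for (f in names(per_f)) {
        for (b in names(per_f[[f]])) {
          arr[b, as.integer(off) + 1L, f, li] <- per_f[[f]][[b]]
        }
      }
    }
  }
  class(arr) <- c("allele_depth_table", class(arr))
  arr
}

test_that("SNP prediction needs two bases and the pooled depth threshold", {
  adt <- adt_of(list(list(
    `10` = list(A = c(A = 60), B = c(G = 50)),    # biallelic, depth 110
    `20` = list(A = c(A = 99)),                   # monomorphic
    `30` = list(A = c(A = 60), B = c(G = 30))     # biallelic, depth 90
  )))
  pred <- predict_snps(adt, min_pooled_depth = 100)
  expect_equal(pred$sites$offset, 10)
  expect_equal(pred$sites$pooled_depth, 110)
  expect_equal(pred$counts[1, "A", "A"], 60)
  expect_equal(pred$counts[1, "B", "G"], 50)
})

test_that("each filter rule removes its documented case", {
  f5 <- LETTERS[1:5]
  site <- function(...) {
    m <- matrix(0L, 5, 4, dimnames = list(f5, c("A", "C", "G", "T")))
    args <- list(...)
    for (f in names(args)) m[f, names(args[[f]])] <- args[[f]]
    m
  }
  hom <- c(C = 40L)
  # balanced heterozygote in A, everyone else homozygous: passes
  s_ok <- site(A = c(C = 40, T = 38), B = hom, C = hom, D = hom, E = hom)
  # founder depth 301: rule 2
  s_deep <- site(A = c(C = 301), B = hom, C = hom, D = hom, E = hom)
  # present-allele ratio 4 in A: rule 4
  s_ratio <- site(A = c(C = 40, T = 10), B = hom, C = hom, D = hom, E = hom)
  # three present alleles in A: rule 3
  s_tri <- site(A = c(C = 30, T = 30, G = 30), B = hom, C = hom, D = hom,
                E = hom)
  # minor allele nowhere present (2 of 42 reads in A): not a 2-allele SNP
  s_noise <- site(A = c(C = 40, T = 2), B = hom, C = hom, D = hom, E = hom)
  counts <- array(0L, dim = c(5, 5, 4))
  for (i in seq_along(list(s_ok, s_deep, s_ratio, s_tri, s_noise))) {
    counts[i, , ] <- list(s_ok, s_deep, s_ratio, s_tri, s_noise)[[i]]
  }
  put <- filter_snps(make_predicted(counts, f5))
  expect_equal(put$sites$locus_index, 1L)
  expect_equal(put$sites$major, "C")
  expect_equal(put$sites$minor, "T")
  expect_equal(put$n_predicted, 5L)
  expect_equal(put$n_putative, 1L)
})

test_that("rule 1 zeroes singleton depths before the later rules", {
  f5 <- LETTERS[1:5]
  counts <- array(0L, dim = c(1, 5, 4))
  # A has 30 C / 1 T; B-E homozygous C; the singleton T must not create a
  # second allele anywhere
  counts[1, 1, 2] <- 30; counts[1, 1, 4] <- 1
  counts[1, 2:5, 2] <- 40
  put <- filter_snps(make_predicted(counts, f5))
  expect_equal(put$n_putative, 0L)  # monomorphic after rule 1
})

test_that("filter cascade matches an independent straight-line oracle", {
  set.seed(41)
  n <- 10000
  f5 <- LETTERS[1:5]
  counts <- array(0L, dim = c(n, 5, 4))
  for (i in seq_len(n)) {
    kind <- sample(4, 1)
    for (f in 1:5) {
      b1 <- sample(4, 1)
      d <- sample(c(0:3, 10:80, 250:320), 1)
      counts[i, f, b1] <- counts[i, f, b1] + d
      if (kind >= 2 && runif(1) < 0.6) {
        b2 <- sample(4, 1)
        counts[i, f, b2] <- counts[i, f, b2] + sample(c(1:5, 20:60), 1)
      }
      if (kind == 4 && runif(1) < 0.3) {
        b3 <- sample(4, 1)
        counts[i, f, b3] <- counts[i, f, b3] + sample(1:30, 1)
      }
    }
  }
  put <- filter_snps(make_predicted(counts, f5))
  want <- lapply(seq_len(n), function(i) {
    oracle_filter_site(matrix(counts[i, , ], 5, 4))
  })
  keep <- which(!vapply(want, is.null, logical(1)))
  expect_identical(put$sites$locus_index, keep)
  expect_identical(put$sites$major,
                   vapply(want[keep], `[[`, "", "major"))
  expect_identical(put$sites$minor,
                   vapply(want[keep], `[[`, "", "minor"))
})

test_that("the filter cascade is idempotent on its own output", {
  set.seed(42)
  n <- 2000
  counts <- array(sample(c(0:4, 10:90), n * 5 * 4, replace = TRUE),
                  dim = c(n, 5, 4))
  put <- filter_snps(make_predicted(counts, LETTERS[1:5]))
  again <- filter_snps(putative_to_predicted(put))
  expect_equal(again$n_putative, put$n_putative)
  expect_identical(again$sites$major, put$sites$major)
  expect_identical(again$sites$minor, put$sites$minor)
  expect_identical(unname(again$d_major), unname(put$d_major))
  expect_identical(unname(again$d_minor), unname(put$d_minor))
})

test_that("genotype calling applies depth and presence thresholds", {
  dm <- rbind(c(30, 30, 30, 30, 30),
              c(30, 30, 30, 30, 30),
              c(30, 30, 30, 19, 30))
  dn <- rbind(c(25,  0,  0,  0,  0),
              c( 0,  0,  0,  0,  0),
              c(25, 25, 25,  0, 25))
  colnames(dm) <- colnames(dn) <- LETTERS[1:5]
  put <- make_putative(sprintf("L%d", 1:3), c(5L, 6L, 7L),
                       rep("C", 3), rep("T", 3), dm, dn)
  gm <- call_genotypes(put, min_founder_depth = 20)
  expect_equal(nrow(gm$geno), 2)          # third site: founder D at 19
  expect_equal(unname(gm$geno[1, ]), c("het", rep("hom_major", 4)))
  expect_equal(unname(gm$geno[2, ]), rep("hom_major", 5))
  expect_equal(unname(gm$m[1, ]), c(1L, 2L, 2L, 2L, 2L))
  # dosage coding is consistent with the genotype labels
  expect_true(all((gm$geno == "het") == (gm$m == 1L)))
})

test_that("clean depth separation phases into two haplotypes", {
  dm <- rbind(c(18, 6, 6), c(18, 6, 6))   # pooled major 30
  dn <- rbind(c(12, 4, 4), c(12, 4, 4))   # pooled minor 20
  colnames(dm) <- colnames(dn) <- c("A", "B", "C")
  put <- make_putative(c("LX", "LX"), c(10L, 150L), c("A", "C"),
                       c("G", "T"), dm, dn)
  hs <- deduce_haplotypes(put, tolerance = 4)
  expect_length(hs, 1)
  expect_equal(hs[[1]]$status, "determined")
  expect_length(hs[[1]]$haplotypes, 2)
  deps <- sort(vapply(hs[[1]]$haplotypes, `[[`, 0, "depth"))
  expect_equal(deps, c(20, 30))
  al <- lapply(hs[[1]]$haplotypes, `[[`, "alleles")
  al <- al[order(vapply(hs[[1]]$haplotypes, `[[`, 0, "depth"),
                 decreasing = TRUE)]
  expect_equal(unname(al[[1]]), c("A", "C"))
  expect_equal(unname(al[[2]]), c("G", "T"))
})

test_that("symmetric depths within tolerance are undetermined", {
  dm <- rbind(c(30, 0, 0), c(29, 0, 0))
  dn <- rbind(c(28, 0, 0), c(27, 0, 0))
  colnames(dm) <- colnames(dn) <- c("A", "B", "C")
  put <- make_putative(c("LY", "LY"), c(3L, 9L), c("A", "C"), c("G", "T"),
                       dm, dn)
  hs <- deduce_haplotypes(put, tolerance = 4)
  expect_equal(hs[[1]]$status, "undetermined")
})

test_that("haplotype depths conserve the pooled allele depths", {
  set.seed(43)
  for (rep in 1:10) {
    k <- sample(2:4, 1)
    d1 <- sample(30:90, 1)
    d2 <- d1 - sample(10:25, 1)   # well separated
    dm <- matrix(rep(d1 / 3, k * 3), k, 3,
                 dimnames = list(NULL, c("A", "B", "C")))
    dn <- matrix(rep(d2 / 3, k * 3), k, 3,
                 dimnames = list(NULL, c("A", "B", "C")))
    put <- make_putative(rep("LZ", k), seq_len(k) * 11L,
                         rep("A", k), rep("G", k), dm, dn)
    hs <- deduce_haplotypes(put, tolerance = 4)
    expect_equal(hs[[1]]$status, "determined")
    expect_equal(sort(vapply(hs[[1]]$haplotypes, `[[`, 0, "depth")),
                 c(d2, d1))
  }
})

test_that("haplotype summary partitions loci and formats the fraction", {
  hs <- c(
    lapply(1:7, function(i) haplotype_set(paste0("D", i), vector("list", 2),
                                          "determined")),
    lapply(1:3, function(i) haplotype_set(paste0("U", i), vector("list", 3),
                                          "undetermined")))
  s <- summarize_haplotypes(hs)
  expect_equal(s$n_determined, 7)
  expect_equal(s$n_undetermined, 3)
  expect_equal(s$pct_determined, 70.0)
  expect_equal(sum(s$histogram), s$n_determined)
  empty <- summarize_haplotypes(list())
  expect_true(is.na(empty$pct_determined))
})

test_that("VCF output places reverse offsets on the consensus strand", {
  dm <- rbind(c(30, 30, 30, 30, 30), c(30, 30, 30, 30, 30))
  dn <- rbind(c(25, 0, 0, 0, 0), c(25, 0, 0, 0, 0))
  colnames(dm) <- colnames(dn) <- LETTERS[1:5]
  put <- make_putative(c("L1", "L1"), c(10L, 101L), c("C", "C"),
                       c("T", "T"), dm, dn)
  path <- tempfile(fileext = ".vcf")
  write_snp_vcf(put, path)
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  expect_length(body, 2)
  fields <- strsplit(body, "\t")
  expect_equal(as.integer(c(fields[[1]][2], fields[[2]][2])), c(11L, 300L))
  expect_equal(fields[[2]][4], "G")  # complement of major C on the tail
  expect_equal(fields[[1]][10], "0/1:30,25")
})
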