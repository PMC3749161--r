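Package: rrlmarkers
Title: Reference-Free SNP and STR Discovery from Reduced-Representation
    Sequencing of Founder Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reference-free discovery and genotyping of SNP and short tandem
    repeat (STR) markers from reduced-representation library (RRL) paired-end
    sequencing of a small founder cohort, together with a seeded simulator of
    the whole experiment (restriction digestion, size selection, indexed
    paired-end sequencing with substitution errors) so every stage can be
    tested against planted truth. The pipeline groups read pairs by their
    restriction-site terminal sequences, clusters them into 300-bp consensus
    loci, maps read pairs back with a bounded mismatch count, applies a
    depth-based SNP filter cascade with per-founder genotyping and read-depth
    haplotype phasing, detects and genotypes STR loci, and summarises founder
    genetic diversity by founder-specific allele counts, zygosity, pairwise
    genotype sharing, correlation-based PCA, classical MDS, and average-linkage
    clustering with multiscale-bootstrap AU/BP support values.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
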