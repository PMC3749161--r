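# rrlmarkers

Reference-free discovery and genotyping of SNP and STR markers from
reduced-representation library (RRL) sequencing of a small founder cohort,
with a fully seeded simulator of the experiment so every stage can be
validated against planted truth.

## The problem

Captive-breeding programmes for endangered species often descend from a
handful of founder animals with no reference genome and no pedigree.
Managing such a population needs genome-wide polymorphic markers *and*
per-founder genotypes at those markers. RRL sequencing provides both at
once: each founder's genome is digested with HaeIII (GG^CC) and MboI
(^GATC), 250–350 bp fragments are size-selected, and the indexed libraries
are sequenced paired-end (101 cycles). Because all founders are sequenced
at the same restriction loci, the data define their own reference.

## The method

For read pairs grouped by their 5′-terminal restriction signatures
(both-end HaeIII, both-end MboI, others), the pipeline:

1. **clusters** near-identical pairs greedily (≤ 3 substitutions over both
   mates to a cluster representative, no positional shifts) and builds
   300-bp consensus loci — 101 forward bases, 98 `N`, 101 reverse bases —
   keeping those with depth ≥ 10 as the reference;
2. **maps** every pair back end-to-end (total mismatches ≤ 3, minimum-
   mismatch hit, deterministic ties) and tallies per-offset, per-founder
   allele depths in read pairs;
3. **calls SNPs**: predicted sites (≥ 2 bases, pooled depth ≥ 100) pass a
   four-rule cascade — singleton depths ignored; founder depth capped at
   300; an allele "present" in a founder iff its depth > 5% of the founder
   total, with exactly two present alleles required and ≥ 3 present in any
   founder fatal; allelic ratio ≤ 3 in two-allele founders — then
   genotypes are called where every founder has depth ≥ 20;
4. **phases** multi-SNP loci by depth matching (alleles whose pooled
   depths agree within < 4 ride the same haplotype; ambiguous or
   incomplete groupings stay undetermined);
5. **detects STRs** (≥ 8 di-, ≥ 5 tri-, ≥ 4 tetra-nucleotide units),
   groups consensus loci identical outside the repeat run, and genotypes
   repeat-count alleles by read-pair depth;
6. **summarises founder diversity**: zygosity, single-founder-specific
   alleles, pairwise genotype sharing, PCA on the founder dosage
   correlation matrix, classical MDS on 1 − correlation, and an
   average-linkage dendrogram with AU/BP support from a multiscale
   bootstrap (scales 0.5–1.4, AU = 1 − Φ(v − c) from a normal-quantile
   regression on √r and 1/√r).

The simulator (`simulate_rrl()`) emulates the entire experiment — diploid
founders from a shared ancestor with Beta-distributed allele frequencies,
planted SNPs/STRs, complete digestion, size selection, Poisson sequencing
depth, substitution errors — and records truth tables used by
`evaluate_snp_recovery()` / `evaluate_str_recovery()`.

## A worked example

```r
library(rrlmarkers)

cfg <- pipeline_config(
  sim = sim_config(ancestral_length = 5e5, snp_rate = 5e-4,
                   str_count = 0, error_rate = 0.002, seed = 1),
  nboot = 500)
res <- run_rrl_pipeline(cfg, "rrl_run")
#> [simulate] seeding experiment (seed 1)
#> [reads] 151724 pairs kept (0 discarded)
#> [cluster] 1243 consensus loci, 513 references (depth >= 10)
#> [map] 151592 of 151724 pairs mapped
#> [snps] 46014 predicted -> 47 putative -> 47 genotyped
#> [strs] 0 candidate runs -> 0 STR loci
ev <- evaluate_snp_recovery(res)
c(recall = ev$recall, precision = ev$precision)
#>    recall precision
#>         1         1
```

The numbers mean: ~152k simulated read pairs collapse to 513 reference
loci; of ~46k *predicted* polymorphic offsets (mostly single sequencing
errors riding on deep loci), the filter cascade keeps 47 putative SNPs,
all genotypable in every founder — and all 46 planted, detectable SNPs
were recovered with no false calls. (SNP-recovery scoring needs stable
genome coordinates, so it applies to simulations without planted STR
indels; STR recovery has its own evaluator,
`evaluate_str_recovery()`.) Each run writes per-stage TSVs, a reference
FASTA, a VCF of putative SNPs, an AU/BP-annotated Newick dendrogram and a
JSON manifest under the output directory.

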