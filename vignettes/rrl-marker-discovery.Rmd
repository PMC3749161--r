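---
title: "Reference-free SNP and STR discovery from reduced-representation sequencing"
author: "rrlmarkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-free SNP and STR discovery from reduced-representation sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrlmarkers)
```

## The problem

When a captive-breeding programme descends from a handful of founder
animals and no reference genome exists, two questions dominate genetic
management: which polymorphic markers segregate among the founders, and how
genetically similar the founders are to one another. `rrlmarkers`
implements a reference-free answer built on reduced-representation library
(RRL) sequencing: each founder's genome is digested with HaeIII (GG^CC) and
MboI (^GATC), 250–350 bp fragments are size-selected (long enough that
101-bp mates never overlap), and the pooled, index-tagged libraries are
sequenced paired-end. Because every founder is sequenced at the *same*
restriction loci, the fragments themselves become the reference: read pairs
are clustered into consensus loci, reads are mapped back, and depth does
the rest.

The package has two halves:

* a **simulator** (`sim_config()`, `simulate_rrl()`) that emulates the
  whole experiment — diploid founders drawn from a shared ancestor with
  planted SNPs and short tandem repeats (STRs), complete digestion, size
  selection, and paired-end sequencing with substitution errors — and
  records a truth table, so every downstream stage can be scored against
  known answers;
* the **discovery pipeline** (`run_rrl_pipeline()`): terminal-sequence
  grouping, greedy clustering into 300-bp consensus loci, mismatch-bounded
  paired mapping, a depth-based SNP filter cascade with per-founder
  genotyping and read-depth haplotype phasing, STR detection/grouping/
  genotyping, and founder diversity statistics (zygosity, founder-specific
  alleles, pairwise genotype sharing, correlation PCA, classical MDS, and
  average-linkage clustering with multiscale-bootstrap AU/BP support).

## Pipeline model and assumptions

**Terminal groups.** The cut chemistry fixes what a fragment's sequenced
ends look like: HaeIII fragments start `CC` and end `GG` (so both mates of
a both-end HaeIII pair begin `CC`), MboI fragments begin `GATC` at both
ends once the 5′ overhang is filled during end repair. Pairs are split
into `HAEIII_BOTH`, `MBOI_BOTH` and `OTHER` by exact 2- or 4-base prefix
match; errors at a terminus legitimately demote a pair to `OTHER`. The
simulator models the MboI fill at the terminal-base level: interior MboI
fragments carry the duplicated `GATC`, so error-free reads remain exact
substrings of their haplotype.

**Clustering.** Within a group, distinct (forward, reverse) sequence pairs
are processed in decreasing multiplicity (ties lexicographic). Each joins
the first cluster whose *representative* — the founding sequence — is
within `max_mismatch` (default 3) substitutions summed over both mates; no
positional shifts are searched, because the insert size is pinned by the
size selection. Processing by multiplicity makes high-copy true sequences
the representatives, so error-bearing reads join their source cluster.
Consensus is a per-column majority vote with ties broken by the fixed base
order A < C < G < T (determinism); the stored locus is 101 forward
consensus bases, a 98-base `N` spacer, and the reverse-complemented
reverse consensus — 202 informative bases. Loci with pooled depth ≥ 10
become the mapping reference.

**Mapping.** Mates are anchored end-to-end at their fixed consensus
offsets; a pair maps to the reference with the minimum total mismatch
count ≤ 3, ties to the lowest locus id (a deterministic stand-in for an
aligner's arbitrary best-hit choice). Candidates come from an exact-seed
index on a 16-base prefix of either mate with a full scan as fallback;
when references are mutually separated by more than twice the mismatch
bound — true by construction for restriction loci of a non-repetitive
genome — this equals the exhaustive scan, which the test suite verifies
against an independent oracle.

**SNP calling.** Depth, counted in read pairs, is the only evidence. A
*predicted* SNP is any informative offset with ≥ 2 observed bases and
pooled depth ≥ 100. The filter cascade then applies, in order:

1. alleles with depth exactly 1 in a founder are ignored (zeroed) there;
2. sites where any founder's total depth exceeds 300 are removed
   (collapsed paralogs);
3. an allele is *present* in a founder when its depth is strictly above 5%
   of that founder's site depth; sites with ≥ 3 present alleles in any
   founder, or whose presence-qualified allele set is not exactly two, are
   removed;
4. for founders with exactly two present alleles, sites with an allele
   depth ratio above 3 are removed (allelic imbalance beyond binomial
   expectation at these depths).

The biallelic test in rule 3 deliberately counts alleles present in at
least one founder rather than alleles with any nonzero pooled depth: at a
0.002 per-base error rate, a pair of identical error reads in a deep
founder would otherwise survive as a phantom "SNP" that no founder
actually carries. All comparisons are strict, following the rules'
"more than" phrasing; the rule-2 cap is evaluated on post-rule-1 depths
(the printed order lists rule 1 first, and a singleton error read should
not push a site over a paralog cap).

Genotypes enter the analysis matrix only when *every* founder has site
depth ≥ 20; a founder is heterozygous when both alleles are present under
rule 3, else homozygous. The matrix is coded as the per-founder count of
the major allele (0/1/2).

**Haplotype phasing by depth matching.** Within a multi-SNP consensus
locus, alleles supported by (nearly) the same pooled depth are taken to
ride on one haplotype: records (offset, allele, depth) are sorted by depth
descending and grouped greedily, a record joining the first group whose
running mean depth is within 4 (strict) and which lacks an allele at that
offset. The locus is `determined` only when every group covers every
offset exactly once *and* no record was depth-compatible with two groups —
near-symmetric depths are honestly ambiguous and stay `undetermined`.

**STRs.** The two informative segments of each consensus are scanned for
maximal pure tandem runs: ≥ 8 units for dinucleotide motifs, ≥ 5 for tri-,
≥ 4 for tetra-. Motifs that are repeats of a shorter unit are excluded and
reported motifs are canonicalised to their least rotation, so one physical
run is never double-counted. Candidates whose consensus sequences are
identical outside the run merge into one STR locus; because the tail
window is anchored at the fragment *end*, tail-segment runs are matched at
their run end (a longer allele shifts the run start, not its end), while
head-segment runs are matched at their start. Allele depths are read-pair
counts on the member consensus carrying each repeat count, genotyped under
the same 5% presence and ≥ 20 depth rules as SNPs.

**Diversity statistics.** Zygosity, founder-specific allele counts (an
allele present in exactly one founder — the quantity whose loss is
irreversible), and pairwise genotype sharing are direct tabulations of the
genotype matrix. PCA is the eigendecomposition of the 5×5 founder
correlation matrix of dosage vectors (variance proportions are eigenvalues
over the founder count; founder coordinates are loadings scaled by the
root eigenvalue), MDS is classical Torgerson scaling of 1 − correlation,
and the dendrogram is average-linkage on the same distance. Eigenvector
signs are fixed so each vector's largest-magnitude entry is positive —
plots are sign-invariant, determinism is not.

**Multiscale bootstrap.** Node support uses scale factors r = 0.5, 0.6,
…, 1.4: at each scale, `nboot` replicates resample ⌊n·r⌋ loci with
replacement and the tree is rebuilt. BP is the recovery frequency at
r = 1; AU comes from a weighted least-squares fit of the normal quantiles
z(r) = Φ⁻¹(1 − BP(r)) on (√r, 1/√r), with AU = 1 − Φ(v − c) where v and c
are the fitted signed distance and curvature. Weights are the delta-method
binomial variances; nodes recovered always (or never) at nearly every
scale collapse to AU 1 (or 0). The default of 10,000 replicates matches
the study design; below 100 the fit is unstable and the function warns.

## What the simulator emulates — and what it does not

Founders share an ancestral sequence; each planted SNP draws an
alternate-allele frequency from Beta(1, 1) and every haplotype samples
from it, giving "related but distinct" founders. Haplotype alleles are
resampled until each planted site actually segregates, so the truth table
is exactly the set of planted variants. STR loci carry two repeat-count
alleles (base counts 8–12/5–8/4–6 units for di/tri/tetra motifs, the
alternate allele 1–2 units longer) with flanks broken so the planted unit
count is exact. Each fragment draws Poisson(`target_depth`) read pairs,
substitution errors are uniform per base, and qualities are a constant
placeholder — per-cycle quality decay, indel errors, adaptor read-through,
partial digestion and index hopping are deliberately out of scope. Passing
tests therefore show the pipeline's correctness under clean, uniform
noise, not robustness to every artefact of real instruments.

A planted two-pair founder structure used by the bootstrap checks is
generated directly at the genotype-matrix level (two founders copying a
third's dosages at 95% of loci); sequence-level simulation adds nothing to
that particular test.

## Scoring against truth: what "detectable" means

Recall is reported against *detectable* truth variants, not all planted
ones, because an RRL interrogates only ~10% of the genome and some planted
variants are structurally invisible to the assay itself:

* a SNP must fall in the informative 101-base head or tail of a
  size-selected fragment, with realised pooled depth ≥ 100 (the prediction
  threshold) and **both alleles** covered by ≥ 2 realised read pairs.
  The per-allele requirement matters: a variant that creates or destroys a
  restriction site changes the carriers' fragmentation, so carrier
  haplotypes contribute no reads at the locus — allele dropout, a known
  property of restriction-site-based assays — and no base caller could see
  it;
* an STR allele must have its run fully inside an informative window of a
  fragment carrying it, with realised pooled depth ≥ 10; loci whose
  alleles' error-free reads differ at ≤ 3 positions (the run reaches the
  window edge, so the repeat absorbs the length difference) are flagged
  `confounded` and excluded — the reads carry no distinguishing signal.

Precision has no such adjustment: every called SNP is scored against the
truth table. Under the default study conditions (2 Mb ancestor, five
founders, SNP density 5×10⁻⁴, error rate 0.002, depth 30) the acceptance
suite requires recall ≥ 0.95 and precision ≥ 0.99, and exact STR allele
recovery at error rate 0.

## Numerical and design choices

* Percentages print to one decimal with round-half-up, matching the
  founder summary tables the pipeline mirrors.
* Major/minor allele ties (equal pooled depth) break to the
  lexicographically smaller base; consensus column ties to A < C < G < T;
  mapping ties to the lowest locus id; cluster processing ties to
  lexicographic order — every tie-break is a determinism device, none is a
  scientific claim.
* The per-fragment sequencing depth is Poisson with mean `target_depth`
  per haplotype copy; thresholds 10/100/300/20, the 5% presence rule, the
  ratio cap 3, the haplotype tolerance 4 and the STR unit minima 8/5/4 are
  the pipeline defaults and are exposed in `pipeline_config()`.
* Cross-group deduplication is not attempted: a fragment whose termini
  qualify for two groups can yield two loci; downstream counts tolerate
  that redundancy.
* Problem sizes in the test suite: oracle equivalences run at 200 pairs
  (clustering), 1,000 pairs × 50 references (mapping) and 10,000
  randomised sites (filter cascade); end-to-end recovery uses a 2 Mb
  cohort (~560,000 read pairs) and bootstrap checks use 10,000 loci at
  1,000 replicates — sizes chosen so the full suite runs on a laptop in a
  few minutes while keeping every estimate's sampling error far from the
  asserted bounds.

## Known limitations

* Indels (other than planted STR length differences) are not simulated and
  not called; gapped alignment is out of scope.
* Reads from fragments sequenced in opposite orientation would form a
  second locus for the same fragment; the simulator fixes orientation, so
  this redundancy is untested beyond the design's tolerance for it.
* The haplotype phasing heuristic assumes one diploid pool per locus;
  collapsed paralogs that survive the 300-depth cap can still phase into
  plausible-looking haplotypes.
* AU p-values follow the standard multiscale-bootstrap fit; with five
  leaves and strong structure most nodes are degenerate (BP ≈ 1), where AU
  is reported as exactly 1 rather than extrapolated.

## A worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(
  sim = sim_config(ancestral_length = 5e5, snp_rate = 5e-4,
                   str_count = 20, error_rate = 0.002, seed = 1),
  nboot = 500)
res <- run_rrl_pipeline(cfg, "rrl_run")
evaluate_snp_recovery(res)
res$diversity$zygosity
as_newick(res$diversity$hclust)
```

The run writes per-stage TSVs, the reference FASTA, a VCF of putative
SNPs, the AU/BP-annotated Newick tree and a JSON manifest of every
parameter and count under `rrl_run/`.
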