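#' Pipeline configuration
#'
#' Bundles every module parameter with the study's published thresholds as
#' defaults: reference depth 10, predicted-SNP pooled depth 100, per-founder
#' depth cap 300, genotyping depth 20, 5% allele presence, allele ratio cap
#' 3, haplotype depth tolerance 4, STR unit thresholds 8/5/4 (di/tri/tetra),
#' and 10,000 bootstrap replicates. The configuration round-trips through
#' YAML unchanged.
#'
#' @param sim A [sim_config()] describing the simulated experiment.
#' @param max_mismatch Substitution bound used for clustering, mapping and
#'   STR flank grouping; default 3.
#' @param seed_len Mapping seed prefix length; default 16.
#' @param min_ref_depth Consensus depth to become a reference; default 10.
#' @param min_pooled_depth Pooled depth for a predicted SNP; default 100.
#' @param max_founder_depth Per-founder depth cap (strict); default 300.
#' @param min_founder_depth Per-founder genotyping depth; default 20.
#' @param presence_frac Allele presence threshold (strict); default 0.05.
#' @param max_ratio Allele depth ratio cap (strict); default 3.
#' @param hap_tolerance Haplotype depth tolerance (strict); default 4.
#' @param str_min_units STR unit thresholds for motif lengths 2/3/4;
#'   default `c(8, 5, 4)`.
#' @param nboot Bootstrap replicates for AU/BP; default 10000.
#' @param seed Master seed for every stochastic stage.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), max_mismatch = 3,
                            seed_len = 16, min_ref_depth = 10,
                            min_pooled_depth = 100, max_founder_depth = 300,
                            min_founder_depth = 20, presence_frac = 0.05,
                            max_ratio = 3, hap_tolerance = 4,
                            str_min_units = c(8, 5, 4), nboot = 10000,
                            seed = sim$seed) {
  stopifnot(inherits(sim, "sim_config"), max_mismatch >= 0,
            length(str_min_units) == 3)
  structure(list(sim = sim, max_mismatch = max_mismatch,
                 seed_len = as.integer(seed_len),
                 min_ref_depth = min_ref_depth,
                 min_pooled_depth = min_pooled_depth,
                 max_founder_depth = max_founder_depth,
                 min_founder_depth = min_founder_depth,
                 presence_frac = presence_frac, max_ratio = max_ratio,
                 hap_tolerance = hap_tolerance,
                 str_min_units = as.integer(str_min_units),
                 nboot = as.integer(nboot), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Serialise / restore a pipeline configuration
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `write_pipeline_config()` returns `path` invisibly;
#'   `read_pipeline_config()` returns the restored `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  x$sim <- unclass(x$sim)
  x$sim$enzymes <- lapply(x$sim$enzymes, unclass)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  sim_args <- x$sim
  sim_args$enzymes <- lapply(sim_args$enzymes, function(e) {
    restriction_enzyme(e$name, e$site, e$cut_offset)
  })
  sim <- do.call(sim_config, sim_args)
  x$sim <- NULL
  do.call(pipeline_config, c(list(sim = sim), x))
}

#' Pipeline stage names, in order
#' @return Character vector of stage names.
#' @export
pipeline_stages <- function() {
  c("simulate", "reads", "cluster", "map", "snps", "strs", "analyze")
}

# majority source fragment per consensus locus, from simulator read ids
# ("<founder>:<frag>:<serial>"); NA when ids do not carry provenance
majority_fragment <- function(read_ids, assignment, n_clusters) {
  frag <- suppressWarnings(
    as.integer(sub("^[^:]+:([0-9]+):[0-9]+$", "\\1", read_ids)))
  out <- rep(NA_integer_, n_clusters)
  ok <- !is.na(frag)
  if (!any(ok)) return(out)
  for (ci in unique(assignment[ok])) {
    f <- frag[ok & assignment == ci]
    tab <- sort(table(f), decreasing = TRUE)
    out[ci] <- as.integer(names(tab)[1])
  }
  out
}

#' Run the marker-discovery pipeline
#'
#' Executes a prefix-closed chain of stages — simulate, reads, cluster, map,
#' snps, strs, analyze — writing per-stage TSV/FASTA/VCF outputs and a JSON
#' manifest (parameters, seed, per-stage counts) under `outdir`. Rerunning
#' with an identical configuration reproduces identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory.
#' @param stages Contiguous prefix of [pipeline_stages()] to run.
#' @return An object of class `rrl_result` collecting every intermediate:
#'   `sim`, `pairs`, `loci`, `refs`, `mapped`, `adt`, `predicted`,
#'   `putative`, `gm`, `hapsets`, `hap_summary`, `strs`, `str_geno`,
#'   `diversity`, `manifest`.
#' @export
run_rrl_pipeline <- function(config, outdir,
                             stages = pipeline_stages()) {
  stopifnot(inherits(config, "pipeline_config"))
  all_stages <- pipeline_stages()
  if (!identical(stages, all_stages[seq_along(stages)])) {
    stop("stages must be a contiguous prefix of: ",
         paste(all_stages, collapse = ", "))
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  manifest <- list(seed = config$seed,
                   parameters = yaml::yaml.load(yaml::as.yaml({
                     x <- unclass(config)
                     x$sim <- unclass(x$sim)
                     x$sim$enzymes <- lapply(x$sim$enzymes, unclass)
                     x
                   })),
                   stages = list())
  tsv <- function(df, name) {
    write.table(df, file.path(outdir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  message("[simulate] seeding experiment (seed ", config$seed, ")")
  res$sim <- simulate_rrl(config$sim, outdir = file.path(outdir, "fastq"))
  write_truth_tables(res$sim, outdir)
  manifest$stages$simulate <- list(
    n_fragments = nrow(res$sim$fragments),
    n_selected = nrow(res$sim$selected),
    n_pairs = nrow(res$sim$reads$pairs))
  if (!"reads" %in% stages) return(finish_result(res, manifest, outdir))

  files <- res$sim$reads$files
  pair_list <- lapply(seq_len(nrow(files)), function(i) {
    load_pairs(files$r1[i], files$r2[i], files$founder[i])
  })
  raw <- do.call(rbind, pair_list)
  flt <- filter_pairs(raw)
  res$pairs <- classify_terminal(flt$pairs)
  qs <- quality_summary(res$pairs, flt$n_discarded)
  tsv(qs, "read_summary.tsv")
  manifest$stages$reads <- list(n_raw = nrow(raw),
                                n_discarded = flt$n_discarded,
                                n_kept = nrow(res$pairs))
  message("[reads] ", nrow(res$pairs), " pairs kept (",
          flt$n_discarded, " discarded)")
  if (!"cluster" %in% stages) return(finish_result(res, manifest, outdir))

  loci_list <- list()
  for (g in c("HAEIII_BOTH", "MBOI_BOTH", "OTHER")) {
    p <- res$pairs[res$pairs$group == g, , drop = FALSE]
    if (nrow(p) == 0) next
    cl <- cluster_pairs(p, config$max_mismatch)
    loci <- consensus_loci(p, cl$assignment, g)
    loci$frag_id <- majority_fragment(p$read_id, cl$assignment,
                                      cl$n_clusters)
    loci_list[[g]] <- loci
  }
  res$loci <- do.call(rbind, loci_list)
  rownames(res$loci) <- NULL
  res$refs <- select_references(res$loci, config$min_ref_depth)
  tsv(consensus_summary(res$loci, config$min_ref_depth),
      "consensus_summary.tsv")
  tsv(res$refs[, c("locus_id", "group", "depth")], "references.tsv")
  write_reference_fasta(res$refs, file.path(outdir, "references.fasta"))
  manifest$stages$cluster <- list(n_consensus = nrow(res$loci),
                                  n_reference = nrow(res$refs))
  message("[cluster] ", nrow(res$loci), " consensus loci, ",
          nrow(res$refs), " references (depth >= ", config$min_ref_depth, ")")
  if (!"map" %in% stages) return(finish_result(res, manifest, outdir))

  res$mapped <- map_read_pairs(res$pairs, res$refs, config$max_mismatch,
                               config$seed_len)
  rep_tab <- mapping_report(res$mapped)
  tsv(rep_tab, "mapping_summary.tsv")
  founders <- sort(unique(res$mapped$founder))
  res$adt <- tally_alleles(res$mapped, res$refs, founders)
  manifest$stages$map <- list(n_mapped = sum(!is.na(res$mapped$locus_index)))
  message("[map] ", manifest$stages$map$n_mapped, " of ",
          nrow(res$mapped), " pairs mapped")
  if (!"snps" %in% stages) return(finish_result(res, manifest, outdir))

  res$predicted <- predict_snps(res$adt, config$min_pooled_depth)
  res$putative <- filter_snps(res$predicted, config$max_founder_depth,
                              config$presence_frac, config$max_ratio)
  res$gm <- call_genotypes(res$putative, config$min_founder_depth,
                           config$presence_frac)
  res$hapsets <- deduce_haplotypes(res$putative, config$hap_tolerance)
  res$hap_summary <- summarize_haplotypes(res$hapsets)
  write_snp_vcf(res$putative, file.path(outdir, "putative_snps.vcf"),
                config$sim$read_length, config$presence_frac)
  tsv(res$putative$sites, "putative_snps.tsv")
  manifest$stages$snps <- list(
    n_predicted = res$putative$n_predicted,
    n_putative = res$putative$n_putative,
    n_genotyped = nrow(res$gm$sites),
    n_multi_snp_loci = length(res$hapsets),
    n_haplotype_determined = res$hap_summary$n_determined)
  message("[snps] ", res$putative$n_predicted, " predicted -> ",
          res$putative$n_putative, " putative -> ",
          nrow(res$gm$sites), " genotyped")
  if (!"strs" %in% stages) return(finish_result(res, manifest, outdir))

  cand <- detect_strs(res$refs, config$str_min_units)
  res$strs <- group_str_loci(cand, res$refs, config$max_mismatch)
  res$str_geno <- genotype_strs(res$strs, res$mapped, founders,
                                config$min_founder_depth,
                                config$presence_frac)
  tsv(res$str_geno$summary, "str_summary.tsv")
  manifest$stages$strs <- list(n_candidates = nrow(cand),
                               n_str_loci = length(res$strs))
  message("[strs] ", nrow(cand), " candidate runs -> ",
          length(res$strs), " STR loci")
  if (!"analyze" %in% stages) return(finish_result(res, manifest, outdir))

  div <- list()
  if (!is.null(res$gm) && nrow(res$gm$geno) >= 3 &&
      ncol(res$gm$geno) >= 3 &&
      all(apply(res$gm$m, 2, stats::sd) > 0)) {
    div$zygosity <- zygosity_summary(res$gm)
    div$specific <- count_specific_alleles(res$gm)
    div$shared <- pairwise_shared_genotypes(res$gm)
    div$correlation <- founder_correlation(res$gm)
    div$pca <- pca_founders(div$correlation)
    div$mds <- mds_founders(div$correlation)
    div$hclust <- hclust_founders(res$gm, nboot = config$nboot,
                                  seed = config$seed + 2L)
    tsv(div$zygosity, "zygosity.tsv")
    tsv(data.frame(founder = names(div$specific),
                   n_specific = as.integer(div$specific)), "specific_alleles.tsv")
    write.table(div$shared$table, file.path(outdir, "shared_genotypes.tsv"),
                sep = "\t", quote = FALSE, col.names = NA)
    write.table(div$pca$coordinates, file.path(outdir, "pca_coordinates.tsv"),
                sep = "\t", quote = FALSE, col.names = NA)
    write.table(div$mds$coordinates, file.path(outdir, "mds_coordinates.tsv"),
                sep = "\t", quote = FALSE, col.names = NA)
    as_newick(div$hclust, file.path(outdir, "dendrogram.nwk"))
    manifest$stages$analyze <- list(
      n_loci = nrow(res$gm$geno),
      mean_pct_het = mean(div$zygosity$pct_het))
  } else {
    manifest$stages$analyze <- list(
      skipped = "too few genotyped loci or zero-variance founder")
  }
  res$diversity <- div
  finish_result(res, manifest, outdir)
}

finish_result <- function(res, manifest, outdir) {
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$manifest <- manifest
  structure(res, class = "rrl_result")
}
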