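# End-to-end pipeline: simulate -> write standard formats -> read back ->
# merge/filter -> landscape -> association scans -> haplotype tests, with
# a JSON run report. Every stage is deterministic under the config seed.

#' Run the full synthetic PAV pipeline
#'
#' Simulates a study from `config`, writes the caller callsets (VCF),
#' gene models (GFF3) and phenotypes (TSV) to `out_dir`, reads them back
#' through the parsers, merges and filters the callsets into a genotype
#' matrix, characterizes the PAV landscape (size spectrum, genomic
#' context, hotspot regions), runs the PC-adjusted permutation-threshold
#' association scan for each trait, runs a haplotype t-test at each
#' trait's top significant locus, and writes all intermediates plus a
#' JSON report.
#'
#' @param config a [pav_sim_config()].
#' @param out_dir output directory (created if needed).
#' @param merge a [merge_params()].
#' @param filters a [filter_params()].
#' @param window_size,step,top_frac hotspot-detection parameters.
#' @param flank_bp flank width for context classification and gene
#'   mapping.
#' @param n_pcs PC covariates for the scan.
#' @param n_permutations permutations per trait for the significance
#'   threshold (default 200 at desk scale).
#' @param alpha family-wise error target.
#' @param traits traits to scan (default: all configured traits).
#' @param phenotype_path optional path to an existing phenotype TSV used
#'   instead of the simulated table (the file must exist when the
#'   association stage runs).
#' @return a `pav_report` (list; also written as `report.json`).
#' @export
run_pav_pipeline <- function(config = pav_sim_config(), out_dir,
                             merge = merge_params(),
                             filters = filter_params(),
                             window_size = 1e6, step = 5e5,
                             top_frac = 0.10, flank_bp = 3000,
                             n_pcs = 3, n_permutations = 200,
                             alpha = 0.05, traits = NULL,
                             phenotype_path = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  sim <- stage("simulate", simulate_pav_study(config))
  chrom_len <- chromosome_lengths(config)

  stage("write", {
    write_gff3(sim$annotation, file.path(out_dir, "genes.gff3"))
    for (cl in names(sim$callsets)) {
      write_sv_vcf(sim$callsets[[cl]],
                   file.path(out_dir, paste0(cl, ".vcf")),
                   contig_lengths = chrom_len)
    }
    write_phenotype_table(sim$phenotypes,
                          file.path(out_dir, "phenotypes.tsv"))
  })

  callsets <- stage("read", {
    lapply(stats::setNames(nm = names(sim$callsets)), function(cl) {
      read_sv_vcf(file.path(out_dir, paste0(cl, ".vcf")), caller = cl)
    })
  })
  annotation <- stage("read", read_gff3(file.path(out_dir, "genes.gff3")))
  annotation$chrom_lengths <- chrom_len

  n_input_records <- sum(vapply(callsets, function(cs) nrow(cs$records),
                                integer(1)))
  gm_all <- stage("merge", merge_callsets(callsets, merge, filters = NULL,
                                          samples = sim$truth$samples))
  gm <- stage("filter", apply_variant_filters(gm_all, filters))
  utils::write.table(
    cbind(locus_id = gm$loci$locus_id,
          as.data.frame(t(gm$genotypes))),
    file.path(out_dir, "genotype_matrix.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(gm$loci, file.path(out_dir, "locus_metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  land <- stage("landscape", {
    spec <- size_spectrum(gm$loci$size)
    ctx <- summarize_context(gm, annotation, flank_bp)
    wc <- count_breakpoints_in_windows(gm, chrom_len, window_size, step)
    hs <- detect_hotspots(wc, top_frac)
    utils::write.table(wc, file.path(out_dir, "window_counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(hs)) {
      write_bed(data.frame(chrom = hs$chrom, start = hs$start + 1,
                           end = hs$end,
                           name = sprintf("hotspot%02d", seq_len(nrow(hs)))),
                file.path(out_dir, "hotspots.bed"))
    }
    list(size = spec, context = ctx, windows = wc, hotspots = hs,
         per_chromosome = count_per_chromosome(gm, names(chrom_len)))
  })

  phenotypes <- stage("gwas", {
    path <- phenotype_path %||% file.path(out_dir, "phenotypes.tsv")
    read_phenotype_table(path)
  })
  trait_names <- traits %||% setdiff(names(phenotypes), "sample_id")
  scans <- list()
  haplo <- list()
  for (i in seq_along(trait_names)) {
    tr <- trait_names[i]
    scan <- stage("gwas", pav_gwas(
      gm, phenotypes, trait = tr, n_pcs = n_pcs,
      n_permutations = n_permutations, alpha = alpha,
      seed = derive_seed(config$seed, "permutation") + i
    ))
    utils::write.table(scan$results,
                       file.path(out_dir, paste0("gwas_", tr, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    genes <- map_to_genes(
      gm$loci[gm$loci$locus_id %in% scan$significant$locus, , drop = FALSE],
      annotation, flank_bp)
    scans[[tr]] <- scan
    if (nrow(scan$significant)) {
      top <- scan$significant$locus[1]
      haplo[[tr]] <- stage("haplotype", tryCatch(
        haplotype_test(gm, phenotypes, tr, top),
        error = function(e) NULL))
    }
    utils::write.table(genes,
                       file.path(out_dir, paste0("genes_", tr, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  report <- summarize_counts(
    config = config, n_input_records = n_input_records,
    n_merged = ncol(gm_all$genotypes), gm = gm, land = land, scans = scans,
    haplo = haplo)
  json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
  writeLines(json, file.path(out_dir, "report.json"))
  structure(c(report, list(scans = scans, genotypes = gm,
                           annotation = annotation, details = land)),
            class = "pav_report")
}

#' Summarize pipeline stage counts into a run report
#'
#' Collects per-stage record counts, per-chromosome locus counts (with
#' the per-chromosome mean rounded half-down to an integer), landscape
#' summaries and per-trait significant counts with their total.
#'
#' @param config the run's [pav_sim_config()].
#' @param n_input_records records read across callers.
#' @param n_merged merged locus count before variant filters.
#' @param gm the filtered `pav_genotypes`.
#' @param land landscape summary list.
#' @param scans named list of `pav_gwas` objects.
#' @param haplo named list of `haplotype_comparison` objects (or NULL).
#' @return a plain list of report fields.
#' @export
summarize_counts <- function(config, n_input_records, n_merged, gm, land,
                             scans, haplo = list()) {
  per_trait <- vapply(scans, function(s) nrow(s$significant), integer(1))
  per_chrom <- land$per_chromosome
  list(
    seed = config$seed,
    n_samples = config$n_samples,
    parameters = list(
      n_true_pavs = config$n_true_pavs,
      n_chromosomes = config$n_chromosomes,
      chromosome_length_bp = config$chromosome_length_bp
    ),
    counts = list(
      input_records = n_input_records,
      merged_loci = n_merged,
      filtered_loci = ncol(gm$genotypes),
      per_chromosome = as.list(per_chrom),
      mean_per_chromosome = round_half_down(
        ncol(gm$genotypes) / length(per_chrom))
    ),
    landscape = list(
      short_fraction = land$size$short_fraction,
      pct_genic = land$context$pct_genic,
      pct_intergenic = unname(land$context$pct["intergenic"]),
      pct_flank_within_genic = land$context$pct_flank_within_genic,
      n_hotspot_regions = nrow(land$hotspots)
    ),
    association = list(
      per_trait_significant = as.list(per_trait),
      total_significant = sum(per_trait),
      thresholds = lapply(scans, function(s) s$threshold)
    ),
    haplotype = lapply(haplo, function(h) {
      if (is.null(h)) return(NULL)
      list(locus = h$locus_id, n1 = h$n1, n2 = h$n2, p = h$p,
           significant = h$significant)
    })
  )
}

#' @export
print.pav_report <- function(x, ...) {
  cat("PAV pipeline report\n")
  cat(sprintf("  %d input records -> %d merged loci -> %d after filters\n",
              x$counts$input_records, x$counts$merged_loci,
              x$counts$filtered_loci))
  cat(sprintf("  short-PAV fraction %.3f; genic %.1f%%; intergenic %.1f%%\n",
              x$landscape$short_fraction, x$landscape$pct_genic,
              x$landscape$pct_intergenic))
  cat(sprintf("  hotspot regions: %d\n", x$landscape$n_hotspot_regions))
  pt <- unlist(x$association$per_trait_significant)
  cat(sprintf("  significant loci: %s (total %d)\n",
              paste(sprintf("%s=%d", names(pt), pt), collapse = ", "),
              x$association$total_significant))
  invisible(x)
}
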