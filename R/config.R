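#' Simulation configuration for a synthetic PAV study
#'
#' Builds the configuration object consumed by the synthetic-data
#' generators. The defaults describe a desk-scale inbred rice-like
#' population: 150 fully homozygous samples from two subpopulations
#' (roughly 74% / 26%, mirroring an indica/japonica split), a genome of 12
#' chromosomes, a decreasing PAV size distribution with a 50 bp floor
#' calibrated so that short PAVs (50--1000 bp) carry about 75% of the
#' mass, one planted breakpoint hotspot, and five quantitative traits
#' (days to heading, plant height, flag leaf length, flag leaf width,
#' panicle number) each with one planted causal PAV plus a subpopulation
#' mean shift and Gaussian noise.
#'
#' @param seed integer seed controlling every random draw downstream.
#' @param n_samples number of inbred samples.
#' @param n_chromosomes number of chromosomes.
#' @param chromosome_length_bp length of each chromosome in bp.
#' @param n_genes number of gene models to place genome-wide.
#' @param n_true_pavs number of true PAV loci in the truth set.
#' @param min_pav_size_bp minimum PAV size (bp); structural variants are
#'   defined as events of at least 50 bp, so values below 50 are rejected.
#' @param max_pav_size_bp maximum PAV size (bp). Short-read SV callers do
#'   not resolve megabase-scale events; the default 100 kb keeps sizes on
#'   the scale such callsets actually contain (and within chromosome
#'   bounds).
#' @param size_decay tail index of the truncated power-law size
#'   distribution (P(S > s) proportional to s^-size_decay on
#'   [min, max]). The default 0.425 places ~75% of mass on 50--1000 bp
#'   under the default truncation.
#' @param prop_deletion fraction of PAVs that are deletions (the rest are
#'   insertions).
#' @param hotspot_regions data.frame with columns `chrom`, `start`, `end`,
#'   `enrichment`: regions where PAV breakpoint density is multiplied by
#'   `enrichment` relative to the uniform background.
#' @param n_subpopulations number of subpopulations (currently 2).
#' @param subpop_fraction fraction of samples assigned to subpopulation 1.
#' @param traits data.frame describing simulated traits, one row per trait,
#'   with columns `name`, `baseline` (trait mean in its own units),
#'   `noise_sd` (residual SD), `subpop_shift` (mean offset added to
#'   subpopulation 2), `n_causal` (planted causal PAVs) and
#'   `variance_explained` (per causal locus). See [default_trait_table()].
#' @param caller_breakpoint_jitter_sd SD (bp) of Gaussian jitter each
#'   pseudo-caller adds to reported breakpoints.
#' @param caller_false_negative_rate per-caller probability of missing a
#'   true locus entirely.
#' @param caller_lowqual_rate probability a reported record carries a
#'   non-PASS filter tag.
#' @param genotype_missing_rate probability an individual genotype call is
#'   missing in a caller's output.
#'
#' @return a list of class `pav_sim_config`.
#' @export
pav_sim_config <- function(seed = 1L,
                           n_samples = 150L,
                           n_chromosomes = 12L,
                           chromosome_length_bp = 2.5e6,
                           n_genes = 3000L,
                           n_true_pavs = 2000L,
                           min_pav_size_bp = 50L,
                           max_pav_size_bp = 1e5,
                           size_decay = 0.425,
                           prop_deletion = 0.97,
                           hotspot_regions = default_hotspot_table(),
                           n_subpopulations = 2L,
                           subpop_fraction = 109 / 148,
                           traits = default_trait_table(),
                           caller_breakpoint_jitter_sd = 30,
                           caller_false_negative_rate = 0.05,
                           caller_lowqual_rate = 0.05,
                           genotype_missing_rate = 0.02) {
  cfg <- list(
    seed = as.integer(seed),
    n_samples = as.integer(n_samples),
    n_chromosomes = as.integer(n_chromosomes),
    chromosome_length_bp = as.numeric(chromosome_length_bp),
    n_genes = as.integer(n_genes),
    n_true_pavs = as.integer(n_true_pavs),
    min_pav_size_bp = as.numeric(min_pav_size_bp),
    max_pav_size_bp = as.numeric(max_pav_size_bp),
    size_decay = as.numeric(size_decay),
    prop_deletion = as.numeric(prop_deletion),
    hotspot_regions = hotspot_regions,
    n_subpopulations = as.integer(n_subpopulations),
    subpop_fraction = as.numeric(subpop_fraction),
    traits = traits,
    caller_breakpoint_jitter_sd = as.numeric(caller_breakpoint_jitter_sd),
    caller_false_negative_rate = as.numeric(caller_false_negative_rate),
    caller_lowqual_rate = as.numeric(caller_lowqual_rate),
    genotype_missing_rate = as.numeric(genotype_missing_rate)
  )
  class(cfg) <- "pav_sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Default simulated trait table
#'
#' Five rice-like quantitative traits with baselines near the population
#' means reported for improved Asian rice panels (days to heading ~96.8 d,
#' plant height ~91.3 cm, flag leaf length ~26.9 cm, flag leaf width
#' ~1.4 cm, panicle number ~9.2). Each trait gets one planted causal PAV
#' explaining 25% of phenotypic variance and a subpopulation shift of half
#' the residual SD.
#'
#' @return data.frame with one row per trait.
#' @export
default_trait_table <- function() {
  data.frame(
    name = c("days_to_heading", "plant_height", "flag_leaf_length",
             "flag_leaf_width", "panicle_number"),
    baseline = c(96.8, 91.3, 26.9, 1.4, 9.2),
    noise_sd = c(10, 14, 4, 0.18, 1.8),
    subpop_shift = c(5, 7, 2, 0.09, 0.9),
    n_causal = 1L,
    variance_explained = 0.25,
    stringsAsFactors = FALSE
  )
}

#' Default planted hotspot table
#'
#' One 1 Mb hotspot on chromosome 11 with 8-fold breakpoint enrichment,
#' emulating the kind of localized PAV clustering seen on rice
#' chromosome 11.
#'
#' @return data.frame with columns chrom, start, end, enrichment.
#' @export
default_hotspot_table <- function() {
  data.frame(
    chrom = "chr11", start = 1000001, end = 2000000, enrichment = 8,
    stringsAsFactors = FALSE
  )
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "pav_sim_config"))
  if (cfg$min_pav_size_bp < 50) {
    stop("min_pav_size_bp must be >= 50: PAVs are structural variants")
  }
  rates <- c(cfg$caller_false_negative_rate, cfg$caller_lowqual_rate,
             cfg$genotype_missing_rate, cfg$subpop_fraction,
             cfg$prop_deletion)
  if (any(rates < 0 | rates > 1)) {
    stop("all rates, probabilities and fractions must lie in [0, 1]")
  }
  if (cfg$size_decay <= 0) stop("size_decay must be positive")
  if (cfg$max_pav_size_bp <= cfg$min_pav_size_bp) {
    stop("max_pav_size_bp must exceed min_pav_size_bp")
  }
  if (cfg$n_subpopulations != 2L) {
    stop("only two subpopulations are supported")
  }
  hs <- cfg$hotspot_regions
  if (!is.null(hs) && nrow(hs)) {
    stopifnot(all(c("chrom", "start", "end", "enrichment") %in% names(hs)))
    if (any(hs$enrichment <= 0)) stop("hotspot enrichment must be > 0")
    if (any(hs$start < 1 | hs$end > cfg$chromosome_length_bp)) {
      stop("hotspot regions must lie within chromosome bounds")
    }
    known <- hs$chrom %in% chromosome_names(cfg)
    if (!all(known)) {
      stop("hotspot chromosome not in the simulated genome: ",
           paste(hs$chrom[!known], collapse = ", "))
    }
  }
  tr <- cfg$traits
  stopifnot(all(c("name", "baseline", "noise_sd", "subpop_shift",
                  "n_causal", "variance_explained") %in% names(tr)))
  if (any(tr$variance_explained * tr$n_causal >= 1)) {
    stop("variance_explained values must sum to < 1 per trait")
  }
  if (any(tr$noise_sd < 0)) stop("noise_sd must be non-negative")
  invisible(cfg)
}

chromosome_names <- function(cfg) {
  paste0("chr", seq_len(cfg$n_chromosomes))
}

chromosome_lengths <- function(cfg) {
  stats::setNames(rep(cfg$chromosome_length_bp, cfg$n_chromosomes),
                  chromosome_names(cfg))
}

#' @export
print.pav_sim_config <- function(x, ...) {
  cat("PAV simulation config\n")
  cat(sprintf("  samples: %d (%d subpopulations, fraction %.2f)\n",
              x$n_samples, x$n_subpopulations, x$subpop_fraction))
  cat(sprintf("  genome: %d chromosomes x %.3g Mb; %d genes\n",
              x$n_chromosomes, x$chromosome_length_bp / 1e6, x$n_genes))
  cat(sprintf("  true PAVs: %d (min size %d bp, decay %.3f, %d%% DEL)\n",
              x$n_true_pavs, as.integer(x$min_pav_size_bp), x$size_decay,
              round(100 * x$prop_deletion)))
  cat(sprintf("  hotspots: %d; traits: %d; seed: %d\n",
              if (is.null(x$hotspot_regions)) 0L else nrow(x$hotspot_regions),
              nrow(x$traits), x$seed))
  invisible(x)
}
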