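# Synthetic-data generators: gene annotation, PAV truth set with planted
# hotspots, two imperfect pseudo-caller callsets, and structured phenotypes
# with planted causal PAVs. Every generator is deterministic under the
# config seed.

#' Simulate non-overlapping gene models
#'
#' Places `n_genes` gene models across the simulated genome, allocating
#' genes to chromosomes as evenly as possible and spacing them with
#' uniformly split inter-gene gaps so models never overlap. Each gene has
#' 1--5 exons; the first and last exon donate a 5' / 3' UTR segment when
#' long enough, the remainder is CDS, and introns are the gaps between
#' consecutive exons.
#'
#' @param config a [pav_sim_config()].
#' @return a `gene_annotation` object: a list with data.frames `genes`
#'   (gene_id, chrom, start, end, strand), `exons`, `cds`, `utr` and
#'   `introns` (each gene_id, chrom, start, end), all 1-based inclusive.
#' @export
simulate_gene_annotation <- function(config) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, "annotation"))
  chroms <- chromosome_names(config)
  n <- config$n_genes
  if (n == 0L) return(empty_gene_annotation(chromosome_lengths(config)))

  per_chrom <- tabulate(rep_len(seq_along(chroms), n), length(chroms))
  genes <- exons <- cds <- utr <- list()
  gid <- 0L
  for (ci in seq_along(chroms)) {
    ng <- per_chrom[ci]
    if (ng == 0L) next
    structs <- lapply(seq_len(ng), random_gene_structure)
    lens <- vapply(structs, function(s) s$span, numeric(1))
    free <- config$chromosome_length_bp - sum(lens)
    if (free < ng + 1) {
      stop("gene placement failure: chromosome ", chroms[ci],
           " too small for ", ng, " genes")
    }
    # split free space into ng+1 gaps via sorted uniforms
    cuts <- sort(stats::runif(ng, 0, free))
    gaps <- diff(c(0, cuts))
    pos <- 1
    for (gi in seq_len(ng)) {
      pos <- pos + floor(gaps[gi])
      s <- structs[[gi]]
      gid <- gid + 1L
      id <- sprintf("gene%04d", gid)
      gstart <- pos
      genes[[gid]] <- data.frame(
        gene_id = id, chrom = chroms[ci], start = gstart,
        end = gstart + s$span - 1,
        strand = sample(c("+", "-"), 1), stringsAsFactors = FALSE
      )
      ex <- data.frame(gene_id = id, chrom = chroms[ci],
                       start = gstart + s$exon_start - 1,
                       end = gstart + s$exon_end - 1,
                       stringsAsFactors = FALSE)
      exons[[gid]] <- ex
      # UTRs: first 100 bp of first exon and last 150 bp of last exon,
      # when the exon is long enough to leave >= 50 bp of CDS.
      utr5 <- utr3 <- NULL
      cds_ex <- ex
      if (ex$end[1] - ex$start[1] + 1 >= 150) {
        utr5 <- data.frame(gene_id = id, chrom = chroms[ci],
                           start = ex$start[1], end = ex$start[1] + 99,
                           stringsAsFactors = FALSE)
        cds_ex$start[1] <- ex$start[1] + 100
      }
      k <- nrow(ex)
      if (ex$end[k] - cds_ex$start[k] + 1 >= 200) {
        utr3 <- data.frame(gene_id = id, chrom = chroms[ci],
                           start = ex$end[k] - 149, end = ex$end[k],
                           stringsAsFactors = FALSE)
        cds_ex$end[k] <- ex$end[k] - 150
      }
      cds[[gid]] <- cds_ex
      utr[[gid]] <- rbind(utr5, utr3)
      pos <- gstart + s$span
    }
  }
  ann <- list(
    genes = do.call(rbind, genes),
    exons = do.call(rbind, exons),
    cds = do.call(rbind, cds),
    utr = if (length(utr)) do.call(rbind, utr) else empty_feature_df(),
    chrom_lengths = chromosome_lengths(config)
  )
  ann$utr <- ann$utr %||% empty_feature_df()
  ann$introns <- compute_introns(ann$exons)
  class(ann) <- "gene_annotation"
  validate_gene_annotation(ann)
  ann
}

random_gene_structure <- function(i) {
  n_ex <- sample(1:5, 1)
  ex_len <- round(stats::runif(n_ex, 150, 1200))
  in_len <- if (n_ex > 1) round(stats::runif(n_ex - 1, 100, 1000)) else numeric(0)
  starts <- cumsum(c(1, utils::head(ex_len, -1) + in_len))
  list(exon_start = starts, exon_end = starts + ex_len - 1,
       span = starts[n_ex] + ex_len[n_ex] - 1)
}

empty_feature_df <- function() {
  data.frame(gene_id = character(0), chrom = character(0),
             start = numeric(0), end = numeric(0), stringsAsFactors = FALSE)
}

empty_gene_annotation <- function(chrom_lengths = NULL) {
  ann <- list(
    genes = data.frame(gene_id = character(0), chrom = character(0),
                       start = numeric(0), end = numeric(0),
                       strand = character(0), stringsAsFactors = FALSE),
    exons = empty_feature_df(), cds = empty_feature_df(),
    utr = empty_feature_df(), introns = empty_feature_df(),
    chrom_lengths = chrom_lengths
  )
  class(ann) <- "gene_annotation"
  ann
}

compute_introns <- function(exons) {
  if (!nrow(exons)) return(empty_feature_df())
  out <- lapply(split(exons, exons$gene_id), function(ex) {
    ex <- ex[order(ex$start), ]
    if (nrow(ex) < 2) return(NULL)
    data.frame(gene_id = ex$gene_id[1], chrom = ex$chrom[1],
               start = ex$end[-nrow(ex)] + 1, end = ex$start[-1] - 1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out %||% empty_feature_df()
}

validate_gene_annotation <- function(ann) {
  g <- ann$genes
  if (!nrow(g)) return(invisible(ann))
  for (ch in unique(g$chrom)) {
    gs <- g[g$chrom == ch, ]
    gs <- gs[order(gs$start), ]
    if (nrow(gs) > 1 && any(gs$start[-1] <= gs$end[-nrow(gs)])) {
      stop("internal error: overlapping gene models on ", ch)
    }
  }
  invisible(ann)
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(sprintf("gene_annotation: %d genes, %d exons, %d introns\n",
              nrow(x$genes), nrow(x$exons), nrow(x$introns)))
  invisible(x)
}

#' Simulate the PAV truth set
#'
#' Draws true PAV loci with breakpoints uniform outside hotspots and
#' `enrichment`-times denser inside, sizes from a power-law (Pareto)
#' distribution truncated at the minimum PAV size, per-subpopulation
#' presence frequencies from Uniform(0.05, 0.95), and homozygous
#' presence/absence genotypes for fully inbred samples. Causal loci for
#' each configured trait are chosen among loci with realized minor allele
#' frequency >= 0.05 and their effect sizes back-computed from the target
#' variance explained.
#'
#' @param config a [pav_sim_config()].
#' @param annotation gene models from [simulate_gene_annotation()]
#'   (carried along for downstream context classification; PAV placement
#'   is independent of gene positions).
#' @return a `pav_truth` object: list with `loci` (data.frame chrom,
#'   start, end, svtype, size), `genotypes` (samples x loci 0/1 matrix),
#'   `subpop` (per-sample labels), `causal` (data.frame trait, locus,
#'   effect, variance_explained), `hotspots` (the planted regions),
#'   `samples`, `chrom_lengths`.
#' @export
simulate_pav_truth <- function(config, annotation = NULL) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, "truth"))
  n <- config$n_true_pavs
  chroms <- chromosome_names(config)
  clen <- config$chromosome_length_bp
  hs <- config$hotspot_regions

  seg <- hotspot_segments(chroms, clen, hs)
  wt <- seg$weight * (seg$end - seg$start + 1)
  seg_idx <- sample.int(nrow(seg), n, replace = TRUE, prob = wt)
  start <- floor(stats::runif(n, seg$start[seg_idx], seg$end[seg_idx] + 1))
  chrom <- seg$chrom[seg_idx]

  # truncated Pareto sizes on [min, max] via inverse CDF
  alpha <- config$size_decay
  smin <- config$min_pav_size_bp
  smax <- min(config$max_pav_size_bp, clen - 1)
  tail_ratio <- (smin / smax)^alpha
  u <- stats::runif(n)
  size <- round(smin * (1 - u * (1 - tail_ratio))^(-1 / alpha))
  size <- pmin(pmax(size, smin), smax)

  is_del <- stats::runif(n) < config$prop_deletion
  svtype <- ifelse(is_del, "DEL", "INS")
  # deletions must fit on the chromosome
  over <- is_del & (start + size > clen)
  start[over] <- pmax(1, clen - size[over])
  end <- ifelse(is_del, start + size, start)

  ord <- order(match(chrom, chroms), start, end)
  loci <- data.frame(
    locus_id = sprintf("pav%05d", seq_len(n)),
    chrom = chrom[ord], start = start[ord], end = end[ord],
    svtype = svtype[ord], size = size[ord], stringsAsFactors = FALSE
  )

  samples <- sprintf("S%03d", seq_len(config$n_samples))
  n1 <- round(config$n_samples * config$subpop_fraction)
  subpop <- stats::setNames(
    rep(c("pop1", "pop2"), c(n1, config$n_samples - n1)), samples)

  f1 <- stats::runif(n, 0.05, 0.95)
  f2 <- stats::runif(n, 0.05, 0.95)
  freq <- rbind(pop1 = f1, pop2 = f2)
  geno <- matrix(0L, config$n_samples, n,
                 dimnames = list(samples, loci$locus_id))
  for (p in c("pop1", "pop2")) {
    rows <- which(subpop == p)
    if (!length(rows)) next
    geno[rows, ] <- matrix(
      stats::rbinom(length(rows) * n, 1L, rep(freq[p, ], each = length(rows))),
      nrow = length(rows))
  }

  causal <- choose_causal_effects(config, geno, subpop)

  truth <- list(
    loci = loci, genotypes = geno, subpop = subpop, samples = samples,
    causal = causal, hotspots = hs, chrom_lengths = chromosome_lengths(config)
  )
  class(truth) <- "pav_truth"
  truth
}

# Partition each chromosome into constant-density segments: weight 1
# outside hotspots, `enrichment` inside.
hotspot_segments <- function(chroms, clen, hs) {
  segs <- list()
  for (ch in chroms) {
    h <- if (is.null(hs)) hs else hs[hs$chrom == ch, , drop = FALSE]
    if (is.null(h) || !nrow(h)) {
      segs[[ch]] <- data.frame(chrom = ch, start = 1, end = clen, weight = 1)
      next
    }
    h <- h[order(h$start), ]
    cuts <- sort(unique(c(1, h$start, h$end + 1, clen + 1)))
    st <- cuts[-length(cuts)]
    en <- cuts[-1] - 1
    w <- rep(1, length(st))
    for (i in seq_len(nrow(h))) {
      inside <- st >= h$start[i] & en <= h$end[i]
      w[inside] <- h$enrichment[i]
    }
    segs[[ch]] <- data.frame(chrom = ch, start = st, end = en, weight = w)
  }
  do.call(rbind, c(segs, list(make.row.names = FALSE)))
}

# Back-compute per-locus effect sizes so each causal locus explains its
# target fraction of phenotypic variance:
#   b^2 p(1-p) = ve / (1 - sum(ve)) * V0,
# where V0 = noise_sd^2 + shift^2 f(1-f) is the non-causal variance.
choose_causal_effects <- function(config, geno, subpop) {
  tr <- config$traits
  p_hat <- colMeans(geno)
  maf <- pmin(p_hat, 1 - p_hat)
  eligible <- which(maf >= 0.05)
  f <- mean(subpop == "pop2")
  out <- list()
  for (i in seq_len(nrow(tr))) {
    nc <- tr$n_causal[i]
    if (nc == 0L) next
    if (length(eligible) < nc) {
      stop("not enough polymorphic loci to plant causal effects for trait ",
           tr$name[i])
    }
    idx <- sample(eligible, nc)
    ve <- rep(tr$variance_explained[i], nc)
    v0 <- tr$noise_sd[i]^2 + tr$subpop_shift[i]^2 * f * (1 - f)
    denom <- 1 - sum(ve)
    pq <- p_hat[idx] * (1 - p_hat[idx])
    if (denom <= 0 || any(pq <= 0)) {
      stop("variance_explained infeasible for trait ", tr$name[i])
    }
    # degenerate noiseless case: no residual variance to scale against,
    # fall back to a unit effect so the locus still splits the phenotype
    b <- if (v0 == 0) rep(1, nc) else sqrt(ve / denom * v0 / pq)
    out[[i]] <- data.frame(
      trait = tr$name[i], locus_id = colnames(geno)[idx], locus_index = idx,
      effect = as.numeric(b), variance_explained = ve,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  res %||% data.frame(trait = character(0), locus_id = character(0),
                      locus_index = integer(0), effect = numeric(0),
                      variance_explained = numeric(0))
}

#' @export
print.pav_truth <- function(x, ...) {
  cat(sprintf(
    "pav_truth: %d loci (%d DEL / %d INS), %d samples, %d causal effects\n",
    nrow(x$loci), sum(x$loci$svtype == "DEL"), sum(x$loci$svtype == "INS"),
    length(x$samples), nrow(x$causal)))
  invisible(x)
}

#' Simulate two imperfect caller callsets from a truth set
#'
#' Each pseudo-caller reports each true locus unless it drops it entirely
#' (probability `caller_false_negative_rate`), adds Gaussian jitter to the
#' reported breakpoints (rounded, clamped to the chromosome, size floored
#' at the minimum PAV size), tags a fraction of records with a non-PASS
#' filter, and sets a fraction of per-sample genotypes to missing.
#'
#' @param truth a `pav_truth` object.
#' @param config the same [pav_sim_config()].
#' @return list of two `pav_callset` objects (named caller1, caller2),
#'   each a list with `records` (data.frame chrom, start, end, svtype,
#'   svlen, filter, caller, truth_id) and `genotypes` (records x samples
#'   integer matrix, NA = missing).
#' @export
simulate_caller_callsets <- function(truth, config) {
  stopifnot(inherits(truth, "pav_truth"))
  if (!nrow(truth$loci)) stop("truth set is empty")
  set.seed(derive_seed(config$seed, "caller"))
  lapply(stats::setNames(nm = c("caller1", "caller2")), function(cl) {
    one_caller_callset(cl, truth, config)
  })
}

one_caller_callset <- function(caller, truth, config) {
  loci <- truth$loci
  n <- nrow(loci)
  keep <- stats::runif(n) >= config$caller_false_negative_rate
  loci <- loci[keep, , drop = FALSE]
  geno <- truth$genotypes[, keep, drop = FALSE]
  m <- nrow(loci)
  if (m == 0L) {
    recs <- cbind(empty_record_df(),
                  data.frame(truth_id = character(0)))
    gmat <- matrix(NA_integer_, 0, length(truth$samples),
                   dimnames = list(NULL, truth$samples))
    return(structure(list(records = recs, genotypes = gmat,
                          caller = caller), class = "pav_callset"))
  }
  jit <- config$caller_breakpoint_jitter_sd
  clen <- truth$chrom_lengths[loci$chrom]

  is_del <- loci$svtype == "DEL"
  start <- loci$start + round(stats::rnorm(m, 0, jit))
  start <- pmin(pmax(start, 1),
                ifelse(is_del, clen - config$min_pav_size_bp, clen))
  end <- loci$end + round(stats::rnorm(m, 0, jit))
  # DEL reported span stays on-chromosome and >= the minimum PAV size
  end <- ifelse(is_del,
                pmin(pmax(end, start + config$min_pav_size_bp), clen),
                start)
  size <- ifelse(is_del, end - start,
                 pmax(loci$size + round(stats::rnorm(m, 0, jit)),
                      config$min_pav_size_bp))
  filt <- ifelse(stats::runif(m) < config$caller_lowqual_rate,
                 "LowQual", "PASS")

  gmat <- t(geno)  # records x samples
  if (config$genotype_missing_rate > 0 && length(gmat)) {
    miss <- stats::runif(length(gmat)) < config$genotype_missing_rate
    gmat[miss] <- NA_integer_
  }
  records <- data.frame(
    record_id = sprintf("%s_r%05d", caller, seq_len(m)),
    chrom = loci$chrom, start = as.numeric(start), end = as.numeric(end),
    svtype = loci$svtype,
    svlen = ifelse(is_del, -size, size),
    filter = filt, caller = caller, truth_id = loci$locus_id,
    stringsAsFactors = FALSE
  )
  rownames(gmat) <- records$record_id
  structure(list(records = records, genotypes = gmat, caller = caller),
            class = "pav_callset")
}

#' @export
print.pav_callset <- function(x, ...) {
  cat(sprintf("pav_callset '%s': %d records x %d samples (%d PASS)\n",
              x$caller, nrow(x$records), ncol(x$genotypes),
              sum(x$records$filter == "PASS")))
  invisible(x)
}

#' Simulate phenotypes with planted causal PAVs
#'
#' Each trait is baseline + sum(effect x presence) over its causal loci
#' + subpopulation shift (added to subpopulation 2) + Gaussian noise.
#'
#' @param truth a `pav_truth` object (carries the causal effects).
#' @param config the same [pav_sim_config()].
#' @return data.frame with `sample_id` then one numeric column per trait.
#' @export
simulate_phenotypes <- function(truth, config) {
  stopifnot(inherits(truth, "pav_truth"))
  set.seed(derive_seed(config$seed, "phenotype"))
  tr <- config$traits
  n <- length(truth$samples)
  shift_ind <- as.numeric(truth$subpop == "pop2")
  out <- data.frame(sample_id = truth$samples, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(tr))) {
    y <- rep(tr$baseline[i], n)
    ca <- truth$causal[truth$causal$trait == tr$name[i], , drop = FALSE]
    if (nrow(ca)) {
      g <- truth$genotypes[, ca$locus_index, drop = FALSE]
      gc <- as.numeric(g %*% ca$effect)
      y <- y + gc - mean(gc)  # centered: baseline is the population mean
    }
    shift <- tr$subpop_shift[i] * shift_ind
    y <- y + shift - mean(shift) + stats::rnorm(n, 0, tr$noise_sd[i])
    out[[tr$name[i]]] <- y
  }
  rownames(out) <- NULL
  out
}

#' Run the full synthetic study
#'
#' Convenience wrapper: annotation, truth set, two caller callsets and
#' phenotypes from one config, all deterministic under the config seed.
#'
#' @param config a [pav_sim_config()].
#' @return list with `config`, `annotation`, `truth`, `callsets`,
#'   `phenotypes`.
#' @export
simulate_pav_study <- function(config = pav_sim_config()) {
  annotation <- simulate_gene_annotation(config)
  truth <- simulate_pav_truth(config, annotation)
  callsets <- simulate_caller_callsets(truth, config)
  phenotypes <- simulate_phenotypes(truth, config)
  list(config = config, annotation = annotation, truth = truth,
       callsets = callsets, phenotypes = phenotypes)
}
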