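# Independent oracles and small fixture builders used across test files.

# Brute-force all-pairs connected-components clustering (the merge oracle).
# Adjacency enumerated with outer(); components via igraph.
oracle_cluster_membership <- function(records, D = 1000, same_type = TRUE) {
  n <- nrow(records)
  if (n == 0L) return(integer(0))
  same_chrom <- outer(records$chrom, records$chrom, "==")
  ok_type <- if (same_type) outer(records$svtype, records$svtype, "==") else TRUE
  ds <- abs(outer(records$start, records$start, "-")) <= D
  de <- abs(outer(records$end, records$end, "-")) <= D
  adj <- same_chrom & ok_type & ds & de
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  unname(igraph::components(g)$membership)
}

# Two membership vectors describe the same partition?
same_partition <- function(m1, m2) {
  identical(outer(m1, m1, "=="), outer(m2, m2, "=="))
}

# Random callset record table for merge stress tests.
random_records <- function(n, seed, n_chrom = 3, span = 1e5) {
  set.seed(seed)
  chrom <- sample(paste0("chr", seq_len(n_chrom)), n, replace = TRUE)
  svtype <- sample(c("DEL", "INS"), n, replace = TRUE, prob = c(0.8, 0.2))
  start <- sample.int(span, n, replace = TRUE)
  size <- sample(50:5000, n, replace = TRUE)
  end <- ifelse(svtype == "DEL", start + size, start)
  data.frame(
    record_id = sprintf("r%04d", seq_len(n)), chrom = chrom,
    start = start, end = end, svtype = svtype,
    svlen = ifelse(svtype == "DEL", -size, size),
    filter = "PASS",
    caller = sample(c("caller1", "caller2"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

# Hand-built two-exon gene annotation used by context and mapping tests:
# gene on chr1 spanning [10000, 20000], exon1 [10000, 12000],
# exon2 [12500, 20000] => intron [12001, 12499].
toy_annotation <- function() {
  ann <- list(
    genes = data.frame(gene_id = "g1", chrom = "chr1", start = 10000,
                       end = 20000, strand = "+", stringsAsFactors = FALSE),
    exons = data.frame(gene_id = "g1", chrom = "chr1",
                       start = c(10000, 12500), end = c(12000, 20000),
                       stringsAsFactors = FALSE),
    cds = data.frame(gene_id = "g1", chrom = "chr1",
                     start = c(10100, 12500), end = c(12000, 19850),
                     stringsAsFactors = FALSE),
    utr = data.frame(gene_id = "g1", chrom = "chr1",
                     start = c(10000, 19851), end = c(10099, 20000),
                     stringsAsFactors = FALSE),
    chrom_lengths = c(chr1 = 1e6)
  )
  ann$introns <- pavscape:::compute_introns(ann$exons)
  class(ann) <- "gene_annotation"
  ann
}

toy_loci <- function(start, end, svtype = "DEL", chrom = "chr1") {
  data.frame(locus_id = sprintf("L%03d", seq_along(start)), chrom = chrom,
             start = start, end = end, svtype = svtype,
             size = ifelse(svtype == "DEL", end - start, 100),
             stringsAsFactors = FALSE)
}

# Per-locus context classification by plain interval arithmetic (oracle
# for classify_context), independent of GenomicRanges.
oracle_context <- function(loci, ann, flank_bp = 3000) {
  overlaps <- function(s1, e1, s2, e2) s1 <= e2 & e1 >= s2
  n <- nrow(loci)
  out <- matrix(FALSE, n, 5,
                dimnames = list(loci$locus_id,
                                c("flank_3kb", "CDS", "UTR", "intron",
                                  "intergenic")))
  g <- ann$genes
  flanks <- if (nrow(g)) {
    rbind(
      data.frame(chrom = g$chrom, start = pmax(1, g$start - flank_bp),
                 end = g$start - 1),
      data.frame(chrom = g$chrom, start = g$end + 1, end = g$end + flank_bp)
    )
  } else data.frame(chrom = character(0), start = numeric(0),
                    end = numeric(0))
  genic <- rbind(flanks, if (nrow(g))
    data.frame(chrom = g$chrom, start = g$start, end = g$end))
  feats <- list(flank_3kb = flanks, CDS = ann$cds, UTR = ann$utr,
                intron = ann$introns)
  for (i in seq_len(n)) {
    s <- loci$start[i]
    e <- if (loci$svtype[i] == "INS") loci$start[i] else loci$end[i]
    for (cls in names(feats)) {
      f <- feats[[cls]]
      if (!nrow(f)) next
      hit <- f$chrom == loci$chrom[i] & overlaps(s, e, f$start, f$end)
      out[i, cls] <- any(hit)
    }
    # intergenic: any base not covered by genes-or-flanks
    cover <- genic[genic$chrom == loci$chrom[i] &
                     overlaps(s, e, genic$start, genic$end), , drop = FALSE]
    if (!nrow(cover)) {
      out[i, "intergenic"] <- TRUE
    } else {
      bases <- rep(FALSE, e - s + 1)
      for (j in seq_len(nrow(cover))) {
        lo <- max(s, cover$start[j]) - s + 1
        hi <- min(e, cover$end[j]) - s + 1
        bases[lo:hi] <- TRUE
      }
      out[i, "intergenic"] <- !all(bases)
    }
  }
  out
}

# Brute-force per-window breakpoint membership scan.
oracle_window_counts <- function(loci, chrom_lengths, window_size, step) {
  res <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq(0, len - 1, by = step)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + window_size, len),
               count = vapply(starts, function(ws) {
                 we <- min(ws + window_size, len)
                 sum(loci$chrom == ch & loci$start > ws & loci$start <= we)
               }, numeric(1)))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# Quantile-by-enumeration hotspot window set (oracle for detect_hotspots).
oracle_hotspot_windows <- function(count, top_frac = 0.10) {
  k <- ceiling(top_frac * length(count))
  cutoff <- sort(count, decreasing = TRUE)[k]
  which(count >= cutoff & count > 0)
}

# Small noiseless config shared by recovery tests.
noiseless_config <- function(seed = 1L, n_true_pavs = 200L, ...) {
  pav_sim_config(
    seed = seed, n_true_pavs = n_true_pavs,
    caller_breakpoint_jitter_sd = 0, caller_false_negative_rate = 0,
    caller_lowqual_rate = 0, genotype_missing_rate = 0, ...
  )
}
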