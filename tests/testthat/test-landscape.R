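# Landscape characterization: size spectrum, context classification vs
# interval-arithmetic oracle, window counting, hotspot detection.

test_that("size spectrum bins and short fraction follow the contract", {
  out <- size_spectrum(c(60, 500, 1500), bin_edges = c(50, 1000, 10000))
  expect_equal(unname(out$counts), c(2L, 1L))
  expect_equal(out$short_fraction, 2 / 3)
  empty <- size_spectrum(numeric(0))
  expect_true(is.na(empty$short_fraction))
  expect_true(all(empty$counts == 0))
  expect_error(size_spectrum(c(60, 40)), "50")
})

test_that("context classes follow the flank/intron geometry examples", {
  ann <- toy_annotation()  # gene [10000, 20000], flank starts at 7000
  ctx <- classify_context(toy_loci(6500, 6900), ann)
  expect_equal(colnames(ctx)[which(ctx[1, ])], "intergenic")
  ctx <- classify_context(toy_loci(6500, 7100), ann)
  expect_setequal(colnames(ctx)[which(ctx[1, ])],
                  c("intergenic", "flank_3kb"))
  # fully inside the intron [12001, 12499]
  ctx <- classify_context(toy_loci(12100, 12400), ann)
  expect_equal(colnames(ctx)[which(ctx[1, ])], "intron")
  # spanning UTR + CDS, inside the gene: no intergenic, no flank
  ctx <- classify_context(toy_loci(10050, 10200), ann)
  expect_setequal(colnames(ctx)[which(ctx[1, ])], c("UTR", "CDS"))
  # insertions are points: INS at 12100 with nominal end far away
  ctx <- classify_context(toy_loci(12100, 12100, svtype = "INS"), ann)
  expect_equal(colnames(ctx)[which(ctx[1, ])], "intron")
  # unknown chromosome: intergenic with a warning
  expect_warning(
    ctx <- classify_context(toy_loci(100, 200, chrom = "chrX"), ann),
    "absent")
  expect_equal(colnames(ctx)[which(ctx[1, ])], "intergenic")
})

test_that("context summary percentages match direct enumeration", {
  ctx <- matrix(FALSE, 4, 5,
                dimnames = list(NULL, c("flank_3kb", "CDS", "UTR",
                                        "intron", "intergenic")))
  ctx[1, "intergenic"] <- TRUE
  ctx[2, "flank_3kb"] <- TRUE
  ctx[3, c("flank_3kb", "intergenic")] <- TRUE
  ctx[4, "CDS"] <- TRUE
  s <- summarize_context(ctx)
  expect_equal(unname(s$pct["intergenic"]), 50)
  expect_equal(unname(s$pct["flank_3kb"]), 50)
  expect_equal(unname(s$pct["CDS"]), 25)
  expect_equal(s$pct_genic, 75)
  # all intergenic -> genic 0
  ctx0 <- ctx; ctx0[] <- FALSE; ctx0[, "intergenic"] <- TRUE
  expect_equal(summarize_context(ctx0)$pct_genic, 0)
})

test_that("classification agrees with the per-base interval oracle", {
  cfg <- pav_sim_config(seed = 61, n_chromosomes = 1L,
                        chromosome_length_bp = 2e6, n_genes = 100L,
                        n_true_pavs = 500L, hotspot_regions = NULL)
  ann <- simulate_gene_annotation(cfg)
  truth <- simulate_pav_truth(cfg, ann)
  loci <- truth$loci
  loci$end <- pmin(loci$end, 2e6)  # oracle works on clipped intervals
  got <- classify_context(loci, ann)
  want <- oracle_context(loci, ann)
  expect_identical(got, want)
  # summary percentages therefore match the recount
  s1 <- summarize_context(got)
  s2 <- summarize_context(want)
  expect_equal(s1, s2)
})

test_that("window arithmetic produces clipped half-open sliding windows", {
  wc <- count_breakpoints_in_windows(
    toy_loci(750000, 750100), c(chr1 = 3e6), 1e6, 5e5)
  expect_equal(nrow(wc), 6L)
  expect_equal(wc$start, seq(0, 2.5e6, by = 5e5))
  expect_equal(wc$end, c(1e6, 1.5e6, 2e6, 2.5e6, 3e6, 3e6))
  # breakpoint at 750,000 falls in windows [0,1M) and [0.5M,1.5M)
  expect_equal(wc$count, c(1, 1, 0, 0, 0, 0))
})

test_that("window counts equal the brute-force membership scan", {
  cfg <- pav_sim_config(seed = 67, n_chromosomes = 3L,
                        chromosome_length_bp = 4.2e6, n_true_pavs = 500L,
                        hotspot_regions = NULL)
  truth <- simulate_pav_truth(cfg)
  lens <- truth$chrom_lengths
  wc <- count_breakpoints_in_windows(truth$loci, lens, 1e6, 5e5)
  oc <- oracle_window_counts(truth$loci, lens, 1e6, 5e5)
  expect_equal(wc$chrom, oc$chrom)
  expect_equal(wc$start, oc$start)
  expect_equal(wc$end, oc$end)
  expect_equal(as.numeric(wc$count), oc$count)
  # conservation: total mass = sum over loci of windows covering the start
  per_locus <- vapply(seq_len(nrow(truth$loci)), function(i) {
    sum(oc$chrom == truth$loci$chrom[i] &
          oc$start < truth$loci$start[i] & truth$loci$start[i] <= oc$end)
  }, numeric(1))
  expect_equal(sum(wc$count), sum(per_locus))
  expect_error(
    count_breakpoints_in_windows(toy_loci(5e6, 5.1e6), c(chr1 = 3e6)),
    "beyond")
})

make_counts <- function(counts, step = 5e5, window = 1e6, chrom = "chr1") {
  starts <- seq(0, by = step, length.out = length(counts))
  structure(
    data.frame(chrom = chrom, start = starts, end = starts + window,
               count = counts, stringsAsFactors = FALSE),
    window_size = window, step = step,
    class = c("window_counts", "data.frame"))
}

test_that("tied top windows are kept and merged into one region", {
  wc <- make_counts(c(9, 9, 1, 1, 1, 1, 1, 1, 1, 1))
  hs <- detect_hotspots(wc, top_frac = 0.10)  # k = 1, cutoff 9, tie kept
  expect_equal(attr(hs, "cutoff"), 9)
  expect_equal(attr(hs, "n_hotspot_windows"), 2L)
  expect_equal(nrow(hs), 1L)
  expect_equal(hs$start, 0)
  expect_equal(hs$end, 1.5e6)  # union of [0,1M) and [0.5M,1.5M)
  expect_equal(hs$total_breakpoints, 18)
})

test_that("zero-count windows are never hotspots", {
  expect_equal(nrow(detect_hotspots(make_counts(rep(0, 10)))), 0L)
  wc <- make_counts(c(rep(0, 12), 5, rep(0, 7)))
  hs <- detect_hotspots(wc, top_frac = 0.10)
  expect_equal(nrow(hs), 1L)
  expect_equal(hs$n_windows, 1L)
  expect_equal(hs$max_count, 5)
  expect_error(detect_hotspots(wc, top_frac = 0), "top_frac")
})

test_that("hotspot windows match quantile-by-enumeration on random counts", {
  for (s in 1:25) {
    set.seed(3000 + s)
    counts <- stats::rpois(40, sample(c(0.5, 2, 8), 1))
    wc <- make_counts(counts)
    hs <- detect_hotspots(wc, top_frac = 0.10)
    want <- oracle_hotspot_windows(counts, 0.10)
    expect_equal(attr(hs, "n_hotspot_windows"), length(want))
    # regions are disjoint and cover every hotspot window exactly once
    if (nrow(hs) > 1) {
      expect_true(all(hs$start[-1] > hs$end[-nrow(hs)]))
    }
    covered <- vapply(want, function(w) {
      ws <- wc$start[w]
      sum(hs$start <= ws & hs$end >= wc$end[w])
    }, numeric(1))
    expect_true(all(covered == 1))
  }
})

test_that("a planted 8x hotspot region is detected", {
  hits <- vapply(1:10, function(s) {
    cfg <- pav_sim_config(
      seed = 7000 + s, n_chromosomes = 1L, chromosome_length_bp = 3e7,
      n_true_pavs = 10000L,
      hotspot_regions = data.frame(chrom = "chr1", start = 12e6 + 1,
                                   end = 13e6, enrichment = 8))
    truth <- simulate_pav_truth(cfg)
    wc <- count_breakpoints_in_windows(truth$loci, truth$chrom_lengths)
    hs <- detect_hotspots(wc, 0.10)
    any(hs$chrom == "chr1" & hs$start < 13e6 & hs$end > 12e6)
  }, logical(1))
  expect_true(all(hits))
})

test_that("per-chromosome counts include empty chromosomes", {
  loci <- toy_loci(c(100, 200, 300), c(500, 600, 700))
  loci$chrom <- c("chr1", "chr1", "chr2")
  counts <- count_per_chromosome(loci, c("chr1", "chr2", "chr3"))
  expect_equal(unname(counts), c(2L, 1L, 0L))
})
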