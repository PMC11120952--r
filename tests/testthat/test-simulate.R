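# Synthetic-data generators: determinism, placement, size distribution,
# hotspot enrichment, caller noise model, phenotype structure.

test_that("the whole synthetic study is deterministic under the seed", {
  cfg <- pav_sim_config(seed = 11, n_true_pavs = 300L, n_genes = 200L,
                        n_samples = 40L)
  s1 <- simulate_pav_study(cfg)
  s2 <- simulate_pav_study(cfg)
  expect_identical(s1$annotation, s2$annotation)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$callsets, s2$callsets)
  expect_identical(s1$phenotypes, s2$phenotypes)
})

test_that("gene models are pairwise non-overlapping (all-pairs sweep)", {
  cfg <- pav_sim_config(seed = 3, n_chromosomes = 1L,
                        chromosome_length_bp = 1e6, n_genes = 10L,
                        hotspot_regions = NULL)
  ann <- simulate_gene_annotation(cfg)
  expect_equal(nrow(ann$genes), 10L)
  g <- ann$genes
  for (i in seq_len(nrow(g) - 1)) {
    for (j in (i + 1):nrow(g)) {
      expect_true(g$chrom[i] != g$chrom[j] ||
                    g$end[i] < g$start[j] || g$end[j] < g$start[i])
    }
  }
  # exon/CDS/UTR structure: every gene has >= 1 exon within its span
  expect_true(all(g$gene_id %in% ann$exons$gene_id))
  gi <- match(ann$exons$gene_id, g$gene_id)
  expect_true(all(ann$exons$start >= g$start[gi] &
                    ann$exons$end <= g$end[gi]))
})

test_that("an empty annotation yields intergenic-only classification", {
  cfg <- pav_sim_config(seed = 5, n_genes = 0L, n_true_pavs = 50L)
  ann <- simulate_gene_annotation(cfg)
  expect_equal(nrow(ann$genes), 0L)
  truth <- simulate_pav_truth(cfg, ann)
  ctx <- suppressWarnings(classify_context(truth$loci, ann))
  expect_true(all(ctx[, "intergenic"]))
  expect_true(all(!ctx[, c("flank_3kb", "CDS", "UTR", "intron")]))
})

test_that("a genome too small for its genes raises a placement error", {
  cfg <- pav_sim_config(seed = 1, n_chromosomes = 1L,
                        chromosome_length_bp = 5e4, n_genes = 100L,
                        hotspot_regions = NULL)
  expect_error(simulate_gene_annotation(cfg), "placement")
})

test_that("size distribution mass and monotonic decline match the model", {
  # truncated-Pareto CDF on [50, 1e5]:
  # P(S <= 1000) = (1 - (50/1000)^a) / (1 - (50/1e5)^a)
  alpha <- 0.425
  expected_short <- (1 - (50 / 1000)^alpha) / (1 - (50 / 1e5)^alpha)
  cfg <- pav_sim_config(seed = 21, n_true_pavs = 10000L,
                        hotspot_regions = NULL)
  truth <- simulate_pav_truth(cfg)
  expect_true(all(truth$loci$size >= 50 & truth$loci$size <= 1e5))
  expect_true(all(truth$loci$end <= cfg$chromosome_length_bp))
  frac <- mean(truth$loci$size <= 1000)
  expect_lt(abs(frac - expected_short), 0.05)
  expect_lt(abs(frac - 0.75), 0.05)

  counts <- size_spectrum(truth$loci$size)$counts
  tt <- stats::cor.test(seq_along(counts), as.numeric(counts),
                        method = "kendall", alternative = "less")
  expect_lt(tt$p.value, 0.01)
})

test_that("DEL/INS invariants hold in the truth set", {
  cfg <- pav_sim_config(seed = 8, n_true_pavs = 2000L)
  truth <- simulate_pav_truth(cfg)
  del <- truth$loci[truth$loci$svtype == "DEL", ]
  ins <- truth$loci[truth$loci$svtype == "INS", ]
  expect_true(all(del$end - del$start == del$size))
  expect_true(all(ins$end == ins$start))
  expect_true(all(truth$causal$locus_id %in% truth$loci$locus_id))
})

test_that("hotspot enrichment places the closed-form PAV fraction inside", {
  # one hotspot covering 10% of a 10 Mb genome at 8x:
  # expected inside fraction = 8*0.1 / (8*0.1 + 0.9) ~ 0.4706
  cfg <- pav_sim_config(
    seed = 13, n_chromosomes = 1L, chromosome_length_bp = 1e7,
    n_true_pavs = 10000L,
    hotspot_regions = data.frame(chrom = "chr1", start = 2e6 + 1,
                                 end = 3e6, enrichment = 8))
  truth <- simulate_pav_truth(cfg)
  inside <- mean(truth$loci$start > 2e6 & truth$loci$start <= 3e6)
  expect_lt(abs(inside - 8 * 0.1 / (8 * 0.1 + 0.9)), 0.05)

  # density ratio inside/outside within +/-15% of the enrichment factor
  dens_in <- sum(truth$loci$start > 2e6 & truth$loci$start <= 3e6) / 1e6
  dens_out <- sum(truth$loci$start <= 2e6 | truth$loci$start > 3e6) / 9e6
  expect_lt(abs(dens_in / dens_out - 8) / 8, 0.15)

  # enrichment 1 everywhere: no excess
  cfg1 <- pav_sim_config(
    seed = 13, n_chromosomes = 1L, chromosome_length_bp = 1e7,
    n_true_pavs = 10000L,
    hotspot_regions = data.frame(chrom = "chr1", start = 2e6 + 1,
                                 end = 3e6, enrichment = 1))
  t1 <- simulate_pav_truth(cfg1)
  inside1 <- mean(t1$loci$start > 2e6 & t1$loci$start <= 3e6)
  expect_lt(abs(inside1 - 0.1), 0.02)

  expect_error(pav_sim_config(
    hotspot_regions = data.frame(chrom = "chr1", start = 1, end = 1e5,
                                 enrichment = 0)), "enrichment")
})

test_that("noiseless callers reproduce the truth exactly", {
  cfg <- noiseless_config(seed = 17, n_true_pavs = 150L)
  truth <- simulate_pav_truth(cfg)
  cs <- simulate_caller_callsets(truth, cfg)
  for (cl in names(cs)) {
    r <- cs[[cl]]$records
    expect_equal(nrow(r), nrow(truth$loci))
    expect_equal(r$start, truth$loci$start)
    expect_equal(r$end, truth$loci$end)
    expect_true(all(r$filter == "PASS"))
    expect_identical(unname(cs[[cl]]$genotypes),
                     unname(t(truth$genotypes)))
  }
})

test_that("caller dropout follows the configured false-negative rate", {
  cfg <- pav_sim_config(seed = 29, n_true_pavs = 1000L,
                        caller_false_negative_rate = 0.2)
  truth <- simulate_pav_truth(cfg)
  cs <- simulate_caller_callsets(truth, cfg)
  ci_half <- stats::qnorm(0.995) * sqrt(0.8 * 0.2 / 1000)
  for (cl in names(cs)) {
    frac <- nrow(cs[[cl]]$records) / 1000
    expect_lt(abs(frac - 0.8), ci_half)
  }
  # rate 1: empty callsets
  cfg1 <- pav_sim_config(seed = 29, n_true_pavs = 100L,
                         caller_false_negative_rate = 1)
  t1 <- simulate_pav_truth(cfg1)
  cs1 <- simulate_caller_callsets(t1, cfg1)
  expect_equal(nrow(cs1$caller1$records), 0L)
})

test_that("phenotype without causal loci or shift is pure noise", {
  traits <- data.frame(name = "trait", baseline = 0, noise_sd = 2,
                       subpop_shift = 0, n_causal = 0L,
                       variance_explained = 0.25)
  cfg <- pav_sim_config(seed = 31, n_samples = 500L, n_true_pavs = 100L,
                        traits = traits)
  truth <- simulate_pav_truth(cfg)
  ph <- simulate_phenotypes(truth, cfg)
  s2 <- stats::var(ph$trait)
  n <- 500
  lo <- stats::qchisq(0.005, n - 1) * 4 / (n - 1)
  hi <- stats::qchisq(0.995, n - 1) * 4 / (n - 1)
  expect_gt(s2, lo)
  expect_lt(s2, hi)
})

test_that("zero noise with one causal locus yields exactly two values", {
  traits <- data.frame(name = "trait", baseline = 10, noise_sd = 0,
                       subpop_shift = 0, n_causal = 1L,
                       variance_explained = 0.25)
  cfg <- pav_sim_config(seed = 37, n_samples = 60L, n_true_pavs = 100L,
                        traits = traits)
  truth <- simulate_pav_truth(cfg)
  ph <- simulate_phenotypes(truth, cfg)
  expect_equal(length(unique(ph$trait)), 2L)
  g <- truth$genotypes[, truth$causal$locus_index[1]]
  expect_equal(length(unique(ph$trait[g == 1])), 1L)
  expect_equal(length(unique(ph$trait[g == 0])), 1L)
})

test_that("variance explained by the planted locus is calibrated", {
  traits <- data.frame(name = "trait", baseline = 0, noise_sd = 1,
                       subpop_shift = 0, n_causal = 1L,
                       variance_explained = 0.25)
  r2 <- vapply(1:50, function(s) {
    cfg <- pav_sim_config(seed = 100 + s, n_samples = 150L,
                          n_true_pavs = 200L, traits = traits)
    truth <- simulate_pav_truth(cfg)
    ph <- simulate_phenotypes(truth, cfg)
    g <- truth$genotypes[, truth$causal$locus_index[1]]
    stats::cor(g, ph$trait)^2
  }, numeric(1))
  expect_lt(abs(stats::median(r2) - 0.25), 0.1)
})

test_that("infeasible variance_explained is rejected", {
  traits <- data.frame(name = "trait", baseline = 0, noise_sd = 1,
                       subpop_shift = 0, n_causal = 2L,
                       variance_explained = 0.5)
  expect_error(pav_sim_config(traits = traits), "variance_explained")
})
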