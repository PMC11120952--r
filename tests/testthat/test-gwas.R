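# Association scan: encoding, PCA, closed-form regression equivalence,
# permutation threshold conventions, significance calls, gene mapping.

test_that("genotype encoding imputes the per-locus mean for missing", {
  g <- matrix(c(1L, 0L, NA,
                0L, 0L, 0L,
                1L, 1L, 0L), nrow = 3,
              dimnames = list(paste0("S", 1:3), paste0("L", 1:3)))
  e <- encode_genotypes(g)
  expect_equal(unname(e[, 1]), c(1, 0, 0.5))
  expect_equal(unname(attr(e, "usable")), c(TRUE, FALSE, TRUE))
  # no missing: encoding is exactly the 0/1 values
  expect_equal(unname(e[, 3]), c(1, 1, 0))
})

test_that("PCA variance proportions are normalized and rank-aware", {
  set.seed(71)
  e <- matrix(rnorm(40 * 30), 40, 30)
  pca <- compute_pcs(e, k = 3)
  expect_equal(sum(pca$variance_proportion), 1, tolerance = 1e-9)
  expect_equal(ncol(pca$scores), 3L)
  # rank-1 matrix: first component carries everything
  r1 <- outer(rnorm(20), rnorm(15))
  p1 <- compute_pcs(r1, k = 2)
  expect_equal(p1$variance_proportion[1], 1, tolerance = 1e-8)
  expect_error(compute_pcs(e, k = 40), "sample count")
})

test_that("PC1 separates strongly diverged subpopulations", {
  set.seed(73)
  n1 <- 25; n2 <- 25; m <- 200
  f1 <- runif(m, 0.05, 0.95)
  f2 <- 1 - f1
  g <- rbind(
    matrix(rbinom(n1 * m, 1, rep(f1, each = n1)), n1),
    matrix(rbinom(n2 * m, 1, rep(f2, each = n2)), n2))
  pca <- compute_pcs(g + 0, k = 3)
  r <- cor(pca$scores[, 1], rep(c(0, 1), c(n1, n2)))
  expect_gt(abs(r), 0.9)
})

test_that("scan matches the closed-form binary-regression example", {
  g <- matrix(c(0, 0, 0, 1, 1, 1), ncol = 1,
              dimnames = list(paste0("S", 1:6), "L1"))
  y <- c(1, 2, 3, 11, 12, 13)
  res <- association_scan(g, y)
  expect_equal(res$effect, 10)
  expect_equal(res$statistic, sqrt(150), tolerance = 1e-10)  # 12.247
  expect_equal(res$p, 2 * pt(-sqrt(150), df = 4), tolerance = 1e-12)
  expect_lt(abs(res$p - 2.6e-4), 2e-5)
})

test_that("binary-locus scan p equals the pooled two-sample t-test", {
  set.seed(79)
  for (i in 1:10) {
    n <- 40
    g <- matrix(rbinom(n, 1, 0.4), ncol = 1,
                dimnames = list(paste0("S", 1:n), "L1"))
    if (var(g[, 1]) == 0) next
    y <- rnorm(n) + 0.5 * g[, 1]
    res <- association_scan(g, y)
    tt <- t.test(y[g == 1], y[g == 0], var.equal = TRUE)
    expect_equal(res$p, tt$p.value, tolerance = 1e-10)
    expect_equal(abs(res$statistic), abs(unname(tt$statistic)),
                 tolerance = 1e-10)
  }
})

test_that("null p-values are uniform under no association", {
  crit <- 1.628 / sqrt(300)  # KS 1% critical value, n = 300
  ok <- vapply(1:30, function(s) {
    set.seed(500 + s)
    g <- matrix(rbinom(150 * 300, 1, runif(300, 0.1, 0.9)[rep(1:300, each = 150)]),
                150, 300)
    colnames(g) <- sprintf("L%03d", 1:300)
    y <- rnorm(150)
    res <- association_scan(g + 0, y)
    stats::ks.test(res$p, "punif")$statistic < crit
  }, logical(1))
  expect_gte(sum(ok), 27)
})

test_that("a covariate identical to the phenotype absorbs the signal", {
  set.seed(83)
  n <- 60
  covar <- matrix(rnorm(n), ncol = 1)
  y <- covar[, 1] + rnorm(n, sd = 1e-8)
  g <- matrix(rbinom(n, 1, 0.5), ncol = 1, dimnames = list(NULL, "L1"))
  res <- association_scan(g, y, covariates = covar)
  expect_lt(abs(res$effect), 1e-6)
  expect_gt(res$p, 0.5)
})

test_that("constant phenotype and overparameterized fits are errors", {
  g <- matrix(rbinom(10, 1, 0.5), ncol = 1, dimnames = list(NULL, "L1"))
  expect_error(association_scan(g, rep(1, 10)), "constant")
  g2 <- matrix(rbinom(4, 1, 0.5), ncol = 1)
  expect_error(association_scan(g2, rnorm(4), covariates = matrix(rnorm(8), 4)),
               "fewer samples")
})

test_that("permutation threshold follows the order-statistic convention", {
  set.seed(89)
  g <- matrix(rbinom(50 * 100, 1, 0.5), 50, 100,
              dimnames = list(NULL, sprintf("L%03d", 1:100)))
  y <- rnorm(50)
  thr <- permutation_threshold(g + 0, y, n_permutations = 100, seed = 7)
  maxima <- attr(thr, "maxima")
  expect_equal(length(maxima), 100L)
  expect_equal(as.numeric(thr), sort(maxima)[95])
  expect_equal(as.numeric(thr),
               unname(quantile(maxima, 0.95, type = 1)))
  # weakly increasing as alpha decreases
  thr01 <- permutation_threshold(g + 0, y, n_permutations = 100,
                                 alpha = 0.01, seed = 7)
  thr20 <- permutation_threshold(g + 0, y, n_permutations = 100,
                                 alpha = 0.20, seed = 7)
  expect_gte(as.numeric(thr01), as.numeric(thr))
  expect_lte(as.numeric(thr20), as.numeric(thr))
  # deterministic under the seed
  thr2 <- permutation_threshold(g + 0, y, n_permutations = 100, seed = 7)
  expect_identical(as.numeric(thr), as.numeric(thr2))
  expect_warning(
    permutation_threshold(g + 0, y, n_permutations = 10, seed = 1),
    "unstable")
})

test_that("significance calls use the inclusive threshold rule", {
  res <- data.frame(locus = c("a", "b", "c"),
                    p = c(1e-6, 1e-3, 0.5),
                    minus_log10_p = c(6, 3, 0.301))
  sig <- call_significant(res, threshold = 3)  # tie at 3 included
  expect_equal(sig$locus, c("a", "b"))
  expect_equal(nrow(call_significant(res, threshold = 10)), 0L)
})

test_that("PC covariates reduce structure-driven inflation", {
  traits <- data.frame(name = "trait", baseline = 0, noise_sd = 1,
                       subpop_shift = 1.5, n_causal = 0L,
                       variance_explained = 0.25)
  med_diff <- vapply(1:20, function(s) {
    cfg <- pav_sim_config(seed = 900 + s, n_samples = 150L,
                          n_true_pavs = 300L, traits = traits)
    truth <- simulate_pav_truth(cfg)
    ph <- simulate_phenotypes(truth, cfg)
    e <- encode_genotypes(truth$genotypes)
    pcs <- compute_pcs(e, 3)
    no_pc <- association_scan(e, ph$trait)
    with_pc <- association_scan(e, ph$trait, covariates = pcs$scores)
    stats::median(no_pc$minus_log10_p, na.rm = TRUE) -
      stats::median(with_pc$minus_log10_p, na.rm = TRUE)
  }, numeric(1))
  expect_gt(stats::median(med_diff), 0)
  expect_gte(sum(med_diff > 0), 15)
})

test_that("gene mapping honours the 3 kb flank geometry", {
  ann <- toy_annotation()  # gene [10000, 20000] on chr1
  # 55 bp deletion ending 615 bp upstream of the gene start
  del_end <- 10000 - 615
  hits <- map_to_genes(toy_loci(del_end - 55, del_end), ann)
  expect_equal(hits$gene_id, "g1")
  # locus inside the first intron
  hits <- map_to_genes(toy_loci(12100, 12400), ann)
  expect_equal(hits$gene_id, "g1")
  # 10 kb away: nothing
  hits <- map_to_genes(toy_loci(30000, 30100), ann)
  expect_equal(nrow(hits), 0L)
})

test_that("pav_gwas returns a complete fitted object with methods", {
  cfg <- pav_sim_config(seed = 97, n_samples = 80L, n_true_pavs = 150L)
  truth <- simulate_pav_truth(cfg)
  ph <- simulate_phenotypes(truth, cfg)
  gm <- structure(list(genotypes = truth$genotypes, loci = truth$loci,
                       samples = truth$samples), class = "pav_genotypes")
  fit <- pav_gwas(gm, ph, trait = "days_to_heading", n_permutations = 50,
                  seed = 5)
  expect_s3_class(fit, "pav_gwas")
  expect_equal(nrow(fit$results), nrow(truth$loci))
  expect_true(is.finite(fit$threshold))
  expect_named(coef(fit), fit$results$locus)
  expect_output(print(fit), "threshold")
  expect_output(summary(fit), "PC variance")
  # significant set consistent with the inclusive flag rule
  expect_equal(sum(fit$results$significant), nrow(fit$significant))
})
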