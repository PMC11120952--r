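# Single-PAV haplotype groups: split samples by presence/absence at one
# locus and compare trait values between the groups with a t-test.

#' Split samples into haplotype groups at one PAV locus
#'
#' Group 1 is the reference haplotype (PAV absent), group 2 carries the
#' PAV allele. Samples with a missing genotype or missing phenotype are
#' excluded.
#'
#' @param gmatrix a `pav_genotypes`.
#' @param locus_id locus identifier (column of the genotype matrix).
#' @param phenotype named numeric vector (sample id -> trait value), or
#'   NULL to split on genotype only.
#' @return a `haplotype_groups` object: list with `locus_id`, `group1`,
#'   `group2`, `excluded` (sample id vectors).
#' @export
split_haplotypes <- function(gmatrix, locus_id, phenotype = NULL) {
  g <- gmatrix$genotypes
  if (!locus_id %in% colnames(g)) {
    stop("locus not in genotype matrix: ", locus_id)
  }
  v <- g[, locus_id]
  samples <- rownames(g)
  pheno_missing <- if (is.null(phenotype)) rep(FALSE, length(samples))
                   else is.na(phenotype[samples])
  excluded <- samples[is.na(v) | pheno_missing]
  keep <- setdiff(samples, excluded)
  structure(list(
    locus_id = locus_id,
    group1 = keep[v[keep] == 0L],
    group2 = keep[v[keep] == 1L],
    excluded = excluded
  ), class = "haplotype_groups")
}

#' @export
print.haplotype_groups <- function(x, ...) {
  cat(sprintf(
    "haplotype_groups at %s: Hap1 (reference) n=%d, Hap2 (PAV) n=%d, excluded %d\n",
    x$locus_id, length(x$group1), length(x$group2), length(x$excluded)))
  invisible(x)
}

#' Compare trait values between haplotype groups
#'
#' Two-sample t-test between the reference and PAV-carrier groups,
#' Welch (unequal variances) by default; set `var_equal = TRUE` for the
#' pooled-variance variant.
#'
#' @param groups a `haplotype_groups` (or two numeric vectors via
#'   `group1_values` / `group2_values`).
#' @param phenotype named numeric vector (sample id -> trait value).
#' @param var_equal pooled-variance t-test instead of Welch.
#' @return a `haplotype_comparison` object: list with group means, sizes,
#'   t statistic, degrees of freedom, two-sided p, and `significant`
#'   (p < 0.05).
#' @export
compare_groups <- function(groups, phenotype, var_equal = FALSE) {
  v1 <- phenotype[groups$group1]
  v2 <- phenotype[groups$group2]
  v1 <- v1[!is.na(v1)]
  v2 <- v2[!is.na(v2)]
  if (length(v1) < 2 || length(v2) < 2) {
    stop("insufficient group: both haplotype groups need >= 2 members")
  }
  tt <- stats::t.test(v1, v2, var.equal = var_equal)
  structure(list(
    locus_id = groups$locus_id,
    mean1 = mean(v1), mean2 = mean(v2),
    n1 = length(v1), n2 = length(v2),
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p = tt$p.value,
    significant = tt$p.value < 0.05,
    var_equal = var_equal
  ), class = "haplotype_comparison")
}

#' @export
print.haplotype_comparison <- function(x, ...) {
  cat(sprintf("haplotype_comparison at %s (%s t-test)\n",
              x$locus_id %||% "locus",
              if (x$var_equal) "pooled" else "Welch"))
  cat(sprintf("  Hap1 (reference): n=%d mean=%.4g\n", x$n1, x$mean1))
  cat(sprintf("  Hap2 (PAV):       n=%d mean=%.4g\n", x$n2, x$mean2))
  cat(sprintf("  t = %.4g, df = %.4g, p = %.4g %s\n", x$statistic, x$df,
              x$p, if (x$significant) "*" else ""))
  invisible(x)
}

#' Haplotype comparison for one locus and trait
#'
#' Convenience wrapper: split then compare.
#'
#' @param gmatrix a `pav_genotypes`.
#' @param phenotypes phenotype data.frame (sample_id + trait columns).
#' @param trait trait column name.
#' @param locus_id locus identifier.
#' @param var_equal pooled-variance t-test instead of Welch.
#' @return a `haplotype_comparison`.
#' @export
haplotype_test <- function(gmatrix, phenotypes, trait, locus_id,
                           var_equal = FALSE) {
  y <- stats::setNames(phenotypes[[trait]], phenotypes$sample_id)
  groups <- split_haplotypes(gmatrix, locus_id, y)
  compare_groups(groups, y, var_equal = var_equal)
}
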