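# PC-adjusted single-locus association scan with a permutation-derived
# genome-wide significance threshold, and mapping of significant PAVs to
# genes. The engine is a fixed-effects least-squares model per locus:
# phenotype ~ intercept + locus + PC covariates; the permutation
# threshold is computed under the same engine so scan and threshold are
# coherent.

#' Encode presence/absence genotypes as numeric design columns
#'
#' Present -> 1, absent -> 0, missing -> per-locus mean imputation. Loci
#' monomorphic after imputation are flagged unusable.
#'
#' @param gmatrix a `pav_genotypes` or a samples x loci 1/0/NA matrix.
#' @return numeric samples x loci matrix with a logical `usable`
#'   attribute per locus.
#' @export
encode_genotypes <- function(gmatrix) {
  g <- if (inherits(gmatrix, "pav_genotypes")) gmatrix$genotypes else gmatrix
  e <- apply(g, 2, function(col) {
    m <- mean(col, na.rm = TRUE)
    col[is.na(col)] <- m
    col
  })
  e <- matrix(as.numeric(e), nrow(g), ncol(g), dimnames = dimnames(g))
  usable <- apply(e, 2, function(col) {
    !anyNA(col) && stats::var(col) > 0
  })
  attr(e, "usable") <- usable
  e
}

#' Principal components of the encoded genotype matrix
#'
#' Column-centered PCA; per-component variance proportions are
#' eigenvalues over total variance and sum to 1 across all components.
#' Score signs are fixed so each component's largest-magnitude loading is
#' positive, making results deterministic across platforms.
#'
#' @param encoded numeric samples x loci matrix from
#'   [encode_genotypes()].
#' @param k number of components to keep as covariates (default 3).
#' @return a `pav_pca` object: list with `scores` (samples x k),
#'   `variance_proportion` (all components), `k`.
#' @export
compute_pcs <- function(encoded, k = 3) {
  usable <- attr(encoded, "usable")
  if (!is.null(usable)) encoded <- encoded[, usable, drop = FALSE]
  if (!ncol(encoded)) stop("no usable (polymorphic) loci for PCA")
  if (k >= nrow(encoded)) stop("k must be smaller than the sample count")
  pc <- stats::prcomp(encoded, center = TRUE, scale. = FALSE)
  varprop <- pc$sdev^2 / sum(pc$sdev^2)
  k_eff <- min(k, ncol(pc$x))
  scores <- pc$x[, seq_len(k_eff), drop = FALSE]
  for (j in seq_len(k_eff)) {
    load <- pc$rotation[, j]
    if (load[which.max(abs(load))] < 0) scores[, j] <- -scores[, j]
  }
  structure(list(scores = scores, variance_proportion = varprop, k = k_eff),
            class = "pav_pca")
}

#' @export
print.pav_pca <- function(x, ...) {
  cat(sprintf("pav_pca: %d component(s) kept; variance explained %s\n",
              x$k,
              paste(sprintf("%.1f%%",
                            100 * x$variance_proportion[seq_len(x$k)]),
                    collapse = ", ")))
  invisible(x)
}

# Residualize columns of M against the covariate design X (with
# intercept) via one QR decomposition.
residualize <- function(M, qr_x) {
  qr.resid(qr_x, M)
}

scan_core <- function(Gres, yres, df) {
  gss <- colSums(Gres^2)
  gy <- as.numeric(crossprod(Gres, yres))
  usable <- gss > 1e-10
  beta <- ifelse(usable, gy / gss, NA_real_)
  rss <- sum(yres^2) - beta^2 * gss
  rss <- pmax(rss, 0)
  sigma2 <- rss / df
  se <- sqrt(sigma2 / gss)
  tstat <- beta / se
  p <- 2 * stats::pt(-abs(tstat), df)
  list(beta = beta, se = se, t = tstat, p = p, usable = usable)
}

#' Single-locus association scan
#'
#' For each locus, fits phenotype ~ intercept + locus + covariates by
#' least squares and reports the locus coefficient, its standard error,
#' t statistic and two-sided p-value. Samples with missing phenotype are
#' dropped. Monomorphic loci get NA statistics.
#'
#' @param encoded numeric samples x loci matrix ([encode_genotypes()]).
#' @param phenotype named numeric vector aligned with the matrix rows
#'   (names checked when present).
#' @param covariates optional numeric matrix of covariates (e.g. PC
#'   scores), samples in rows.
#' @return data.frame: locus, effect, se, statistic, p, minus_log10_p.
#' @export
association_scan <- function(encoded, phenotype, covariates = NULL) {
  aligned <- align_scan_inputs(encoded, phenotype, covariates)
  with(aligned, {
    if (stats::var(y) == 0) stop("constant phenotype")
    X <- cbind(intercept = rep(1, length(y)), covariates)
    if (nrow(X) <= ncol(X) + 1) stop("fewer samples than model parameters")
    qr_x <- qr(X)
    df <- nrow(X) - qr_x$rank - 1
    Gres <- residualize(G, qr_x)
    yres <- as.numeric(residualize(y, qr_x))
    res <- scan_core(Gres, yres, df)
    data.frame(
      locus = colnames(G) %||% sprintf("L%05d", seq_len(ncol(G))),
      effect = res$beta, se = res$se, statistic = res$t, p = res$p,
      minus_log10_p = -log10(res$p),
      stringsAsFactors = FALSE, row.names = NULL
    )
  })
}

align_scan_inputs <- function(encoded, phenotype, covariates) {
  if (!is.null(names(phenotype)) && !is.null(rownames(encoded))) {
    common <- intersect(rownames(encoded), names(phenotype))
    if (!length(common)) stop("no overlapping samples")
    encoded <- encoded[common, , drop = FALSE]
    phenotype <- phenotype[common]
    if (!is.null(covariates)) {
      covariates <- covariates[common, , drop = FALSE]
    }
  }
  keep <- !is.na(phenotype)
  list(G = encoded[keep, , drop = FALSE], y = as.numeric(phenotype[keep]),
       covariates = if (is.null(covariates)) NULL
                    else as.matrix(covariates)[keep, , drop = FALSE])
}

#' Permutation-derived genome-wide significance threshold
#'
#' Runs `n_permutations` permutations; in each, the phenotype residuals
#' (after regressing out the covariates; `conditioning = "residual"`,
#' the default conditional scheme) or the raw phenotype values
#' (`"raw"`) are permuted across samples, all loci are re-scanned with
#' the same engine, and the genome-wide maximum -log10(p) is recorded.
#' The threshold is the empirical (1 - alpha) quantile of these maxima,
#' taken as an order statistic (type-1 quantile, lower interpolation) so
#' it is exactly reproducible.
#'
#' @param encoded numeric samples x loci matrix.
#' @param phenotype numeric phenotype vector.
#' @param covariates optional covariate matrix.
#' @param n_permutations number of permutations (default 1000).
#' @param alpha family-wise error target (default 0.05).
#' @param seed RNG seed for the permutations.
#' @param conditioning "residual" (permute covariate-adjusted residuals)
#'   or "raw" (permute phenotype labels).
#' @param pooled if TRUE, take the quantile of the pooled permutation
#'   -log10(p) distribution over all loci instead of per-permutation
#'   maxima (non-default variant).
#' @return threshold on the -log10(p) scale, with the permutation maxima
#'   in `attr(, "maxima")`.
#' @export
permutation_threshold <- function(encoded, phenotype, covariates = NULL,
                                  n_permutations = 1000, alpha = 0.05,
                                  seed = 1L,
                                  conditioning = c("residual", "raw"),
                                  pooled = FALSE) {
  conditioning <- match.arg(conditioning)
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (n_permutations < 20 && alpha <= 0.05) {
    warning("fewer than 20 permutations: the ", 1 - alpha,
            " quantile is unstable")
  }
  aligned <- align_scan_inputs(encoded, phenotype, covariates)
  G <- aligned$G
  y <- aligned$y
  X <- cbind(intercept = rep(1, length(y)), aligned$covariates)
  qr_x <- qr(X)
  df <- nrow(X) - qr_x$rank - 1
  Gres <- residualize(G, qr_x)
  base <- if (conditioning == "residual") {
    as.numeric(residualize(y, qr_x))
  } else {
    y
  }
  set.seed(as.integer(seed))
  n <- length(base)
  P <- vapply(seq_len(n_permutations),
              function(b) base[sample.int(n)], numeric(n))
  # permuted vectors are re-residualized so each permutation replays the
  # full covariate-adjusted fit (Freedman-Lane style)
  Pres <- residualize(P, qr_x)
  gss <- colSums(Gres^2)
  usable <- gss > 1e-10
  GY <- crossprod(Gres[, usable, drop = FALSE], Pres)  # m_u x B
  gss_u <- gss[usable]
  yss <- colSums(Pres^2)
  beta <- GY / gss_u
  rss <- pmax(sweep(-beta^2 * gss_u, 2, yss, `+`), 0)
  tstat <- beta / sqrt(rss / df / gss_u)
  if (pooled) {
    logp <- -log10(2 * stats::pt(-abs(tstat), df))
    stat <- as.numeric(logp)
  } else {
    maxt <- apply(abs(tstat), 2, max)
    stat <- -log10(2 * stats::pt(-maxt, df))
  }
  thr <- as.numeric(stats::quantile(stat, 1 - alpha, type = 1, names = FALSE))
  attr(thr, "maxima") <- if (pooled) NULL else stat
  thr
}

#' Call significant loci
#'
#' @param results data.frame from [association_scan()].
#' @param threshold -log10(p) threshold (loci at or above it are
#'   significant).
#' @return the significant subset, sorted by p ascending.
#' @export
call_significant <- function(results, threshold) {
  sig <- results[!is.na(results$minus_log10_p) &
                   results$minus_log10_p >= threshold, , drop = FALSE]
  sig <- sig[order(sig$p), , drop = FALSE]
  rownames(sig) <- NULL
  sig
}

#' Map significant loci to nearby genes
#'
#' Reports every gene whose span extended by `flank_bp` on each side
#' overlaps the locus (insertions as 1 bp points).
#'
#' @param loci data.frame with locus_id, chrom, start, end, svtype.
#' @param annotation a `gene_annotation`.
#' @param flank_bp flank width (default 3000).
#' @return data.frame: locus_id, gene_id, gene_start, gene_end, strand.
#' @export
map_to_genes <- function(loci, annotation, flank_bp = 3000) {
  empty <- data.frame(locus_id = character(0), gene_id = character(0),
                      gene_start = numeric(0), gene_end = numeric(0),
                      strand = character(0), stringsAsFactors = FALSE)
  g <- annotation$genes
  if (!nrow(loci) || is.null(g) || !nrow(g)) return(empty)
  seqlvls <- union(unique(g$chrom), unique(loci$chrom))
  gr_loci <- loci_granges(loci, seqlvls)
  gr_genes <- GenomicRanges::GRanges(
    factor(g$chrom, seqlvls),
    IRanges::IRanges(pmax(1, g$start - flank_bp), g$end + flank_bp))
  ov <- GenomicRanges::findOverlaps(gr_loci, gr_genes)
  if (!length(ov)) return(empty)
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)
  out <- data.frame(
    locus_id = loci$locus_id[qh], gene_id = g$gene_id[sh],
    gene_start = g$start[sh], gene_end = g$end[sh], strand = g$strand[sh],
    stringsAsFactors = FALSE)
  out[order(out$locus_id, out$gene_start), , drop = FALSE]
}

#' PC-adjusted PAV association scan with permutation threshold
#'
#' The front-end fitting function: encodes the genotype matrix, computes
#' principal-component covariates, runs the single-locus scan for one
#' trait, derives the permutation threshold under the same engine, and
#' flags significant loci.
#'
#' @param gmatrix a `pav_genotypes` (filtered).
#' @param phenotypes data.frame from [read_phenotype_table()] or
#'   [simulate_phenotypes()] (column `sample_id` + traits), or a named
#'   numeric vector.
#' @param trait trait column name (ignored when `phenotypes` is a
#'   vector).
#' @param n_pcs number of PC covariates (default 3).
#' @param n_permutations permutations for the threshold (default 1000).
#' @param alpha family-wise error target (default 0.05).
#' @param seed RNG seed for permutations.
#' @param conditioning passed to [permutation_threshold()].
#' @return a `pav_gwas` object with `results`, `threshold`, `pca`,
#'   `significant`, `trait`, `n_samples`.
#' @export
pav_gwas <- function(gmatrix, phenotypes, trait = NULL, n_pcs = 3,
                     n_permutations = 1000, alpha = 0.05, seed = 1L,
                     conditioning = "residual") {
  if (is.data.frame(phenotypes)) {
    if (is.null(trait)) stop("trait must name a phenotype column")
    if (!trait %in% names(phenotypes)) stop("unknown trait: ", trait)
    y <- stats::setNames(phenotypes[[trait]], phenotypes$sample_id)
  } else {
    y <- phenotypes
  }
  encoded <- encode_genotypes(gmatrix)
  pca <- compute_pcs(encoded, k = n_pcs)
  covs <- pca$scores
  results <- association_scan(encoded, y, covs)
  thr <- permutation_threshold(encoded, y, covs,
                               n_permutations = n_permutations,
                               alpha = alpha, seed = seed,
                               conditioning = conditioning)
  results$significant <- !is.na(results$minus_log10_p) &
    results$minus_log10_p >= as.numeric(thr)
  loci <- if (inherits(gmatrix, "pav_genotypes")) gmatrix$loci else NULL
  obj <- list(
    results = results, threshold = as.numeric(thr), pca = pca,
    significant = call_significant(results, as.numeric(thr)),
    trait = trait %||% "phenotype",
    n_samples = sum(!is.na(y)), loci = loci,
    alpha = alpha, n_permutations = n_permutations
  )
  class(obj) <- "pav_gwas"
  obj
}

#' @export
print.pav_gwas <- function(x, ...) {
  cat(sprintf("pav_gwas scan of '%s': %d loci, %d samples\n", x$trait,
              nrow(x$results), x$n_samples))
  cat(sprintf("  threshold -log10(p) = %.3f (%d permutations, alpha %.2f)\n",
              x$threshold, x$n_permutations, x$alpha))
  cat(sprintf("  significant loci: %d\n", nrow(x$significant)))
  invisible(x)
}

#' @export
summary.pav_gwas <- function(object, ...) {
  cat(sprintf("PAV association scan: trait '%s'\n", object$trait))
  cat(sprintf("  %d loci scanned on %d samples; %d PC covariates\n",
              nrow(object$results), object$n_samples, object$pca$k))
  cat(sprintf("  PC variance explained: %s\n",
              paste(sprintf("%.1f%%",
                            100 * object$pca$variance_proportion[
                              seq_len(object$pca$k)]),
                    collapse = ", ")))
  cat(sprintf("  permutation threshold: %.3f (-log10 p)\n",
              object$threshold))
  if (nrow(object$significant)) {
    cat("  top significant loci:\n")
    print(utils::head(object$significant, 10))
  } else {
    cat("  no significant loci\n")
  }
  invisible(object)
}

#' @export
coef.pav_gwas <- function(object, ...) {
  stats::setNames(object$results$effect, object$results$locus)
}

#' Manhattan-style plot of a PAV association scan
#'
#' @param x a `pav_gwas` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.pav_gwas <- function(x, ...) {
  r <- x$results
  if (!is.null(x$loci)) {
    chroms <- unique(x$loci$chrom)
    offs <- c(0, cumsum(tapply(x$loci$start + x$loci$end,
                               factor(x$loci$chrom, chroms), max)))
    pos <- x$loci$start + offs[match(x$loci$chrom, chroms)]
    col <- (match(x$loci$chrom, chroms) %% 2) + 1
  } else {
    pos <- seq_len(nrow(r))
    col <- 1
  }
  graphics::plot(pos, r$minus_log10_p, pch = 20,
                 col = c("grey40", "steelblue")[col],
                 xlab = "genome position", ylab = "-log10(p)",
                 main = sprintf("PAV association: %s", x$trait), ...)
  graphics::abline(h = x$threshold, col = "red", lty = 2)
  invisible(x)
}
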