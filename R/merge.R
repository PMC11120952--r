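# Multi-caller PAV merging: PASS filtering, breakpoint-proximity
# clustering into consensus loci, presence-dominant genotype union, and
# MAF / missing-rate variant filters.

#' Merge parameters
#'
#' @param max_breakpoint_distance maximum distance (bp) between both the
#'   start and the end breakpoints for two records to be linkable.
#' @param require_same_type if TRUE (default) only records of the same
#'   SV type (DEL with DEL, INS with INS) can merge.
#' @param pass_only if TRUE (default) non-PASS records are removed before
#'   clustering.
#' @return list of class `merge_params`.
#' @export
merge_params <- function(max_breakpoint_distance = 1000,
                         require_same_type = TRUE,
                         pass_only = TRUE) {
  if (max_breakpoint_distance < 0) stop("merge distance must be >= 0")
  structure(list(max_breakpoint_distance = as.numeric(max_breakpoint_distance),
                 require_same_type = isTRUE(require_same_type),
                 pass_only = isTRUE(pass_only)),
            class = "merge_params")
}

#' Variant filter parameters
#'
#' @param maf_min minimum minor allele frequency (inclusive bound; the
#'   conventional MAF >= 0.01 cut).
#' @param missing_max maximum missing fraction, exclusive bound
#'   (missing rate must be strictly below it; the conventional < 40% cut).
#' @return list of class `filter_params`.
#' @export
filter_params <- function(maf_min = 0.01, missing_max = 0.40) {
  if (maf_min < 0 || maf_min > 0.5) stop("maf_min must be in [0, 0.5]")
  if (missing_max <= 0 || missing_max > 1) {
    stop("missing_max must be in (0, 1]")
  }
  structure(list(maf_min = maf_min, missing_max = missing_max),
            class = "filter_params")
}

#' Keep only PASS records
#'
#' @param callset a `pav_callset`.
#' @return the callset restricted to records whose FILTER equals "PASS";
#'   the number removed is in `attr(, "n_removed")`.
#' @export
filter_pass <- function(callset) {
  keep <- callset$records$filter == "PASS"
  out <- structure(
    list(records = callset$records[keep, , drop = FALSE],
         genotypes = callset$genotypes[keep, , drop = FALSE],
         caller = callset$caller),
    class = "pav_callset")
  rownames(out$records) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Pool several callsets into one record table
#'
#' @param callsets list of `pav_callset` objects (one per caller).
#' @return a `pav_callset` with all records stacked; genotype columns are
#'   the union of sample sets (callers must agree on sample naming).
#' @export
pool_callsets <- function(callsets) {
  samples <- unique(unlist(lapply(callsets, function(cs) colnames(cs$genotypes))))
  gmats <- lapply(callsets, function(cs) {
    g <- matrix(NA_integer_, nrow(cs$records), length(samples),
                dimnames = list(cs$records$record_id, samples))
    if (ncol(cs$genotypes)) {
      g[, colnames(cs$genotypes)] <- cs$genotypes
    }
    g
  })
  recs <- do.call(rbind, lapply(callsets, function(cs) {
    cs$records[setdiff(names(cs$records), "truth_id")]
  }))
  rownames(recs) <- NULL
  structure(list(records = recs, genotypes = do.call(rbind, gmats),
                 caller = "pooled"),
            class = "pav_callset")
}

#' Cluster PAV records into consensus loci
#'
#' Two records are linkable iff they share a chromosome, share an SV type
#' (when `require_same_type`), and both their start and end breakpoints
#' differ by at most `max_breakpoint_distance`. Clusters are the
#' connected components of the linkability graph, found by a
#' position-sorted sweep; the result is independent of input order.
#' Consensus coordinates are the lower-median of member starts/ends.
#'
#' @param records data.frame of PAV records (chrom, start, end, svtype,
#'   svlen, caller, record_id) or a `pav_callset`.
#' @param params a [merge_params()].
#' @return list with `membership` (cluster index per input record, in
#'   input order) and `loci` (consensus data.frame: locus_id, chrom,
#'   start, end, svtype, size, n_records, callers).
#' @export
cluster_records <- function(records, params = merge_params()) {
  if (inherits(records, "pav_callset")) records <- records$records
  n <- nrow(records)
  D <- params$max_breakpoint_distance
  membership <- integer(n)
  if (n == 0L) {
    return(list(membership = membership, loci = empty_locus_df()))
  }
  type_key <- if (params$require_same_type) records$svtype else ""
  group <- paste(records$chrom, type_key, sep = "\r")

  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (g in unique(group)) {
    idx <- which(group == g)
    idx <- idx[order(records$start[idx], records$end[idx], idx)]
    st <- records$start[idx]
    en <- records$end[idx]
    lo <- 1L
    for (k in seq_along(idx)) {
      while (st[k] - st[lo] > D) lo <- lo + 1L
      if (lo < k) {
        for (j in lo:(k - 1L)) {
          if (abs(en[k] - en[j]) <= D) {
            ri <- find(idx[k]); rj <- find(idx[j])
            if (ri != rj) parent[ri] <- rj
          }
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  # canonical cluster order: by consensus (chrom, start, end, type)
  cl <- split(seq_len(n), roots)
  cons <- lapply(cl, function(ix) {
    r <- records[ix, , drop = FALSE]
    st <- median_lower(r$start)
    en <- if (r$svtype[1] == "INS" && params$require_same_type) st
          else median_lower(r$end)
    if (!params$require_same_type && all(r$svtype == "INS")) en <- st
    data.frame(chrom = r$chrom[1], start = st, end = en,
               svtype = if (length(unique(r$svtype)) == 1L) r$svtype[1] else "MIXED",
               size = if (r$svtype[1] == "DEL") en - st
                      else median_lower(abs(r$svlen)),
               n_records = nrow(r),
               callers = paste(sort(unique(r$caller)), collapse = ","),
               stringsAsFactors = FALSE)
  })
  loci <- do.call(rbind, cons)
  ord <- order(loci$chrom, loci$start, loci$end, loci$svtype)
  loci <- loci[ord, , drop = FALSE]
  loci$locus_id <- sprintf("L%05d", seq_len(nrow(loci)))
  loci <- loci[c("locus_id", "chrom", "start", "end", "svtype", "size",
                 "n_records", "callers")]
  rownames(loci) <- NULL
  remap <- stats::setNames(seq_len(nrow(loci)), names(cl)[ord])
  list(membership = unname(remap[as.character(roots)]), loci = loci)
}

empty_locus_df <- function() {
  data.frame(locus_id = character(0), chrom = character(0),
             start = numeric(0), end = numeric(0), svtype = character(0),
             size = numeric(0), n_records = integer(0),
             callers = character(0), stringsAsFactors = FALSE)
}

#' Build the presence/absence genotype matrix from clustered records
#'
#' Per sample and locus the member records' calls are combined
#' presence-dominant: present if any member record calls the sample
#' present, else absent if any calls it absent, else missing.
#'
#' @param clustering result of [cluster_records()].
#' @param genotypes records x samples matrix aligned with the records
#'   passed to [cluster_records()] (1/0/NA), or a pooled `pav_callset`.
#' @param samples character vector of sample ids (must cover the matrix
#'   columns).
#' @return a `pav_genotypes` object: list with `genotypes` (samples x
#'   loci matrix, 1 present / 0 absent / NA missing), `loci` (consensus
#'   metadata), `samples`.
#' @export
build_genotype_matrix <- function(clustering, genotypes, samples = NULL) {
  if (inherits(genotypes, "pav_callset")) genotypes <- genotypes$genotypes
  samples <- samples %||% colnames(genotypes)
  if (!all(colnames(genotypes) %in% samples)) {
    stop("sample in records but not in sample list: ",
         paste(setdiff(colnames(genotypes), samples), collapse = ", "))
  }
  loci <- clustering$loci
  m <- nrow(loci)
  gm <- matrix(NA_integer_, length(samples), m,
               dimnames = list(samples, loci$locus_id))
  if (m && nrow(genotypes)) {
    gsub <- matrix(NA_integer_, nrow(genotypes), length(samples),
                   dimnames = list(NULL, samples))
    gsub[, colnames(genotypes)] <- genotypes
    for (k in seq_len(m)) {
      rows <- which(clustering$membership == k)
      sub <- gsub[rows, , drop = FALSE]
      any_present <- colSums(sub == 1L, na.rm = TRUE) > 0L
      any_absent <- colSums(sub == 0L, na.rm = TRUE) > 0L
      gm[any_absent, k] <- 0L
      gm[any_present, k] <- 1L
    }
  }
  structure(list(genotypes = gm, loci = loci, samples = samples),
            class = "pav_genotypes")
}

#' @export
print.pav_genotypes <- function(x, ...) {
  g <- x$genotypes
  cat(sprintf("pav_genotypes: %d samples x %d loci", nrow(g), ncol(g)))
  if (length(g)) {
    cat(sprintf(" (%.1f%% present, %.1f%% missing)",
                100 * mean(g == 1L, na.rm = TRUE), 100 * mean(is.na(g))))
  }
  cat("\n")
  if (!is.null(attr(x, "filter_log"))) {
    fl <- attr(x, "filter_log")
    cat(sprintf("  filters: %d below MAF, %d above missing rate, %d kept\n",
                fl$n_maf_removed, fl$n_missing_removed, fl$n_kept))
  }
  invisible(x)
}

#' Minor allele frequency of a presence/absence genotype vector
#'
#' @param genotype_vector 1/0/NA vector.
#' @return min(p, 1 - p) where p is the presence frequency among
#'   non-missing calls.
#' @export
compute_maf <- function(genotype_vector) {
  ok <- !is.na(genotype_vector)
  if (!any(ok)) stop("MAF undefined: all genotypes missing")
  p <- mean(genotype_vector[ok])
  min(p, 1 - p)
}

#' Apply MAF and missing-rate filters to a genotype matrix
#'
#' A locus is kept iff MAF >= `maf_min` and its missing fraction is
#' strictly below `missing_max`. Per-criterion removal counts are stored
#' in `attr(, "filter_log")`.
#'
#' @param gmatrix a `pav_genotypes`.
#' @param params a [filter_params()].
#' @return the filtered `pav_genotypes`.
#' @export
apply_variant_filters <- function(gmatrix, params = filter_params()) {
  g <- gmatrix$genotypes
  miss <- colMeans(is.na(g))
  p <- colMeans(g == 1L, na.rm = TRUE)
  p[is.nan(p)] <- 0
  maf <- pmin(p, 1 - p)
  ok_maf <- maf >= params$maf_min
  ok_miss <- miss < params$missing_max
  keep <- ok_maf & ok_miss
  out <- structure(
    list(genotypes = g[, keep, drop = FALSE],
         loci = gmatrix$loci[keep, , drop = FALSE],
         samples = gmatrix$samples),
    class = "pav_genotypes")
  rownames(out$loci) <- NULL
  attr(out, "filter_log") <- list(
    n_input = ncol(g),
    n_maf_removed = sum(!ok_maf),
    n_missing_removed = sum(!ok_miss),
    n_kept = sum(keep))
  out
}

#' Merge caller callsets into a filtered genotype matrix
#'
#' Convenience wrapper: PASS-filter each callset (when `pass_only`),
#' pool, cluster, build the presence-dominant genotype matrix, and apply
#' the MAF / missing-rate filters.
#'
#' @param callsets list of `pav_callset` objects.
#' @param merge a [merge_params()].
#' @param filters a [filter_params()], or NULL to skip variant filters.
#' @param samples optional full sample list.
#' @return a filtered `pav_genotypes`.
#' @export
merge_callsets <- function(callsets, merge = merge_params(),
                           filters = filter_params(), samples = NULL) {
  if (merge$pass_only) callsets <- lapply(callsets, filter_pass)
  pooled <- pool_callsets(callsets)
  clustering <- cluster_records(pooled$records, merge)
  gm <- build_genotype_matrix(clustering, pooled$genotypes,
                              samples %||% colnames(pooled$genotypes))
  if (!is.null(filters)) gm <- apply_variant_filters(gm, filters)
  gm
}
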