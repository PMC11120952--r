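# PAV landscape characterization: size spectrum, genomic-context
# classification against gene models, per-chromosome counts, and
# sliding-window breakpoint hotspot detection.

#' Default log-spaced size bins
#'
#' Half-open bins from the 50 bp PAV floor up, roughly doubling.
#'
#' @return numeric vector of bin edges (last edge Inf).
#' @export
default_size_bins <- function() {
  c(50, 100, 200, 500, 1000, 2000, 5000, 10000, 20000, 50000, Inf)
}

#' PAV size spectrum
#'
#' Counts PAV sizes in half-open bins [lo, hi) and reports the short-PAV
#' fraction (sizes between 50 and 1000 bp inclusive).
#'
#' @param sizes numeric vector of PAV sizes (bp), all >= 50.
#' @param bin_edges bin edges; defaults to [default_size_bins()].
#' @return list with `counts` (named per-bin), `short_fraction`
#'   (NA when there are no loci), `n`.
#' @export
size_spectrum <- function(sizes, bin_edges = default_size_bins()) {
  if (any(sizes < 50)) stop("PAV size below 50 bp violates the SV floor")
  labs <- paste0("[", utils::head(bin_edges, -1), ",",
                 bin_edges[-1], ")")
  if (!length(sizes)) {
    counts <- stats::setNames(rep(0L, length(labs)), labs)
    return(list(counts = counts, short_fraction = NA_real_, n = 0L))
  }
  idx <- findInterval(sizes, bin_edges, rightmost.closed = FALSE)
  idx[idx == 0L | idx > length(labs)] <- NA
  counts <- stats::setNames(tabulate(idx, length(labs)), labs)
  list(counts = counts,
       short_fraction = mean(sizes >= 50 & sizes <= 1000),
       n = length(sizes))
}

context_classes <- c("flank_3kb", "CDS", "UTR", "intron", "intergenic")

annotation_granges <- function(annotation, flank_bp = 3000,
                               seqlvls = NULL) {
  seqlvls <- seqlvls %||% unique(annotation$genes$chrom)
  mk <- function(df) {
    if (is.null(df) || !nrow(df)) {
      return(GenomicRanges::GRanges(seqlengths = stats::setNames(
        rep(NA_integer_, length(seqlvls)), seqlvls)))
    }
    GenomicRanges::GRanges(factor(df$chrom, seqlvls),
                           IRanges::IRanges(df$start, df$end))
  }
  g <- annotation$genes
  flank <- if (!is.null(g) && nrow(g)) {
    up <- data.frame(chrom = g$chrom, start = pmax(1, g$start - flank_bp),
                     end = g$start - 1)
    dn <- data.frame(chrom = g$chrom, start = g$end + 1,
                     end = g$end + flank_bp)
    both <- rbind(up, dn)
    both <- both[both$end >= both$start, , drop = FALSE]
    mk(both)
  } else GenomicRanges::GRanges()
  genes_gr <- mk(g)
  list(
    flank_3kb = GenomicRanges::reduce(flank),
    CDS = GenomicRanges::reduce(mk(annotation$cds)),
    UTR = GenomicRanges::reduce(mk(annotation$utr)),
    intron = GenomicRanges::reduce(mk(annotation$introns)),
    genic_or_flank = GenomicRanges::reduce(c(genes_gr, flank))
  )
}

loci_granges <- function(loci, seqlvls = NULL) {
  # insertions are breakpoint events: treated as 1 bp points at start
  end <- ifelse(loci$svtype == "INS", loci$start, loci$end)
  chrom <- if (is.null(seqlvls)) loci$chrom else factor(loci$chrom, seqlvls)
  GenomicRanges::GRanges(chrom, IRanges::IRanges(loci$start, end))
}

#' Classify PAV loci by genomic context
#'
#' A locus (insertions as 1 bp points) carries a class for every feature
#' type it overlaps by at least 1 bp: `flank_3kb` (within `flank_bp` of a
#' gene span), `CDS`, `UTR`, `intron`, and `intergenic` (at least one
#' base outside all genes and flanks). The classes are not exclusive: a
#' PAV spanning a gene boundary carries several.
#'
#' @param loci data.frame with chrom, start, end, svtype (or a
#'   `pav_genotypes`).
#' @param annotation a `gene_annotation`.
#' @param flank_bp flank width (default 3000, i.e. the standard +/- 3 kb
#'   regulatory window).
#' @return logical matrix loci x 5 classes.
#' @export
classify_context <- function(loci, annotation, flank_bp = 3000) {
  if (inherits(loci, "pav_genotypes")) loci <- loci$loci
  n <- nrow(loci)
  out <- matrix(FALSE, n, length(context_classes),
                dimnames = list(loci$locus_id, context_classes))
  if (!n) return(out)
  known <- unique(annotation$genes$chrom)
  if (!length(known)) {
    out[, "intergenic"] <- TRUE
    return(out)
  }
  unknown <- !(loci$chrom %in% known)
  if (any(unknown)) {
    warning(sum(unknown), " locus/loci on chromosomes absent from the ",
            "annotation: classified intergenic")
  }
  seqlvls <- union(known, unique(loci$chrom))
  gr <- loci_granges(loci, seqlvls)
  feats <- annotation_granges(annotation, flank_bp, seqlvls)
  for (cls in c("flank_3kb", "CDS", "UTR", "intron")) {
    hit <- GenomicRanges::countOverlaps(gr, feats[[cls]]) > 0
    out[, cls] <- hit
  }
  # intergenic: any base outside all genes and their flanks
  cov <- GenomicRanges::intersect(gr, feats$genic_or_flank)
  covered_width <- rep(0, n)
  ov <- GenomicRanges::findOverlaps(gr, cov)
  if (length(ov)) {
    pi <- GenomicRanges::pintersect(gr[S4Vectors::queryHits(ov)],
                                    cov[S4Vectors::subjectHits(ov)])
    w <- tapply(GenomicRanges::width(pi), S4Vectors::queryHits(ov), sum)
    covered_width[as.integer(names(w))] <- w
  }
  out[, "intergenic"] <- covered_width < GenomicRanges::width(gr)
  out
}

#' Summarize genomic-context percentages
#'
#' Percentages are computed over loci carrying each class; a locus can
#' carry several classes, so percentages may sum above 100. "Genic"
#' means carrying any of flank_3kb/CDS/UTR/intron; the flank share is
#' reported within genic carriers.
#'
#' @param context logical matrix from [classify_context()], or a
#'   `pav_genotypes` plus `annotation`.
#' @param annotation optional `gene_annotation` (when `context` is a
#'   genotype object).
#' @param flank_bp flank width passed through.
#' @return list with `pct` (named percentages per class), `pct_genic`,
#'   `pct_flank_within_genic`, `n`.
#' @export
summarize_context <- function(context, annotation = NULL, flank_bp = 3000) {
  if (!is.matrix(context)) {
    context <- classify_context(context, annotation, flank_bp)
  }
  n <- nrow(context)
  if (!n) {
    return(list(pct = stats::setNames(rep(NA_real_, 5), context_classes),
                pct_genic = NA_real_, pct_flank_within_genic = NA_real_,
                n = 0L))
  }
  pct <- 100 * colMeans(context)
  genic <- rowSums(context[, c("flank_3kb", "CDS", "UTR", "intron"),
                           drop = FALSE]) > 0
  list(
    pct = pct,
    pct_genic = 100 * mean(genic),
    pct_flank_within_genic =
      if (any(genic)) 100 * sum(context[, "flank_3kb"] & genic) / sum(genic)
      else NA_real_,
    n = n
  )
}

#' Per-chromosome PAV counts
#'
#' @param loci data.frame with a chrom column (or `pav_genotypes`).
#' @param chromosomes optional full chromosome list (zero counts kept).
#' @return named integer vector of locus counts per chromosome.
#' @export
count_per_chromosome <- function(loci, chromosomes = NULL) {
  if (inherits(loci, "pav_genotypes")) loci <- loci$loci
  chromosomes <- chromosomes %||% sort(unique(loci$chrom))
  tab <- table(factor(loci$chrom, levels = chromosomes))
  stats::setNames(as.integer(tab), chromosomes)
}

#' Count PAV breakpoints in sliding windows
#'
#' Windows start at 0 and advance by `step` while the start is below the
#' chromosome length; ends are clipped. Each locus contributes its start
#' breakpoint once to every window containing it, so overlapping windows
#' double-count by design (set `both_ends = TRUE` to count DEL end
#' breakpoints too).
#'
#' @param loci data.frame with chrom/start/end/svtype (or
#'   `pav_genotypes`).
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param window_size window width in bp (default 1,000,000).
#' @param step step size in bp (default 500,000).
#' @param both_ends also count DEL end breakpoints.
#' @return a `window_counts` object: data.frame (chrom, start, end,
#'   count) with 0-based half-open window coordinates, plus window/step
#'   attributes.
#' @export
count_breakpoints_in_windows <- function(loci, chrom_lengths,
                                         window_size = 1e6, step = 5e5,
                                         both_ends = FALSE) {
  if (inherits(loci, "pav_genotypes")) loci <- loci$loci
  if (window_size <= 0 || step <= 0) stop("window and step must be positive")
  bp <- data.frame(chrom = loci$chrom, pos = loci$start)
  if (both_ends) {
    dels <- loci[loci$svtype == "DEL", , drop = FALSE]
    bp <- rbind(bp, data.frame(chrom = dels$chrom, pos = dels$end))
  }
  bad <- is.na(match(bp$chrom, names(chrom_lengths))) |
    bp$pos > chrom_lengths[bp$chrom]
  if (any(bad)) {
    stop("breakpoint beyond declared chromosome length: ",
         paste(utils::head(paste0(bp$chrom[bad], ":", bp$pos[bad])),
               collapse = ", "))
  }
  res <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq(0, len - 1, by = step)
    starts <- starts[starts < len]
    ends <- pmin(starts + window_size, len)
    pos <- bp$pos[bp$chrom == ch]
    counts <- integer(length(starts))
    if (length(pos)) {
      for (w in seq_along(starts)) {
        counts[w] <- sum(pos > starts[w] & pos <= ends[w])
      }
    }
    data.frame(chrom = ch, start = starts, end = ends, count = counts,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  structure(out, window_size = window_size, step = step,
            class = c("window_counts", "data.frame"))
}

#' Detect PAV hotspot regions
#'
#' Ranks all windows genome-wide (or per chromosome) by breakpoint count
#' descending; the hotspot windows are those whose count reaches the
#' count of the ceiling(top_frac x n)-th ranked window (ties included)
#' and is nonzero. Step-adjacent or overlapping hotspot windows on a
#' chromosome are merged into maximal regions.
#'
#' @param counts a `window_counts`.
#' @param top_frac fraction of windows called hotspots (default 0.10).
#' @param per_chromosome rank within each chromosome instead of
#'   genome-wide.
#' @return a `pav_hotspots` object: data.frame (chrom, start, end,
#'   n_windows, total_breakpoints, max_count) with 0-based half-open
#'   region coordinates; the count cutoff is in `attr(, "cutoff")`.
#' @export
detect_hotspots <- function(counts, top_frac = 0.10,
                            per_chromosome = FALSE) {
  if (top_frac <= 0 || top_frac > 1) stop("top_frac must be in (0, 1]")
  if (!nrow(counts)) stop("no windows to rank")
  if (per_chromosome) {
    hot <- unlist(lapply(split(seq_len(nrow(counts)), counts$chrom),
                         function(ix) ix[hotspot_mask(counts$count[ix],
                                                      top_frac)]))
    mask <- seq_len(nrow(counts)) %in% hot
    cutoff <- NA_real_
  } else {
    mask <- hotspot_mask(counts$count, top_frac)
    cutoff <- attr(mask, "cutoff")
  }
  hw <- counts[mask, , drop = FALSE]
  regions <- merge_adjacent_windows(hw)
  structure(regions, cutoff = cutoff, n_hotspot_windows = nrow(hw),
            class = c("pav_hotspots", "data.frame"))
}

hotspot_mask <- function(count, top_frac) {
  k <- ceiling(top_frac * length(count))
  cutoff <- sort(count, decreasing = TRUE)[k]
  mask <- count >= cutoff & count > 0
  attr(mask, "cutoff") <- cutoff
  mask
}

merge_adjacent_windows <- function(hw) {
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_windows = integer(0),
                      total_breakpoints = numeric(0), max_count = numeric(0),
                      stringsAsFactors = FALSE)
  if (!nrow(hw)) return(empty)
  out <- lapply(split(hw, hw$chrom), function(w) {
    w <- w[order(w$start), , drop = FALSE]
    grp <- cumsum(c(1, w$start[-1] > cummax(w$end[-nrow(w)])))
    do.call(rbind, lapply(split(w, grp), function(r) {
      data.frame(chrom = r$chrom[1], start = min(r$start), end = max(r$end),
                 n_windows = nrow(r), total_breakpoints = sum(r$count),
                 max_count = max(r$count), stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.pav_hotspots <- function(x, ...) {
  cat(sprintf("pav_hotspots: %d region(s) from %d hotspot window(s)",
              nrow(x), attr(x, "n_hotspot_windows") %||% NA_integer_))
  if (!is.na(attr(x, "cutoff") %||% NA)) {
    cat(sprintf(" (count cutoff %g)", attr(x, "cutoff")))
  }
  cat("\n")
  print.data.frame(x)
  invisible(x)
}
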