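# GFF3 gene-model reading/writing. Import goes through rtracklayer; the
# writer emits the minimal gene/mRNA/exon/CDS/UTR feature set the
# simulator produces.

#' Read gene models from a GFF3 file
#'
#' Builds a `gene_annotation` from gene/mRNA/exon/CDS (and optional
#' five_prime_UTR/three_prime_UTR) features. Exons may be children of an
#' mRNA or directly of a gene. Introns are computed as the gaps between
#' consecutive exons. A gene without exon children is treated as a single
#' exon spanning the gene (documented fallback).
#'
#' @param path GFF3 file path.
#' @return a `gene_annotation` object (1-based inclusive coordinates).
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    id = as.character(gr$ID %||% NA_character_),
    stringsAsFactors = FALSE
  )
  par <- gr$Parent
  df$parent <- if (is.null(par)) NA_character_ else
    vapply(as.list(par), function(p) if (length(p)) p[[1]] else NA_character_,
           character(1))

  genes <- df[df$type == "gene", , drop = FALSE]
  if (!nrow(genes)) return(empty_gene_annotation())
  genes_df <- data.frame(gene_id = genes$id, chrom = genes$chrom,
                         start = genes$start, end = genes$end,
                         strand = genes$strand, stringsAsFactors = FALSE)

  # map every feature up to its gene (through mRNA if needed)
  mrna <- df[df$type == "mRNA", , drop = FALSE]
  to_gene <- stats::setNames(genes$id, genes$id)
  if (nrow(mrna)) to_gene <- c(to_gene, stats::setNames(mrna$parent, mrna$id))

  pick <- function(types) {
    f <- df[df$type %in% types, , drop = FALSE]
    if (!nrow(f)) return(empty_feature_df())
    gene_id <- unname(to_gene[f$parent])
    if (anyNA(gene_id)) {
      stop("feature with unknown parent: ",
           paste(utils::head(f$id[is.na(gene_id)]), collapse = ", "))
    }
    out <- data.frame(gene_id = gene_id, chrom = f$chrom, start = f$start,
                      end = f$end, stringsAsFactors = FALSE)
    out[order(out$gene_id, out$start), , drop = FALSE]
  }
  exons <- pick("exon")
  cds <- pick("CDS")
  utr <- pick(c("five_prime_UTR", "three_prime_UTR"))

  # child features must lie within their gene's span
  for (feat in list(exons, cds, utr)) {
    if (!nrow(feat)) next
    gi <- match(feat$gene_id, genes_df$gene_id)
    bad <- feat$start < genes_df$start[gi] | feat$end > genes_df$end[gi]
    if (any(bad)) {
      stop("feature outside parent gene span: gene ",
           paste(unique(feat$gene_id[bad]), collapse = ", "))
    }
  }
  # exonless genes: whole span counts as one exon
  no_exon <- setdiff(genes_df$gene_id, exons$gene_id)
  if (length(no_exon)) {
    gi <- match(no_exon, genes_df$gene_id)
    exons <- rbind(exons, data.frame(
      gene_id = no_exon, chrom = genes_df$chrom[gi],
      start = genes_df$start[gi], end = genes_df$end[gi],
      stringsAsFactors = FALSE))
    exons <- exons[order(exons$gene_id, exons$start), , drop = FALSE]
  }
  rownames(exons) <- rownames(cds) <- rownames(utr) <- NULL
  ann <- list(genes = genes_df, exons = exons, cds = cds, utr = utr,
              introns = compute_introns(exons), chrom_lengths = NULL)
  class(ann) <- "gene_annotation"
  ann
}

#' Write a gene annotation as GFF3
#'
#' @param annotation a `gene_annotation`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_gff3 <- function(annotation, path) {
  g <- annotation$genes
  lines <- "##gff-version 3"
  fmt <- function(chrom, type, start, end, strand, attrs) {
    paste(chrom, "pavscape", type, as.integer(start), as.integer(end),
          ".", strand, ".", attrs, sep = "\t")
  }
  for (i in seq_len(nrow(g))) {
    id <- g$gene_id[i]
    mid <- paste0(id, ".t1")
    lines <- c(lines,
      fmt(g$chrom[i], "gene", g$start[i], g$end[i], g$strand[i],
          paste0("ID=", id)),
      fmt(g$chrom[i], "mRNA", g$start[i], g$end[i], g$strand[i],
          paste0("ID=", mid, ";Parent=", id)))
    for (feat in c("exons", "cds", "utr")) {
      f <- annotation[[feat]]
      f <- f[f$gene_id == id, , drop = FALSE]
      if (!nrow(f)) next
      type <- c(exons = "exon", cds = "CDS", utr = "UTR")[[feat]]
      if (feat == "utr") {
        # label UTRs by side relative to the CDS extent on + strand layout
        cdsf <- annotation$cds[annotation$cds$gene_id == id, , drop = FALSE]
        cmin <- if (nrow(cdsf)) min(cdsf$start) else Inf
        type <- ifelse(f$end < cmin, "five_prime_UTR", "three_prime_UTR")
      } else {
        type <- rep(type, nrow(f))
      }
      lines <- c(lines, fmt(f$chrom, type, f$start, f$end, g$strand[i],
                            paste0("ID=", mid, ".", feat, seq_len(nrow(f)),
                                   ";Parent=", mid)))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a phenotype table
#'
#' Reads a TSV whose first column is the sample id and remaining columns
#' are numeric trait values. Missing values are "NA" or empty cells.
#' Replicate columns named `trait.rep1`, `trait.rep2`, ... are averaged
#' over non-missing replicates into a single `trait` column.
#'
#' @param path TSV path.
#' @return data.frame with `sample_id` then one column per trait.
#' @export
read_phenotype_table <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""), check.names = FALSE)
  if (ncol(raw) < 2) stop("phenotype table needs sample ids plus traits")
  ids <- as.character(raw[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate sample id: ", ids[duplicated(ids)][1])
  }
  vals <- raw[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(num))
      if (length(bad)) {
        stop(sprintf("non-numeric value in column '%s', row %d",
                     names(vals)[j], bad[1]))
      }
      vals[[j]] <- num
    }
  }
  base <- sub("\\.rep[0-9]+$", "", names(vals))
  out <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  for (tr in unique(base)) {
    cols <- which(base == tr)
    m <- as.matrix(vals[, cols, drop = FALSE])
    avg <- rowMeans(m, na.rm = TRUE)
    avg[!is.finite(avg)] <- NA_real_
    out[[tr]] <- avg
  }
  out
}

#' Write a phenotype table as TSV
#'
#' @param phenotypes data.frame with sample_id plus trait columns.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_phenotype_table <- function(phenotypes, path) {
  utils::write.table(phenotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
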