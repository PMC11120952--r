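# Structural-variant VCF reading/writing in the SVTYPE/END/SVLEN dialect.
# Only <DEL>/<INS> symbolic records are supported; genotypes collapse to
# presence/absence (inbred material, biallelic loci by construction).

#' Read a structural-variant VCF into a PAV callset
#'
#' Parses a VCF 4.2 file whose records carry INFO `SVTYPE`, `END` and
#' `SVLEN` and a per-sample `GT` field. Only DEL and INS records are kept
#' (other SVTYPEs are skipped and counted); `GT` 0/0 maps to absent, any
#' alt-bearing call to present, ./. to missing. Multi-allelic rows and
#' rows without SVTYPE are rejected.
#'
#' @param path VCF file path.
#' @param caller caller label attached to every record (defaults to the
#'   file name without extension).
#' @param expected_samples optional character vector; if given, the file's
#'   sample columns must match it exactly.
#' @return a `pav_callset` (records data.frame + records x samples
#'   genotype matrix); the number of skipped non-DEL/INS rows is in
#'   `attr(, "n_skipped")`.
#' @export
read_sv_vcf <- function(path, caller = NULL, expected_samples = NULL) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  caller <- caller %||% sub("\\.vcf(\\.gz)?$", "", basename(path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v, getINFO = TRUE),
                       stringsAsFactors = FALSE)
  n <- nrow(fix)
  if (is.null(n) || n == 0L) {
    cs <- structure(list(records = empty_record_df(), caller = caller,
                         genotypes = matrix(integer(0), 0, 0)),
                    class = "pav_callset")
    attr(cs, "n_skipped") <- 0L
    return(cs)
  }
  info <- fix$INFO
  svtype <- extract_info_field(info, "SVTYPE")
  if (anyNA(svtype)) {
    warning(sum(is.na(svtype)), " record(s) without SVTYPE rejected")
  }
  if (any(grepl(",", fix$ALT, fixed = TRUE))) {
    stop("multi-allelic SV rows are not supported")
  }
  keep <- !is.na(svtype) & svtype %in% c("DEL", "INS")
  n_skipped <- sum(!is.na(svtype) & !svtype %in% c("DEL", "INS"))

  pos <- as.numeric(fix$POS)
  end_info <- suppressWarnings(as.numeric(extract_info_field(info, "END")))
  svlen <- suppressWarnings(as.numeric(extract_info_field(info, "SVLEN")))
  end <- ifelse(svtype == "DEL", end_info, pos)
  # fall back: DEL end from POS + |SVLEN| or SVLEN from END - POS
  end[svtype == "DEL" & is.na(end)] <-
    (pos + abs(svlen))[svtype == "DEL" & is.na(end)]
  svlen[is.na(svlen) & svtype == "DEL"] <-
    -(end - pos)[is.na(svlen) & svtype == "DEL"]

  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt) %||% character(0)
  if (!is.null(expected_samples) && !identical(samples, expected_samples)) {
    stop("VCF sample columns do not match expected_samples")
  }
  gmat <- gt_to_presence(gt)

  records <- data.frame(
    record_id = sprintf("%s_r%05d", caller, seq_len(n)),
    chrom = fix$CHROM, start = pos, end = end,
    svtype = svtype, svlen = svlen,
    filter = fix$FILTER, caller = caller,
    stringsAsFactors = FALSE
  )
  records <- records[keep, , drop = FALSE]
  gmat <- gmat[keep, , drop = FALSE]
  rownames(gmat) <- records$record_id
  bad <- invalid_record_mask(records)
  if (any(bad)) {
    warning(sum(bad), " record(s) violating PAV invariants rejected")
    records <- records[!bad, , drop = FALSE]
    gmat <- gmat[!bad, , drop = FALSE]
  }
  rownames(records) <- NULL
  cs <- structure(list(records = records, genotypes = gmat, caller = caller),
                  class = "pav_callset")
  attr(cs, "n_skipped") <- n_skipped
  cs
}

empty_record_df <- function() {
  data.frame(record_id = character(0), chrom = character(0),
             start = numeric(0), end = numeric(0), svtype = character(0),
             svlen = numeric(0), filter = character(0), caller = character(0),
             stringsAsFactors = FALSE)
}

extract_info_field <- function(info, key) {
  out <- rep(NA_character_, length(info))
  hit <- grepl(paste0("(^|;)", key, "="), info)
  out[hit] <- sub(paste0(".*(^|;)", key, "=([^;]*).*"), "\\2", info[hit])
  out
}

# GT string -> 1 (any alt allele), 0 (all ref), NA (missing/malformed)
gt_to_presence <- function(gt) {
  if (is.null(gt)) return(matrix(integer(0), 0, 0))
  core <- sub(":.*$", "", gt)
  res <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  ok <- grepl("^[0-9.]([/|][0-9.])*$", core)
  has_alt <- grepl("[1-9]", core)
  has_ref <- grepl("0", core, fixed = TRUE)
  res[ok & has_alt] <- 1L
  res[ok & !has_alt & has_ref] <- 0L
  res
}

invalid_record_mask <- function(records) {
  with(records,
       (svtype == "DEL" & (end <= start | abs(svlen) != end - start)) |
       (svtype == "INS" & (end != start | svlen <= 0)) |
       abs(svlen) < 50)
}

#' Write a PAV callset as a structural-variant VCF
#'
#' Emits a minimal, deterministic VCF 4.2 with INFO SVTYPE/END/SVLEN and
#' FORMAT GT declared in the header, records sorted by (chromosome,
#' position, end).
#'
#' @param callset a `pav_callset` (records + genotype matrix).
#' @param path output path.
#' @param contig_lengths optional named vector of chromosome lengths to
#'   declare as ##contig header lines.
#' @return the path, invisibly.
#' @export
write_sv_vcf <- function(callset, path, contig_lengths = NULL) {
  records <- callset$records
  gmat <- callset$genotypes
  samples <- colnames(gmat)
  if (anyDuplicated(samples)) stop("duplicate sample ids")
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=pavscape",
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="Type of structural variant">',
    '##INFO=<ID=END,Number=1,Type=Integer,Description="End position of the variant">',
    '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="Signed length of the variant">',
    '##FILTER=<ID=LowQual,Description="Low quality call">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'
  )
  if (!is.null(contig_lengths)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contig_lengths),
                          as.integer(contig_lengths)))
  }
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (length(samples)) cols <- c(cols, "FORMAT", samples)
  lines <- c(hdr, paste(cols, collapse = "\t"))
  if (nrow(records)) {
    ord <- order(records$chrom, records$start, records$end)
    records <- records[ord, , drop = FALSE]
    gmat <- gmat[ord, , drop = FALSE]
    info <- sprintf("SVTYPE=%s;END=%d;SVLEN=%d", records$svtype,
                    as.integer(records$end), as.integer(records$svlen))
    body <- paste(records$chrom, as.integer(records$start),
                  records$record_id, "N",
                  paste0("<", records$svtype, ">"), ".",
                  records$filter, info, sep = "\t")
    if (length(samples)) {
      gts <- matrix(c("0/0", "1/1")[gmat + 1L], nrow(gmat), ncol(gmat))
      gts[is.na(gmat)] <- "./."
      body <- paste(body, "GT",
                    apply(gts, 1, paste, collapse = "\t"), sep = "\t")
    }
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write genomic regions as BED
#'
#' Converts 1-based inclusive regions to 0-based half-open BED lines.
#'
#' @param regions data.frame with chrom, start, end (1-based inclusive)
#'   and optionally a name column.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_bed <- function(regions, path) {
  name <- regions$name %||% regions$locus_id %||% "."
  lines <- paste(regions$chrom, as.integer(regions$start) - 1L,
                 as.integer(regions$end), name, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
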