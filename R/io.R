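#' Read bulk allele depths
#'
#' Two formats are supported. The native TSV has columns `chrom`, `pos`,
#' `ref`, `alt`, `M_tall`, `P_tall`, `M_dwarf`, `P_dwarf` (header row
#' required; `.` or empty depth cells become missing). VCF input takes the
#' per-sample AD field of the two bulk samples; which parent matches the
#' REF allele is declared with `maternal` since the maternal/paternal
#' orientation depends on which parent matches the reference assembly.
#' Records are returned in genome order; unsorted input is sorted with a
#' warning, and malformed rows are dropped with a warning naming their
#' count.
#'
#' @param path input file.
#' @param format "tsv" or "vcf".
#' @param samples named character vector for VCF mode: `c(tall = ...,
#'   dwarf = ...)` giving the bulk sample names.
#' @param maternal "ref" (default) or "alt": which VCF allele is the
#'   maternal (recurrent-parent) allele.
#' @return SNP record data.frame with a logical `missing` column (TRUE
#'   where either bulk has zero total depth).
#' @export
read_allele_depths <- function(path, format = c("tsv", "vcf"),
                               samples = c(tall = "tall", dwarf = "dwarf"),
                               maternal = c("ref", "alt")) {
  format <- match.arg(format)
  maternal <- match.arg(maternal)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "tsv") {
    raw <- utils::read.delim(path, colClasses = "character",
                             check.names = FALSE)
    need <- c("chrom", "pos", "ref", "alt",
              "M_tall", "P_tall", "M_dwarf", "P_dwarf")
    if (!all(need %in% names(raw))) {
      stop("allele-depth TSV must have columns: ", paste(need, collapse = ", "))
    }
    num <- function(x) suppressWarnings(as.numeric(ifelse(x %in% c(".", ""), NA, x)))
    rec <- data.frame(chrom = raw$chrom, pos = num(raw$pos),
                      ref = raw$ref, alt = raw$alt,
                      M_tall = num(raw$M_tall), P_tall = num(raw$P_tall),
                      M_dwarf = num(raw$M_dwarf), P_dwarf = num(raw$P_dwarf))
    bad <- is.na(rec$pos)
    if (any(bad)) {
      warning(sum(bad), " malformed row(s) dropped")
      rec <- rec[!bad, , drop = FALSE]
    }
  } else {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    ad <- vcfR::extract.gt(v, element = "AD")
    miss_sample <- setdiff(unname(samples), colnames(ad))
    if (length(miss_sample)) {
      stop("bulk sample(s) absent from VCF: ", paste(miss_sample, collapse = ", "))
    }
    split_ad <- function(x) {
      parts <- strsplit(ifelse(is.na(x) | x == ".", "NA,NA", x), ",")
      ref <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1L)))
      alt <- suppressWarnings(as.numeric(vapply(parts, function(p) {
        if (length(p) >= 2L) p[2L] else NA_character_
      }, "")))
      cbind(ref = ref, alt = alt)
    }
    t_ad <- split_ad(ad[, samples[["tall"]]])
    d_ad <- split_ad(ad[, samples[["dwarf"]]])
    m_col <- if (maternal == "ref") "ref" else "alt"
    p_col <- if (maternal == "ref") "alt" else "ref"
    rec <- data.frame(chrom = vcfR::getCHROM(v), pos = vcfR::getPOS(v),
                      ref = vcfR::getREF(v), alt = vcfR::getALT(v),
                      M_tall = t_ad[, m_col], P_tall = t_ad[, p_col],
                      M_dwarf = d_ad[, m_col], P_dwarf = d_ad[, p_col])
  }
  # NA depth pairs mean no reads observed for that bulk
  for (cc in c("M_tall", "P_tall", "M_dwarf", "P_dwarf")) {
    rec[[cc]][is.na(rec[[cc]])] <- 0
  }
  rec$missing <- (rec$M_tall + rec$P_tall == 0) |
    (rec$M_dwarf + rec$P_dwarf == 0)
  ord <- order(match(rec$chrom, unique(rec$chrom)), rec$pos)
  if (!identical(ord, seq_len(nrow(rec)))) {
    warning("input not in genome order; sorting")
    rec <- rec[ord, , drop = FALSE]
    rownames(rec) <- NULL
  }
  rec
}

#' Write the native allele-depth TSV
#'
#' @param records SNP record data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_allele_depths <- function(records, path) {
  cols <- c("chrom", "pos", "ref", "alt",
            "M_tall", "P_tall", "M_dwarf", "P_dwarf")
  utils::write.table(records[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a minimal two-sample VCF with AD fields
#'
#' Emits one record per SNP with the maternal allele as REF, GT omitted
#' and per-bulk AD = "M,P". Sufficient for round-tripping through
#' [read_allele_depths()] and for external tools expecting allele depths.
#'
#' @param records SNP record data.frame.
#' @param path output file (.vcf, uncompressed).
#' @param samples names of the two bulk sample columns.
#' @return `path`, invisibly.
#' @export
write_allele_vcf <- function(records, path,
                             samples = c(tall = "tall", dwarf = "dwarf")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=bsarna",
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples[["tall"]], samples[["dwarf"]]), collapse = "\t"))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tAD\t%d,%d\t%d,%d",
                  records$chrom, as.integer(records$pos),
                  records$ref, records$alt,
                  as.integer(records$M_tall), as.integer(records$P_tall),
                  as.integer(records$M_dwarf), as.integer(records$P_dwarf))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write and read candidate intervals as BED
#'
#' Internal coordinates are 1-based inclusive; BED is written 0-based
#' half-open per the standard and converted back on reading.
#'
#' @param intervals data.frame `chrom`, `start`, `end` (1-based inclusive).
#' @param path BED file path.
#' @return `path` (writer) / intervals data.frame (reader).
#' @export
write_intervals_bed <- function(intervals, path) {
  bed <- data.frame(chrom = intervals$chrom,
                    start = as.integer(intervals$start) - 1L,
                    end = as.integer(intervals$end),
                    name = sprintf("interval_%d", seq_len(nrow(intervals))))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_intervals_bed
#' @export
read_intervals_bed <- function(path) {
  bed <- utils::read.delim(path, header = FALSE)
  data.frame(chrom = bed[[1L]], start = bed[[2L]] + 1L, end = bed[[3L]])
}

#' Read gene models from BED or GFF3
#'
#' Parsed with `rtracklayer::import`; GFF3 input keeps rows of type
#' "gene". Gene length is the genomic span (end - start + 1), the length
#' used for FPKM when no transcript model is available.
#'
#' @param path .bed/.gff3/.gff file.
#' @return data.frame `gene_id`, `chrom`, `start`, `end`, `length`.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path)
  if (!is.null(gr$type)) gr <- gr[gr$type == "gene"]
  id <- if (!is.null(gr$ID)) gr$ID else gr$name
  data.frame(gene_id = as.character(id),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             length = GenomicRanges::width(gr))
}

#' Write gene models as BED
#'
#' @param genes data.frame `gene_id`, `chrom`, `start`, `end`.
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_gene_bed <- function(genes, path) {
  bed <- data.frame(chrom = genes$chrom,
                    start = as.integer(genes$start) - 1L,
                    end = as.integer(genes$end),
                    name = genes$gene_id)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write and read the count matrix TSV
#'
#' Genes in rows with a `gene_id` and `length` column, one column per
#' sample (header row = sample names).
#'
#' @param counts genes x samples integer matrix with rownames.
#' @param gene_length per-gene lengths.
#' @param path TSV path.
#' @return `path` (writer); list `counts`, `gene_length` (reader).
#' @export
write_count_matrix <- function(counts, gene_length, path) {
  df <- data.frame(gene_id = rownames(counts), length = gene_length,
                   counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  counts <- as.matrix(df[, setdiff(names(df), c("gene_id", "length"))])
  rownames(counts) <- df$gene_id
  list(counts = counts,
       gene_length = stats::setNames(df$length, df$gene_id))
}

#' Read a qPCR Ct table
#'
#' CSV with columns `gene`, `group`, `replicate`, `ct_target`,
#' `ct_reference`.
#'
#' @param path CSV path.
#' @return data.frame as stored.
#' @export
read_qpcr_csv <- function(path) {
  ct <- utils::read.csv(path)
  need <- c("gene", "group", "replicate", "ct_target", "ct_reference")
  if (!all(need %in% names(ct))) {
    stop("qPCR CSV must have columns: ", paste(need, collapse = ", "))
  }
  ct
}

#' Read hormone assay CSVs
#'
#' `read_hormone_standards`: columns `compound`, `concentration`,
#' `response`. `read_hormone_samples`: columns `compound`, `class`,
#' `group`, `replicate`, `peak_area`.
#'
#' @param path CSV path.
#' @return data.frame as stored.
#' @export
read_hormone_standards <- function(path) {
  x <- utils::read.csv(path)
  need <- c("compound", "concentration", "response")
  if (!all(need %in% names(x))) {
    stop("standards CSV must have columns: ", paste(need, collapse = ", "))
  }
  x
}

#' @rdname read_hormone_standards
#' @export
read_hormone_samples <- function(path) {
  x <- utils::read.csv(path)
  need <- c("compound", "class", "group", "replicate", "peak_area")
  if (!all(need %in% names(x))) {
    stop("samples CSV must have columns: ", paste(need, collapse = ", "))
  }
  x
}
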