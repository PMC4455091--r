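## Readers and writers for the standard formats the pipeline consumes:
## chromosome-size tables, bedGraph coverage, BED reads, narrowPeak calls
## and TSS annotation.  Parsing of BED-family formats goes through
## rtracklayer; these wrappers only fix column conventions.

#' Read a two-column chromosome-size table
#'
#' @param path TSV with columns chromosome name and length (no header).
#' @return Named integer vector of sequence lengths.
#' @export
read_genome_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", col.names = c("chrom", "length"),
                          stringsAsFactors = FALSE)
  stats::setNames(as.integer(df$length), df$chrom)
}

#' @rdname read_genome_sizes
#' @param seqlengths Named vector of chromosome lengths.
#' @export
write_genome_sizes <- function(seqlengths, path) {
  utils::write.table(data.frame(names(seqlengths),
                                as.integer(seqlengths)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read coverage intervals (bedGraph) or reads (BED)
#'
#' bedGraph records come back with their \code{score} (used as interval
#' weight by [bin_coverage()]); BED reads carry weight 1 each.
#'
#' @param path File path; format inferred from the extension
#'   (\code{.bedgraph}/\code{.bg} vs \code{.bed}).
#' @return A \code{GRanges}.
#' @export
read_coverage <- function(path) {
  fmt <- if (grepl("\\.(bedgraph|bg)$", path, ignore.case = TRUE))
    "bedGraph" else "BED"
  rtracklayer::import(path, format = fmt)
}

#' Write reads as BED
#'
#' @param reads A \code{GRanges}.
#' @param path Output path.
#' @export
write_reads_bed <- function(reads, path) {
  rtracklayer::export(reads, path, format = "BED")
  invisible(path)
}

#' Write a coverage vector as bedGraph
#'
#' Emits one record per run of equal coverage, computed from the reads.
#'
#' @param reads A \code{GRanges} of reads.
#' @param seqlengths Named chromosome lengths.
#' @param path Output path.
#' @export
write_coverage_bedgraph <- function(reads, seqlengths, path) {
  gr <- GenomicRanges::GRanges(GenomicRanges::seqnames(reads),
                               IRanges::ranges(reads))
  GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
  GenomeInfoDb::seqlengths(gr) <- seqlengths
  cov <- GenomicRanges::coverage(gr)
  covgr <- GenomicRanges::GRanges(cov)
  covgr <- covgr[covgr$score > 0]
  rtracklayer::export(covgr, path, format = "bedGraph")
  invisible(path)
}

#' Read narrowPeak peak calls
#'
#' Ten-column ENCODE narrowPeak.  The returned peak table uses the
#' conventions of this package: absolute \code{summit} (start + offset,
#' 1-based position), linear \code{p_value} (from the -log10 column) and
#' \code{read_count} taken from the score column (NA when 0).
#'
#' @param path narrowPeak file.
#' @return A peak data.frame (see [peak_table()]).
#' @export
read_narrowpeak <- function(path) {
  extra <- c(signalValue = "numeric", pValue = "numeric",
             qValue = "numeric", peak = "integer")
  gr <- rtracklayer::import(path, format = "BED", extraCols = extra)
  peak_table(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             summit = GenomicRanges::start(gr) - 1L + gr$peak,
             p_value = 10^(-gr$pValue),
             read_count = ifelse(gr$score > 0, gr$score, NA_real_),
             name = gr$name)
}

#' Construct a peak table
#'
#' Internal coordinates are 0-based half-open \code{[start, end)};
#' \code{summit} is an absolute 0-based position with
#' \code{start <= summit < end}.
#'
#' @param chrom,start,end,summit,p_value,read_count,name Parallel vectors.
#' @return A data.frame of peaks.
#' @export
peak_table <- function(chrom, start, end, summit, p_value = NA_real_,
                       read_count = NA_real_, name = NULL) {
  if (any(start > summit | summit >= end))
    stop("summit must lie within [start, end)")
  if (any(!is.na(p_value) & p_value <= 0))
    stop("p_value must be > 0")
  if (is.null(name)) name <- paste0("peak_", seq_along(chrom))
  data.frame(chrom = as.character(chrom), start = as.integer(start),
             end = as.integer(end), summit = as.integer(summit),
             p_value = as.numeric(p_value),
             read_count = as.numeric(read_count),
             name = name, stringsAsFactors = FALSE)
}

#' Write peaks as narrowPeak
#'
#' @param peaks Peak data.frame from [peak_table()].
#' @param path Output path.
#' @export
write_narrowpeak <- function(peaks, path) {
  df <- data.frame(peaks$chrom, peaks$start, peaks$end, peaks$name,
                   ifelse(is.na(peaks$read_count), 0,
                          round(peaks$read_count)),
                   ".", 0,
                   ifelse(is.na(peaks$p_value), -1,
                          round(-log10(peaks$p_value), 5)),
                   -1, peaks$summit - peaks$start)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a TSS annotation table
#'
#' Either BED6 (TSS taken as the strand-aware 5' end of each interval) or a
#' TSV with header \code{gene_id, chrom, tss, strand} where \code{tss} is a
#' position.  TSV positions are 1-based by default; pass
#' \code{one_based = FALSE} for 0-based tables.
#'
#' @param path File path.
#' @param one_based Whether TSV positions are 1-based (default TRUE).
#' @return A data.frame \code{gene_id, chrom, tss, strand} with 1-based
#'   \code{tss} positions.
#' @export
read_tss <- function(path, one_based = TRUE) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path, format = "BED")
    neg <- as.character(GenomicRanges::strand(gr)) == "-"
    tss <- ifelse(neg, GenomicRanges::end(gr), GenomicRanges::start(gr))
    nm <- if (!is.null(gr$name)) gr$name else paste0("gene_", seq_along(gr))
    data.frame(gene_id = nm,
               chrom = as.character(GenomicRanges::seqnames(gr)),
               tss = as.integer(tss),
               strand = as.character(GenomicRanges::strand(gr)),
               stringsAsFactors = FALSE)
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    stopifnot(all(c("gene_id", "chrom", "tss", "strand") %in% names(df)))
    if (!one_based) df$tss <- df$tss + 1L
    df
  }
}

#' Write a TSS table as BED6
#'
#' @param tss TSS data.frame (1-based positions).
#' @param path Output path.
#' @export
write_tss_bed <- function(tss, path) {
  df <- data.frame(tss$chrom, tss$tss - 1L, tss$tss, tss$gene_id, 0,
                   tss$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## GRanges of single TSS positions (width 1).
tss_granges <- function(tss) {
  GenomicRanges::GRanges(tss$chrom,
                         IRanges::IRanges(tss$tss, width = 1),
                         gene_id = tss$gene_id)
}

## GRanges of peak summits (width 1, 1-based position = summit + 1).
summit_granges <- function(peaks) {
  GenomicRanges::GRanges(peaks$chrom,
                         IRanges::IRanges(peaks$summit + 1L, width = 1))
}
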