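## Peak post-filters and summit-overlap analyses: p-value/read-count
## retention rules, pairwise summit proximity and the multiway
## membership-pattern (Venn) counts.

#' Filter peaks on p-value and read count
#'
#' Retains peaks with \code{p_value <= p_max} and, when \code{min_reads >
#' 0}, \code{read_count >= min_reads}; input order is preserved.  Typical
#' settings: \code{p_max = 1e-10} for most factors, \code{2e-10} for the
#' weaker antibodies, and \code{min_reads = 100} for low-coverage factor
#' ChIPs whose marginal peaks are unreliable.
#'
#' @param peaks Peak table (see [peak_table()]).
#' @param p_max Maximum MACS p-value (default 1e-10).
#' @param min_reads Minimum aligned reads in the peak (default 0).
#' @return The filtered peak table.
#' @export
filter_peaks <- function(peaks, p_max = 1e-10, min_reads = 0) {
  stopifnot(p_max > 0, p_max < 1, min_reads >= 0)
  if (min_reads > 0 && any(is.na(peaks$read_count)))
    stop("min_reads > 0 but read_count is missing for some peaks")
  keep <- peaks$p_value <= p_max
  if (min_reads > 0) keep <- keep & peaks$read_count >= min_reads
  out <- peaks[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pairs of peaks with nearby summits
#'
#' Two peaks overlap when their summits lie on the same chromosome within
#' \code{max_dist} bp of each other (inclusive).
#'
#' @param a,b Peak tables.
#' @param max_dist Maximum summit distance in bp (default 125).
#' @return A data.frame of index pairs \code{(i, j)} into \code{a} and
#'   \code{b} with the summit \code{distance}.
#' @export
summit_overlap <- function(a, b, max_dist = 125) {
  if (nrow(a) == 0 || nrow(b) == 0)
    return(data.frame(i = integer(), j = integer(), distance = integer()))
  a_gr <- summit_granges(a)
  b_win <- GenomicRanges::GRanges(
    b$chrom, IRanges::IRanges(pmax(1L, b$summit + 1L - max_dist),
                              b$summit + 1L + max_dist))
  ## findOverlaps warns when the sets share no chromosome; that simply
  ## means there are no pairs
  hits <- suppressWarnings(GenomicRanges::findOverlaps(a_gr, b_win))
  i <- S4Vectors::queryHits(hits)
  j <- S4Vectors::subjectHits(hits)
  data.frame(i = i, j = j, distance = abs(a$summit[i] - b$summit[j]))
}

#' Multiway summit-overlap (Venn) pattern counts
#'
#' Summits from all sets are pooled and clustered by single linkage: a
#' cluster extends while consecutive summits (per chromosome) are within
#' \code{max_dist} bp.  Each cluster contributes one count to the pattern
#' given by the sets present in it, so pattern counts sum to the number of
#' clusters.  Pairwise proximity is not transitive, hence chains of peaks
#' each within \code{max_dist} of the next merge into one cluster; this
#' convention is deliberate and documented.
#'
#' @param sets Named list of 2--4 peak tables.
#' @param max_dist Maximum summit distance within a cluster link
#'   (default 125).
#' @return A data.frame with one row per observed membership pattern
#'   (\code{pattern}, set names joined by \code{"+"}) and its \code{count}.
#' @export
multiway_overlap <- function(sets, max_dist = 125) {
  if (length(sets) < 2 || length(sets) > 4)
    stop("between 2 and 4 peak sets are supported")
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("sets must be named")
  pooled <- do.call(rbind, lapply(names(sets), function(nm) {
    p <- sets[[nm]]
    if (nrow(p) == 0) return(NULL)
    data.frame(set = nm, chrom = p$chrom, summit = p$summit,
               stringsAsFactors = FALSE)
  }))
  if (is.null(pooled) || nrow(pooled) == 0)
    return(data.frame(pattern = character(), count = integer()))
  pooled <- pooled[order(pooled$chrom, pooled$summit), , drop = FALSE]
  new_cluster <- c(TRUE, pooled$chrom[-1] != pooled$chrom[-nrow(pooled)] |
                     diff(pooled$summit) > max_dist)
  pooled$cluster <- cumsum(new_cluster)
  pat <- vapply(split(pooled$set, pooled$cluster), function(s)
    paste(names(sets)[names(sets) %in% s], collapse = "+"), character(1))
  tab <- table(pat)
  out <- data.frame(pattern = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(out$pattern), , drop = FALSE]
  rownames(out) <- NULL
  out
}
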