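## Promoter and enhancer region assignment from peak calls and TSS
## annotation, H3K27ac-based ranking, read-overlap fractions and the
## summit-centred occupancy heatmap matrices.

#' Construct a region set
#'
#' Regions are summit-centred windows: \code{center} is a 0-based position
#' (the defining peak summit) and \code{flank} the half-width in bp, so a
#' region covers \code{[center - flank, center + flank]}.
#'
#' @param chrom,center Parallel vectors (0-based summit positions).
#' @param flank Half-width in bp (scalar).
#' @param kind \code{"promoter"} or \code{"enhancer"}.
#' @return A data.frame with attribute \code{kind}; a "region set".
#' @export
region_set <- function(chrom, center, flank, kind) {
  out <- data.frame(chrom = as.character(chrom), center = as.integer(center),
                    flank = as.integer(rep(flank, length(chrom))),
                    stringsAsFactors = FALSE)
  attr(out, "kind") <- match.arg(kind, c("promoter", "enhancer"))
  out
}

region_kind <- function(regions) attr(regions, "kind")

## GRanges of region windows [center - flank, center + flank] (1-based).
region_granges <- function(regions, flank = NULL) {
  if (is.null(flank)) flank <- regions$flank
  GenomicRanges::GRanges(
    regions$chrom,
    IRanges::IRanges(pmax(1L, regions$center + 1L - flank),
                     regions$center + 1L + flank))
}

## Distance from each 0-based position to the nearest TSS (Inf if none on
## the chromosome).
nearest_tss_distance <- function(chrom, pos0, tss) {
  vapply(seq_along(pos0), function(i) {
    cand <- tss$tss[tss$chrom == chrom[i]] - 1L   # 0-based
    if (!length(cand)) return(Inf)
    min(abs(cand - pos0[i]))
  }, numeric(1))
}

#' Promoter regions for heatmaps: H3K4me3 summits near a TSS
#'
#' A promoter region is called for every H3K4me3 peak summit within
#' \code{window} bp (inclusive) of the nearest transcription start site.
#'
#' @param me3_peaks H3K4me3 peak table (see [peak_table()]).
#' @param tss TSS annotation data.frame (see [read_tss()]).
#' @param window Maximum summit-to-TSS distance in bp (default 1000).
#' @param flank Displayed half-width of the region (default 4100 bp).
#' @return A promoter [region_set()] centred on the qualifying summits.
#' @export
call_promoters_heatmap <- function(me3_peaks, tss, window = 1000,
                                   flank = 4100) {
  if (nrow(tss) == 0) stop("TSS table is empty")
  d <- nearest_tss_distance(me3_peaks$chrom, me3_peaks$summit, tss)
  keep <- d <= window
  region_set(me3_peaks$chrom[keep], me3_peaks$summit[keep], flank,
             "promoter")
}

#' Enhancer regions for heatmaps: H3K4me1 summits without H3K4me3 signal
#'
#' A candidate enhancer (H3K4me1 peak summit) is kept when no H3K4me3
#' signal lies within \code{exclusion_flank} bp of the summit.  "Signal"
#' is, by default, any called H3K4me3 peak overlapping the window; with a
#' binned H3K4me3 track as evidence it is any overlapping bin whose value
#' exceeds \code{max_rpm}.
#'
#' @param me1_peaks H3K4me1 peak table.
#' @param me3_evidence Either an H3K4me3 peak table or a [BinnedTrack()].
#' @param exclusion_flank Half-width of the exclusion window (default 4100).
#' @param max_rpm RPM cutoff used in track mode (default 0).
#' @param flank Displayed half-width of the region (default 4100 bp).
#' @return An enhancer [region_set()].
#' @export
call_enhancers_heatmap <- function(me1_peaks, me3_evidence,
                                   exclusion_flank = 4100, max_rpm = 0,
                                   flank = 4100) {
  win <- GenomicRanges::GRanges(
    me1_peaks$chrom,
    IRanges::IRanges(pmax(1L, me1_peaks$summit + 1L - exclusion_flank),
                     me1_peaks$summit + 1L + exclusion_flank))
  if (inherits(me3_evidence, "BinnedTrack")) {
    hot <- which(me3_evidence$values > max_rpm)
    coords <- bin_coordinates(me3_evidence, hot)
    w <- me3_evidence$bin_width
    hot_gr <- GenomicRanges::GRanges(
      coords$chrom, IRanges::IRanges(coords$bin * w + 1L, (coords$bin + 1) * w))
    excluded <- IRanges::overlapsAny(win, hot_gr)
  } else {
    me3_gr <- GenomicRanges::GRanges(
      me3_evidence$chrom,
      IRanges::IRanges(me3_evidence$start + 1L, me3_evidence$end))
    excluded <- IRanges::overlapsAny(win, me3_gr)
  }
  region_set(me1_peaks$chrom[!excluded], me1_peaks$summit[!excluded],
             flank, "enhancer")
}

#' Promoter/enhancer regions from RNA-polymerase-II and P300 peaks
#'
#' The read-overlap definition: promoters are \code{+-flank} windows around
#' summits of significant RNA-Pol-II (Polr2a) peaks within \code{window} bp
#' of a TSS; enhancers are \code{+-flank} windows around P300 summits
#' farther than \code{window} bp from every TSS.
#'
#' @param polr2a_peaks,p300_peaks Peak tables.
#' @param tss TSS annotation.
#' @param window Summit-to-TSS distance cutoff (default 1000 bp).
#' @param flank Region half-width (default 1000 bp).
#' @return A list with elements \code{promoters} and \code{enhancers}.
#' @export
call_regions_polr2a_p300 <- function(polr2a_peaks, p300_peaks, tss,
                                     window = 1000, flank = 1000) {
  d_pol <- nearest_tss_distance(polr2a_peaks$chrom, polr2a_peaks$summit, tss)
  d_p300 <- nearest_tss_distance(p300_peaks$chrom, p300_peaks$summit, tss)
  list(promoters = region_set(polr2a_peaks$chrom[d_pol <= window],
                              polr2a_peaks$summit[d_pol <= window],
                              flank, "promoter"),
       enhancers = region_set(p300_peaks$chrom[d_p300 > window],
                              p300_peaks$summit[d_p300 > window],
                              flank, "enhancer"))
}

#' Fraction of reads overlapping promoter and enhancer regions
#'
#' A read counts as overlapping a region kind if it overlaps any region of
#' that kind by at least one bp; a read overlapping both kinds is counted
#' once per kind, so the two fractions need not sum to at most 1.
#'
#' @param reads A \code{GRanges} of reads.
#' @param promoters,enhancers [region_set()]s.
#' @return A data.frame with per-category read counts and fractions
#'   (promoter, enhancer, neither).
#' @export
read_overlap_fraction <- function(reads, promoters, enhancers) {
  in_prom <- if (nrow(promoters)) IRanges::overlapsAny(
    reads, region_granges(promoters)) else rep(FALSE, length(reads))
  in_enh <- if (nrow(enhancers)) IRanges::overlapsAny(
    reads, region_granges(enhancers)) else rep(FALSE, length(reads))
  n <- length(reads)
  data.frame(category = c("promoter", "enhancer", "neither"),
             n_reads = c(sum(in_prom), sum(in_enh), sum(!in_prom & !in_enh)),
             fraction = if (n > 0)
               c(sum(in_prom), sum(in_enh), sum(!in_prom & !in_enh)) / n
             else rep(NA_real_, 3),
             stringsAsFactors = FALSE)
}

#' Rank regions by H3K27ac read content in a central window
#'
#' Promoters are ranked by H3K27ac reads in their central 2 kb, enhancers
#' by reads in their central 8.2 kb (broad enhancers contribute fully).
#' The sort is stable and descending, ties keeping genome-coordinate order.
#'
#' @param regions A [region_set()].
#' @param k27_reads \code{GRanges} of H3K27ac reads.
#' @param central_window Central window width in bp; defaults to 2000 for
#'   promoters and 8200 for enhancers.
#' @return The region set sorted by \code{ranking_score} (added column).
#' @export
rank_by_k27ac <- function(regions, k27_reads, central_window = NULL) {
  if (is.null(central_window))
    central_window <- if (region_kind(regions) == "promoter") 2000 else 8200
  half <- central_window / 2
  ## central window [center - w/2, center + w/2) in 0-based coords
  win <- GenomicRanges::GRanges(
    regions$chrom,
    IRanges::IRanges(pmax(1L, as.integer(regions$center + 1 - half)),
                     as.integer(regions$center + half)))
  score <- GenomicRanges::countOverlaps(win, k27_reads)
  regions$ranking_score <- score
  ord <- order(-score, match(regions$chrom, unique(regions$chrom)),
               regions$center)
  out <- regions[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "kind") <- region_kind(regions)
  out
}

#' Build a summit-centred occupancy heatmap matrix
#'
#' One row per region (in ranked order), 51 columns of 160 bp spanning
#' 8,160 bp centred on the summit; cell values are reads overlapping the
#' column's window, normalised to reads-per-million using the track's total
#' read count over all displayed regions (promoters and enhancers
#' together, when both are supplied).
#'
#' @param reads \code{GRanges} of the track's reads.
#' @param regions A ranked [region_set()].
#' @param n_bins Number of columns (default 51).
#' @param bin_bp Column width in bp (default 160).
#' @param norm_regions List of region sets defining the normalisation
#'   universe; defaults to \code{list(regions)}.  Pass both the promoter
#'   and enhancer sets to share one constant across the two heatmaps.
#' @param normalize Set \code{FALSE} for raw per-bin read counts.
#' @return A numeric matrix (regions x bins) with attributes
#'   \code{normalization_constant} and \code{regions}.
#' @export
build_heatmap <- function(reads, regions, n_bins = 51, bin_bp = 160,
                          norm_regions = list(regions), normalize = TRUE) {
  if (n_bins < 1 || bin_bp < 1)
    stop("n_bins and bin_bp must be positive")
  span <- n_bins * bin_bp
  half <- span / 2
  if (half != as.integer(half) && n_bins %% 2 == 0)
    stop("n_bins x bin_bp must allow a summit-centred span")
  nr <- nrow(regions)
  m <- matrix(0, nrow = nr, ncol = n_bins)
  if (nr > 0) {
    left <- rep(regions$center, each = n_bins) - half +
      rep(seq_len(n_bins) - 1L, nr) * bin_bp           # 0-based bin starts
    binger <- GenomicRanges::GRanges(
      rep(regions$chrom, each = n_bins),
      IRanges::IRanges(pmax(1, left + 1), left + bin_bp))
    cnt <- GenomicRanges::countOverlaps(binger, reads)
    m <- matrix(cnt, nrow = nr, ncol = n_bins, byrow = TRUE)
  }
  all_wins <- do.call(c, lapply(norm_regions, heatmap_windows, half = half))
  const <- sum(IRanges::overlapsAny(reads, all_wins))
  if (normalize) {
    if (const > 0) m <- m * 1e6 / const
  }
  attr(m, "normalization_constant") <- const
  attr(m, "regions") <- regions
  m
}

## Displayed windows of a region set at the heatmap half-span.
heatmap_windows <- function(regions, half) {
  GenomicRanges::GRanges(
    regions$chrom,
    IRanges::IRanges(pmax(1, regions$center - half + 1),
                     regions$center + half))
}

#' Write a heatmap matrix (with region metadata) as TSV
#'
#' @param m Matrix from [build_heatmap()].
#' @param path Output path.
#' @export
write_heatmap <- function(m, path) {
  regions <- attr(m, "regions")
  df <- data.frame(chrom = regions$chrom, center = regions$center,
                   ranking_score = regions$ranking_score,
                   as.data.frame(unclass(m)))
  names(df)[-(1:3)] <- paste0("bin_", seq_len(ncol(m)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
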