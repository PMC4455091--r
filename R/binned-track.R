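## Genome-wide binned coverage tracks and correlation-based location
## validation: fixed-width bins, RPM normalisation, input subtraction,
## top-signal bin selection and Spearman correlation of a factor's binding
## with the histone marks.

#' A fixed-width binned genome coverage track
#'
#' Bins are 0-based half-open \code{[i*w, (i+1)*w)} laid per chromosome in
#' the order of \code{seqlengths}; the final partial bin of each chromosome
#' is kept.  \code{counts} hold raw (possibly fractional) read mass per bin,
#' \code{values} the working signal (RPM, optionally input-subtracted).
#'
#' @param counts Numeric vector of per-bin raw counts (all chromosomes
#'   concatenated).
#' @param seqlengths Named integer vector of chromosome lengths.
#' @param bin_width Bin width in bp.
#' @param total_reads Library size used for RPM; defaults to
#'   \code{sum(counts)}.
#' @param track_id Character label.
#' @return An object of class \code{"BinnedTrack"}.
#' @export
BinnedTrack <- function(counts, seqlengths, bin_width = 1000,
                        total_reads = sum(counts), track_id = "track") {
  nbins <- bins_per_chrom(seqlengths, bin_width)
  if (length(counts) != sum(nbins))
    stop("counts length does not match the bin grid")
  if (any(counts < 0)) stop("raw bin counts must be nonnegative")
  if (total_reads <= 0) stop("total_reads must be positive")
  structure(list(track_id = track_id,
                 bin_width = as.integer(bin_width),
                 seqlengths = seqlengths,
                 nbins = nbins,
                 counts = as.numeric(counts),
                 total_reads = total_reads,
                 values = as.numeric(counts) * 1e6 / total_reads,
                 input_subtracted = FALSE),
            class = "BinnedTrack")
}

bins_per_chrom <- function(seqlengths, bin_width) {
  n <- as.integer(ceiling(seqlengths / bin_width))
  names(n) <- names(seqlengths)
  n
}

#' @export
print.BinnedTrack <- function(x, ...) {
  cat(sprintf(
    "BinnedTrack '%s': %d bins of %d bp over %d chromosome(s); %s reads%s\n",
    x$track_id, length(x$counts), x$bin_width, length(x$seqlengths),
    format(x$total_reads), if (x$input_subtracted) ", input-subtracted" else ""))
  invisible(x)
}

same_grid <- function(a, b) {
  identical(a$bin_width, b$bin_width) &&
    identical(a$seqlengths, b$seqlengths)
}

## (chrom, bin) coordinates for flat bin indices of a track.
bin_coordinates <- function(track, flat = seq_along(track$counts)) {
  chrom <- rep(names(track$nbins), track$nbins)[flat]
  offset <- cumsum(c(0, track$nbins))[match(chrom, names(track$nbins))]
  data.frame(chrom = chrom, bin = flat - offset - 1L, flat = flat,
             stringsAsFactors = FALSE)
}

#' Bin genome coverage onto a fixed grid
#'
#' Intervals (reads, or bedGraph records carrying a \code{score}) contribute
#' their mass to the bins they overlap, apportioned by fractional overlap,
#' so total mass is conserved: the sum of raw bin counts equals the sum of
#' interval weights.  With \code{mode = "five_prime"} every interval instead
#' contributes its whole weight to the bin containing its 5' position.
#'
#' @param x A \code{GRanges} of reads or coverage intervals.  A numeric
#'   \code{score} metadata column is used as per-interval weight (bedGraph
#'   semantics); otherwise each interval has weight 1 (one read).
#' @param seqlengths Named vector of chromosome lengths.
#' @param bin_width Bin width in bp (default 1000).
#' @param total_reads Library size for RPM; defaults to the summed weights.
#' @param mode \code{"overlap"} (fractional apportioning) or
#'   \code{"five_prime"}.
#' @param track_id Track label.
#' @return A [BinnedTrack()].
#' @export
bin_coverage <- function(x, seqlengths, bin_width = 1000,
                         total_reads = NULL, mode = c("overlap", "five_prime"),
                         track_id = "track") {
  mode <- match.arg(mode)
  bad <- setdiff(as.character(unique(GenomicRanges::seqnames(x))),
                 names(seqlengths))
  if (length(bad))
    stop("chromosome(s) absent from the genome table: ",
         paste(bad, collapse = ", "))
  ends <- seqlengths[as.character(GenomicRanges::seqnames(x))]
  over <- GenomicRanges::end(x) > ends
  if (any(over))
    stop("interval(s) beyond chromosome end, e.g. record ",
         which(over)[1])
  w <- if (!is.null(x$score)) as.numeric(x$score) else
    rep(1, length(x))
  nbins <- bins_per_chrom(seqlengths, bin_width)
  offset <- stats::setNames(cumsum(c(0L, nbins))[seq_along(nbins)],
                            names(nbins))
  counts <- numeric(sum(nbins))
  add_mass <- function(counts, flat, mass) {
    acc <- rowsum(mass, flat)
    ii <- as.integer(rownames(acc))
    counts[ii] <- counts[ii] + acc[, 1]
    counts
  }
  if (length(x)) {
    chrom <- as.character(GenomicRanges::seqnames(x))
    off <- unname(offset[chrom])
    if (mode == "five_prime") {
      pos5 <- ifelse(as.character(GenomicRanges::strand(x)) == "-",
                     GenomicRanges::end(x), GenomicRanges::start(x))
      counts <- add_mass(counts, off + (pos5 - 1L) %/% bin_width + 1L, w)
    } else {
      s <- GenomicRanges::start(x) - 1    # 0-based
      e <- as.numeric(GenomicRanges::end(x))  # half-open end
      len <- e - s
      first <- s %/% bin_width
      last <- (e - 1) %/% bin_width
      one <- first == last
      if (any(one))
        counts <- add_mass(counts, off[one] + first[one] + 1L, w[one])
      multi <- which(!one)
      if (length(multi)) {
        ## first and last (partial) bins, vectorised
        ov_first <- (first[multi] + 1) * bin_width - s[multi]
        ov_last <- e[multi] - last[multi] * bin_width
        counts <- add_mass(counts, off[multi] + first[multi] + 1L,
                           w[multi] * ov_first / len[multi])
        counts <- add_mass(counts, off[multi] + last[multi] + 1L,
                           w[multi] * ov_last / len[multi])
        ## interior bins (only intervals spanning >= 3 bins)
        wide <- multi[last[multi] - first[multi] >= 2]
        for (i in wide) {
          bins <- (first[i] + 1L):(last[i] - 1L)
          flat <- off[i] + bins + 1L
          counts[flat] <- counts[flat] + w[i] * bin_width / len[i]
        }
      }
    }
  }
  if (is.null(total_reads)) total_reads <- sum(w)
  if (total_reads <= 0) total_reads <- 1   # empty/zero-mass track: RPM all 0
  BinnedTrack(counts, seqlengths, bin_width, total_reads = total_reads,
              track_id = track_id)
}

#' Subtract an input (control) track
#'
#' Working values become RPM(track) - RPM(input).  Negative values are
#' retained: downstream statistics are rank-based and clamping at zero
#' would create massive ties among background bins.
#'
#' @param track,input_track [BinnedTrack()]s on the same bin grid.
#' @return The track with input-subtracted \code{values}.
#' @export
subtract_input <- function(track, input_track) {
  if (!same_grid(track, input_track))
    stop("bin grids differ between track and input")
  track$values <- track$counts * 1e6 / track$total_reads -
    input_track$counts * 1e6 / input_track$total_reads
  track$input_subtracted <- TRUE
  track
}

#' Select the top-signal bins of a track
#'
#' The \code{k} bins with the highest working value.  Ties at the cutoff are
#' broken by genome coordinate (chromosome order, then bin index) so the
#' selection is deterministic and implementation-independent.  If fewer than
#' \code{k} bins have nonzero value, only those are returned, with a warning.
#'
#' @param track A [BinnedTrack()].
#' @param k Number of bins to select (default 4000).
#' @return A data.frame (\code{chrom}, \code{bin}, \code{flat},
#'   \code{value}) sorted by genome coordinate; a "bin selection".
#' @export
top_bins <- function(track, k = 4000) {
  if (k < 1) stop("k must be >= 1")
  nonzero <- sum(track$values != 0)
  if (nonzero == 0) stop("track has no nonzero bin")
  if (k > nonzero) {
    warning("only ", nonzero, " nonzero bins available; returning those")
    k <- nonzero
  }
  ord <- order(-track$values, seq_along(track$values))
  sel <- sort(ord[seq_len(k)])
  out <- bin_coordinates(track, sel)
  out$value <- track$values[sel]
  out
}

#' Union of bin selections
#'
#' The unified list over which factor-vs-mark correlations are computed:
#' the union of the factor's own top bins with those of the four histone
#' marks, deduplicated and sorted by genome coordinate.
#'
#' @param ... Bin selections from [top_bins()] (data.frames or a single
#'   list of them).
#' @return A coordinate-sorted data.frame with \code{chrom}, \code{bin},
#'   \code{flat}.
#' @export
unified_bins <- function(...) {
  sels <- list(...)
  if (length(sels) == 1L && !is.data.frame(sels[[1]]))
    sels <- sels[[1]]
  merged <- do.call(rbind, lapply(sels, `[`, , c("chrom", "bin", "flat")))
  merged <- merged[!duplicated(merged$flat), , drop = FALSE]
  merged <- merged[order(merged$flat), , drop = FALSE]
  rownames(merged) <- NULL
  merged
}

#' Spearman correlation of two tracks over selected bins
#'
#' Rank correlation (average ranks on ties) of the working values of the
#' two tracks restricted to the selected bins.
#'
#' @param track_a,track_b [BinnedTrack()]s on the same grid.
#' @param bins A bin selection (needs a \code{flat} column).
#' @return The correlation in \code{[-1, 1]}, or \code{NA} (with a warning)
#'   when fewer than two bins are selected or either track has zero
#'   variance over them.
#' @export
spearman_correlation <- function(track_a, track_b, bins) {
  if (!same_grid(track_a, track_b)) stop("bin grids differ")
  a <- track_a$values[bins$flat]
  b <- track_b$values[bins$flat]
  if (length(a) < 2 || stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("Spearman correlation undefined over the selected bins")
    return(NA_real_)
  }
  stats::cor(a, b, method = "spearman")
}

#' Predict location from mark correlations
#'
#' Maps the histone mark with the highest correlation to its location:
#' H3K4me3 -> promoter, H3K4me1 -> enhancer, H3K9me3 -> heterochromatin.
#' H3K27ac marks both active promoters and active enhancers, so it is
#' reported as an activity readout but excluded from the argmax.  Ties are
#' resolved in the same priority order as the emPAI-based call.
#'
#' @param correlations Named numeric vector containing at least
#'   \code{H3K4me3}, \code{H3K4me1} and \code{H3K9me3}.
#' @return The location string, or \code{NA} (no-call) when a required
#'   correlation is missing or undefined.
#' @export
predict_by_correlation <- function(correlations) {
  need <- names(LOCATION_CHANNELS)
  if (!all(need %in% names(correlations))) {
    warning("missing correlation(s): ",
            paste(setdiff(need, names(correlations)), collapse = ", "))
    return(NA_character_)
  }
  v <- correlations[need]
  if (anyNA(v)) return(NA_character_)
  unname(LOCATION_CHANNELS[which.max(v)])
}

#' Concordance between emPAI-based and correlation-based location calls
#'
#' @param ms_calls Location-call data.frame from [predict_location()].
#' @param corr_calls Named character vector of correlation-based locations
#'   (names are protein ids).
#' @return A data.frame per location: \code{n}, \code{n_agree},
#'   \code{pct_agree} (integer percent), ordered promoter, enhancer,
#'   heterochromatin; empty when the protein sets do not intersect.
#' @export
concordance_table <- function(ms_calls, corr_calls) {
  common <- intersect(ms_calls$protein_id, names(corr_calls))
  locs <- unname(LOCATION_CHANNELS)
  ms <- ms_calls[match(common, ms_calls$protein_id), ]
  keep <- ms$location %in% locs
  ms <- ms[keep, ]
  common <- common[keep]
  if (length(common) == 0L)
    return(data.frame(location = character(), n = integer(),
                      n_agree = integer(), pct_agree = numeric()))
  agree <- ms$location == corr_calls[common]
  out <- do.call(rbind, lapply(locs, function(l) {
    sel <- ms$location == l
    data.frame(location = l, n = sum(sel), n_agree = sum(agree[sel]),
               stringsAsFactors = FALSE)
  }))
  out$pct_agree <- ifelse(out$n > 0, round(100 * out$n_agree / out$n), NA)
  out
}
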