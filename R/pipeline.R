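## End-to-end pipelines over a dataset (real or synthetic): the MS path
## (evidence -> filters -> emPAI profiles -> location calls), the
## genome-correlation path (tracks -> bins -> Spearman -> location calls),
## the target-gene path, and planted-truth evaluation of a synthetic run.

#' MS path: evidence table to location calls
#'
#' @param evidence MS evidence data.frame (see [read_ms_evidence()]).
#' @param thresholds Per-sample significance thresholds.
#' @param params Filter parameters.
#' @param exclusion_list Protein ids excluded by annotation.
#' @return A list: \code{profiles} (all, with filter flags),
#'   \code{included} (inclusion list), \code{calls} (location calls for
#'   included proteins).
#' @export
ms_location_pipeline <- function(evidence,
                                 thresholds = default_thresholds(),
                                 params = filter_params(),
                                 exclusion_list = character()) {
  filtered <- apply_mascot_filters(evidence, thresholds, params)
  profiles <- build_empai_profiles(filtered)
  included <- build_inclusion_list(profiles, params, exclusion_list)
  calls <- predict_location(included)
  list(profiles = attr(included, "all_profiles"), included = included,
       calls = calls)
}

#' Correlation path: factor and mark tracks to location calls
#'
#' Bins every track on a common grid, normalises to RPM, subtracts the
#' input from every non-input track, selects each track's top bins, and
#' correlates each factor with each mark over the union of the factor's
#' and the four marks' top bins.  The mark with the highest Spearman
#' correlation decides the location call.
#'
#' @param factor_reads Named list of factor read \code{GRanges}.
#' @param mark_reads Named list with the four mark \code{GRanges}.
#' @param input_reads Input \code{GRanges} (NULL to skip subtraction).
#' @param seqlengths Named chromosome lengths.
#' @param bin_width Bin width in bp (default 1000).
#' @param k Top bins per track (default 4000).
#' @return A data.frame: factor, one correlation column per mark,
#'   \code{predicted_location}.
#' @export
correlation_location_pipeline <- function(factor_reads, mark_reads,
                                          input_reads = NULL, seqlengths,
                                          bin_width = 1000, k = 4000) {
  stopifnot(all(MARK_CHANNELS %in% names(mark_reads)))
  input_track <- if (!is.null(input_reads))
    bin_coverage(input_reads, seqlengths, bin_width, track_id = "input")
  prep <- function(reads, id) {
    tr <- bin_coverage(reads, seqlengths, bin_width, track_id = id)
    if (!is.null(input_track)) tr <- subtract_input(tr, input_track)
    tr
  }
  mark_tracks <- lapply(stats::setNames(MARK_CHANNELS, MARK_CHANNELS),
                        function(m) prep(mark_reads[[m]], m))
  mark_sels <- lapply(mark_tracks, top_bins, k = k)
  rows <- lapply(names(factor_reads), function(f) {
    ftr <- prep(factor_reads[[f]], f)
    fsel <- top_bins(ftr, k)
    bins <- unified_bins(c(list(fsel), mark_sels))
    cors <- vapply(MARK_CHANNELS, function(m)
      spearman_correlation(ftr, mark_tracks[[m]], bins), numeric(1))
    data.frame(factor = f, t(cors),
               predicted_location = predict_by_correlation(cors),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[2:5] <- paste0("r_", MARK_CHANNELS)
  rownames(out) <- NULL
  out
}

#' Target path: peaks plus expression to bound and target genes
#'
#' @param peaks Factor peak table (unfiltered).
#' @param genes Gene/TSS table.
#' @param probes Probe-level fold-change table.
#' @param p_max,min_reads Peak post-filters (see [filter_peaks()]).
#' @param tss_window Bound-gene window in bp.
#' @param min_fold,max_adj_p,direction Target rule (see [target_genes()]).
#' @return A list: \code{peaks} (filtered), \code{bound}, \code{gene_fc},
#'   \code{targets}.
#' @export
target_gene_pipeline <- function(peaks, genes, probes, p_max = 1e-10,
                                 min_reads = 0, tss_window = 1000,
                                 min_fold = 2, max_adj_p = 0.10,
                                 direction = "down") {
  filtered <- filter_peaks(peaks, p_max, min_reads)
  bound <- bound_genes(filtered, genes, tss_window)
  gene_fc <- aggregate_probes(probes)
  targets <- target_genes(bound, gene_fc, min_fold, max_adj_p, direction)
  list(peaks = filtered, bound = bound, gene_fc = gene_fc,
       targets = targets)
}

#' Evaluate a synthetic run against its planted truth
#'
#' Runs the MS path, the correlation path and the target path on a
#' synthetic dataset and scores them against the planted labels.
#' Location recovery uses all planted factors as denominator (a factor
#' lost by the inclusion filters counts as a miss).
#'
#' @param sim Output of [simulate_dataset()].
#' @param correlation Whether to run the (more expensive) correlation
#'   path.
#' @return A list of percentages and supporting tables:
#'   \code{ms_recovery_pct}, \code{corr_recovery_pct},
#'   \code{path_agreement_pct}, \code{target_sensitivity_pct},
#'   \code{target_precision_pct}, plus \code{ms}, \code{corr},
#'   \code{targets}, \code{concordance}.
#' @export
evaluate_sim <- function(sim, correlation = TRUE) {
  truth <- sim$factors$truth
  ms <- ms_location_pipeline(sim$factors$evidence)
  ms_loc <- ms$calls$location[match(truth$factor_id, ms$calls$protein_id)]
  ms_recovery <- 100 * mean(!is.na(ms_loc) & ms_loc == truth$class)

  corr <- NULL; corr_recovery <- NA_real_; agreement <- NA_real_
  concord <- NULL
  if (correlation) {
    corr <- correlation_location_pipeline(
      sim$factors$reads, sim$marks$reads[MARK_CHANNELS],
      sim$marks$reads$input, sim$seqlengths,
      bin_width = sim$config$bin_width)
    corr_loc <- corr$predicted_location[match(truth$factor_id,
                                              corr$factor)]
    corr_recovery <- 100 * mean(!is.na(corr_loc) &
                                  corr_loc == truth$class)
    both <- !is.na(ms_loc) & !is.na(corr_loc)
    agreement <- 100 * mean(ms_loc[both] == corr_loc[both])
    concord <- concordance_table(
      ms$calls, stats::setNames(corr$predicted_location, corr$factor))
  }

  tg <- target_gene_pipeline(
    sim$factors$peaks[[sim$factors$knockout_factor]],
    sim$expression$genes, sim$expression$probes,
    p_max = 1e-10, min_reads = 100, tss_window = 1000,
    min_fold = 2, max_adj_p = 0.10, direction = "down")
  truth_targets <- sim$expression$true_targets
  tp <- length(intersect(tg$targets, truth_targets))
  sens <- 100 * tp / length(truth_targets)
  prec <- if (length(tg$targets)) 100 * tp / length(tg$targets)
          else NA_real_

  list(ms_recovery_pct = ms_recovery,
       corr_recovery_pct = corr_recovery,
       path_agreement_pct = agreement,
       target_sensitivity_pct = sens,
       target_precision_pct = prec,
       ms = ms, corr = corr, targets = tg, concordance = concord)
}
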