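## ChIP-MS evidence handling: emPAI computation, Mascot-score filtering and
## the inclusion filters that define the analyzable factor list.

#' Names of the ChIP channels used throughout the package
#'
#' Four histone-modification channels plus the GFP control channel.
#'
#' @format Character vectors.
#' @name channels
NULL

#' @rdname channels
#' @export
MARK_CHANNELS <- c("H3K4me3", "H3K4me1", "H3K27ac", "H3K9me3")

#' @rdname channels
#' @export
ALL_CHANNELS <- c(MARK_CHANNELS, "GFP")

## Channels whose highest emPAI defines a location, in tie-priority order.
LOCATION_CHANNELS <- c(H3K4me3 = "promoter", H3K4me1 = "enhancer",
                       H3K9me3 = "heterochromatin")

#' Exponentially modified protein abundance index (emPAI)
#'
#' emPAI is a label-free, semi-quantitative proxy for the amount of a protein
#' in an MS sample: the number of peptides observed for the protein,
#' normalised for the number of peptides that theoretically should be
#' identifiable, exponentiated so that the score scales roughly linearly
#' with protein amount:
#' \deqn{\mathrm{emPAI} = 10^{N_{obs}/N_{obl}} - 1}
#'
#' @param n_observed Number of observed peptides (or spectra); nonnegative.
#' @param n_observable Number of theoretically observable peptides; >= 1.
#' @return Nonnegative numeric, same length as the inputs (recycled).
#'   Zero exactly when \code{n_observed} is zero.
#' @examples
#' compute_empai(3, 10)   # 10^0.3 - 1
#' compute_empai(0, 10)   # 0
#' @export
compute_empai <- function(n_observed, n_observable) {
  if (any(is.na(n_observable)) || any(n_observable < 1))
    stop("n_observable must be >= 1")
  if (any(is.na(n_observed)) || any(n_observed < 0))
    stop("n_observed must be >= 0")
  10^(n_observed / n_observable) - 1
}

#' Default filter parameters for ChIP-MS inclusion
#'
#' @param mascot_primary Minimum Mascot score required in at least one
#'   histone-modification channel for a protein to enter the list (default 50).
#' @param mascot_secondary Minimum Mascot score for an individual observation
#'   to be kept at all (default 45).
#' @param manual_check_max Scores in \code{[mascot_secondary,
#'   manual_check_max)} additionally require \code{manually_validated}
#'   (default 60): in that range individual MS/MS spectra are expected to
#'   have been inspected by the analyst.
#' @param gfp_fold Required fold of the best histone-mark emPAI over every
#'   GFP-control replicate emPAI (default 5).
#' @param discrimination_fold Required fold between some pair of
#'   histone-mark emPAIs (default 3); excludes indiscriminate chromatin
#'   binders.
#' @return A list with class \code{"chipms_filter_params"}.
#' @export
filter_params <- function(mascot_primary = 50, mascot_secondary = 45,
                          manual_check_max = 60, gfp_fold = 5,
                          discrimination_fold = 3) {
  stopifnot(mascot_primary > 0, mascot_secondary > 0,
            mascot_secondary <= mascot_primary,
            gfp_fold > 0, discrimination_fold > 0)
  structure(list(mascot_primary = mascot_primary,
                 mascot_secondary = mascot_secondary,
                 manual_check_max = manual_check_max,
                 gfp_fold = gfp_fold,
                 discrimination_fold = discrimination_fold),
            class = "chipms_filter_params")
}

#' Read a ChIP-MS evidence table
#'
#' Expected columns: \code{protein_id, channel, replicate, mascot_score,
#' n_observed, n_observable} and optionally \code{manually_validated}
#' (defaults to \code{TRUE} when absent, reproducing permissive behaviour
#' for tables without spectrum-inspection annotation).
#'
#' @param path Path to a tab-separated evidence file with header.
#' @return A data.frame of MS observations.
#' @export
read_ms_evidence <- function(path) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_ms_evidence(ev)
}

#' @rdname read_ms_evidence
#' @param evidence A data.frame to validate in place of a file.
#' @export
validate_ms_evidence <- function(evidence) {
  required <- c("protein_id", "channel", "replicate", "mascot_score",
                "n_observed", "n_observable")
  missing <- setdiff(required, names(evidence))
  if (length(missing))
    stop("evidence table lacks columns: ", paste(missing, collapse = ", "))
  bad <- setdiff(unique(evidence$channel), ALL_CHANNELS)
  if (length(bad))
    stop("unknown channel name(s): ", paste(bad, collapse = ", "))
  if (any(evidence$replicate < 1))
    stop("replicate must be >= 1")
  if (any(evidence$n_observable < 1))
    stop("n_observable must be >= 1")
  if (any(evidence$mascot_score < 0) || any(evidence$n_observed < 0))
    stop("mascot_score and n_observed must be nonnegative")
  if (is.null(evidence$manually_validated))
    evidence$manually_validated <- TRUE
  evidence
}

#' Per-sample Mascot peptide significance thresholds
#'
#' One minimum peptide Mascot score per ChIP sample (channel x replicate),
#' as reported by the search engine at P < 0.05 for that sample.
#'
#' @param channel,replicate,threshold Parallel vectors defining the map.
#' @return A data.frame with columns \code{channel, replicate, threshold}.
#' @export
significance_thresholds <- function(channel, replicate, threshold) {
  stopifnot(length(channel) == length(replicate),
            length(channel) == length(threshold), all(threshold > 0))
  data.frame(channel = as.character(channel),
             replicate = as.integer(replicate),
             threshold = as.numeric(threshold))
}

#' Uniform significance thresholds for every channel/replicate
#'
#' @param value Threshold applied to every sample (default 28, a typical
#'   P < 0.05 peptide score).
#' @param replicates Number of replicates per channel.
#' @export
default_thresholds <- function(value = 28, replicates = 2) {
  grid <- expand.grid(channel = ALL_CHANNELS, replicate = seq_len(replicates),
                      stringsAsFactors = FALSE)
  significance_thresholds(grid$channel, grid$replicate, rep(value, nrow(grid)))
}

#' Apply Mascot-score inclusion filters to MS observations
#'
#' A protein is retained only if at least one histone-modification (non-GFP)
#' observation reaches \code{mascot_primary}.  For retained proteins,
#' individual observations are kept when their score is at or above both the
#' per-sample peptide significance threshold and \code{mascot_secondary};
#' scores in \code{[mascot_secondary, manual_check_max)} are kept only when
#' flagged \code{manually_validated}.
#'
#' @param observations Evidence data.frame (see [read_ms_evidence()]).
#' @param thresholds Per-sample thresholds (see [significance_thresholds()]).
#' @param params Filter parameters from [filter_params()].
#' @return The filtered observation data.frame.
#' @export
apply_mascot_filters <- function(observations,
                                 thresholds = default_thresholds(),
                                 params = filter_params()) {
  observations <- validate_ms_evidence(observations)
  if (nrow(observations) == 0L) return(observations)
  key <- paste(observations$channel, observations$replicate)
  tkey <- paste(thresholds$channel, thresholds$replicate)
  idx <- match(key, tkey)
  if (anyNA(idx)) {
    miss <- unique(key[is.na(idx)])
    stop("no significance threshold for sample(s): ",
         paste(miss, collapse = ", "))
  }
  thr <- thresholds$threshold[idx]
  score <- observations$mascot_score
  obs_ok <- score >= thr & score >= params$mascot_secondary &
    (score >= params$manual_check_max | observations$manually_validated)
  gate <- obs_ok & observations$channel != "GFP" &
    score >= params$mascot_primary
  keep_protein <- unique(observations$protein_id[gate])
  out <- observations[obs_ok & observations$protein_id %in% keep_protein, ,
                      drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build channel-averaged emPAI profiles
#'
#' One profile per protein.  Per histone-mark channel the emPAI is averaged
#' over replicates, a replicate without an observation contributing emPAI 0
#' (non-detection is treated as absence).  GFP-control replicates are kept
#' individually because the control filter compares against each of them.
#'
#' @param observations Mascot-filtered observations.
#' @param n_replicates Number of replicates per channel (default 2).
#' @return A data.frame with one row per protein: \code{protein_id},
#'   \code{empai_<mark>} for the four marks, \code{empai_GFP_r<i>}.
#' @export
build_empai_profiles <- function(observations, n_replicates = 2) {
  observations <- validate_ms_evidence(observations)
  gfp_cols <- paste0("empai_GFP_r", seq_len(n_replicates))
  cols <- c(paste0("empai_", MARK_CHANNELS), gfp_cols)
  proteins <- sort(unique(observations$protein_id))
  prof <- matrix(0, nrow = length(proteins), ncol = length(cols),
                 dimnames = list(proteins, cols))
  if (nrow(observations)) {
    if (any(observations$replicate > n_replicates))
      stop("replicate index exceeds n_replicates")
    dup <- duplicated(observations[, c("protein_id", "channel", "replicate")])
    if (any(dup))
      stop("duplicated protein/channel/replicate observation(s)")
    observations$empai <- compute_empai(observations$n_observed,
                                        observations$n_observable)
    col <- ifelse(observations$channel == "GFP",
                  paste0("empai_GFP_r", observations$replicate),
                  paste0("empai_", observations$channel))
    val <- ifelse(observations$channel == "GFP", observations$empai,
                  observations$empai / n_replicates)
    ij <- cbind(match(observations$protein_id, proteins), match(col, cols))
    for (i in seq_len(nrow(observations)))        # marks accumulate over reps
      prof[ij[i, 1], ij[i, 2]] <- prof[ij[i, 1], ij[i, 2]] + val[i]
  }
  out <- data.frame(protein_id = proteins, prof, row.names = NULL,
                    stringsAsFactors = FALSE)
  out
}

## Mark-channel emPAI columns of a profile data.frame as a matrix.
mark_empai <- function(profiles) {
  as.matrix(profiles[, paste0("empai_", MARK_CHANNELS), drop = FALSE])
}

gfp_empai <- function(profiles) {
  as.matrix(profiles[, grep("^empai_GFP_r", names(profiles)), drop = FALSE])
}

#' GFP-control exclusion filter
#'
#' Passes a profile when its best histone-mark averaged emPAI is at least
#' \code{gfp_fold} times every individual GFP-replicate emPAI ("no or very
#' low presence in any of the control ChIPs").  A positive mark signal over
#' an all-zero GFP control passes; an all-zero profile fails.
#'
#' @param profiles Profile data.frame from [build_empai_profiles()].
#' @param params Filter parameters.
#' @return Logical vector, one per profile row.
#' @export
gfp_exclusion_filter <- function(profiles, params = filter_params()) {
  mark_max <- apply(mark_empai(profiles), 1, max)
  gfp_max <- apply(gfp_empai(profiles), 1, max)
  mark_max > 0 & mark_max >= params$gfp_fold * gfp_max
}

#' Histone-mark discrimination filter
#'
#' Passes when some ordered pair of histone-mark channels (a, b) satisfies
#' emPAI(a) >= \code{discrimination_fold} x emPAI(b) with emPAI(a) > 0.
#' Excludes proteins that bind chromatin indiscriminately of the tested
#' modifications (all channels within the fold of each other).
#'
#' @inheritParams gfp_exclusion_filter
#' @return Logical vector, one per profile row.
#' @export
discrimination_filter <- function(profiles, params = filter_params()) {
  m <- mark_empai(profiles)
  hi <- apply(m, 1, max)
  lo <- apply(m, 1, min)
  hi > 0 & hi >= params$discrimination_fold * lo
}

#' Assemble the ChIP-MS inclusion list
#'
#' Applies the GFP-control and discrimination filters and removes proteins
#' on a user-supplied exclusion list (typically cytoskeletal/cytoplasmic
#' annotations).  The result is sorted by protein id for determinism.
#'
#' @inheritParams gfp_exclusion_filter
#' @param exclusion_list Character vector of protein ids to drop.
#' @return The profile data.frame restricted to included proteins, with
#'   logical columns \code{passed_gfp}, \code{passed_discrimination} and an
#'   \code{excluded_reason} column attached to the full table available via
#'   \code{attr(, "all_profiles")}.
#' @export
build_inclusion_list <- function(profiles, params = filter_params(),
                                 exclusion_list = character()) {
  profiles$passed_gfp <- gfp_exclusion_filter(profiles, params)
  profiles$passed_discrimination <- discrimination_filter(profiles, params)
  excluded <- profiles$protein_id %in% exclusion_list
  profiles$excluded_reason <- ifelse(
    excluded, "exclusion_list",
    ifelse(!profiles$passed_gfp, "gfp_control",
           ifelse(!profiles$passed_discrimination, "no_discrimination", "")))
  keep <- profiles$passed_gfp & profiles$passed_discrimination & !excluded
  out <- profiles[keep, , drop = FALSE]
  out <- out[order(out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "all_profiles") <- profiles
  out
}

#' Write an emPAI profile table
#'
#' @param profiles Profile data.frame (optionally with filter columns).
#' @param path Output TSV path.
#' @export
write_profiles <- function(profiles, path) {
  attr(profiles, "all_profiles") <- NULL
  utils::write.table(profiles, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
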