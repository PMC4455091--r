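## Location prediction: assign each included factor a genomic compartment
## (promoter / enhancer / heterochromatin) from its emPAI profile, plus the
## H3K27ac activity ratio.

#' Predict the genomic location class of factors from emPAI profiles
#'
#' The channel with the highest averaged emPAI among the three
#' location-defining marks decides the call: H3K4me3 -> promoter, H3K4me1 ->
#' enhancer, H3K9me3 -> heterochromatin.  Ties are resolved in that priority
#' order, so equal H3K4me3 and H3K4me1 scores give "promoter" (active
#' promoters carry some H3K4me1 in their flanks, so a promoter binder can
#' legitimately show both).  A factor observed exclusively in the H3K27ac
#' fraction cannot be placed (H3K27ac marks both active promoters and active
#' enhancers) and is called \code{"k27ac_only"}.
#'
#' @param profiles Profile data.frame from [build_empai_profiles()],
#'   normally restricted to the inclusion list.
#' @param ratio_reliable_min Minimum of max(H3K4me3, H3K4me1) emPAI for the
#'   H3K27ac ratio to be considered reliable (default 0.1, well above the
#'   MS detection limit).
#' @return A data.frame of location calls: \code{protein_id},
#'   \code{location}, \code{winning_empai}, \code{h3k27ac_ratio} (NA when
#'   both H3K4 emPAIs are zero), \code{ratio_reliable}, \code{tie} (TRUE
#'   when the argmax was not unique).
#' @export
predict_location <- function(profiles, ratio_reliable_min = 0.1) {
  m <- mark_empai(profiles)
  loc_m <- m[, paste0("empai_", names(LOCATION_CHANNELS)), drop = FALSE]
  if (any(rowSums(m) == 0))
    stop("profile(s) with all-zero histone-mark emPAI: ",
         paste(profiles$protein_id[rowSums(m) == 0], collapse = ", "),
         " (should not have passed inclusion filters)")
  win <- apply(loc_m, 1, max)
  ## which.max picks the first maximum: column order encodes tie priority
  arg <- apply(loc_m, 1, which.max)
  location <- unname(LOCATION_CHANNELS[arg])
  tie <- apply(loc_m, 1, function(v) sum(v == max(v)) > 1) & win > 0
  k27_only <- win == 0 & m[, "empai_H3K27ac"] > 0
  location[k27_only] <- "k27ac_only"
  ratio <- h3k27ac_ratio(profiles)
  data.frame(protein_id = profiles$protein_id,
             location = location,
             winning_empai = unname(win),
             h3k27ac_ratio = ratio$ratio,
             ratio_reliable = ratio$k4_max >= ratio_reliable_min,
             tie = unname(tie),
             stringsAsFactors = FALSE)
}

#' H3K27ac activity ratio
#'
#' The averaged H3K27ac emPAI divided by the larger of the H3K4me3 and
#' H3K4me1 averaged emPAIs.  The ratio predicts the activity level of the
#' promoters or enhancers a factor binds, while compensating for the large
#' differences in MS detection level between proteins.  Undefined (NA) when
#' both H3K4 emPAIs are zero.
#'
#' @inheritParams predict_location
#' @return A data.frame with \code{protein_id}, \code{ratio} and
#'   \code{k4_max} (the denominator).
#' @export
h3k27ac_ratio <- function(profiles) {
  k4max <- pmax(profiles$empai_H3K4me3, profiles$empai_H3K4me1)
  ratio <- ifelse(k4max > 0, profiles$empai_H3K27ac / k4max, NA_real_)
  data.frame(protein_id = profiles$protein_id, ratio = ratio, k4_max = k4max,
             stringsAsFactors = FALSE)
}

#' Export the activity-map coordinate table
#'
#' Tabular stand-in for the graphical factor map: one row per factor with
#' its location panel, its H3K27ac ratio (the axis coordinate for activity)
#' and its rank within the location by decreasing ratio.  Ordering is fully
#' deterministic (location, ratio descending, protein id), with undefined
#' ratios placed last within their location.
#'
#' @param calls Location-call data.frame from [predict_location()].
#' @param path Optional TSV output path.
#' @return The ordered table (invisibly written to \code{path} if given).
#' @export
export_activity_map <- function(calls, path = NULL) {
  ord <- order(match(calls$location,
                     c(unname(LOCATION_CHANNELS), "k27ac_only")),
               is.na(calls$h3k27ac_ratio), -xtfrm(calls$h3k27ac_ratio),
               calls$protein_id)
  out <- calls[ord, c("protein_id", "location", "h3k27ac_ratio",
                      "ratio_reliable"), drop = FALSE]
  out$rank <- stats::ave(seq_len(nrow(out)), out$location,
                         FUN = seq_along)
  rownames(out) <- NULL
  if (!is.null(path)) {
    fmt <- out
    fmt$h3k27ac_ratio <- ifelse(is.na(fmt$h3k27ac_ratio), "",
                                format(fmt$h3k27ac_ratio, digits = 15,
                                       trim = TRUE, scientific = FALSE))
    utils::write.table(fmt, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  out
}
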