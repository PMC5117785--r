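#' Reallocate cases with unknown FIGO stage
#'
#' Stage 1A is assumed always recorded, so unknown-stage cases are treated as
#' missing at random among the other stages within their age band. The default
#' distributes each band's unknown count over stages 1B, 2 and 3+ in
#' proportion to the band's known counts of those stages; within a receiving
#' stage the unknowns follow the stage's screening-category distribution
#' (their own screening histories are not tabulated). Counts stay fractional
#' and band totals are conserved.
#'
#' Sensitivity variants: \code{"none"} drops the unknown rows (unknown-stage
#' cases excluded), \code{"all_stage2"} / \code{"all_stage3"} push every
#' unknown into stage 2 / stage 3+, and \code{"proportional_all"} spreads them
#' over all four stages including 1A.
#'
#' @param counts a [case_count_table] with \code{stage = "unknown"} rows
#' @param mode reallocation rule, see Details
#' @return a [case_count_table] without unknown rows
#' @export
reallocate_missing <- function(counts,
                               mode = c("proportional_1b_2_3", "none",
                                        "all_stage2", "all_stage3",
                                        "proportional_all")) {
  mode <- match.arg(mode)
  counts <- case_count_table(counts)
  known <- counts[counts$stage != "unknown", ]
  unk <- counts[counts$stage == "unknown", ]
  if (mode == "none" || nrow(unk) == 0 || sum(unk$count) == 0) {
    out <- known
    rownames(out) <- NULL
    return(case_count_table(out))
  }
  receiving <- switch(mode,
                      proportional_1b_2_3 = c("1B", "2", "3plus"),
                      all_stage2 = "2",
                      all_stage3 = "3plus",
                      proportional_all = stage_levels())
  for (band in unique(unk$age_band)) {
    u <- sum(unk$count[unk$age_band == band])
    if (u == 0) next
    idx <- known$age_band == band & known$stage %in% receiving
    denom <- sum(known$count[idx])
    if (denom == 0)
      stop("band ", band, ": unknown-stage cases but no receiving-stage counts")
    # scaling each receiving cell by a common factor implements both the
    # across-stage and the within-stage category proportionality at once
    known$count[idx] <- known$count[idx] * (1 + u / denom)
  }
  rownames(known) <- NULL
  case_count_table(known)
}
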