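.edss_grid_ok <- function(x) {
  x >= 0 & x <= 10 & abs(x * 2 - round(x * 2)) < 1e-8
}

#' EDSS increment required for disability progression
#'
#' The threshold depends on the baseline score: 1.5 points from a baseline of
#' 0, 1 point for baselines 1.0--5.0, and 0.5 points for baselines of 5.5 or
#' higher.  A baseline of 0.5 falls outside the stated branches; it is given
#' the 1-point threshold and a warning is emitted.
#'
#' @param edss_baseline Baseline EDSS score(s) on the 0--10 half-point grid.
#' @return Numeric threshold(s).
#' @export
progression_threshold <- function(edss_baseline) {
  if (any(!.edss_grid_ok(edss_baseline)))
    stop("EDSS scores must lie on the 0-10 half-point grid")
  if (any(edss_baseline == 0.5))
    warning("baseline EDSS 0.5 is not covered by the progression rule; ",
            "using the 1-point threshold")
  ifelse(edss_baseline == 0, 1.5, ifelse(edss_baseline >= 5.5, 0.5, 1.0))
}

#' Binary disability-progression label from an EDSS pair
#'
#' A patient is labeled progressed (1) when the follow-up EDSS exceeds the
#' baseline by at least the baseline-dependent threshold (see
#' [progression_threshold()]); the comparison is `increase >= threshold`.
#'
#' @param edss_baseline Baseline EDSS score(s).
#' @param edss_followup Follow-up EDSS score(s), same length.
#' @return Integer 0/1 vector, 1 = progressed.
#' @export
#' @examples
#' progression_label(0, 1.5)   # 1
#' progression_label(3.5, 4.5) # 1
#' progression_label(4.0, 4.5) # 0
progression_label <- function(edss_baseline, edss_followup) {
  if (length(edss_baseline) != length(edss_followup))
    stop("baseline and follow-up vectors must have the same length")
  if (any(!.edss_grid_ok(edss_followup)))
    stop("EDSS scores must lie on the 0-10 half-point grid")
  thr <- progression_threshold(edss_baseline)
  as.integer(edss_followup - edss_baseline >= thr - 1e-8)
}

#' Label a patient table
#'
#' @param patients data.frame with columns `edss_baseline` and
#'   `edss_followup` (and typically `patient_id`, `site`).
#' @return The same data.frame with a `label` column appended (1 =
#'   progressed).
#' @export
label_patients <- function(patients) {
  stopifnot(all(c("edss_baseline", "edss_followup") %in% names(patients)))
  patients$label <- progression_label(patients$edss_baseline,
                                      patients$edss_followup)
  patients
}
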