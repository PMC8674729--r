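#' Meary's-angle severity grading of foot collapse
#'
#' Applies the commonly used clinical thresholds to Meary's angle:
#' normal if v <= 4, mild if 4 < v < 15, moderate if 15 <= v <= 30, severe if
#' v > 30 (boundary values 4, 15 and 30 map to normal, moderate and moderate
#' respectively, reading the threshold chain literally). When grading an
#' observer panel the conventional input is the mean over observers.
#'
#' By default the magnitude |v| is graded (\code{mode = "signed_abs"}), since
#' the thresholds are magnitudes while \code{\link{measureAll}} reports a
#' signed angle; \code{mode = "raw"} grades the value as given.
#'
#' @param ma_deg numeric vector of Meary's angles in degrees.
#' @param mode "signed_abs" (grade |value|, default) or "raw".
#' @param thresholds length-3 numeric c(normal_max, moderate_min, moderate_max);
#'   overridable for non-standard grading schemes.
#' @return factor with levels normal < mild < moderate < severe.
#' @export
classifyMearys <- function(ma_deg, mode = c("signed_abs", "raw"),
                           thresholds = c(4, 15, 30)) {
  mode <- match.arg(mode)
  if (any(!is.finite(ma_deg))) {
    fmStop("fm_invalid_value", "non-finite Meary's angle")
  }
  v <- if (mode == "signed_abs") abs(ma_deg) else ma_deg
  lab <- ifelse(v <= thresholds[1], "normal",
         ifelse(v < thresholds[2], "mild",
         ifelse(v <= thresholds[3], "moderate", "severe")))
  factor(lab, levels = severityLevels(), ordered = TRUE)
}

#' Severity class labels in increasing order
#' @return character vector of the four class labels.
#' @export
severityLevels <- function() c("normal", "mild", "moderate", "severe")
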