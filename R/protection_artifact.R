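# Radiation-protection and artifact categorization from filtered
# detections. Both resolve mixed evidence toward the worst category:
# added evidence never raises the quality score.

#' Radiation-protection rubric category
#'
#' Flags are set iff at least one filtered box of the respective label
#' (neck_protection / abdomen_protection) is present anywhere in the
#' coronal detections.
#'
#' @param detections filtered detection table for the
#'   radiation-protection task.
#' @return List with \code{neckProtected}, \code{abdomenProtected} and
#'   \code{category} (\code{"both"}, \code{"one"} or \code{"none"}).
#' @export
protectionCategory <- function(detections) {
  neck <- any(detections$label == "neck_protection")
  abdomen <- any(detections$label == "abdomen_protection")
  category <- c("none", "one", "both")[neck + abdomen + 1L]
  list(neckProtected = neck, abdomenProtected = abdomen,
       category = category)
}

#' Artifact rubric category for an axial series
#'
#' Worst-first precedence: any radial-artifact box in any image decides
#' radial_artifact; otherwise any foreign-matter box decides
#' foreign_matter; otherwise no_exist.
#'
#' @param series axial [CTSeries-class].
#' @param detector detection backend.
#' @param minScore confidence cutoff (default 0.70).
#' @return \code{"radial_artifact"}, \code{"foreign_matter"} or
#'   \code{"no_exist"}.
#' @export
artifactCategory <- function(series, detector, minScore = 0.70) {
  boxes <- filterDetections(detect(detector, series, "artifact"), minScore)
  if (any(boxes$label == "radial_artifact")) return("radial_artifact")
  if (any(boxes$label == "foreign_matter")) return("foreign_matter")
  "no_exist"
}
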