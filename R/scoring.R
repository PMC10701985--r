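# The multi-task scoring rubric: category -> points lookup per
# sub-part, per-task and overall aggregation, and the two binary
# acceptability decisions. The rubric is data-driven so alternative
# rubrics can be evaluated; the defaults are the study values.

#' The default scoring rubric
#'
#' One row per (sub-part, category) pair with the points awarded.
#' Inspiration sub-parts: tracheal carina convex/flat/concave scores
#' 10/5/0; rib visible/corrugation/double shadow/multiple shadows and
#' bronchial beam visible/fuzzy/double shadow/curly each score
#' 15/10/5/0. Scan baseline both/one/none correct scores 10/5/0;
#' radiation protection both/one/none 10/5/0; artifact no
#' exist/foreign matter/radial artifact 10/5/0; arms raised/not raised
#' 5/0; body inside/outside the FOV centre 5/0.
#'
#' @return data.frame with columns subpart, category, points.
#' @export
#' @examples
#' subset(defaultRubric(), subpart == "rib")
defaultRubric <- function() {
  rbind(
    data.frame(subpart = "tracheal_carina",
               category = c("convex", "flat", "concave"),
               points = c(10L, 5L, 0L)),
    data.frame(subpart = "bronchial_beam",
               category = c("visible", "fuzzy", "double_shadow", "curly"),
               points = c(15L, 10L, 5L, 0L)),
    data.frame(subpart = "rib",
               category = c("visible", "corrugation", "double_shadow",
                            "multiple_shadows"),
               points = c(15L, 10L, 5L, 0L)),
    data.frame(subpart = "scan_baseline",
               category = c("both_correct", "one_correct", "none_correct"),
               points = c(10L, 5L, 0L)),
    data.frame(subpart = "body_position",
               category = c("inside", "outside"),
               points = c(5L, 0L)),
    data.frame(subpart = "arms_position",
               category = c("raised", "not_raised"),
               points = c(5L, 0L)),
    data.frame(subpart = "radiation_protection",
               category = c("both", "one", "none"),
               points = c(10L, 5L, 0L)),
    data.frame(subpart = "artifact",
               category = c("no_exist", "foreign_matter", "radial_artifact"),
               points = c(10L, 5L, 0L))
  )
}

#' Read / write a rubric as YAML
#'
#' The YAML dialect is a map from sub-part to a category -> points map.
#'
#' @param file path to a YAML file.
#' @param rubric rubric data.frame (see [defaultRubric()]).
#' @return \code{readRubric} returns the rubric data.frame;
#'   \code{writeRubric} returns \code{file} invisibly.
#' @export
readRubric <- function(file) {
  y <- yaml::read_yaml(file)
  do.call(rbind, lapply(names(y), function(sp) {
    data.frame(subpart = sp, category = names(y[[sp]]),
               points = as.integer(unlist(y[[sp]])))
  }))
}

#' @rdname readRubric
#' @export
writeRubric <- function(rubric, file) {
  y <- lapply(split(rubric, rubric$subpart), function(d)
    as.list(stats::setNames(d$points, d$category)))
  yaml::write_yaml(y, file)
  invisible(file)
}

#' Points per category of one sub-part
#'
#' @param subpart sub-part name.
#' @param rubric rubric data.frame.
#' @return Named integer vector, categories in rubric order.
#' @export
categoryPoints <- function(subpart, rubric = defaultRubric()) {
  r <- rubric[rubric$subpart == subpart, , drop = FALSE]
  if (nrow(r) == 0L)
    stop("unknown subpart: ", subpart)
  stats::setNames(r$points, r$category)
}

#' Worst (lowest-scoring) category of a sub-part
#'
#' Fallback category when a sub-part cannot be evaluated (missing
#' detections or planes): an unevaluable sub-part must not inflate
#' quality.
#'
#' @inheritParams categoryPoints
#' @return Category name.
#' @export
worstCategory <- function(subpart, rubric = defaultRubric()) {
  pts <- categoryPoints(subpart, rubric)
  names(pts)[which.min(pts)]
}

#' Rubric lookup: points for a sub-part category
#'
#' @param subpart sub-part name.
#' @param category category name, valid for the sub-part.
#' @param rubric rubric data.frame.
#' @return Integer points.
#' @export
#' @examples
#' scoreSubpart("tracheal_carina", "flat")   # 5
scoreSubpart <- function(subpart, category, rubric = defaultRubric()) {
  pts <- categoryPoints(subpart, rubric)
  if (!category %in% names(pts))
    stop("invalid category '", category, "' for subpart '", subpart, "'")
  unname(pts[category])
}

#' Inspiration acceptability decision
#'
#' The inspiration task (carina + bronchial beam + rib) has a maximum
#' of 40 points; quality is acceptable iff the score strictly exceeds
#' half of it, i.e. > 20. A score of exactly 20 is inacceptable.
#'
#' @param score integer in 0..40.
#' @return \code{TRUE} iff acceptable.
#' @export
decideInspiration <- function(score) {
  if (score < 0 || score > 40)
    stop("inspiration score out of range 0..40: ", score)
  score > 20
}

#' Overall acceptability decision
#'
#' All eight sub-parts sum to at most 80 points; quality is acceptable
#' iff the total strictly exceeds 40.
#'
#' @param score integer in 0..80.
#' @return \code{TRUE} iff acceptable.
#' @export
decideOverall <- function(score) {
  if (score < 0 || score > 80)
    stop("overall score out of range 0..80: ", score)
  score > 40
}

#' Aggregate sub-part categories into a QualityReport
#'
#' @param categories named character vector mapping every one of the
#'   eight sub-parts to its assessed category.
#' @param patientID patient identifier.
#' @param rubric rubric data.frame.
#' @return A [QualityReport-class].
#' @export
#' @examples
#' best <- c(tracheal_carina = "convex", bronchial_beam = "visible",
#'           rib = "visible", scan_baseline = "both_correct",
#'           body_position = "inside", arms_position = "raised",
#'           radiation_protection = "both", artifact = "no_exist")
#' totalScore(aggregateReport(best))   # 80
aggregateReport <- function(categories, patientID = "patient",
                            rubric = defaultRubric()) {
  missing <- setdiff(subpartNames(), names(categories))
  if (length(missing))
    stop("incomplete assessment: missing ",
         paste(missing, collapse = ", "))
  sp <- data.frame(
    subpart = subpartNames(),
    category = unname(categories[subpartNames()]),
    stringsAsFactors = FALSE)
  sp$points <- mapply(scoreSubpart, sp$subpart, sp$category,
                      MoreArgs = list(rubric = rubric))
  insp <- sum(sp$points[sp$subpart %in% INSPIRATION_SUBPARTS])
  total <- sum(sp$points)
  new("QualityReport", patientID = patientID, subparts = sp,
      inspirationScore = as.integer(insp), totalScore = as.integer(total),
      inspirationAcceptable = decideInspiration(insp),
      overallAcceptable = decideOverall(total))
}

#' Serialize a QualityReport
#'
#' Writes the report as JSON (full structure) and/or CSV (the flat
#' one-row form of [as.data.frame.QualityReport()]).
#'
#' @param report a [QualityReport-class].
#' @param json,csv optional output paths.
#' @return The report, invisibly.
#' @export
writeReport <- function(report, json = NULL, csv = NULL) {
  if (!is.null(json)) {
    jsonlite::write_json(list(
      patient_id = report@patientID,
      subparts = report@subparts,
      inspiration_score = report@inspirationScore,
      total_score = report@totalScore,
      inspiration_acceptable = report@inspirationAcceptable,
      overall_acceptable = report@overallAcceptable),
      json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (!is.null(csv))
    utils::write.csv(as.data.frame(report), csv, row.names = FALSE)
  invisible(report)
}
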