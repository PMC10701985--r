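#' @import methods
NULL

VALID_PLANES <- c("coronal", "axial", "sagittal")

#' All eight evaluation sub-parts
#'
#' Names of the eight quality sub-parts assessed per patient, in rubric
#' order: the three inspiration sub-parts first (tracheal carina,
#' bronchial beam, rib), then position (scan baseline, body position,
#' arms position), radiation protection and artifact.
#'
#' @return Character vector of length 8.
#' @export
#' @examples
#' subpartNames()
subpartNames <- function() {
  c("tracheal_carina", "bronchial_beam", "rib",
    "scan_baseline", "body_position", "arms_position",
    "radiation_protection", "artifact")
}

INSPIRATION_SUBPARTS <- c("tracheal_carina", "bronchial_beam", "rib")

#' Detection label sets per task
#'
#' The category (label) vocabulary a detection backend may emit for each
#' detection-driven sub-part. Bronchial-beam clarity is graded visible,
#' fuzzy, double shadow or curly; rib clarity visible, corrugation,
#' double shadow or multiple shadows. The remaining tasks carry
#' presence-style labels.
#'
#' @return Named list mapping task name to its character label set.
#' @export
#' @examples
#' taskCategories()$rib
taskCategories <- function() {
  list(
    tracheal_carina      = "carina",
    bronchial_beam       = c("visible", "fuzzy", "double_shadow", "curly"),
    rib                  = c("visible", "corrugation", "double_shadow",
                             "multiple_shadows"),
    arms_position        = c("arms_raised", "arms_not_raised"),
    radiation_protection = c("neck_protection", "abdomen_protection"),
    artifact             = c("foreign_matter", "radial_artifact")
  )
}

# ---- BaselinePair -----------------------------------------------------------

#' @title Scan-baseline row pair
#'
#' @description Pixel rows (0-based, top-left origin, y increasing
#' downward) of the operator-set start and end scan baselines overlaid
#' on a localizer image. The start line is always above the end line.
#'
#' @slot yStart integer row of the starting baseline.
#' @slot yEnd integer row of the ending baseline.
#' @exportClass BaselinePair
setClass("BaselinePair",
  representation(yStart = "integer", yEnd = "integer"),
  validity = function(object) {
    if (length(object@yStart) != 1L || length(object@yEnd) != 1L)
      return("yStart and yEnd must be single integers")
    if (is.na(object@yStart) || is.na(object@yEnd))
      return("baseline rows must not be NA")
    if (object@yStart < 0L)
      return("yStart must be non-negative")
    if (object@yStart >= object@yEnd)
      return("yStart must lie strictly above yEnd")
    TRUE
  })

#' Construct a BaselinePair
#'
#' @param yStart,yEnd 0-based pixel rows of the start and end baselines;
#'   the pair is sorted so the topmost row becomes the start.
#' @return A [BaselinePair-class] object.
#' @export
#' @examples
#' BaselinePair(40, 460)
BaselinePair <- function(yStart, yEnd) {
  rows <- sort(as.integer(c(yStart, yEnd)))
  new("BaselinePair", yStart = rows[1L], yEnd = rows[2L])
}

#' @describeIn BaselinePair-class Display the two baseline rows.
#' @param object A \code{BaselinePair}.
#' @export
setMethod("show", "BaselinePair", function(object) {
  cat(sprintf("BaselinePair: y_start = %d, y_end = %d\n",
              object@yStart, object@yEnd))
})

#' Baseline accessors
#'
#' @param x A [BaselinePair-class].
#' @return Integer pixel row (0-based).
#' @export
yStart <- function(x) x@yStart

#' @rdname yStart
#' @export
yEnd <- function(x) x@yEnd

# ---- CTSeries ---------------------------------------------------------------

#' @title A plane-tagged CT image series
#'
#' @description An ordered stack of 8-bit RGB images from one scan plane
#' of one patient, with an optional pair of scan-baseline rows extracted
#' from the localizer overlay. All images in a series share dimensions.
#' Images are stored as H x W x 3 numeric arrays with channel values in
#' 0..255.
#'
#' @slot patientID opaque patient identifier.
#' @slot plane one of \code{"coronal"}, \code{"axial"}, \code{"sagittal"}.
#' @slot images list of H x W x 3 arrays.
#' @slot baselines a [BaselinePair-class] or \code{NULL}.
#' @exportClass CTSeries
setClass("CTSeries",
  representation(patientID = "character", plane = "character",
                 images = "list", baselines = "ANY"),
  validity = function(object) {
    if (length(object@plane) != 1L || !object@plane %in% VALID_PLANES)
      return(sprintf("plane must be one of %s",
                     paste(VALID_PLANES, collapse = ", ")))
    if (length(object@images) == 0L)
      return("images must be non-empty")
    dims <- lapply(object@images, dim)
    for (d in dims) {
      if (is.null(d) || length(d) != 3L || d[3L] != 3L)
        return("every image must be an H x W x 3 array")
    }
    ref <- dims[[1L]]
    if (!all(vapply(dims, function(d) all(d == ref), logical(1))))
      return("all images in a series must share dimensions")
    if (!is.null(object@baselines)) {
      if (!is(object@baselines, "BaselinePair"))
        return("baselines must be a BaselinePair or NULL")
      h <- ref[1L]
      if (object@baselines@yEnd >= h)
        return("baseline rows must lie inside the image height")
    }
    TRUE
  })

#' Construct a CTSeries
#'
#' @param images list of H x W x 3 arrays (values 0..255). Single-channel
#'   matrices are replicated to three identical channels.
#' @param plane scan plane, one of coronal/axial/sagittal.
#' @param patientID patient identifier string.
#' @param baselines optional [BaselinePair-class].
#' @return A [CTSeries-class] object.
#' @export
#' @examples
#' img <- array(0, dim = c(8, 8, 3))
#' CTSeries(list(img), plane = "axial", patientID = "p1")
CTSeries <- function(images, plane, patientID = "patient",
                     baselines = NULL) {
  images <- lapply(images, function(im) {
    if (is.matrix(im)) im <- array(rep(im, 3L), dim = c(dim(im), 3L))
    im
  })
  new("CTSeries", patientID = patientID, plane = plane,
      images = images, baselines = baselines)
}

#' CTSeries accessors
#'
#' @param x A [CTSeries-class].
#' @return \code{seriesImages} the image list; \code{seriesPlane} the
#'   plane string; \code{seriesBaselines} the [BaselinePair-class] or
#'   \code{NULL}; \code{patientID} the identifier.
#' @export
seriesImages <- function(x) x@images

#' @rdname seriesImages
#' @export
seriesPlane <- function(x) x@plane

#' @rdname seriesImages
#' @export
seriesBaselines <- function(x) x@baselines

#' @rdname seriesImages
#' @export
patientID <- function(x) x@patientID

#' @describeIn CTSeries-class Summarise the series.
#' @param object A \code{CTSeries}.
#' @export
setMethod("show", "CTSeries", function(object) {
  d <- dim(object@images[[1L]])
  cat(sprintf("CTSeries '%s': %d %s image(s), %d x %d px%s\n",
              object@patientID, length(object@images), object@plane,
              d[1L], d[2L],
              if (is.null(object@baselines)) "" else ", baselines attached"))
})

# ---- QualityReport ----------------------------------------------------------

#' @title Per-patient quality report
#'
#' @description The scored result of a full eight-sub-part assessment:
#' the category and rubric points per sub-part, the inspiration score
#' (tracheal carina + bronchial beam + rib, maximum 40), the overall
#' total (maximum 80), and the two binary acceptability decisions
#' (acceptable iff the score strictly exceeds half its maximum, i.e.
#' > 20 and > 40 respectively).
#'
#' @slot patientID patient identifier.
#' @slot subparts data.frame with columns subpart, category, points
#'   (one row per sub-part, all eight present).
#' @slot inspirationScore integer in 0..40.
#' @slot totalScore integer in 0..80.
#' @slot inspirationAcceptable logical.
#' @slot overallAcceptable logical.
#' @exportClass QualityReport
setClass("QualityReport",
  representation(patientID = "character", subparts = "data.frame",
                 inspirationScore = "integer", totalScore = "integer",
                 inspirationAcceptable = "logical",
                 overallAcceptable = "logical"),
  validity = function(object) {
    sp <- object@subparts
    if (!all(c("subpart", "category", "points") %in% names(sp)))
      return("subparts must have columns subpart, category, points")
    if (!setequal(sp$subpart, subpartNames()) ||
        nrow(sp) != length(subpartNames()))
      return("subparts must contain each of the 8 sub-parts exactly once")
    if (object@totalScore != sum(sp$points))
      return("totalScore must equal the sum of sub-part points")
    insp <- sum(sp$points[sp$subpart %in% INSPIRATION_SUBPARTS])
    if (object@inspirationScore != insp)
      return("inspirationScore must equal the sum of inspiration points")
    if (object@inspirationScore < 0L || object@inspirationScore > 40L)
      return("inspirationScore out of range 0..40")
    if (object@totalScore < 0L || object@totalScore > 80L)
      return("totalScore out of range 0..80")
    TRUE
  })

#' QualityReport accessors
#'
#' @param x A [QualityReport-class].
#' @return \code{reportSubparts} the per-sub-part data.frame;
#'   \code{inspirationScore}/\code{totalScore} integers;
#'   \code{inspirationAcceptable}/\code{overallAcceptable} logicals.
#' @export
reportSubparts <- function(x) x@subparts

#' @rdname reportSubparts
#' @export
inspirationScore <- function(x) x@inspirationScore

#' @rdname reportSubparts
#' @export
totalScore <- function(x) x@totalScore

#' @rdname reportSubparts
#' @export
inspirationAcceptable <- function(x) x@inspirationAcceptable

#' @rdname reportSubparts
#' @export
overallAcceptable <- function(x) x@overallAcceptable

#' @describeIn QualityReport-class Print the scored rubric.
#' @param object A \code{QualityReport}.
#' @export
setMethod("show", "QualityReport", function(object) {
  cat(sprintf("QualityReport for '%s'\n", object@patientID))
  sp <- object@subparts
  for (i in seq_len(nrow(sp)))
    cat(sprintf("  %-20s %-18s %2d\n", sp$subpart[i], sp$category[i],
                sp$points[i]))
  cat(sprintf("  inspiration: %d/40 (%s)\n", object@inspirationScore,
              if (object@inspirationAcceptable) "acceptable"
              else "inacceptable"))
  cat(sprintf("  overall:     %d/80 (%s)\n", object@totalScore,
              if (object@overallAcceptable) "acceptable"
              else "inacceptable"))
})

#' Coerce a QualityReport to a one-row data.frame
#'
#' @param x A [QualityReport-class].
#' @param row.names,optional,... passed for S3 compatibility (unused).
#' @return A one-row data.frame with patient id, one points column per
#'   sub-part, the two scores and the two acceptability flags.
#' @export
as.data.frame.QualityReport <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  sp <- x@subparts
  pts <- as.list(sp$points)
  names(pts) <- sp$subpart
  cbind(data.frame(patient_id = x@patientID, stringsAsFactors = FALSE),
        as.data.frame(pts),
        data.frame(inspiration_score = x@inspirationScore,
                   total_score = x@totalScore,
                   inspiration_acceptable = x@inspirationAcceptable,
                   overall_acceptable = x@overallAcceptable))
}
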