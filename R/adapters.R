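# Backend seams for object detection and semantic segmentation, the
# confidence filter applied to every detection list entering the
# decision algorithms, and a deterministic scripted mock backend.
#
# A detection table is a data.frame with one row per box and columns
#   image_index (1-based within the series), label, confidence,
#   xmin, ymin, xmax, ymax   (pixels, 0-based, half-open).

DETECTION_COLS <- c("image_index", "label", "confidence",
                    "xmin", "ymin", "xmax", "ymax")

#' An empty detection table
#'
#' @return Zero-row data.frame with the detection-table columns.
#' @export
emptyDetections <- function() {
  data.frame(image_index = integer(), label = character(),
             confidence = numeric(), xmin = numeric(), ymin = numeric(),
             xmax = numeric(), ymax = numeric(), stringsAsFactors = FALSE)
}

#' Construct/validate a detection table
#'
#' @param df data.frame with the detection-table columns.
#' @param task optional task name; when given, labels must belong to the
#'   task's category set.
#' @return The validated data.frame.
#' @export
detectionTable <- function(df, task = NULL) {
  if (!all(DETECTION_COLS %in% names(df)))
    stop("detection table must have columns ",
         paste(DETECTION_COLS, collapse = ", "))
  df <- df[, DETECTION_COLS, drop = FALSE]
  if (nrow(df)) {
    if (any(df$confidence < 0 | df$confidence > 1))
      stop("confidence must lie in [0, 1]")
    if (any(df$xmin >= df$xmax | df$ymin >= df$ymax))
      stop("boxes must satisfy xmin < xmax and ymin < ymax")
    if (!is.null(task)) {
      cats <- taskCategories()[[task]]
      bad <- setdiff(unique(df$label), cats)
      if (length(bad))
        stop("labels outside the '", task, "' category set: ",
             paste(bad, collapse = ", "))
    }
  }
  df
}

#' Filter detections by confidence
#'
#' Keeps only boxes whose confidence strictly exceeds \code{minScore}
#' (default 0.70, so a box at exactly 0.70 is dropped). Order is
#' preserved; the result is a subsequence of the input.
#'
#' @param boxes detection table.
#' @param minScore confidence cutoff (default 0.70).
#' @return Detection table containing the surviving rows.
#' @export
#' @examples
#' d <- emptyDetections()
#' filterDetections(d)   # empty in, empty out
filterDetections <- function(boxes, minScore = 0.70) {
  boxes[boxes$confidence > minScore, , drop = FALSE]
}

# ---- generics ---------------------------------------------------------------

#' Run a detection backend over a series
#'
#' @param backend a detector backend object.
#' @param series a [CTSeries-class].
#' @param task one of the eight sub-part names; the returned boxes carry
#'   labels only from that task's category set.
#' @return Unfiltered detection table (callers apply
#'   [filterDetections()]).
#' @export
setGeneric("detect", function(backend, series, task)
  standardGeneric("detect"))

#' Run a segmentation backend on one image
#'
#' @param backend a segmenter backend object.
#' @param image H x W x 3 array.
#' @param target one of \code{"tracheal_carina"}, \code{"body_contour"},
#'   \code{"lung_contour"}.
#' @return H x W x 3 mask array aligned to \code{image}.
#' @export
setGeneric("segmentROI", function(backend, image, target)
  standardGeneric("segmentROI"))

SEGMENT_TARGETS <- c("tracheal_carina", "body_contour", "lung_contour")

# ---- scripted mock backend --------------------------------------------------

#' @title Scripted mock detector
#'
#' @description Deterministic detection backend that replays a scripted
#' table of boxes keyed by (plane, task, image index). Images with no
#' entry yield no boxes. Used to exercise the decision layer without a
#' trained model.
#'
#' @slot script data.frame with columns plane, task and the
#'   detection-table columns.
#' @exportClass MockDetector
setClass("MockDetector", representation(script = "data.frame"))

#' Construct a scripted mock detector
#'
#' @param script data.frame with columns \code{plane}, \code{task},
#'   \code{image_index}, \code{label}, \code{confidence}, \code{xmin},
#'   \code{ymin}, \code{xmax}, \code{ymax}; or a path to a JSON fixture
#'   holding the same records.
#' @return A [MockDetector-class].
#' @export
MockDetector <- function(script = NULL) {
  if (is.character(script))
    script <- as.data.frame(jsonlite::read_json(script,
                                                simplifyVector = TRUE))
  if (is.null(script) || nrow(script) == 0L) {
    script <- cbind(data.frame(plane = character(), task = character(),
                               stringsAsFactors = FALSE),
                    emptyDetections())
  }
  need <- c("plane", "task", DETECTION_COLS)
  if (!all(need %in% names(script)))
    stop("mock script must have columns ", paste(need, collapse = ", "))
  new("MockDetector", script = script[, need, drop = FALSE])
}

#' @describeIn MockDetector-class Replay scripted boxes for the series'
#'   plane and the requested task.
#' @inheritParams detect
#' @export
setMethod("detect", "MockDetector", function(backend, series, task) {
  if (!task %in% subpartNames())
    stop("unknown task: ", task)
  s <- backend@script
  s <- s[s$plane == seriesPlane(series) & s$task == task, , drop = FALSE]
  detectionTable(s[, DETECTION_COLS, drop = FALSE],
                 task = if (task %in% names(taskCategories())) task)
})

#' @title Scripted mock segmenter
#'
#' @description Deterministic segmentation backend returning fixture
#' masks keyed by target. The fixture mask must match the source image
#' dimensions (for the tracheal carina, the crop handed in by the
#' pipeline).
#'
#' @slot masks named list of H x W x 3 arrays keyed by target.
#' @exportClass MockSegmenter
setClass("MockSegmenter", representation(masks = "list"))

#' Construct a scripted mock segmenter
#'
#' @param masks named list of H x W x 3 arrays; names are segmentation
#'   targets.
#' @return A [MockSegmenter-class].
#' @export
MockSegmenter <- function(masks = list()) {
  new("MockSegmenter", masks = masks)
}

#' @describeIn MockSegmenter-class Return the scripted mask for the
#'   target, checking its size against the source image.
#' @inheritParams segmentROI
#' @export
setMethod("segmentROI", "MockSegmenter", function(backend, image, target) {
  if (!target %in% SEGMENT_TARGETS)
    stop("unknown segmentation target: ", target)
  mask <- backend@masks[[target]]
  if (is.null(mask))
    stop("mock segmenter has no mask for target: ", target)
  if (is.matrix(mask))
    mask <- array(rep(mask, 3L), dim = c(dim(mask), 3L))
  if (!all(dim(mask)[1:2] == dim(image)[1:2]))
    stop("mask/source size mismatch")
  mask
})

#' Look up a detector backend by registry name
#'
#' Registry seam keyed by configuration name. Only the deterministic
#' \code{"mock"} backend ships with the package; adapters for trained
#' models plug in here.
#'
#' @param name backend name.
#' @param ... passed to the backend constructor.
#' @return A detector backend object.
#' @export
detectorBackend <- function(name, ...) {
  switch(name,
    mock = MockDetector(...),
    stop("unknown detector backend: ", name))
}
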