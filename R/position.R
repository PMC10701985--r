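# Position-evaluation decision algorithms: region measurement (is the
# body centred in the scan FOV?), distance measurement (are the start
# and end scan baselines aligned with the lung extent?), and arms
# position. All pixel coordinates are 0-based, top-left origin.

#' Centroid of a binary body mask
#'
#' Mean (x, y) of the foreground pixels, 0-based.
#'
#' @param mask H x W matrix of 0/1 values (see [binarize()]).
#' @return Named numeric vector \code{c(x = , y = )}.
#' @export
#' @examples
#' m <- matrix(0, 60, 60); m[41:50, 21:30] <- 1
#' bodyCentroid(m)   # x = 24.5, y = 44.5
bodyCentroid <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    stop("no body contour")
  c(x = mean(idx[, 2L]) - 1, y = mean(idx[, 1L]) - 1)
}

#' Geometric centre of an image
#'
#' @param image matrix or array whose first two dimensions are H, W.
#' @return Named numeric vector \code{c(x = (W-1)/2, y = (H-1)/2)}.
#' @export
imageCenter <- function(image) {
  d <- dim(image)
  c(x = (d[2L] - 1) / 2, y = (d[1L] - 1) / 2)
}

#' Region-measurement centring decision
#'
#' Euclidean distance between the body-contour centroid (the "blue"
#' point) and the image centre (the "green" point, centre of a circle
#' of the given radius). The body is inside the scan FOV centre region
#' iff distance < radius (strict by default; set
#' \code{comparator = "le"} for distance <= radius).
#'
#' @param blue body centroid, \code{c(x, y)}.
#' @param green image centre, \code{c(x, y)}.
#' @param radius circle radius in pixels (default 50).
#' @param comparator \code{"lt"} (default) or \code{"le"}.
#' @return List with \code{bodyCentroid}, \code{imageCenter},
#'   \code{distance} and \code{decision} (\code{"inside"} or
#'   \code{"outside"}).
#' @export
#' @examples
#' regionDecision(c(44, 30), c(0, 0))$distance   # sqrt(2836) ~ 53.25
regionDecision <- function(blue, green, radius = 50,
                           comparator = c("lt", "le")) {
  comparator <- match.arg(comparator)
  stopifnot(radius > 0)
  d <- sqrt(sum((as.numeric(blue[1:2]) - as.numeric(green[1:2]))^2))
  inside <- if (comparator == "lt") d < radius else d <= radius
  list(bodyCentroid = blue, imageCenter = green, distance = d,
       decision = if (inside) "inside" else "outside")
}

#' Tight bounding box of a binary lung mask
#'
#' @param mask H x W matrix of 0/1 values.
#' @return Named numeric vector \code{c(y_top, y_bottom, x_left,
#'   x_right)}, 0-based inclusive.
#' @export
lungBBox <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    stop("no lung contour")
  c(y_top = min(idx[, 1L]) - 1, y_bottom = max(idx[, 1L]) - 1,
    x_left = min(idx[, 2L]) - 1, x_right = max(idx[, 2L]) - 1)
}

#' Distance-measurement baseline-alignment decision
#'
#' Signed distances from the lung bounding box to the scan baselines:
#' \code{distance_start = y_top - y_start} (start line above the lung)
#' and \code{distance_end = y_end - y_bottom} (end line below it). A
#' baseline is accurately placed iff 0 <= D <= T. A negative D means
#' the baseline crosses the lung extent, truncating anatomy, and is
#' inaccurate.
#'
#' @param box lung bounding box from [lungBBox()] (or any vector with
#'   \code{y_top} and \code{y_bottom}).
#' @param baselines a [BaselinePair-class] or numeric \code{c(yStart,
#'   yEnd)}.
#' @param tolerance T, the pixel tolerance (default 15).
#' @return List with the box rows, both signed distances and both
#'   decisions (\code{"accurate"}/\code{"inaccurate"}).
#' @export
#' @examples
#' b <- c(y_top = 100, y_bottom = 400)
#' baselineAlignment(b, BaselinePair(85, 410))   # D = 15, 10: both accurate
baselineAlignment <- function(box, baselines, tolerance = 15) {
  if (is(baselines, "BaselinePair"))
    baselines <- c(yStart(baselines), yEnd(baselines))
  dStart <- box[["y_top"]] - baselines[1L]
  dEnd <- baselines[2L] - box[["y_bottom"]]
  ok <- function(d) if (d >= 0 && d <= tolerance) "accurate" else "inaccurate"
  list(y_boxtop = box[["y_top"]], y_boxbottom = box[["y_bottom"]],
       distance_start = dStart, distance_end = dEnd,
       decision_start = ok(dStart), decision_end = ok(dEnd))
}

#' Scan-baseline rubric category
#'
#' @param alignment result of [baselineAlignment()].
#' @return \code{"both_correct"}, \code{"one_correct"} or
#'   \code{"none_correct"}.
#' @export
scanBaselineCategory <- function(alignment) {
  n <- sum(alignment$decision_start == "accurate",
           alignment$decision_end == "accurate")
  c("none_correct", "one_correct", "both_correct")[n + 1L]
}

#' Arms-position rubric category
#'
#' Scans the filtered detections of a coronal series. Any
#' arms-not-raised box dominates (worst case wins when contradictory
#' evidence co-occurs); otherwise an arms-raised box yields raised; no
#' boxes at all fall back to the worst category.
#'
#' @param series coronal [CTSeries-class].
#' @param detector detection backend.
#' @param minScore confidence cutoff (default 0.70).
#' @return \code{"raised"} or \code{"not_raised"}.
#' @export
armsPositionCategory <- function(series, detector, minScore = 0.70) {
  boxes <- filterDetections(detect(detector, series, "arms_position"),
                            minScore)
  if (any(boxes$label == "arms_not_raised")) return("not_raised")
  if (any(boxes$label == "arms_raised")) return("raised")
  "not_raised"
}
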