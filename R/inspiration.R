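# Inspiration-adequacy algorithms: pixel-threshold (PT) classification
# of tri-colour tracheal carina masks, carina-image selection, and the
# neural-statistics (NS) tally over detection boxes for bronchial beam
# and rib clarity.

PT_WHITE_RANGE <- c(200, 255)
PT_COLOR_RANGE <- c(150, 255)

MORPHOLOGY_OF_COLOR <- c(white = "convex", green = "flat", red = "concave")

# argmax with ties broken toward the lowest rubric score: ambiguous
# evidence is penalized rather than rewarded
argmaxLowestScore <- function(counts, points) {
  stopifnot(all(names(counts) %in% names(points)))
  top <- names(counts)[counts == max(counts)]
  top[which.min(points[top])]
}

#' Classify one RGB pixel of a carina mask
#'
#' A pixel is white when all three channels lie in [200, 255]; otherwise
#' green when the green channel lies in [150, 255] and is at least the
#' red channel; otherwise red when the red channel lies in [150, 255];
#' otherwise unclassified. White is tested first because its condition
#' is the most specific (a white pixel also satisfies both colour
#' branches); remaining green/red overlap is resolved by the larger
#' channel, green winning exact ties.
#'
#' @param r,g,b 8-bit channel values (0..255).
#' @return One of \code{"white"}, \code{"green"}, \code{"red"},
#'   \code{"unclassified"}.
#' @export
#' @examples
#' classifyPixel(255, 255, 255)  # white
#' classifyPixel(100, 200, 100)  # green
#' classifyPixel(200, 100, 100)  # red
classifyPixel <- function(r, g, b) {
  vals <- c(r, g, b)
  if (any(vals < 0 | vals > 255) || any(is.na(vals)))
    stop("invalid channel value")
  if (all(vals >= PT_WHITE_RANGE[1L] & vals <= PT_WHITE_RANGE[2L]))
    return("white")
  if (g >= PT_COLOR_RANGE[1L] && g <= PT_COLOR_RANGE[2L] && g >= r)
    return("green")
  if (r >= PT_COLOR_RANGE[1L] && r <= PT_COLOR_RANGE[2L])
    return("red")
  "unclassified"
}

#' Pixel-threshold classification of a carina mask
#'
#' Counts white, green and red pixels over the whole tri-colour
#' segmentation mask (see [classifyPixel()]) and returns the carina
#' morphology with the highest count: white encodes convex, green flat,
#' red concave. Count ties break toward the lower-scoring morphology
#' (concave < flat < convex).
#'
#' @param mask H x W x 3 array, channel values 0..255.
#' @return List with \code{morphology} (one of convex/flat/concave) and
#'   \code{counts}, a named vector (white, green, red, unclassified)
#'   summing to H*W.
#' @export
#' @examples
#' m <- array(0, dim = c(4, 4, 3))
#' m[1:2, , 1] <- 255; m[1:2, , 2] <- 255; m[1:2, , 3] <- 255
#' ptClassify(m)$morphology   # convex
ptClassify <- function(mask) {
  if (!is.array(mask) || length(dim(mask)) != 3L || dim(mask)[3L] != 3L)
    stop("invalid image")
  R <- mask[, , 1L]; G <- mask[, , 2L]; B <- mask[, , 3L]
  if (any(mask < 0 | mask > 255))
    stop("invalid channel value")
  white <- R >= 200 & R <= 255 & G >= 200 & G <= 255 & B >= 200 & B <= 255
  green <- !white & G >= 150 & G <= 255 & G >= R
  red   <- !white & !green & R >= 150 & R <= 255
  counts <- c(white = sum(white), green = sum(green), red = sum(red))
  counts <- c(counts, unclassified = length(R) - sum(counts))
  if (sum(counts[c("white", "green", "red")]) == 0L)
    stop("no mask content")
  pts <- c(white = 10, green = 5, red = 0)  # convex/flat/concave scores
  winner <- argmaxLowestScore(counts[c("white", "green", "red")], pts)
  list(morphology = unname(MORPHOLOGY_OF_COLOR[winner]), counts = counts)
}

#' Select the carina image from an axial series
#'
#' A CT series typically contains one image best showing the tracheal
#' carina; it is taken as the image holding the highest-confidence
#' carina detection after the confidence filter. Confidence ties break
#' toward the lowest image index, then toward the first-listed box.
#'
#' @param series axial [CTSeries-class].
#' @param detector detection backend.
#' @param minScore confidence cutoff (default 0.70).
#' @return List with \code{imageIndex} (1-based), \code{image} and
#'   \code{box} (one-row detection table).
#' @export
selectCarinaImage <- function(series, detector, minScore = 0.70) {
  boxes <- filterDetections(detect(detector, series, "tracheal_carina"),
                            minScore)
  if (nrow(boxes) == 0L)
    stop("carina not found")
  boxes <- boxes[order(-boxes$confidence, boxes$image_index), , drop = FALSE]
  best <- boxes[1L, , drop = FALSE]
  list(imageIndex = best$image_index,
       image = seriesImages(series)[[best$image_index]],
       box = best)
}

#' Crop an image to a detection box
#'
#' @param image H x W x 3 array.
#' @param box one-row detection table or vector with xmin, ymin, xmax,
#'   ymax (0-based, half-open).
#' @return The (ymax-ymin) x (xmax-xmin) x 3 crop.
#' @export
cropToBox <- function(image, box) {
  if (is.data.frame(box)) box <- unlist(box[1L, c("xmin", "ymin",
                                                  "xmax", "ymax")])
  rows <- (box[["ymin"]] + 1):box[["ymax"]]
  cols <- (box[["xmin"]] + 1):box[["xmax"]]
  image[rows, cols, , drop = FALSE]
}

#' Neural-statistics category assessment over a series
#'
#' Mimics a radiologist reviewing many images: every filtered detection
#' box across the whole series (or several series) is tallied by
#' category, and the category with the highest box count wins. Count
#' ties break toward the lower-scoring category. An image contributing
#' two boxes of one category counts twice.
#'
#' @param series a [CTSeries-class] or list of them (e.g. the axial and
#'   sagittal stacks).
#' @param detector detection backend.
#' @param task \code{"bronchial_beam"} or \code{"rib"}.
#' @param minScore confidence cutoff (default 0.70).
#' @param rubric scoring rubric used for the tie order (default
#'   [defaultRubric()]).
#' @return List with \code{category} and \code{tally}, a named count
#'   vector over the full task category set.
#' @export
nsAssess <- function(series, detector, task, minScore = 0.70,
                     rubric = defaultRubric()) {
  if (!task %in% c("bronchial_beam", "rib"))
    stop("nsAssess handles tasks bronchial_beam and rib, got: ", task)
  if (is(series, "CTSeries")) series <- list(series)
  cats <- taskCategories()[[task]]
  tally <- stats::setNames(integer(length(cats)), cats)
  for (s in series) {
    kept <- filterDetections(detect(detector, s, task), minScore)
    if (nrow(kept)) {
      tab <- table(factor(kept$label, levels = cats))
      tally <- tally + as.integer(tab)
    }
  }
  if (sum(tally) == 0L)
    stop("no detections")
  pts <- categoryPoints(task, rubric)
  list(category = argmaxLowestScore(tally, pts), tally = tally)
}
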