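# Series loading and the grayscale/binarization primitives shared by the
# geometry algorithms. Pixel coordinates are 0-based (top-left origin, x
# rightward, y downward); image indices within a series are 1-based.

#' Read one 8-bit image file
#'
#' Reads a PNG or TIFF file into an H x W x 3 array with channel values
#' in 0..255. Grayscale sources are replicated across the three
#' channels; an alpha channel, if present, is dropped.
#'
#' @param file path to a .png, .tif or .tiff file.
#' @return H x W x 3 numeric array, values in 0..255.
#' @export
readImage8 <- function(file) {
  ext <- tolower(tools::file_ext(file))
  px <- switch(ext,
    png  = png::readPNG(file),
    tif  = ,
    tiff = tiff::readTIFF(file),
    stop("unsupported image format: ", ext))
  px <- round(px * 255)
  if (is.matrix(px))
    px <- array(rep(px, 3L), dim = c(dim(px), 3L))
  if (dim(px)[3L] >= 4L)
    px <- px[, , 1:3, drop = FALSE]
  if (dim(px)[3L] == 1L)
    px <- array(rep(px, 3L), dim = c(dim(px)[1:2], 3L))
  px
}

#' Load a CT series from a directory
#'
#' Reads every PNG/TIFF image in \code{path} in lexicographic filename
#' order into a [CTSeries-class]. If a \code{baselines.json} sidecar is
#' present it is parsed with [extractBaselines()] and attached.
#'
#' @param path directory containing at least one readable image file.
#' @param plane scan plane tag for the series.
#' @param patientID identifier; defaults to the directory name.
#' @return A [CTSeries-class].
#' @export
loadSeries <- function(path, plane, patientID = basename(path)) {
  files <- list.files(path, pattern = "\\.(png|tif|tiff)$",
                      ignore.case = TRUE, full.names = TRUE)
  files <- sort(files)
  if (length(files) == 0L)
    stop("no images in ", path)
  images <- lapply(files, readImage8)
  dims <- lapply(images, dim)
  if (!all(vapply(dims, function(d) all(d == dims[[1L]]), logical(1))))
    stop("inconsistent series: images differ in dimensions")
  sidecar <- file.path(path, "baselines.json")
  baselines <- if (file.exists(sidecar)) extractBaselines(sidecar) else NULL
  CTSeries(images, plane = plane, patientID = patientID,
           baselines = baselines)
}

#' Extract the scan-baseline rows
#'
#' Recovers the start and end scan-baseline rows that an operator drew
#' on the localizer. Two dialects are accepted: a JSON sidecar
#' \code{\{"y_start": r1, "y_end": r2\}}, or an overlay bitmap (a path
#' to a PNG/TIFF, a matrix, or an H x W x 3 array) in which the baseline
#' rows are the only non-zero pixels. In the bitmap dialect each maximal
#' run of consecutive non-zero rows is one horizontal segment; exactly
#' two segments must be present, and the middle row of each segment is
#' reported (0-based). The topmost segment is the start regardless of
#' storage order.
#'
#' @param x sidecar path, bitmap path, matrix or array as above.
#' @return A [BaselinePair-class].
#' @export
#' @examples
#' ov <- matrix(0, 500, 64); ov[41, ] <- 1; ov[461, ] <- 1
#' extractBaselines(ov)   # rows 40 and 460, 0-based
extractBaselines <- function(x) {
  if (is.character(x)) {
    if (!file.exists(x))
      stop("missing baseline overlay: ", x)
    if (tolower(tools::file_ext(x)) == "json") {
      j <- jsonlite::read_json(x)
      if (is.null(j$y_start) || is.null(j$y_end))
        stop("missing baseline overlay: sidecar lacks y_start/y_end")
      return(BaselinePair(j$y_start, j$y_end))
    }
    x <- readImage8(x)
  }
  if (is.array(x) && length(dim(x)) == 3L)
    x <- toGray(x)
  if (!is.matrix(x))
    stop("invalid image")
  setRows <- which(rowSums(x != 0) > 0)   # 1-based
  if (length(setRows) == 0L)
    stop("missing baseline overlay: no set rows")
  # group consecutive rows into segments
  breaks <- c(0L, which(diff(setRows) > 1L), length(setRows))
  segs <- mapply(function(a, b) setRows[(a + 1L):b],
                 utils::head(breaks, -1L), breaks[-1L], SIMPLIFY = FALSE)
  if (length(segs) != 2L)
    stop("ambiguous overlay: expected 2 horizontal segments, found ",
         length(segs))
  mids <- vapply(segs, function(s) s[ceiling(length(s) / 2)], numeric(1))
  BaselinePair(min(mids) - 1L, max(mids) - 1L)   # to 0-based
}

#' Convert an image to grayscale
#'
#' Unweighted mean of the three channels; a matrix passes through.
#'
#' @param image H x W x 3 array or H x W matrix.
#' @return H x W numeric matrix.
#' @export
toGray <- function(image) {
  if (is.matrix(image)) return(image)
  if (!is.array(image) || length(dim(image)) != 3L)
    stop("invalid image")
  (image[, , 1L] + image[, , 2L] + image[, , 3L]) / 3
}

#' Binarize an image at an intensity threshold
#'
#' Converts to grayscale (channel mean) and maps each pixel to 1 iff
#' its intensity is greater than or equal to \code{threshold}, else 0.
#' The default threshold of 5 separates painted mask foreground from a
#' black background.
#'
#' @param image H x W x 3 array or H x W matrix, values 0..255.
#' @param threshold intensity cut (default 5).
#' @return H x W matrix of 0/1 values.
#' @export
#' @examples
#' binarize(matrix(c(0, 4, 5, 255), 2, 2))
binarize <- function(image, threshold = 5) {
  if (!is.numeric(image) || (!is.matrix(image) && !is.array(image)))
    stop("invalid image")
  g <- toGray(image)
  (g >= threshold) * 1
}
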