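# Synthetic fixture generation. Everything the pipeline consumes can be
# generated here under a seed: tri-colour carina masks, body/lung
# contour images with controlled geometry, baseline pairs, and scripted
# detection streams. Ground truth is derived analytically from the
# generation parameters at generation time -- never by running the
# pipeline -- so closed-loop tests cannot be circular.

#' Generate a tri-colour carina mask with known morphology
#'
#' Paints disjoint pixel sets in colours near white (227,227,227),
#' green (20,200,20) and red (200,20,20) on a black background, with
#' bounded uniform channel noise that can never cross a classification
#' threshold. The expected morphology is the argmax of the painted
#' counts, ties toward the lower-scoring morphology.
#'
#' @param fractions named numeric \code{c(white=, green=, red=)}, pixel
#'   fractions summing to at most 1.
#' @param size \code{c(H, W)} of the mask.
#' @param noise half-width of the uniform channel noise in intensity
#'   units (default 10; values above 27 could push a white channel
#'   below 200 and are rejected as ambiguous).
#' @param seed optional RNG seed for a self-contained call.
#' @return List with \code{mask} (H x W x 3 array), \code{counts}
#'   (painted pixels per colour) and \code{expected} morphology (NA if
#'   nothing was painted).
#' @export
genCarinaMask <- function(fractions, size = c(48, 48), noise = 10,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fractions <- fractions[c("white", "green", "red")]
  fractions[is.na(fractions)] <- 0
  if (sum(fractions) > 1)
    stop("fractions must sum to at most 1")
  if (noise > 27)
    stop("ambiguous spec: noise of ", noise,
         " can cross a classification threshold")
  H <- size[1L]; W <- size[2L]; n <- H * W
  counts <- round(fractions * n)
  over <- sum(counts) - n
  if (over > 0) counts["white"] <- counts["white"] - over
  idx <- sample.int(n, sum(counts))
  split <- rep(names(counts), counts)
  base <- list(white = c(227, 227, 227), green = c(20, 200, 20),
               red = c(200, 20, 20))
  mask <- array(0, dim = c(H, W, 3L))
  for (col in names(counts)) {
    px <- idx[split == col]
    if (length(px) == 0L) next
    for (ch in 1:3) {
      jitter <- sample(seq(-noise, noise), length(px), replace = TRUE)
      mask[px + (ch - 1L) * n] <- pmin(255, pmax(0, base[[col]][ch] + jitter))
    }
  }
  expected <- if (sum(counts) == 0L) NA_character_ else {
    pts <- c(white = 10, green = 5, red = 0)
    morph <- c(white = "convex", green = "flat", red = "concave")
    unname(morph[argmaxLowestScore(counts, pts)])
  }
  list(mask = mask, counts = counts, expected = expected)
}

#' Generate body/lung contour images with controlled geometry
#'
#' The body image holds a filled white rectangle of odd extents whose
#' centroid sits exactly at the image centre plus \code{bodyOffset};
#' the lung image holds a white block whose bounding-box rows are
#' placed so that the signed baseline distances are exactly
#' \code{dStart} and \code{dEnd} for the returned [BaselinePair-class].
#' Expected categories are derived from the centring rule (distance <
#' radius) and the alignment rule (0 <= D <= tolerance).
#'
#' @param size \code{c(H, W)}; odd dimensions keep the image centre on
#'   an integer pixel (default 161 x 161).
#' @param bodyOffset integer \code{c(dx, dy)} of the body centroid from
#'   the image centre.
#' @param dStart,dEnd target signed distances (pixels) from the lung
#'   box to the start and end baselines.
#' @param yStartLine,yEndLine baseline rows (defaults 20 and H - 21).
#' @param radius,tolerance decision parameters used for the expected
#'   categories (defaults 50 and 15).
#' @return List with \code{body}, \code{lung} (H x W x 3 arrays),
#'   \code{baselines}, \code{expected} (list with body_position and
#'   scan_baseline categories) and the exact \code{centroid}.
#' @export
genPositionImages <- function(size = c(161, 161), bodyOffset = c(0, 0),
                              dStart = 10, dEnd = 10,
                              yStartLine = 20, yEndLine = size[1L] - 21,
                              radius = 50, tolerance = 15) {
  H <- size[1L]; W <- size[2L]
  stopifnot(H %% 2L == 1L, W %% 2L == 1L)
  cx <- (W - 1L) / 2L; cy <- (H - 1L) / 2L
  halfW <- 10L; halfH <- 14L   # odd extents 21 x 29
  bx <- cx + bodyOffset[1L]; by <- cy + bodyOffset[2L]
  if (bx - halfW < 0 || bx + halfW > W - 1 ||
      by - halfH < 0 || by + halfH > H - 1)
    stop("body offset pushes the blob outside the image")
  body <- array(0, dim = c(H, W, 3L))
  body[(by - halfH + 1):(by + halfH + 1),
       (bx - halfW + 1):(bx + halfW + 1), ] <- 255
  yTop <- yStartLine + dStart
  yBottom <- yEndLine - dEnd
  if (yTop < 0 || yBottom > H - 1 || yTop >= yBottom)
    stop("requested baseline distances do not fit the image")
  lung <- array(0, dim = c(H, W, 3L))
  lung[(yTop + 1):(yBottom + 1), 41:(W - 40), ] <- 255
  dist <- sqrt(sum(bodyOffset^2))
  aligned <- function(d) d >= 0 && d <= tolerance
  nOK <- aligned(dStart) + aligned(dEnd)
  list(body = body, lung = lung,
       baselines = BaselinePair(yStartLine, yEndLine),
       centroid = c(x = bx, y = by),
       expected = list(
         body_position = if (dist < radius) "inside" else "outside",
         scan_baseline = c("none_correct", "one_correct",
                           "both_correct")[nOK + 1L]))
}

randomBox <- function(n, size = c(161, 161)) {
  x0 <- sample(0:(size[2L] - 41L), n, replace = TRUE)
  y0 <- sample(0:(size[1L] - 41L), n, replace = TRUE)
  data.frame(xmin = x0, ymin = y0,
             xmax = x0 + sample(20:40, n, replace = TRUE),
             ymax = y0 + sample(20:40, n, replace = TRUE))
}

#' Generate a scripted detection stream with known NS outcome
#'
#' Emits \code{counts[cat]} boxes per category with confidences above
#' the 0.70 cutoff, spread over \code{nImages} images, plus optional
#' below-cutoff distractor boxes that the filter must remove. The
#' expected final category is the argmax of \code{counts} (tie toward
#' the lower-scoring category); it is \code{NA} when all counts are
#' zero.
#'
#' @param task \code{"bronchial_beam"} or \code{"rib"}.
#' @param counts named integer vector over the task's category set
#'   (missing categories count 0).
#' @param nImages number of images in the stream (default 5).
#' @param plane plane tag written into the script (default
#'   \code{"axial"}).
#' @param nBelow number of distractor boxes with confidence <= 0.70
#'   (default 0).
#' @param size image size for box coordinates.
#' @param seed optional RNG seed.
#' @return List with \code{script} (mock-detector rows) and
#'   \code{expected} category.
#' @export
genDetectionStream <- function(task, counts, nImages = 5,
                               plane = "axial", nBelow = 0,
                               size = c(161, 161), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cats <- taskCategories()[[task]]
  full <- stats::setNames(integer(length(cats)), cats)
  full[names(counts)] <- as.integer(counts)
  n <- sum(full)
  rows <- data.frame(plane = character(), task = character(),
                     stringsAsFactors = FALSE)
  script <- cbind(
    data.frame(plane = rep(plane, n + nBelow),
               task = rep(task, n + nBelow),
               image_index = sample.int(nImages, n + nBelow,
                                        replace = TRUE),
               label = c(rep(names(full), full),
                         sample(cats, nBelow, replace = TRUE)),
               confidence = c(stats::runif(n, 0.71, 0.99),
                              stats::runif(nBelow, 0.30, 0.70)),
               stringsAsFactors = FALSE),
    randomBox(n + nBelow, size))
  expected <- if (n == 0L) NA_character_ else
    argmaxLowestScore(full, categoryPoints(task))
  list(script = script, expected = expected)
}

#' Draw a random fixture specification
#'
#' Samples one category uniformly for each of the eight sub-parts plus
#' the geometry consistent with it. The implied ground-truth points and
#' scores are carried by [genPatient()].
#'
#' @param seed integer seed; the spec (and the fixture built from it)
#'   is a pure function of it.
#' @return A fixture spec list (seed plus target categories).
#' @export
randomFixtureSpec <- function(seed) {
  set.seed(seed)
  rubric <- defaultRubric()
  categories <- vapply(subpartNames(), function(sp) {
    cats <- rubric$category[rubric$subpart == sp]
    sample(cats, 1L)
  }, character(1))
  list(seed = seed, categories = categories)
}

carinaFractionsFor <- function(morphology) {
  # dominant colour strictly ahead so the analytic argmax is unambiguous
  dominant <- c(convex = "white", flat = "green", concave = "red")[morphology]
  f <- c(white = 0.05, green = 0.10, red = 0.02)
  f[dominant] <- 0.5
  f
}

offsetFor <- function(decision) {
  # inside: |offset| <= 30 each axis -> distance <= sqrt(1800) < 50
  # outside: dx >= 50 -> distance >= 50 whatever dy
  if (decision == "inside")
    c(sample(-30:30, 1L), sample(-30:30, 1L))
  else
    c(sample(50:60, 1L) * sample(c(-1L, 1L), 1L), sample(-20:20, 1L))
}

baselineDistancesFor <- function(category) {
  good <- function() sample(0:15, 1L)
  bad <- function() if (stats::runif(1) < 0.3) sample(-5:-1, 1L)
         else sample(16:24, 1L)
  switch(category,
    both_correct = c(good(), good()),
    one_correct = if (stats::runif(1) < 0.5) c(good(), bad())
                  else c(bad(), good()),
    none_correct = c(bad(), bad()))
}

nsCountsFor <- function(task, category) {
  cats <- taskCategories()[[task]]
  counts <- stats::setNames(sample(0:3, length(cats), replace = TRUE), cats)
  counts[category] <- max(counts) + sample(1:3, 1L)
  counts
}

#' Generate a complete synthetic patient fixture
#'
#' Builds the full multi-plane input set for one patient -- axial,
#' sagittal and coronal series, a scripted mock detector, a mock
#' segmenter holding the carina/body/lung masks, and baselines -- such
#' that the analytically implied category of every sub-part equals the
#' spec's target category. Below-cutoff distractor detections are mixed
#' in so the confidence filter is exercised.
#'
#' @param spec a spec from [randomFixtureSpec()], or any list with
#'   \code{seed} and a full \code{categories} vector.
#' @return List with \code{series} (named list of [CTSeries-class]),
#'   \code{detector}, \code{segmenter}, and \code{expected} (the
#'   analytic ground truth: categories, per-sub-part points, scores and
#'   acceptability flags).
#' @export
genPatient <- function(spec) {
  set.seed(spec$seed)
  want <- spec$categories
  size <- c(161L, 161L)
  blank <- function() array(30, dim = c(size, 3L))
  scripts <- list()
  masks <- list()

  # tracheal carina: one detection on axial image 2, mask sized to the crop
  carinaBox <- c(xmin = 40, ymin = 40, xmax = 88, ymax = 88)
  carina <- genCarinaMask(carinaFractionsFor(want[["tracheal_carina"]]),
                          size = c(48, 48))
  masks$tracheal_carina <- carina$mask
  scripts$carina <- cbind(
    data.frame(plane = "axial", task = "tracheal_carina",
               image_index = 2L, label = "carina", confidence = 0.9,
               stringsAsFactors = FALSE),
    as.data.frame(as.list(carinaBox)))
  # a sub-cutoff carina distraction on another image
  scripts$carinaLow <- cbind(
    data.frame(plane = "axial", task = "tracheal_carina",
               image_index = 1L, label = "carina", confidence = 0.55,
               stringsAsFactors = FALSE),
    as.data.frame(as.list(carinaBox)))

  # bronchial beam and rib streams split over axial and sagittal
  for (task in c("bronchial_beam", "rib")) {
    counts <- nsCountsFor(task, want[[task]])
    axN <- floor(counts / 2)
    sgN <- counts - axN
    scripts[[paste0(task, "_ax")]] <-
      genDetectionStream(task, axN, nImages = 3, plane = "axial",
                         nBelow = 2, size = size)$script
    scripts[[paste0(task, "_sg")]] <-
      genDetectionStream(task, sgN, nImages = 2, plane = "sagittal",
                         nBelow = 1, size = size)$script
  }

  # geometry: body centring and baseline alignment
  dd <- baselineDistancesFor(want[["scan_baseline"]])
  pos <- genPositionImages(size = size,
                           bodyOffset = offsetFor(want[["body_position"]]),
                           dStart = dd[1L], dEnd = dd[2L])
  stopifnot(pos$expected$body_position == want[["body_position"]],
            pos$expected$scan_baseline == want[["scan_baseline"]])
  masks$body_contour <- pos$body
  masks$lung_contour <- pos$lung

  # arms, protection, artifact presence streams on the routed planes
  presence <- function(plane, task, labels, conf = 0.9) {
    if (length(labels) == 0L) return(NULL)
    cbind(data.frame(plane = plane, task = task, image_index = 1L,
                     label = labels, confidence = conf,
                     stringsAsFactors = FALSE),
          randomBox(length(labels), size))
  }
  scripts$arms <- presence("coronal", "arms_position",
    if (want[["arms_position"]] == "raised") "arms_raised"
    else "arms_not_raised")
  scripts$prot <- presence("coronal", "radiation_protection",
    switch(want[["radiation_protection"]],
           both = c("neck_protection", "abdomen_protection"),
           one = sample(c("neck_protection", "abdomen_protection"), 1L),
           none = character()))
  scripts$art <- presence("axial", "artifact",
    switch(want[["artifact"]],
           no_exist = character(),
           foreign_matter = "foreign_matter",
           radial_artifact = c("radial_artifact",
                               if (stats::runif(1) < 0.5) "foreign_matter")))
  # sub-cutoff artifact noise: must never downgrade a clean series
  scripts$artLow <- presence("axial", "artifact", "radial_artifact",
                             conf = 0.4)

  script <- do.call(rbind, Filter(Negate(is.null), unname(scripts)))
  series <- list(
    axial = CTSeries(list(blank(), blank(), blank()), "axial",
                     patientID = sprintf("synth-%d", spec$seed)),
    sagittal = CTSeries(list(blank(), blank()), "sagittal",
                        patientID = sprintf("synth-%d", spec$seed)),
    coronal = CTSeries(list(blank(), blank()), "coronal",
                       patientID = sprintf("synth-%d", spec$seed),
                       baselines = pos$baselines))

  rubric <- defaultRubric()
  points <- vapply(subpartNames(), function(sp) {
    r <- rubric[rubric$subpart == sp, ]
    r$points[match(want[[sp]], r$category)]
  }, integer(1))
  insp <- sum(points[INSPIRATION_SUBPARTS])
  total <- sum(points)
  list(series = series,
       detector = MockDetector(script),
       segmenter = MockSegmenter(masks),
       expected = list(categories = want, points = points,
                       inspiration_score = insp, total_score = total,
                       inspiration_acceptable = insp > 20,
                       overall_acceptable = total > 40),
       spec = spec)
}

#' Write / read a patient fixture on disk
#'
#' Serializes a [genPatient()] fixture as plain files: one PNG per
#' image under \code{plane/} subdirectories, the coronal
#' \code{baselines.json} sidecar, the detection script as
#' \code{detections.json}, the segmentation masks as PNGs under
#' \code{masks/}, and the analytic ground truth as
#' \code{expected_report.json}. \code{readPatientFixture} reconstructs
#' the in-memory fixture from such a directory.
#'
#' @param fixture a [genPatient()] result.
#' @param dir output directory (created if missing).
#' @return \code{writePatientFixture} returns \code{dir} invisibly;
#'   \code{readPatientFixture} returns a fixture-shaped list.
#' @export
writePatientFixture <- function(fixture, dir) {
  for (plane in names(fixture$series)) {
    pd <- file.path(dir, plane)
    dir.create(pd, recursive = TRUE, showWarnings = FALSE)
    imgs <- seriesImages(fixture$series[[plane]])
    for (i in seq_along(imgs))
      png::writePNG(imgs[[i]] / 255, file.path(pd, sprintf("%02d.png", i)))
    bl <- seriesBaselines(fixture$series[[plane]])
    if (!is.null(bl))
      jsonlite::write_json(list(y_start = yStart(bl), y_end = yEnd(bl)),
                           file.path(pd, "baselines.json"),
                           auto_unbox = TRUE)
  }
  jsonlite::write_json(fixture$detector@script,
                       file.path(dir, "detections.json"), digits = NA)
  md <- file.path(dir, "masks")
  dir.create(md, showWarnings = FALSE)
  for (target in names(fixture$segmenter@masks))
    png::writePNG(fixture$segmenter@masks[[target]] / 255,
                  file.path(md, paste0(target, ".png")))
  jsonlite::write_json(fixture$expected,
                       file.path(dir, "expected_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname writePatientFixture
#' @export
readPatientFixture <- function(dir) {
  planes <- intersect(c("axial", "sagittal", "coronal"), list.dirs(
    dir, recursive = FALSE, full.names = FALSE))
  series <- stats::setNames(lapply(planes, function(p)
    loadSeries(file.path(dir, p), plane = p, patientID = basename(dir))),
    planes)
  masks <- list()
  for (f in list.files(file.path(dir, "masks"), pattern = "\\.png$",
                       full.names = TRUE))
    masks[[tools::file_path_sans_ext(basename(f))]] <- readImage8(f)
  expected <- NULL
  ef <- file.path(dir, "expected_report.json")
  if (file.exists(ef))
    expected <- jsonlite::read_json(ef, simplifyVector = TRUE)
  list(series = series,
       detector = MockDetector(file.path(dir, "detections.json")),
       segmenter = MockSegmenter(masks),
       expected = expected)
}
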