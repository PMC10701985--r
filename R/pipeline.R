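# Pipeline orchestration: route each plane's series to its evaluation
# tasks, run the backends, apply the four decision algorithms, score
# and report.

#' Default plane-to-task routing
#'
#' Inspiration sub-parts draw on the axial and sagittal planes (the
#' carina image is selected from the axial stack), position on the
#' axial and coronal planes, radiation protection on the coronal plane
#' and artifact on the axial plane.
#'
#' @return Named list mapping sub-part to the planes it consumes.
#' @export
defaultRouting <- function() {
  list(tracheal_carina = "axial",
       bronchial_beam = c("axial", "sagittal"),
       rib = c("axial", "sagittal"),
       scan_baseline = "coronal",
       body_position = "axial",
       arms_position = "coronal",
       radiation_protection = "coronal",
       artifact = "axial")
}

#' Pipeline configuration
#'
#' One object holding every tunable of the decision layer, defaulting
#' to the study values: confidence filter 0.70 (strict), centring
#' radius 50 px, baseline tolerance 15 px, binarization threshold 5,
#' strict comparator for the centring rule, the default routing and
#' rubric.
#'
#' @param backend detector backend registry name (default
#'   \code{"mock"}).
#' @param minScore detection confidence cutoff.
#' @param radius centring circle radius in pixels.
#' @param tolerance baseline alignment tolerance in pixels.
#' @param binarizeThreshold grayscale threshold for mask binarization.
#' @param comparator \code{"lt"} or \code{"le"} for the centring rule.
#' @param routing plane routing map (see [defaultRouting()]).
#' @param rubric scoring rubric (see [defaultRubric()]).
#' @return A list of class \code{ctqaConfig}.
#' @export
ctqaConfig <- function(backend = "mock", minScore = 0.70, radius = 50,
                       tolerance = 15, binarizeThreshold = 5,
                       comparator = c("lt", "le"),
                       routing = defaultRouting(),
                       rubric = defaultRubric()) {
  structure(list(backend = backend, minScore = minScore, radius = radius,
                 tolerance = tolerance,
                 binarizeThreshold = binarizeThreshold,
                 comparator = match.arg(comparator), routing = routing,
                 rubric = rubric),
            class = "ctqaConfig")
}

# evaluate one sub-part, falling back to the worst category (with a
# warning) when it cannot be assessed -- an unevaluable sub-part must
# not inflate quality
assessOrWorst <- function(subpart, rubric, expr) {
  tryCatch(expr, error = function(e) {
    worst <- worstCategory(subpart, rubric)
    warning(sprintf("%s could not be assessed (%s); scored as '%s'",
                    subpart, conditionMessage(e), worst), call. = FALSE)
    worst
  })
}

#' Evaluate one patient's multi-plane series set
#'
#' Runs all eight sub-part evaluations over the supplied series,
#' aggregates the rubric points and returns the scored report. A
#' missing plane (or missing detections/baselines) downgrades the
#' affected sub-parts to their worst category with a warning rather
#' than aborting the patient.
#'
#' @param series named list of [CTSeries-class] objects keyed by plane
#'   (\code{axial}, \code{sagittal}, \code{coronal}); at least one must
#'   be present.
#' @param detector detection backend.
#' @param segmenter segmentation backend.
#' @param config a [ctqaConfig()].
#' @param patientID identifier; defaults to the first series' id.
#' @return A [QualityReport-class].
#' @export
evaluatePatient <- function(series, detector, segmenter,
                            config = ctqaConfig(), patientID = NULL) {
  if (length(series) == 0L)
    stop("no series supplied")
  if (is.null(patientID))
    patientID <- patientID(series[[1L]])
  rubric <- config$rubric
  routed <- function(subpart)
    Filter(Negate(is.null), series[config$routing[[subpart]]])

  categories <- c(
    tracheal_carina = assessOrWorst("tracheal_carina", rubric, {
      ax <- routed("tracheal_carina")
      if (length(ax) == 0L) stop("no axial series")
      sel <- selectCarinaImage(ax[[1L]], detector, config$minScore)
      crop <- cropToBox(sel$image, sel$box)
      mask <- segmentROI(segmenter, crop, "tracheal_carina")
      ptClassify(mask)$morphology
    }),
    bronchial_beam = assessOrWorst("bronchial_beam", rubric, {
      planes <- routed("bronchial_beam")
      if (length(planes) == 0L) stop("no inspiration planes")
      nsAssess(planes, detector, "bronchial_beam", config$minScore,
               rubric)$category
    }),
    rib = assessOrWorst("rib", rubric, {
      planes <- routed("rib")
      if (length(planes) == 0L) stop("no inspiration planes")
      nsAssess(planes, detector, "rib", config$minScore, rubric)$category
    }),
    scan_baseline = assessOrWorst("scan_baseline", rubric, {
      cor <- routed("scan_baseline")
      if (length(cor) == 0L) stop("no coronal series")
      baselines <- seriesBaselines(cor[[1L]])
      if (is.null(baselines)) stop("missing baseline overlay")
      img <- seriesImages(cor[[1L]])[[1L]]
      mask <- segmentROI(segmenter, img, "lung_contour")
      box <- lungBBox(binarize(mask, config$binarizeThreshold))
      scanBaselineCategory(
        baselineAlignment(box, baselines, config$tolerance))
    }),
    body_position = assessOrWorst("body_position", rubric, {
      ax <- routed("body_position")
      if (length(ax) == 0L) stop("no axial series")
      imgs <- seriesImages(ax[[1L]])
      # the most representative cross-section: largest body area
      bins <- lapply(imgs, function(im)
        binarize(segmentROI(segmenter, im, "body_contour"),
                 config$binarizeThreshold))
      best <- which.max(vapply(bins, sum, numeric(1)))
      regionDecision(bodyCentroid(bins[[best]]), imageCenter(imgs[[best]]),
                     config$radius, config$comparator)$decision
    }),
    arms_position = assessOrWorst("arms_position", rubric, {
      cor <- routed("arms_position")
      if (length(cor) == 0L) stop("no coronal series")
      armsPositionCategory(cor[[1L]], detector, config$minScore)
    }),
    radiation_protection = assessOrWorst("radiation_protection", rubric, {
      cor <- routed("radiation_protection")
      if (length(cor) == 0L) stop("no coronal series")
      boxes <- filterDetections(
        detect(detector, cor[[1L]], "radiation_protection"),
        config$minScore)
      protectionCategory(boxes)$category
    }),
    artifact = assessOrWorst("artifact", rubric, {
      ax <- routed("artifact")
      if (length(ax) == 0L) stop("no axial series")
      artifactCategory(ax[[1L]], detector, config$minScore)
    }))
  aggregateReport(categories, patientID = patientID, rubric = rubric)
}

#' Evaluate a cohort of patients
#'
#' Runs [evaluatePatient()] over a list of patient inputs and tabulates
#' the reports. When a ground-truth acceptability vector is supplied,
#' the cohort confusion counts and binary metrics against it are
#' attached.
#'
#' @param patients non-empty list; each element either a fixture
#'   directory path (see [writePatientFixture()]) or a list with
#'   \code{series}, \code{detector} and \code{segmenter}.
#' @param config a [ctqaConfig()].
#' @param truth optional logical vector of true overall acceptability,
#'   one per patient.
#' @return List with \code{table} (one row per patient), \code{reports}
#'   (the [QualityReport-class] objects) and, when truth is given,
#'   \code{confusion} and \code{metrics}.
#' @export
evaluateCohort <- function(patients, config = ctqaConfig(), truth = NULL) {
  if (length(patients) == 0L)
    stop("empty manifest")
  reports <- lapply(patients, function(p) {
    if (is.character(p)) p <- readPatientFixture(p)
    evaluatePatient(p$series, p$detector, p$segmenter, config)
  })
  tab <- do.call(rbind, lapply(reports, as.data.frame))
  out <- list(table = tab, reports = reports)
  if (!is.null(truth)) {
    out$confusion <- confusionCounts(truth, tab$overall_acceptable)
    out$metrics <- binaryMetrics(out$confusion)
  }
  out
}
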