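# Classification metrics: 2x2 confusion tallies for patient-level
# acceptability comparisons, the four standard binary metrics,
# macro-averaging over subclasses, and greedy IoU box matching for
# detector evaluation.

#' Confusion counts for binary decisions
#'
#' Standard 2x2 tally with "acceptable" as the positive class.
#'
#' @param truth,pred logical (or 0/1) vectors of equal length.
#' @return Named integer vector \code{c(tp, tn, fp, fn)}.
#' @export
#' @examples
#' confusionCounts(c(TRUE, TRUE, FALSE), c(TRUE, TRUE, FALSE))
confusionCounts <- function(truth, pred) {
  if (length(truth) != length(pred))
    stop("truth and pred must have equal length")
  truth <- as.logical(truth); pred <- as.logical(pred)
  c(tp = sum(truth & pred), tn = sum(!truth & !pred),
    fp = sum(!truth & pred), fn = sum(truth & !pred))
}

#' Binary classification metrics
#'
#' Precision = TP/(TP+FP), sensitivity = TP/(TP+FN), specificity =
#' TN/(FP+TN), and F1 the harmonic mean of precision and sensitivity.
#' A metric whose denominator is zero is undefined and returned as NA
#' (never coerced to 0, which would bias macro averages). Values are
#' exact fractions; round only at report time.
#'
#' @param counts named vector with tp, tn, fp, fn (see
#'   [confusionCounts()]).
#' @return Named numeric vector \code{c(precision, sensitivity,
#'   specificity, f1)}.
#' @export
#' @examples
#' round(binaryMetrics(c(tp = 26, tn = 9, fp = 4, fn = 2)), 2)
binaryMetrics <- function(counts) {
  tp <- counts[["tp"]]; tn <- counts[["tn"]]
  fp <- counts[["fp"]]; fn <- counts[["fn"]]
  if (tp + tn + fp + fn == 0)
    stop("empty confusion counts")
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- safe(tp, tp + fp)
  sensitivity <- safe(tp, tp + fn)
  specificity <- safe(tn, fp + tn)
  f1 <- if (is.na(precision) || is.na(sensitivity) ||
            precision + sensitivity == 0) NA_real_
        else 2 * precision * sensitivity / (precision + sensitivity)
  c(precision = precision, sensitivity = sensitivity,
    specificity = specificity, f1 = f1)
}

#' Macro-average metrics over subclasses
#'
#' Unweighted mean of each metric across per-class metric sets,
#' skipping undefined (NA) values.
#'
#' @param perClass list of vectors as returned by [binaryMetrics()].
#' @return Named numeric vector with the four averaged metrics.
#' @export
macroMetrics <- function(perClass) {
  if (length(perClass) == 0L)
    stop("no classes to average")
  m <- do.call(rbind, perClass)
  apply(m, 2L, mean, na.rm = TRUE)
}

#' Intersection over union of two axis-aligned boxes
#'
#' Boxes are \code{c(xmin, ymin, xmax, ymax)}, half-open.
#'
#' @param a,b box vectors.
#' @return IoU in [0, 1].
#' @export
boxIoU <- function(a, b) {
  iw <- max(0, min(a[[3L]], b[[3L]]) - max(a[[1L]], b[[1L]]))
  ih <- max(0, min(a[[4L]], b[[4L]]) - max(a[[2L]], b[[2L]]))
  inter <- iw * ih
  areaA <- (a[[3L]] - a[[1L]]) * (a[[4L]] - a[[2L]])
  areaB <- (b[[3L]] - b[[1L]]) * (b[[4L]] - b[[2L]])
  if (inter == 0) return(0)
  inter / (areaA + areaB - inter)
}

#' Greedy IoU matching of predicted against ground-truth boxes
#'
#' Predictions are visited in descending confidence order; each may
#' claim one still-unmatched truth box of the same label with IoU
#' strictly greater than \code{iouMin} (the truth with the highest IoU
#' is claimed). Matched predictions are true positives, unmatched
#' predictions false positives, unmatched truths false negatives. True
#' negatives are undefined for detection and reported as 0.
#'
#' @param pred,truth detection tables on the same image; \code{truth}
#'   needs no confidence column.
#' @param iouMin IoU cutoff (default 0.70, strict).
#' @return data.frame with one row per label and columns label, tp, fp,
#'   fn.
#' @export
matchBoxes <- function(pred, truth, iouMin = 0.70) {
  labels <- sort(unique(c(pred$label, truth$label)))
  if (is.null(pred$confidence)) pred$confidence <- 1
  ord <- order(-pred$confidence)
  matchedTruth <- rep(FALSE, nrow(truth))
  predTP <- rep(FALSE, nrow(pred))
  for (i in ord) {
    cand <- which(!matchedTruth & truth$label == pred$label[i])
    if (length(cand) == 0L) next
    ious <- vapply(cand, function(j)
      boxIoU(unlist(pred[i, c("xmin", "ymin", "xmax", "ymax")]),
             unlist(truth[j, c("xmin", "ymin", "xmax", "ymax")])),
      numeric(1))
    best <- which.max(ious)
    if (ious[best] > iouMin) {
      matchedTruth[cand[best]] <- TRUE
      predTP[i] <- TRUE
    }
  }
  do.call(rbind, lapply(labels, function(lab) {
    data.frame(label = lab,
               tp = sum(predTP & pred$label == lab),
               fp = sum(!predTP & pred$label == lab),
               fn = sum(!matchedTruth & truth$label == lab))
  }))
}

#' Two-tailed t-test on paired score vectors
#'
#' Thin convenience wrapper used when comparing per-patient quality
#' scores between two raters or methods.
#'
#' @param x,y numeric score vectors.
#' @param paired passed to [stats::t.test()].
#' @return The p-value of the two-sided test.
#' @export
scoreTTest <- function(x, y, paired = FALSE) {
  stats::t.test(x, y, alternative = "two.sided", paired = paired)$p.value
}
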