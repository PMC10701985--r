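# Small in-code fixtures shared across the suite.

blankImage <- function(size = c(32, 32), value = 30) {
  array(value, dim = c(size, 3L))
}

mkSeries <- function(n = 3, plane = "axial", size = c(32, 32),
                     baselines = NULL, patientID = "p1") {
  CTSeries(replicate(n, blankImage(size), simplify = FALSE), plane,
           patientID = patientID, baselines = baselines)
}

# one scripted detection row for the mock backend
scriptRow <- function(plane, task, image_index, label, confidence,
                      xmin = 0, ymin = 0, xmax = 10, ymax = 10) {
  data.frame(plane = plane, task = task, image_index = image_index,
             label = label, confidence = confidence, xmin = xmin,
             ymin = ymin, xmax = xmax, ymax = ymax,
             stringsAsFactors = FALSE)
}

# paint exact per-colour pixel counts into a tri-colour mask (pure base
# colours, no noise) -- independent of genCarinaMask
paintMask <- function(nWhite, nGreen, nRed, size = c(20, 20)) {
  n <- prod(size)
  stopifnot(nWhite + nGreen + nRed <= n)
  mask <- array(0, dim = c(size, 3L))
  idx <- seq_len(nWhite + nGreen + nRed)
  cols <- c(rep(list(c(255, 255, 255)), nWhite),
            rep(list(c(0, 200, 0)), nGreen),
            rep(list(c(200, 0, 0)), nRed))
  for (k in seq_along(idx))
    for (ch in 1:3) mask[idx[k] + (ch - 1L) * n] <- cols[[k]][ch]
  mask
}

bestCategories <- function() {
  c(tracheal_carina = "convex", bronchial_beam = "visible",
    rib = "visible", scan_baseline = "both_correct",
    body_position = "inside", arms_position = "raised",
    radiation_protection = "both", artifact = "no_exist")
}

worstCategories <- function() {
  c(tracheal_carina = "concave", bronchial_beam = "curly",
    rib = "multiple_shadows", scan_baseline = "none_correct",
    body_position = "outside", arms_position = "not_raised",
    radiation_protection = "none", artifact = "radial_artifact")
}

# brute-force reference for aggregate scoring: direct Table-style sums
bruteForceScores <- function(categories) {
  pts <- c(convex = 10, flat = 5, concave = 0,
           visible_bb = 15, fuzzy = 10, double_shadow_bb = 5, curly = 0,
           visible_rib = 15, corrugation = 10, double_shadow_rib = 5,
           multiple_shadows = 0,
           both_correct = 10, one_correct = 5, none_correct = 0,
           inside = 5, outside = 0, raised = 5, not_raised = 0,
           both = 10, one = 5, none = 0,
           no_exist = 10, foreign_matter = 5, radial_artifact = 0)
  key <- function(sp, cat) {
    if (sp == "bronchial_beam" && cat %in% c("visible", "double_shadow"))
      paste0(cat, "_bb")
    else if (sp == "rib" && cat %in% c("visible", "double_shadow"))
      paste0(cat, "_rib")
    else cat
  }
  p <- vapply(names(categories), function(sp)
    pts[[key(sp, categories[[sp]])]], numeric(1))
  list(points = p,
       inspiration = sum(p[c("tracheal_carina", "bronchial_beam", "rib")]),
       total = sum(p))
}
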