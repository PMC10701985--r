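test_that("classifyPixel applies the threshold ranges with white precedence", {
  expect_equal(classifyPixel(255, 255, 255), "white")
  expect_equal(classifyPixel(200, 200, 200), "white")   # range boundary
  expect_equal(classifyPixel(100, 200, 100), "green")
  expect_equal(classifyPixel(200, 100, 100), "red")
  expect_equal(classifyPixel(10, 10, 10), "unclassified")
  # overlap resolution: both colour branches satisfied -> larger channel,
  # green winning exact ties
  expect_equal(classifyPixel(200, 200, 0), "green")
  expect_equal(classifyPixel(220, 160, 0), "red")
  expect_equal(classifyPixel(150, 149, 0), "red")
  expect_error(classifyPixel(-1, 0, 0), "invalid channel value")
  expect_error(classifyPixel(0, 256, 0), "invalid channel value")
})

test_that("ptClassify takes the majority colour as the morphology", {
  res <- ptClassify(paintMask(500, 100, 3, size = c(25, 25)))
  expect_equal(res$morphology, "convex")
  expect_equal(unname(res$counts[c("white", "green", "red")]),
               c(500, 100, 3))
})

test_that("ptClassify breaks count ties toward the lower-scoring morphology", {
  expect_equal(ptClassify(paintMask(0, 40, 40))$morphology, "concave")
  expect_equal(ptClassify(paintMask(40, 40, 0))$morphology, "flat")
  expect_equal(ptClassify(paintMask(40, 0, 40))$morphology, "concave")
})

test_that("pure single-colour masks map to their morphology", {
  expect_equal(ptClassify(paintMask(400, 0, 0))$morphology, "convex")
  expect_equal(ptClassify(paintMask(0, 400, 0))$morphology, "flat")
  expect_equal(ptClassify(paintMask(0, 0, 400))$morphology, "concave")
})

test_that("ptClassify errors when nothing in the mask is classifiable", {
  expect_error(ptClassify(array(10, dim = c(5, 5, 3))), "no mask content")
})

test_that("ptClassify counts equal a per-pixel classifyPixel loop on random masks", {
  set.seed(21)
  for (rep in 1:50) {
    mask <- array(sample(0:255, 12 * 10 * 3, replace = TRUE),
                  dim = c(12, 10, 3))
    want <- c(white = 0, green = 0, red = 0, unclassified = 0)
    for (i in 1:12) for (j in 1:10) {
      cls <- classifyPixel(mask[i, j, 1], mask[i, j, 2], mask[i, j, 3])
      want[cls] <- want[cls] + 1
    }
    got <- tryCatch(ptClassify(mask)$counts, error = function(e) NULL)
    if (is.null(got)) {
      expect_equal(sum(want[c("white", "green", "red")]), 0)
    } else {
      expect_equal(got, want)
      expect_equal(sum(got), 120)   # conservation: counts sum to H*W
    }
  }
})

test_that("selectCarinaImage picks the highest-confidence filtered box", {
  script <- rbind(scriptRow("axial", "tracheal_carina", 2L, "carina", 0.8),
                  scriptRow("axial", "tracheal_carina", 5L, "carina", 0.9))
  sel <- selectCarinaImage(mkSeries(6, "axial"), MockDetector(script))
  expect_equal(sel$imageIndex, 5L)
  expect_equal(sel$box$confidence, 0.9)
})

test_that("selectCarinaImage fails when nothing survives the filter", {
  script <- rbind(scriptRow("axial", "tracheal_carina", 1L, "carina", 0.70),
                  scriptRow("axial", "tracheal_carina", 2L, "carina", 0.60))
  expect_error(selectCarinaImage(mkSeries(3, "axial"), MockDetector(script)),
               "carina not found")
})

test_that("selectCarinaImage confidence ties go to the first image, stably", {
  rows <- rbind(scriptRow("axial", "tracheal_carina", 7L, "carina", 0.9),
                scriptRow("axial", "tracheal_carina", 3L, "carina", 0.9),
                scriptRow("axial", "tracheal_carina", 5L, "carina", 0.8))
  set.seed(4)
  for (perm in 1:5) {
    shuffled <- rows[sample(nrow(rows)), ]
    sel <- selectCarinaImage(mkSeries(8, "axial"), MockDetector(shuffled))
    expect_equal(sel$imageIndex, 3L)
  }
})

test_that("nsAssess tallies filtered boxes and takes the argmax", {
  script <- rbind(
    do.call(rbind, Map(scriptRow, "axial", "bronchial_beam",
                       rep(1:5, 2)[1:7], "visible", 0.9)),
    do.call(rbind, Map(scriptRow, "axial", "bronchial_beam",
                       c(6L, 7L), "fuzzy", 0.85)))
  res <- nsAssess(mkSeries(10, "axial"), MockDetector(script),
                  "bronchial_beam")
  expect_equal(res$category, "visible")
  expect_equal(unname(res$tally["visible"]), 7L)
  expect_equal(unname(res$tally["fuzzy"]), 2L)
})

test_that("nsAssess breaks tallies ties toward the lower-scoring category", {
  script <- rbind(
    do.call(rbind, Map(scriptRow, "axial", "bronchial_beam", 1:3,
                       "visible", 0.9)),
    do.call(rbind, Map(scriptRow, "axial", "bronchial_beam", 1:3,
                       "curly", 0.9)))
  res <- nsAssess(mkSeries(3, "axial"), MockDetector(script),
                  "bronchial_beam")
  expect_equal(res$category, "curly")
})

test_that("nsAssess errors on zero surviving boxes", {
  script <- scriptRow("axial", "rib", 1L, "visible", 0.5)  # below cutoff
  expect_error(nsAssess(mkSeries(2, "axial"), MockDetector(script), "rib"),
               "no detections")
  expect_error(nsAssess(mkSeries(2, "axial"), MockDetector(NULL), "rib"),
               "no detections")
  expect_error(nsAssess(mkSeries(2, "axial"), MockDetector(NULL),
                        "tracheal_carina"), "bronchial_beam and rib")
})

test_that("nsAssess matches a loop oracle on a 200-box random stream", {
  set.seed(31)
  cats <- taskCategories()$rib
  script <- do.call(rbind, lapply(1:200, function(i)
    scriptRow("axial", "rib", sample(1:8, 1), sample(cats, 1),
              round(stats::runif(1), 2))))
  res <- nsAssess(mkSeries(8, "axial"), MockDetector(script), "rib")
  want <- stats::setNames(numeric(length(cats)), cats)
  for (i in 1:200)
    if (script$confidence[i] > 0.70)
      want[script$label[i]] <- want[script$label[i]] + 1
  expect_equal(as.numeric(res$tally), as.numeric(want[names(res$tally)]))
})

test_that("nsAssess is invariant to image and box order", {
  set.seed(32)
  cats <- taskCategories()$bronchial_beam
  script <- do.call(rbind, lapply(1:40, function(i)
    scriptRow("axial", "bronchial_beam", sample(1:4, 1), sample(cats, 1),
              stats::runif(1, 0.75, 0.99))))
  base <- nsAssess(mkSeries(4, "axial"), MockDetector(script),
                   "bronchial_beam")
  for (perm in 1:5) {
    shuffled <- script[sample(nrow(script)), ]
    res <- nsAssess(mkSeries(4, "axial"), MockDetector(shuffled),
                    "bronchial_beam")
    expect_equal(res$category, base$category)
    expect_equal(res$tally, base$tally)
  }
})

test_that("adding boxes of the winning category never changes the winner", {
  set.seed(33)
  cats <- taskCategories()$rib
  script <- do.call(rbind, lapply(1:30, function(i)
    scriptRow("axial", "rib", sample(1:3, 1), sample(cats, 1),
              stats::runif(1, 0.75, 0.99))))
  base <- nsAssess(mkSeries(3, "axial"), MockDetector(script), "rib")
  for (extra in c(1, 5, 20)) {
    more <- do.call(rbind, lapply(seq_len(extra), function(i)
      scriptRow("axial", "rib", 1L, base$category, 0.95)))
    res <- nsAssess(mkSeries(3, "axial"),
                    MockDetector(rbind(script, more)), "rib")
    expect_equal(res$category, base$category)
  }
})
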