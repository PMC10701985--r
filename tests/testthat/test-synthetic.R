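test_that("genCarinaMask paints the requested fractions with a known winner", {
  g <- genCarinaMask(c(white = 0.6, green = 0.1, red = 0), seed = 1)
  expect_equal(g$expected, "convex")
  expect_equal(unname(g$counts["white"]), round(0.6 * 48 * 48))
  expect_error(genCarinaMask(c(white = 0.7, green = 0.4, red = 0.2)),
               "at most 1")
  expect_error(genCarinaMask(c(white = 0.5, green = 0, red = 0),
                             noise = 30), "ambiguous spec")
})

test_that("genCarinaMask is deterministic under a fixed seed", {
  a <- genCarinaMask(c(white = 0.3, green = 0.2, red = 0.1), seed = 99)
  b <- genCarinaMask(c(white = 0.3, green = 0.2, red = 0.1), seed = 99)
  expect_identical(a$mask, b$mask)
})

test_that("ptClassify recovers the generated morphology for 100 random specs", {
  set.seed(71)
  for (rep in 1:100) {
    f <- stats::runif(3, 0, 0.3)
    f[sample(3, 1)] <- stats::runif(1, 0.35, 0.5)   # a clear dominant
    g <- genCarinaMask(c(white = f[1], green = f[2], red = f[3]),
                       size = c(24, 24))
    expect_equal(ptClassify(g$mask)$morphology, g$expected)
    expect_equal(unname(ptClassify(g$mask)$counts[c("white", "green", "red")]),
                 unname(g$counts))
  }
})

test_that("genPositionImages realizes exact geometry", {
  g <- genPositionImages(bodyOffset = c(0, 0), dStart = 15, dEnd = 16)
  expect_equal(g$expected$body_position, "inside")
  expect_equal(g$expected$scan_baseline, "one_correct")
  # the painted geometry, measured, matches the request
  bin <- binarize(g$body)
  expect_equal(bodyCentroid(bin), g$centroid)
  box <- lungBBox(binarize(g$lung))
  al <- baselineAlignment(box, g$baselines)
  expect_equal(al$distance_start, 15)
  expect_equal(al$distance_end, 16)
})

test_that("boundary sweep: offsets and distances map to the right categories", {
  for (off in c(0, 49, 50, 51)) {
    g <- genPositionImages(bodyOffset = c(off, 0))
    want <- if (off < 50) "inside" else "outside"
    expect_equal(g$expected$body_position, want)
    bin <- binarize(g$body)
    got <- regionDecision(bodyCentroid(bin),
                          imageCenter(g$body))$decision
    expect_equal(got, want)
  }
  for (D in c(-1, 0, 15, 16)) {
    g <- genPositionImages(dStart = D, dEnd = 5)
    want <- if (D >= 0 && D <= 15) "both_correct" else "one_correct"
    expect_equal(g$expected$scan_baseline, want)
    box <- lungBBox(binarize(g$lung))
    expect_equal(scanBaselineCategory(baselineAlignment(box, g$baselines)),
                 want)
  }
})

test_that("genDetectionStream closed loop: nsAssess recovers the category", {
  g <- genDetectionStream("bronchial_beam", c(visible = 5), seed = 3)
  expect_equal(g$expected, "visible")
  # below-cutoff boxes flip the outcome once filtered
  low <- do.call(rbind, Map(scriptRow, "axial", "bronchial_beam", 1:5,
                            "visible", 0.65))
  high <- scriptRow("axial", "bronchial_beam", 1L, "fuzzy", 0.8)
  res <- nsAssess(mkSeries(5, "axial"), MockDetector(rbind(low, high)),
                  "bronchial_beam")
  expect_equal(res$category, "fuzzy")
  set.seed(72)
  for (rep in 1:100) {
    task <- sample(c("bronchial_beam", "rib"), 1)
    cats <- taskCategories()[[task]]
    counts <- stats::setNames(sample(0:4, length(cats), TRUE), cats)
    counts[sample(cats, 1)] <- 8    # strict winner
    g <- genDetectionStream(task, counts, nImages = 4, nBelow = 3)
    res <- nsAssess(mkSeries(4, "axial"), MockDetector(g$script), task)
    expect_equal(res$category, g$expected)
  }
})

test_that("patient fixtures are deterministic and carry analytic truth", {
  a <- genPatient(randomFixtureSpec(7))
  b <- genPatient(randomFixtureSpec(7))
  expect_identical(a$detector@script, b$detector@script)
  expect_identical(a$segmenter@masks, b$segmenter@masks)
  expect_identical(seriesImages(a$series$axial),
                   seriesImages(b$series$axial))
  expect_identical(a$expected, b$expected)
  # ground truth is consistent with a brute-force rubric sum
  bf <- bruteForceScores(as.list(a$expected$categories))
  expect_equal(unname(a$expected$points), unname(bf$points))
  expect_equal(a$expected$total_score, bf$total)
})

test_that("all-best and all-worst specs hit the score extremes", {
  best <- genPatient(list(seed = 1, categories = bestCategories()))
  expect_equal(best$expected$total_score, 80)
  expect_equal(best$expected$inspiration_score, 40)
  expect_true(best$expected$overall_acceptable)
  worst <- genPatient(list(seed = 2, categories = worstCategories()))
  expect_equal(worst$expected$total_score, 0)
  expect_false(worst$expected$inspiration_acceptable)
  expect_false(worst$expected$overall_acceptable)
})

test_that("fixtures round-trip through disk serialization", {
  fx <- genPatient(randomFixtureSpec(13))
  dir <- withr::local_tempdir()
  writePatientFixture(fx, dir)
  back <- readPatientFixture(dir)
  expect_identical(seriesImages(back$series$axial),
                   seriesImages(fx$series$axial))
  expect_equal(yStart(seriesBaselines(back$series$coronal)),
               yStart(seriesBaselines(fx$series$coronal)))
  expect_equal(back$detector@script$label, fx$detector@script$label)
  expect_equal(back$detector@script$confidence, fx$detector@script$confidence)
  expect_identical(back$segmenter@masks$tracheal_carina,
                   fx$segmenter@masks$tracheal_carina)
  expect_equal(back$expected$total_score, fx$expected$total_score)
  # and the reloaded fixture evaluates to the same report
  r1 <- evaluatePatient(fx$series, fx$detector, fx$segmenter)
  r2 <- evaluatePatient(back$series, back$detector, back$segmenter,
                        patientID = patientID(fx$series$axial))
  expect_equal(as.data.frame(r1), as.data.frame(r2))
})
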