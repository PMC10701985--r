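test_that("bodyCentroid returns the foreground mean in 0-based pixels", {
  m <- matrix(0, 60, 60)
  m[41:50, 21:30] <- 1            # rows 40..49, cols 20..29 (0-based)
  expect_equal(bodyCentroid(m), c(x = 24.5, y = 44.5))
  p <- matrix(0, 10, 10); p[4, 8] <- 1
  expect_equal(bodyCentroid(p), c(x = 7, y = 3))
  expect_error(bodyCentroid(matrix(0, 5, 5)), "no body contour")
})

test_that("bodyCentroid matches a brute-force coordinate mean on random blobs", {
  set.seed(41)
  for (rep in 1:50) {
    m <- matrix(stats::rbinom(30 * 20, 1, 0.2), 30, 20)
    if (sum(m) == 0) m[5, 5] <- 1
    xs <- c(); ys <- c()
    for (i in 1:30) for (j in 1:20)
      if (m[i, j] == 1) { xs <- c(xs, j - 1); ys <- c(ys, i - 1) }
    expect_equal(bodyCentroid(m), c(x = mean(xs), y = mean(ys)))
  }
})

test_that("regionDecision applies the strict circle rule", {
  expect_equal(regionDecision(c(10, 10), c(10, 10))$decision, "inside")
  r <- regionDecision(c(60, 10), c(10, 10))   # 50 px to the right
  expect_equal(r$distance, 50)
  expect_equal(r$decision, "outside")
  r2 <- regionDecision(c(44, 30), c(0, 0))
  expect_equal(r2$distance, sqrt(2836))       # sqrt(44^2 + 30^2) ~ 53.25
  expect_equal(r2$decision, "outside")
  # the comparator is configurable: "le" admits the boundary
  expect_equal(regionDecision(c(60, 10), c(10, 10),
                              comparator = "le")$decision, "inside")
})

test_that("regionDecision is invariant under joint translation", {
  set.seed(42)
  for (rep in 1:20) {
    blue <- stats::runif(2, 0, 100); green <- stats::runif(2, 0, 100)
    shift <- stats::runif(2, -200, 200)
    a <- regionDecision(blue, green)
    b <- regionDecision(blue + shift, green + shift)
    expect_equal(a$distance, b$distance)
    expect_equal(a$decision, b$decision)
  }
})

test_that("lungBBox is the tight box over foreground pixels", {
  m <- matrix(0, 400, 100)
  m[101:301, 21:61] <- 1
  expect_equal(lungBBox(m),
               c(y_top = 100, y_bottom = 300, x_left = 20, x_right = 60))
  p <- matrix(0, 10, 10); p[3, 7] <- 1
  expect_equal(lungBBox(p),
               c(y_top = 2, y_bottom = 2, x_left = 6, x_right = 6))
  expect_error(lungBBox(matrix(0, 5, 5)), "no lung contour")
})

test_that("lungBBox matches brute-force min/max and never shrinks on dilation", {
  set.seed(43)
  for (rep in 1:50) {
    m <- matrix(stats::rbinom(25 * 25, 1, 0.1), 25, 25)
    if (sum(m) == 0) m[10, 10] <- 1
    idx <- which(m == 1, arr.ind = TRUE)
    expect_equal(lungBBox(m),
                 c(y_top = min(idx[, 1]) - 1, y_bottom = max(idx[, 1]) - 1,
                   x_left = min(idx[, 2]) - 1, x_right = max(idx[, 2]) - 1))
    # crude dilation: shift-OR in four directions
    d <- m
    d[-1, ] <- pmax(d[-1, ], m[-25, ]); d[-25, ] <- pmax(d[-25, ], m[-1, ])
    d[, -1] <- pmax(d[, -1], m[, -25]); d[, -25] <- pmax(d[, -25], m[, -1])
    b0 <- lungBBox(m); b1 <- lungBBox(d)
    expect_true(b1["y_top"] <= b0["y_top"] && b1["x_left"] <= b0["x_left"])
    expect_true(b1["y_bottom"] >= b0["y_bottom"] &&
                b1["x_right"] >= b0["x_right"])
  }
})

test_that("baselineAlignment computes signed distances and the 0..T rule", {
  box <- c(y_top = 100, y_bottom = 400)
  a <- baselineAlignment(box, BaselinePair(85, 420))
  expect_equal(a$distance_start, 15)
  expect_equal(a$decision_start, "accurate")
  b <- baselineAlignment(box, BaselinePair(84, 420))
  expect_equal(b$distance_start, 16)
  expect_equal(b$decision_start, "inaccurate")
  # baseline inside the lung extent (truncation) is never accurate
  cc <- baselineAlignment(box, c(110, 420))
  expect_equal(cc$distance_start, -10)
  expect_equal(cc$decision_start, "inaccurate")
})

test_that("baseline decision matches a truth-table oracle over D in -3..20", {
  for (D in -3:20) {
    box <- c(y_top = 50 + D, y_bottom = 400)
    a <- baselineAlignment(box, c(50, 410), tolerance = 15)
    expect_equal(a$distance_start, D)
    expect_equal(a$decision_start,
                 if (D >= 0 && D <= 15) "accurate" else "inaccurate")
  }
})

test_that("raising the tolerance never flips accurate to inaccurate", {
  box <- c(y_top = 60, y_bottom = 400)
  for (D in 0:20) {
    b <- c(60 - D, 410)
    prev <- baselineAlignment(box, b, tolerance = 5)$decision_start
    for (T in 6:25) {
      cur <- baselineAlignment(box, b, tolerance = T)$decision_start
      if (prev == "accurate") expect_equal(cur, "accurate")
      prev <- cur
    }
  }
})

test_that("scanBaselineCategory maps decision pairs to rubric categories", {
  al <- function(ds, de) list(decision_start = ds, decision_end = de)
  expect_equal(scanBaselineCategory(al("accurate", "accurate")),
               "both_correct")
  expect_equal(scanBaselineCategory(al("accurate", "inaccurate")),
               "one_correct")
  expect_equal(scanBaselineCategory(al("inaccurate", "accurate")),
               "one_correct")
  expect_equal(scanBaselineCategory(al("inaccurate", "inaccurate")),
               "none_correct")
})

test_that("arms position enumerates all presence combinations worst-first", {
  s <- mkSeries(1, "coronal")
  mk <- function(raised, notRaised) {
    rows <- list()
    if (raised) rows <- c(rows, list(
      scriptRow("coronal", "arms_position", 1L, "arms_raised", 0.9)))
    if (notRaised) rows <- c(rows, list(
      scriptRow("coronal", "arms_position", 1L, "arms_not_raised", 0.8)))
    MockDetector(if (length(rows)) do.call(rbind, rows) else NULL)
  }
  expect_equal(armsPositionCategory(s, mk(TRUE, FALSE)), "raised")
  expect_equal(armsPositionCategory(s, mk(TRUE, TRUE)), "not_raised")
  expect_equal(armsPositionCategory(s, mk(FALSE, TRUE)), "not_raised")
  expect_equal(armsPositionCategory(s, mk(FALSE, FALSE)), "not_raised")
  # sub-cutoff raised box does not count
  low <- MockDetector(scriptRow("coronal", "arms_position", 1L,
                                "arms_raised", 0.70))
  expect_equal(armsPositionCategory(s, low), "not_raised")
})
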