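test_that("fitSpline interpolates knots and degenerates to a line", {
  pts <- cbind(c(0, 10, 25, 40), c(5, 8, 3, 9))
  cv <- fitSpline(pts)
  expect_lt(max(abs(evalCurve(cv, cv$knots) - pts)), 1e-9)

  lin <- cbind(c(0, 5, 10), c(0, 5, 10))
  cl <- fitSpline(lin)
  s <- evalCurve(cl, seq(0, 1, length.out = 500))
  expect_lt(max(abs(s[, 2] - s[, 1])), 1e-9)

  expect_error(fitSpline(cbind(c(0, 0, 1), c(0, 0, 1))),
               class = "fm_degenerate_knot")
  expect_error(fitSpline(cbind(0:1, 0:1)), class = "fm_degenerate_geometry")
})

test_that("fitSpline matches an independent natural-spline solver", {
  th <- seq(0.2, 1.8, length.out = 7)
  pts <- cbind(50 * cos(th), 50 * sin(th))
  cv <- fitSpline(pts)
  tt <- refChordParams(pts)
  tout <- seq(0, 1, length.out = 5000)
  refx <- refNaturalSpline(tt, pts[, 1], tout)
  refy <- refNaturalSpline(tt, pts[, 2], tout)
  got <- evalCurve(cv, tout)
  expect_lt(max(abs(got - cbind(refx, refy))), 1e-6)
})

test_that("calcaneal tilt matches closed-form constructions", {
  lm45 <- templateWith(list(`10` = c(0, 0), `11` = c(10, 0), `12` = c(10, 10)))
  expect_equal(calcanealTilt(lm45), 45, tolerance = 1e-9)

  col <- templateWith(list(`10` = c(0, 0), `11` = c(10, 0), `12` = c(25, 0)))
  expect_equal(calcanealTilt(col), 0, tolerance = 1e-9)

  # rigid rotation leaves the angle unchanged
  p <- landmarkPoints(lm45)
  rot <- landmarkSet(rotatePts(p, 33), pixelSpacing(lm45))
  expect_equal(calcanealTilt(rot), 45, tolerance = 1e-9)

  # always reduced to the acute angle
  obtuse <- templateWith(list(`10` = c(0, 0), `11` = c(10, 0), `12` = c(-10, 1)))
  expect_lte(calcanealTilt(obtuse), 90)

  deg <- templateWith(list(`10` = c(0, 0), `11` = c(0, 0), `12` = c(1, 1)))
  expect_error(calcanealTilt(deg), class = "fm_degenerate_geometry")
})

test_that("cuboid height handles parallel, touching and signed cases", {
  sc <- footScheme()
  ord <- sc@splineDefs$cuboid_inferior
  mk <- function(ys) {
    ov <- list(`13` = c(0, 100), `15` = c(700, 100))
    for (k in seq_along(ord)) ov[[as.character(ord[k])]] <- c(400 + 20 * k, ys[k])
    lm <- templateWith(ov); lm@spacing <- c(0.5, 0.5); lm
  }
  # baseline at y = 100, all cuboid spline points at y = 90, spacing 0.5
  expect_equal(cuboidHeight(mk(rep(90, 7))), 5, tolerance = 1e-9)

  # end control point on the baseline -> minimum 0
  expect_equal(cuboidHeight(mk(c(90, 90, 90, 90, 90, 95, 100))), 0,
               tolerance = 1e-6)

  # crossing inferior to the line -> negative
  expect_lt(cuboidHeight(mk(c(90, 90, 90, 104, 90, 90, 90))), 0)

  expect_error(
    cuboidHeight(templateWith(list(`13` = c(0, 0), `15` = c(0, 0)))),
    class = "fm_degenerate_geometry")
})

test_that("cuboid height equals a dense brute-force minimum", {
  sc <- footScheme()
  for (seed in 1:20) {
    lm <- footTemplate()
    p <- landmarkPoints(lm)
    set.seed(seed)
    p[sc@splineDefs$cuboid_inferior, ] <-
      p[sc@splineDefs$cuboid_inferior, ] + matrix(rnorm(14, 0, 4), ncol = 2)
    lm <- landmarkSet(p, pixelSpacing(lm))
    got <- cuboidHeight(lm)
    cv <- fitSpline(p[sc@splineDefs$cuboid_inferior, ])
    s <- evalCurve(cv, seq(0, 1, length.out = 1e5))
    a <- p[13, ]; b <- p[15, ]
    d <- (b - a) / sqrt(sum((b - a)^2)); n <- c(d[2], -d[1])
    if (n[2] > 0) n <- -n
    brute <- min(sweep(s, 2, a) %*% n) * mean(pixelSpacing(lm))
    expect_lt(abs(got - brute), 1e-4)
  }
})

test_that("talar axis uses midpoints and the most superior spline point", {
  lm <- templateWith(list(`4` = c(0, 0), `5` = c(20, 10)))
  sc <- footScheme()
  curve <- fitSpline(landmarkPoints(lm)[sc@splineDefs$talus_superior, ])
  # centre A is the midpoint of points 4 and 5: verify via the axis line
  ax <- talarAxis(lm)
  A <- c(10, 5)
  off <- A - ax$point
  cross <- off[1] * ax$direction[2] - off[2] * ax$direction[1]
  expect_lt(abs(cross), 1e-6) # A lies on the axis

  # a unique strict y-minimum at a knot is found exactly
  ov <- list()
  ys <- c(370, 370, 370, 320, 370, 370, 370)
  for (k in seq_along(sc@splineDefs$talus_superior)) {
    ov[[as.character(sc@splineDefs$talus_superior[k])]] <- c(380 + 30 * k, ys[k])
  }
  lm2 <- templateWith(ov)
  curve2 <- fitSpline(landmarkPoints(lm2)[sc@splineDefs$talus_superior, ])
  smin <- footmark:::.minimizeOnCurve(curve2, function(q) q[, 2],
                                      df = function(t) curve2$fy(t, deriv = 1))
  expect_lt(abs(smin$point[2] - 320), 1e-3 + 0.35) # spline may dip slightly

  # interior minimum matches 1e5-sample brute force
  s <- evalCurve(curve, seq(0, 1, length.out = 1e5))
  brute <- s[which.min(s[, 2]), ]
  smin3 <- footmark:::.minimizeOnCurve(curve, function(q) q[, 2],
                                       df = function(t) curve$fy(t, deriv = 1))
  expect_lt(max(abs(smin3$point - brute)), 1e-3)
})

test_that("metatarsal axis is the centre line and is rotation-equivariant", {
  sc <- footScheme()
  ov <- list()
  for (k in 1:5) ov[[as.character(19 + k)]] <- c(50 + 10 * (k - 1), -5)
  for (k in 1:4) ov[[as.character(24 + k)]] <- c(50 + 40 * (k - 1) / 3, 5)
  lm <- templateWith(ov)
  ax <- metatarsalAxis(lm)
  expect_equal(ax$direction, c(1, 0), tolerance = 1e-9)
  expect_lt(abs(ax$point[2]), 1e-9)

  p <- landmarkPoints(lm)
  lmr <- landmarkSet(rotatePts(p, 28), pixelSpacing(lm))
  axr <- metatarsalAxis(lmr)
  expect_equal(axr$direction, c(cos(28 * pi / 180), sin(28 * pi / 180)),
               tolerance = 1e-9)
})

test_that("metatarsal axis of non-parallel borders matches a denser fit", {
  sc <- footScheme()
  ov <- list()
  for (k in 1:5) ov[[as.character(19 + k)]] <-
    c(50 + 10 * (k - 1), -4 - 0.08 * 10 * (k - 1))
  for (k in 1:4) ov[[as.character(24 + k)]] <-
    c(50 + 40 * (k - 1) / 3, 4 + 0.04 * 40 * (k - 1) / 3)
  lm <- templateWith(ov)
  a1 <- metatarsalAxis(lm, m = 200L)
  a2 <- metatarsalAxis(lm, m = 2000L)
  ang <- function(d) atan2(d[2], d[1]) * 180 / pi
  expect_lt(abs(ang(a1$direction) - ang(a2$direction)), 1e-3)
})

test_that("Meary's angle sign convention and mirror invariance hold", {
  lm <- footTemplate()
  base <- mearysAngle(lm)

  # rotate the metatarsal block down by 20 deg: angle increases by 20
  sc <- footScheme()
  p <- landmarkPoints(lm)
  met <- sc@blocks$metatarsal
  p[met, ] <- rotatePts(p[met, ], 20, pivot = colMeans(p[c(20, 25), ]))
  expect_equal(mearysAngle(landmarkSet(p, pixelSpacing(lm))), base + 20,
               tolerance = 1e-6)

  # mirrored set measures identically after orientation normalization
  mir <- normalizeOrientation(mirrorLandmarks(lm))$landmarks
  expect_equal(mearysAngle(mir), base, tolerance = 1e-9)

  # unsigned mode is the magnitude
  expect_equal(mearysAngle(lm, mode = "unsigned"), abs(base))
})

test_that("measureAll is invariant to translation, rotation and unit rescaling", {
  lm <- deformTemplate(footTemplate(), deformationParams(12, ct_delta = -4,
                                                         ch_delta = -3))
  m0 <- measureAll(lm)
  p <- landmarkPoints(lm)

  tr <- landmarkSet(sweep(p, 2, c(500, 300), "+"), pixelSpacing(lm))
  expect_equal(unname(measureAll(tr) - m0), rep(0, 3), tolerance = 1e-9)

  ro <- landmarkSet(rotatePts(p, 12, colMeans(p)), pixelSpacing(lm))
  expect_equal(unname(measureAll(ro) - m0), rep(0, 3), tolerance = 1e-9)

  half <- landmarkSet(p / 2, pixelSpacing(lm) * 2)
  expect_equal(unname(measureAll(half) - m0), rep(0, 3), tolerance = 1e-9)

  mirrored <- mirrorLandmarks(lm)
  expect_equal(unname(measureAll(mirrored) - m0), rep(0, 3), tolerance = 1e-9)
})

test_that("the template measures as a normal foot", {
  m <- measureAll(footTemplate())
  expect_equal(m[["ct_deg"]], 18, tolerance = 0.1)
  expect_equal(m[["ch_mm"]], 20, tolerance = 0.15)
  expect_lt(abs(m[["ma_deg"]]), 2)
  expect_equal(as.character(classifyMearys(m[["ma_deg"]])), "normal")
})
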