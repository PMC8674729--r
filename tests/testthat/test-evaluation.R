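mkPanel <- function(M, measurement = "CT", auto = NULL) {
  # M: images x observers matrix -> long panel (plus optional AUTO column)
  rows <- expand.grid(i = seq_len(nrow(M)), o = seq_len(ncol(M)))
  p <- data.frame(image_id = sprintf("I%02d", rows$i),
                  subject_id = sprintf("I%02d", rows$i),
                  observer_id = paste0("E", rows$o),
                  measurement = measurement,
                  value = M[cbind(rows$i, rows$o)],
                  missing = is.na(M[cbind(rows$i, rows$o)]))
  if (!is.null(auto)) {
    p <- rbind(p, data.frame(image_id = sprintf("I%02d", seq_len(nrow(M))),
                             subject_id = sprintf("I%02d", seq_len(nrow(M))),
                             observer_id = "AUTO", measurement = measurement,
                             value = auto, missing = is.na(auto)))
  }
  p
}

test_that("point errors match direct recomputation", {
  gt <- footTemplate()
  expect_equal(pointToPointError(gt, gt), 0)

  p <- landmarkPoints(gt)
  sh <- landmarkSet(sweep(p, 2, c(3, 4), "+"), 1)
  gt1 <- landmarkSet(p, 1)
  expect_equal(pointToPointError(sh, gt1), 5) # 3-4-5 triangle

  set.seed(3)
  pert <- p + matrix(rnorm(122, 0, 2), ncol = 2)
  au <- landmarkSet(pert, pixelSpacing(gt))
  manual <- mean(sqrt(rowSums((pert - p)^2))) * 0.15
  expect_equal(pointToPointError(au, gt), manual, tolerance = 1e-9)

  bad <- landmarkSet(p, 0.3)
  expect_error(pointToPointError(bad, gt), class = "fm_unit_error")
})

test_that("point-to-curve error forgives tangential slippage", {
  gt <- footTemplate()
  expect_equal(pointToCurveError(gt, gt), 0)

  # slide point 22 along its own ground-truth curve: p2c stays ~0, p2p > 0
  sc <- footScheme()
  g <- sc@boneGroups$met1_sup
  cv <- fitSpline(landmarkPoints(gt)[g, ])
  t22 <- cv$knots[which(g == 22L)]
  slid <- landmarkPoints(gt)
  slid[22, ] <- evalCurve(cv, t22 + 0.06)
  au <- landmarkSet(slid, pixelSpacing(gt))
  p2p <- pointToPointError(au, gt)
  p2c <- pointToCurveError(au, gt)
  expect_gt(p2p, 0.03)
  expect_lt(p2c, p2p / 5)
})

test_that("point-to-curve distances match dense brute force", {
  gt <- footTemplate()
  set.seed(11)
  pert <- landmarkPoints(gt) + matrix(rnorm(122, 0, 3), ncol = 2)
  sc <- footScheme()
  for (gname in c("talus", "cuboid", "met1_sup")) {
    g <- sc@boneGroups[[gname]]
    cv <- fitSpline(landmarkPoints(gt)[g, ])
    s <- evalCurve(cv, seq(0, 1, length.out = 1e5))
    for (i in g[c(1, length(g) %/% 2)]) {
      got <- footmark:::.distToCurve(cv, pert[i, ])
      brute <- min(sqrt((s[, 1] - pert[i, 1])^2 + (s[, 2] - pert[i, 2])^2))
      expect_lt(abs(got - brute), 1e-3)
    }
  }
})

test_that("perfect agreement yields ICC2 = 1 with no observer variance", {
  M <- matrix(rep(c(10, 14, 19, 23, 30, 8), 5), ncol = 5)
  r <- icc2Panel(mkPanel(M), "CT")
  expect_equal(r$icc2, 1)
  expect_equal(r$iov, 0)
  expect_equal(r$pov, 0)
})

test_that("ICC2 and variance components match the lme4 REML oracle", {
  skip_if_not_installed("lme4")
  set.seed(7)
  for (rep in 1:12) {
    n <- 50; k <- 5
    M <- 20 + matrix(rnorm(n, 0, 4), n, k) +
      matrix(rnorm(k, 0, 1.2), n, k, byrow = TRUE) +
      matrix(rnorm(n * k, 0, 1.5), n, k)
    r <- icc2Panel(mkPanel(M), "CT")
    p <- mkPanel(M)
    fit <- lme4::lmer(value ~ 1 + (1 | image_id) + (1 | observer_id), data = p,
                      REML = TRUE)
    vc <- as.data.frame(lme4::VarCorr(fit))
    vi <- vc$vcov[vc$grp == "image_id"]
    vo <- vc$vcov[vc$grp == "observer_id"]
    ve <- vc$vcov[vc$grp == "Residual"]
    icc_reml <- vi / (vi + vo + ve)
    expect_lt(abs(r$icc2 - icc_reml), 0.02)
    expect_lt(abs(r$iiv - vi) / max(vi, 1), 0.1)
    expect_lt(abs(r$residual - ve) / ve, 0.1)
  }
})

test_that("a constant observer offset lowers ICC2 and raises IOV", {
  set.seed(2)
  base <- 20 + rnorm(40, 0, 5)
  M <- matrix(base, 40, 5)
  M[, 3] <- M[, 3] + 4
  M <- M + matrix(rnorm(200, 0, 0.4), 40, 5)
  r <- icc2Panel(mkPanel(M), "CT")
  expect_lt(r$icc2, 1)
  expect_gt(r$iov, 0.5)
  expect_true(r$ci[1] <= r$icc2 && r$icc2 <= r$ci[2])
})

test_that("incomplete panels are rejected until filtered", {
  M <- matrix(rnorm(20, 20), 4, 5)
  M[2, 3] <- NA
  p <- mkPanel(M)
  expect_error(icc2Panel(p, "CT"), class = "fm_exclusion_violation")
  fc <- filterComplete(p)
  expect_equal(fc$nExcluded, 1L)
  expect_equal(fc$excluded, "I02")
  r <- icc2Panel(fc$panel, "CT")
  expect_true(is.finite(r$icc2))
})

test_that("bias model recovers exact shifts and the balanced-mean identity", {
  set.seed(5)
  M <- 20 + matrix(rnorm(30 * 5, 0, 3), 30, 5)
  # derived identical to every observer's value is impossible; use obs mean
  auto <- rowMeans(M)
  p0 <- mkPanel(M, auto = rowMeans(M))
  # exact +1 shift
  p1 <- mkPanel(M, auto = rowMeans(M) + 1)
  b1 <- biasModel(p1, "CT")
  D <- (rowMeans(M) + 1) - M
  expect_equal(b1$bias, mean(D)) # identity: grand mean of differences
  expect_equal(b1$bias, 1, tolerance = 1e-9)

  # derived == manual everywhere -> bias 0, p = 1
  Mc <- matrix(rep(seq(10, 29), 5), 20, 5)
  pc <- mkPanel(Mc, auto = Mc[, 1])
  bc <- biasModel(pc, "CT")
  expect_equal(bc$bias, 0)
  expect_equal(bc$p.value, 1)
})

test_that("bias test type-I error is calibrated under the null", {
  set.seed(99)
  n <- 188; k <- 5
  rej <- logical(400)
  for (r in seq_len(400)) {
    # clustered null differences: image and observer random effects + noise
    D <- matrix(rnorm(n, 0, 1.0), n, k) +
      matrix(rnorm(k, 0, 0.7), n, k, byrow = TRUE) +
      matrix(rnorm(n * k, 0, 1.2), n, k)
    pm <- mkPanel(20 - D, auto = rep(20, n)) # derived - manual == D
    rej[r] <- biasModel(pm, "CT")$p.value < 0.05
  }
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.08)
})

test_that("PCC is 1 with degenerate CI for perfect agreement, and seeded", {
  set.seed(8)
  M <- 20 + matrix(rnorm(60, 0, 5), 60, 5) + matrix(rnorm(60 * 5, 0, 1), 60, 5)
  p <- mkPanel(M, auto = rowMeans(M))
  r <- pccBootstrap(p, "CT", seed = 3)
  expect_equal(r$pcc, 1)
  expect_equal(r$ci, c(1, 1), tolerance = 1e-12)
  r2 <- pccBootstrap(p, "CT", seed = 3)
  expect_identical(r, r2)
  # pooled pairing also computes
  rp <- pccBootstrap(p, "CT", pairing = "pooled", seed = 3)
  expect_gt(rp$pcc, 0.8)
})

test_that("independent derived values give PCC near zero with CI covering 0", {
  set.seed(21)
  M <- 20 + matrix(rnorm(500 * 5, 0, 3), 500, 5)
  p <- mkPanel(M, auto = rnorm(500, 20, 3))
  r <- pccBootstrap(p, "CT", seed = 1)
  expect_lt(abs(r$pcc), 0.1)
  expect_lt(r$ci[1], 0)
  expect_gt(r$ci[2], 0)
})

test_that("within-range is boundary-inclusive and monotone", {
  M <- matrix(c(8, 9, 10, 11, 12), 1, 5)
  expect_equal(withinRange(mkPanel(M, auto = 10), "CT")$percent, 100)
  expect_equal(withinRange(mkPanel(M, auto = 12), "CT")$percent, 100)
  expect_equal(withinRange(mkPanel(M, auto = 12.01), "CT")$percent, 0)
  # derived equal to one observer's values -> always within
  set.seed(4)
  Mn <- 20 + matrix(rnorm(25 * 5, 0, 3), 25, 5)
  expect_equal(withinRange(mkPanel(Mn, auto = Mn[, 2]), "CT")$percent, 100)
  # widening an observer's value away from derived never flips within -> out
  a <- rowMeans(Mn)
  base <- withinRange(mkPanel(Mn, auto = a), "CT")$within
  Mw <- Mn; Mw[, 1] <- Mw[, 1] + ifelse(Mw[, 1] >= a, 5, -5)
  wide <- withinRange(mkPanel(Mw, auto = a), "CT")$within
  expect_true(all(wide >= base))
})

test_that("filterComplete handles the all-missing and no-missing cases", {
  M <- matrix(rnorm(15, 20), 3, 5)
  p <- mkPanel(M)
  expect_equal(filterComplete(p)$nExcluded, 0L)
  p$value <- NA; p$missing <- TRUE
  fc <- filterComplete(p)
  expect_equal(fc$nExcluded, 3L)
  expect_equal(nrow(fc$panel), 0L)
})

test_that("fold assignment is balanced, grouped and deterministic", {
  ids <- sprintf("I%02d", 1:20)
  subs <- rep(sprintf("S%02d", 1:10), each = 2)
  f <- assignFolds(ids, subs, k = 5, seed = 1)
  tab <- table(f$fold)
  expect_true(all(tab == 4)) # 2 subjects x 2 images per fold
  expect_true(all(tapply(f$fold, f$subject_id,
                         function(x) length(unique(x))) == 1))
  expect_identical(f, assignFolds(ids, subs, k = 5, seed = 1))

  # a 13-image subject is never split
  ids2 <- c(sprintf("A%02d", 1:13), sprintf("B%d", 1:6))
  subs2 <- c(rep("SA", 13), sprintf("SB%d", 1:6))
  f2 <- assignFolds(ids2, subs2, k = 3, seed = 2)
  expect_equal(length(unique(f2$fold[f2$subject_id == "SA"])), 1L)

  expect_error(assignFolds(ids, subs, k = 11), class = "fm_config_error")
})

test_that("fold image counts respect the greedy packing bound", {
  for (seed in 1:25) {
    set.seed(seed + 1000)
    ns <- 30
    nim <- sample(1:13, ns, replace = TRUE, prob = 13:1)
    subs <- rep(sprintf("S%02d", 1:ns), nim)
    ids <- sprintf("I%03d", seq_along(subs))
    f <- assignFolds(ids, subs, k = 5, seed = seed)
    sizes <- table(factor(f$fold, levels = 1:5))
    expect_lte(max(sizes) - min(sizes), max(nim))
    expect_true(all(tapply(f$fold, f$subject_id,
                           function(x) length(unique(x))) == 1))
  }
})

test_that("error CDF summaries match sort-based statistics", {
  e <- errorCdf(c(1, 2, 3, 4))
  expect_equal(e$median, 2.5)
  expect_equal(e$fractionBelow(3), 0.5)
  expect_equal(e$quantile(0.5), median(c(1, 2, 3, 4)))
  set.seed(6)
  v <- rexp(101)
  expect_equal(errorCdf(v)$quantile(0.5), sort(v)[51], tolerance = 1e-12)
  one <- errorCdf(rep(2.2, 5))
  expect_true(all(one$x == 2.2))
  expect_error(errorCdf(numeric(0)), class = "fm_config_error")
})
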