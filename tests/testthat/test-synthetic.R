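test_that("deformation hits its targets and identity is a fixed point", {
  tm <- footTemplate()
  m0 <- measureAll(tm)
  id <- deformTemplate(tm, deformationParams(ma_target = m0[["ma_deg"]]))
  expect_lt(max(abs(landmarkPoints(id) - landmarkPoints(tm))), 1e-6)

  for (ma in c(0, 8, 20, 35)) {
    lm <- deformTemplate(tm, deformationParams(ma, ct_delta = -2, ch_delta = -4))
    m <- measureAll(lm)
    expect_lt(abs(m[["ma_deg"]] - ma), 0.1)
    expect_lt(abs(m[["ct_deg"]] - (m0[["ct_deg"]] - 2)), 0.1)
    expect_lt(abs(m[["ch_mm"]] - (m0[["ch_mm"]] - 4)), 0.1)
  }
})

test_that("rigid pose does not change any measurement", {
  tm <- footTemplate()
  a <- deformTemplate(tm, deformationParams(15, ch_delta = -6))
  b <- deformTemplate(tm, deformationParams(15, ch_delta = -6, rotation = -8,
                                            translation = c(123, -45),
                                            scale = 0.37))
  expect_equal(unname(measureAll(a)), unname(measureAll(b)), tolerance = 1e-6)
})

test_that("out-of-range targets are rejected", {
  expect_error(deformationParams(ma_target = 50), class = "fm_target_infeasible")
  expect_error(deformationParams(1, ch_delta = 20), class = "fm_target_infeasible")
})

test_that("observer panels reproduce truth exactly when noise-free", {
  obs0 <- observerModel(offsetSd = c(CT = 0, CH = 0, MA = 0),
                        noiseSd = c(CT = 0, CH = 0, MA = 0))
  truth <- c(ct_deg = 18, ch_mm = 20, ma_deg = 3)
  p <- simulatePanel(as.list(truth), obs0)
  expect_equal(nrow(p), 15) # 5 observers x 3 measurements
  expect_equal(p$value[p$measurement == "CT"], rep(18, 5))
  expect_equal(p$value[p$measurement == "MA"], rep(3, 5))
  expect_false(any(p$missing))
})

test_that("panel noise variance matches the observer model (LLN)", {
  set.seed(42)
  obs <- observerModel(offsetSd = c(CT = 0, CH = 0, MA = 0),
                       noiseSd = c(CT = 2, CH = 1, MA = 3),
                       nObservers = 1)
  vals <- replicate(1e4, simulatePanel(list(ct_deg = 0, ch_mm = 0, ma_deg = 0),
                                       obs)$value)
  expect_equal(sd(vals[1, ]), 2, tolerance = 0.05)
  expect_equal(sd(vals[3, ]), 3, tolerance = 0.06)
})

test_that("full missingness empties the panel values", {
  obs <- observerModel(missingRate = 1)
  p <- simulatePanel(list(ct_deg = 18, ch_mm = 20, ma_deg = 3), obs)
  expect_true(all(p$missing))
  expect_true(all(is.na(p$value)))
})

test_that("cohorts have the requested structure and are reproducible", {
  spec <- cohortSpec(nSubjects = 10, imagesPerSubject = 2)
  co <- generateCohort(spec, seed = 4)
  expect_equal(length(co$landmarks), 20L)
  expect_equal(length(unique(co$truth$subject_id)), 10L)
  co2 <- generateCohort(spec, seed = 4)
  expect_identical(co$truth, co2$truth)
  expect_identical(co$panel, co2$panel)
  expect_equal(landmarkPoints(co$landmarks[[5]]),
               landmarkPoints(co2$landmarks[[5]]))
})

test_that("the severity mix is honoured by reclassifying generated truth", {
  spec <- cohortSpec(nSubjects = 20, imagesPerSubject = 2,
                     severityMix = c(normal = 0.5, severe = 0.5,
                                     mild = 0, moderate = 0))
  co <- generateCohort(spec, seed = 9)
  cls <- classifyMearys(co$truth$ma_deg)
  expect_equal(as.vector(table(cls)[c("normal", "severe")]), c(20L, 20L))
  expect_identical(as.character(cls), co$truth$severity)
})

test_that("per-subject anatomy is shared and pixel spacing varies per image", {
  co <- generateCohort(cohortSpec(nSubjects = 6, imagesPerSubject = 3), seed = 2)
  tr <- co$truth
  # images of one subject stay in one severity class
  bysub <- tapply(tr$severity, tr$subject_id, function(x) length(unique(x)))
  expect_true(all(bysub == 1))
  sp <- vapply(co$landmarks, function(l) pixelSpacing(l)[1], 0)
  expect_true(all(sp >= 0.45 & sp <= 0.55))
  expect_gt(length(unique(round(sp, 6))), 1)
})

test_that("rendering is deterministic and bones are brighter than background", {
  lm <- deformTemplate(footTemplate(), deformationParams(8, scale = 0.3))
  r1 <- renderRadiograph(lm, seed = 7)
  r2 <- renderRadiograph(lm, seed = 7)
  expect_identical(r1$image, r2$image)

  r0 <- renderRadiograph(lm, blurSigma = 0, noiseSd = 0)
  img <- r0$image
  pts <- landmarkPoints(r0$landmarks)
  # sample bone interiors at the talar dome centroid and calcaneus centroid
  sc <- footScheme()
  for (g in list(sc@boneGroups$talus, sc@boneGroups$calcaneus)) {
    ctr <- round(colMeans(pts[g, ]))
    expect_gt(img[ctr[2], ctr[1]], img[3, 3] + 0.1)
  }
  # landmarks lie inside the canvas
  expect_true(all(pts[, 1] >= 1 & pts[, 1] <= ncol(img)))
  expect_true(all(pts[, 2] >= 1 & pts[, 2] <= nrow(img)))
})

test_that("a fixed canvas too small for the foot is expanded with a warning", {
  lm <- deformTemplate(footTemplate(), deformationParams(5, scale = 0.3))
  expect_warning(rr <- renderRadiograph(lm, canvas = c(20, 20), noiseSd = 0),
                 "expanding")
  expect_true(all(dim(rr$image) >= 20))
})
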