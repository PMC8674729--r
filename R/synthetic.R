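# Synthetic foot phantoms: a canonical 61-point template, severity-controlled
# block deformations solved by root finding (so the generator's measurement
# labels are exact by construction), observer measurement panels, cohort
# structure with repeated imaging per subject, and schematic pseudo-radiograph
# rendering. This is the package's test bed; it emulates the structure of a
# clinical cohort, not X-ray physics.

#' Canonical 61-point foot template
#'
#' A normal-foot configuration (toes toward +x, y down) at 0.15 mm/px with
#' calcaneal tilt near 18 degrees, cuboid height near 20 mm and Meary's angle
#' near 0-2 degrees, consistent with the landmark scheme's bone outlines.
#'
#' @param spacing template pixel spacing in mm/px.
#' @return A \linkS4class{LandmarkSet} with source "synthetic_truth".
#' @export
footTemplate <- function(spacing = 0.15) {
  pts <- matrix(c(
    435.0, 408.0,   # 1  talus inferior, posterior
    480.0, 418.0,   # 2  talus inferior, middle
    545.0, 420.0,   # 3  talus inferior, anterior
    564.3, 399.3,   # 4  talar neck, superior
    584.3, 419.3,   # 5  talar neck, inferior/distal
    550.0, 358.0,   # 6  talar dome, anterior
    475.0, 330.0,   # 7  talar dome, apex
    405.0, 365.0,   # 8  talar dome, posterior
    420.0, 430.0,   # 9  talus posterior-inferior
    160.0, 595.0,   # 10 calcaneus posterior-inferior (tilt vertex)
    400.0, 595.0,   # 11 calcaneus anterior-inferior (tilt base ray)
    426.3, 508.5,   # 12 calcaneal ramp point (tilt ramp ray)
    175.0, 598.0,   # 13 inferior calcaneus (cuboid-height baseline)
    515.0, 465.3,   # 14 cuboid inferior apex
    700.0, 598.0,   # 15 fifth metatarsal base (baseline)
    425.0, 348.0,   # 16 talar dome
    450.0, 336.0,   # 17 talar dome
    500.0, 333.0,   # 18 talar dome
    525.0, 342.0,   # 19 talar dome
    593.1, 456.4,   # 20 first metatarsal superior border
    670.6, 473.9,   # 21
    748.1, 491.4,   # 22
    825.6, 508.9,   # 23
    903.1, 526.4,   # 24
    586.9, 483.6,   # 25 first metatarsal inferior border
    690.3, 506.9,   # 26
    793.6, 530.3,   # 27
    896.9, 553.6,   # 28
    440.0, 540.0,   # 29 calcaneus anterior
    130.0, 560.0,   # 30 calcaneus posterior
    135.0, 500.0,   # 31 calcaneus posterior-superior
    180.0, 460.0,   # 32 calcaneal tuberosity, superior
    280.0, 470.0,   # 33 calcaneus superior-anterior
    460.0, 430.0,   # 34 cuboid superior-posterior
    515.0, 420.0,   # 35 cuboid superior
    570.0, 428.0,   # 36 cuboid superior-anterior
    455.0, 458.0,   # 37 cuboid inferior outline
    475.0, 462.0,   # 38
    495.0, 464.5,   # 39
    535.0, 464.8,   # 40
    555.0, 462.5,   # 41
    575.0, 459.0,   # 42
    565.0, 430.0,   # 43 navicular
    595.0, 425.0,   # 44
    600.0, 455.0,   # 45
    570.0, 460.0,   # 46
    615.0, 435.0,   # 47 medial cuneiform
    645.0, 440.0,   # 48
    620.0, 465.0,   # 49
    760.0, 590.0,   # 50 fifth metatarsal shaft
    820.0, 583.0,   # 51
    880.0, 577.0,   # 52
    930.0, 573.0,   # 53
    920.0, 560.0,   # 54 first metatarsal head, inferior
    925.0, 535.0,   # 55 first metatarsal head, superior
    390.0, 280.0,   # 56 distal tibia
    440.0, 285.0,   # 57
    470.0, 300.0,   # 58
    420.0, 310.0,   # 59
    150.0, 430.0,   # 60 posterior soft tissue
    950.0, 560.0    # 61 forefoot soft tissue
  ), ncol = 2, byrow = TRUE)
  landmarkSet(pts, spacing = spacing, imageId = "template",
              subjectId = "template", source = "synthetic_truth")
}

#' Deformation parameters for the synthetic generator
#'
#' @param ma_target target Meary's angle in degrees (|ma_target| <= 45).
#' @param ct_delta change in calcaneal tilt relative to the template, degrees.
#' @param ch_delta change in cuboid height relative to the template, mm
#'   (|ch_delta| <= 15).
#' @param rotation,translation,scale rigid pose applied after the anatomical
#'   deformation (degrees, px, unitless). Scaling also rescales the recorded
#'   pixel spacing so mm measurements are pose-invariant.
#' @return list of class "DeformationParams".
#' @export
deformationParams <- function(ma_target = 1, ct_delta = 0, ch_delta = 0,
                              rotation = 0, translation = c(0, 0), scale = 1) {
  if (abs(ma_target) > 45 || abs(ch_delta) > 15) {
    fmStop("fm_target_infeasible",
           "targets outside admissible range (|MA| <= 45 deg, |ch_delta| <= 15 mm)")
  }
  structure(list(ma_target = ma_target, ct_delta = ct_delta,
                 ch_delta = ch_delta, rotation = rotation,
                 translation = translation, scale = scale),
            class = "DeformationParams")
}

.rotateAbout <- function(pts, pivot, deg) {
  th <- deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  sweep(sweep(pts, 2, pivot) %*% t(R), 2, pivot, "+")
}

#' Deform the foot template to hit measurement targets exactly
#'
#' The metatarsal block is rotated about its proximal pivot until Meary's
#' angle equals \code{ma_target}; the calcaneal ramp block is rotated about
#' point 10 until calcaneal tilt equals template tilt + \code{ct_delta}; the
#' cuboid block is translated vertically by exactly
#' \code{-ch_delta / spacing}. The blocks are disjoint from each other's
#' measurement landmarks, so the three 1-D solves are independent and the
#' achieved measurements match the targets to root-finder tolerance. A rigid
#' pose (rotation, translation, scale with compensating spacing) is applied
#' last.
#'
#' @param template LandmarkSet from \code{\link{footTemplate}}.
#' @param params a \code{\link{deformationParams}} object.
#' @param scheme the landmark scheme (supplies block membership).
#' @param imageId,subjectId identifiers for the output.
#' @return A \linkS4class{LandmarkSet} with source "synthetic_truth".
#' @export
deformTemplate <- function(template, params, scheme = footScheme(),
                           imageId = "phantom", subjectId = imageId) {
  pts <- template@points
  sp <- template@spacing
  mk <- function(p, spac = sp) landmarkSet(p, spac, imageId, subjectId,
                                           "synthetic_truth", scheme = NULL)
  base <- measureAll(mk(pts), scheme)

  # Meary's angle: rotate the first-metatarsal block about its proximal base
  met <- scheme@blocks$metatarsal
  pivot_m <- (pts[20, ] + pts[25, ]) / 2
  g_ma <- function(d) {
    q <- pts; q[met, ] <- .rotateAbout(pts[met, ], pivot_m, d)
    mearysAngle(mk(q), scheme) - params$ma_target
  }
  d0 <- params$ma_target - base["ma_deg"]
  sol <- tryCatch(
    stats::uniroot(g_ma, c(d0 - 5, d0 + 5), extendInt = "yes", tol = 1e-9),
    error = function(e) fmStop("fm_target_infeasible",
                               "Meary's-angle solve failed: %s", conditionMessage(e)))
  pts[met, ] <- .rotateAbout(pts[met, ], pivot_m, sol$root)

  # calcaneal tilt: rotate the ramp block about point 10
  if (params$ct_delta != 0) {
    ramp <- scheme@blocks$calcaneus_ramp
    target_ct <- base["ct_deg"] + params$ct_delta
    if (target_ct <= 0.5 || target_ct >= 89.5) {
      fmStop("fm_target_infeasible", "calcaneal-tilt target %.1f out of range", target_ct)
    }
    g_ct <- function(d) {
      q <- pts; q[ramp, ] <- .rotateAbout(pts[ramp, ], pts[10, ], d)
      calcanealTilt(mk(q), scheme) - target_ct
    }
    sol <- tryCatch(
      stats::uniroot(g_ct, c(-params$ct_delta - 5, -params$ct_delta + 5),
                     extendInt = "yes", tol = 1e-9),
      error = function(e) fmStop("fm_target_infeasible",
                                 "calcaneal-tilt solve failed: %s", conditionMessage(e)))
    pts[ramp, ] <- .rotateAbout(pts[ramp, ], pts[10, ], sol$root)
  }

  # cuboid height: vertical translation is exactly linear in the target
  cub <- scheme@blocks$cuboid
  pts[cub, 2] <- pts[cub, 2] - params$ch_delta / mean(sp)

  # rigid pose; spacing compensates the scale so mm values are unchanged
  ctr <- colMeans(pts)
  pts <- .rotateAbout(pts, ctr, params$rotation)
  pts <- sweep(sweep(pts, 2, ctr) * params$scale, 2, ctr + params$translation, "+")
  mk(pts, sp / params$scale)
}

#' Observer panel model
#'
#' Five clinical experts measuring each image: observer o reports
#' truth + offset_o + noise, with the systematic offsets drawn once per
#' observer (per panel/cohort) and independent noise per report. Default
#' offset SDs are the square roots of realistic inter-observer variances for
#' the three measurements; residual noise SDs are plausible within-observer
#' values. All SDs are in measurement units (deg, mm, deg).
#'
#' @param nObservers number of observers.
#' @param offsetSd per-measurement SD of the systematic observer offsets.
#' @param noiseSd per-measurement SD of the per-report noise.
#' @param pointJitterSd SD (px) for annotation-level point jitter simulation.
#' @param missingRate probability a single (observer, measurement) cell is
#'   missing (for exclusion-rule testing).
#' @return list of class "ObserverModel".
#' @export
observerModel <- function(nObservers = 5,
                          offsetSd = c(CT = sqrt(2.4), CH = sqrt(3.6), MA = sqrt(6.6)),
                          noiseSd = c(CT = 2.0, CH = 2.0, MA = 3.5),
                          pointJitterSd = 0, missingRate = 0) {
  stopifnot(nObservers >= 1, all(offsetSd >= 0), all(noiseSd >= 0),
            missingRate >= 0, missingRate <= 1)
  structure(list(nObservers = as.integer(nObservers),
                 offsetSd = offsetSd, noiseSd = noiseSd,
                 pointJitterSd = pointJitterSd, missingRate = missingRate),
            class = "ObserverModel")
}

.measNames <- c(CT = "ct_deg", CH = "ch_mm", MA = "ma_deg")

#' Draw per-observer systematic offsets
#'
#' @param obs an \code{\link{observerModel}}.
#' @return nObservers x 3 matrix of offsets (columns CT, CH, MA).
#' @export
drawObserverOffsets <- function(obs) {
  m <- vapply(names(.measNames),
              function(k) stats::rnorm(obs$nObservers, 0, obs$offsetSd[[k]]),
              numeric(obs$nObservers))
  matrix(m, nrow = obs$nObservers,
         dimnames = list(paste0("E", seq_len(obs$nObservers)), names(.measNames)))
}

#' Simulate one image's observer measurement panel
#'
#' @param truth named numeric c(ct_deg, ch_mm, ma_deg) for the image.
#' @param obs an \code{\link{observerModel}}.
#' @param offsets per-observer offset matrix from
#'   \code{\link{drawObserverOffsets}}; drawn fresh when NULL.
#' @param imageId,subjectId identifiers attached to the rows.
#' @return long data.frame: image_id, subject_id, observer_id, measurement
#'   (CT/CH/MA), value, missing.
#' @export
simulatePanel <- function(truth, obs = observerModel(), offsets = NULL,
                          imageId = "img", subjectId = imageId) {
  if (is.null(offsets)) offsets <- drawObserverOffsets(obs)
  ids <- rownames(offsets)
  rows <- do.call(rbind, lapply(names(.measNames), function(k) {
    val <- truth[[.measNames[[k]]]] + offsets[, k] +
      stats::rnorm(obs$nObservers, 0, obs$noiseSd[[k]])
    miss <- stats::runif(obs$nObservers) < obs$missingRate
    data.frame(image_id = imageId, subject_id = subjectId, observer_id = ids,
               measurement = k, value = ifelse(miss, NA_real_, val),
               missing = miss, stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  rows
}

#' Cohort specification for the synthetic generator
#'
#' Defaults emulate the structure of a clinical podiatry cohort: subjects
#' carry between 1 and 13 images (median 2, IQR 1-3), the severity mix of
#' images is 69:68:34:17 (normal:mild:moderate:severe), and pixel spacing
#' varies across images.
#'
#' @param nSubjects number of subjects.
#' @param imagesPerSubject a single integer (every subject gets that many
#'   images) or a probability vector over 1..length for the per-subject image
#'   count.
#' @param severityMix named proportions over the four classes.
#' @param spacingRange (min, max) mm/px of the per-image pixel spacing.
#' @return list of class "CohortSpec".
#' @export
cohortSpec <- function(nSubjects = 79,
                       imagesPerSubject = c(0.33, 0.27, 0.16, 0.09, 0.05, 0.03,
                                            0.02, 0.015, 0.01, 0.008, 0.006,
                                            0.003, 0.003),
                       severityMix = c(normal = 69, mild = 68, moderate = 34,
                                       severe = 17) / 188,
                       spacingRange = c(0.45, 0.55)) {
  if (abs(sum(severityMix) - 1) > 1e-6) severityMix <- severityMix / sum(severityMix)
  if (!all(names(severityMix) %in% severityLevels())) {
    fmStop("fm_config_error", "severityMix names must be severity classes")
  }
  structure(list(nSubjects = as.integer(nSubjects),
                 imagesPerSubject = imagesPerSubject,
                 severityMix = severityMix, spacingRange = spacingRange),
            class = "CohortSpec")
}

# MA target intervals per class, kept strictly inside the grading boundaries
# so that the class implied by the target survives the root-finder tolerance.
.maIntervals <- list(normal = c(-3.5, 3.8), mild = c(4.6, 14.4),
                     moderate = c(15.3, 29.7), severe = c(30.5, 42))
# class-dependent calcaneal-tilt and cuboid-height changes (mean, sd):
# the arch flattens and the cuboid drops as collapse progresses
.ctDelta <- list(normal = c(2, 4), mild = c(-2, 3.5),
                 moderate = c(-6, 3), severe = c(-10, 3))
.chDelta <- list(normal = c(1, 4), mild = c(-2, 3.5),
                 moderate = c(-6, 3), severe = c(-11, 2.5))

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate a synthetic cohort
#'
#' Subjects are assigned image counts from the cohort spec, severity classes
#' are packed onto subjects so the image-level class mix matches the spec
#' within rounding (largest-deficit greedy over subjects sorted by image
#' count), and each subject carries a base deformation shared by its images
#' plus a linear per-image progression drift, clamped within the subject's
#' class interval. Every image gets its own rigid pose and pixel spacing.
#'
#' @param spec a \code{\link{cohortSpec}}.
#' @param template the foot template LandmarkSet.
#' @param obs an \code{\link{observerModel}} for the measurement panel.
#' @param seed integer seed; the whole cohort is reproducible from it.
#' @return list with \code{landmarks} (list of truth LandmarkSets),
#'   \code{truth} (data.frame image_id, subject_id, ct_deg, ch_mm, ma_deg,
#'   severity) and \code{panel} (long observer measurement data.frame).
#' @export
generateCohort <- function(spec = cohortSpec(), template = footTemplate(),
                           obs = observerModel(), seed = 1) {
  set.seed(seed)
  ns <- spec$nSubjects
  nim <- if (length(spec$imagesPerSubject) == 1L) {
    rep(as.integer(spec$imagesPerSubject), ns)
  } else {
    sample(seq_along(spec$imagesPerSubject), ns, replace = TRUE,
           prob = spec$imagesPerSubject)
  }
  total <- sum(nim)

  # greedy class packing: subjects with many images first, each to the class
  # with the largest remaining image deficit
  classes <- names(spec$severityMix)
  deficit <- spec$severityMix * total
  subjClass <- character(ns)
  for (i in order(nim, decreasing = TRUE)) {
    k <- which.max(deficit)
    subjClass[i] <- classes[k]
    deficit[k] <- deficit[k] - nim[i]
  }

  tmpl_sp <- mean(template@spacing)
  landmarks <- list(); truthRows <- list(); panelRows <- list()
  offsets <- drawObserverOffsets(obs)
  img_i <- 0L
  for (s in seq_len(ns)) {
    cls <- subjClass[s]
    iv <- .maIntervals[[cls]]
    ma_base <- stats::runif(1, iv[1], iv[2])
    drift <- stats::rnorm(1, 0.3, 0.2)
    ct_base <- .clamp(stats::rnorm(1, .ctDelta[[cls]][1], .ctDelta[[cls]][2]), -14, 10)
    ch_base <- .clamp(stats::rnorm(1, .chDelta[[cls]][1], .chDelta[[cls]][2]), -14.5, 10)
    sid <- sprintf("S%03d", s)
    for (j in seq_len(nim[s])) {
      img_i <- img_i + 1L
      iid <- sprintf("%s_I%02d", sid, j)
      ma_t <- .clamp(ma_base + (j - 1) * drift, iv[1], iv[2])
      ct_t <- .clamp(ct_base + stats::rnorm(1, 0, 0.3), -14, 10)
      ch_t <- .clamp(ch_base + stats::rnorm(1, 0, 0.3), -14.5, 10)
      sp_img <- stats::runif(1, spec$spacingRange[1], spec$spacingRange[2])
      prm <- deformationParams(
        ma_target = ma_t, ct_delta = ct_t, ch_delta = ch_t,
        rotation = stats::runif(1, -5, 5),
        translation = stats::runif(2, -15, 15),
        scale = tmpl_sp / sp_img
      )
      lm <- deformTemplate(template, prm, imageId = iid, subjectId = sid)
      tr <- measureAll(lm)
      landmarks[[iid]] <- lm
      truthRows[[iid]] <- data.frame(
        image_id = iid, subject_id = sid, ct_deg = tr[["ct_deg"]],
        ch_mm = tr[["ch_mm"]], ma_deg = tr[["ma_deg"]],
        severity = as.character(classifyMearys(tr[["ma_deg"]])),
        stringsAsFactors = FALSE)
      panelRows[[iid]] <- simulatePanel(as.list(tr), obs, offsets, iid, sid)
    }
  }
  list(landmarks = landmarks,
       truth = do.call(rbind, c(truthRows, list(make.row.names = FALSE))),
       panel = do.call(rbind, c(panelRows, list(make.row.names = FALSE))))
}
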