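# Pipeline front ends wiring the modules into reproducible batch runs. Each
# run writes its resolved configuration next to its outputs, and batch jobs
# never abort on a single-image failure: failures become flagged rows.

.writeRunConfig <- function(outDir, command, params) {
  cfg <- c(list(tool = "footmark",
                version = as.character(utils::packageVersion("footmark")),
                command = command), params)
  jsonlite::write_json(cfg, file.path(outDir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
}

#' Simulate a synthetic dataset to disk
#'
#' Writes, per image, a rendered pseudo-radiograph (PNG plus a JSON sidecar
#' with pixel spacing, or a DICOM file) and a truth landmark file in the JSON
#' annotation dialect (image coordinates), plus a truth measurement CSV, the
#' observer panel CSV and the resolved run config.
#'
#' @param outDir output directory (created if missing).
#' @param spec a \code{\link{cohortSpec}}.
#' @param obs an \code{\link{observerModel}}.
#' @param seed cohort seed; the whole dataset is reproducible from it.
#' @param format "png" (with sidecar) or "dicom".
#' @param render write images at all (truth points and tables are always
#'   written).
#' @return invisibly, the generated cohort (with image-coordinate landmarks).
#' @export
runSimulate <- function(outDir, spec = cohortSpec(), obs = observerModel(),
                        seed = 1, format = c("png", "dicom"), render = TRUE) {
  format <- match.arg(format)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generateCohort(spec, obs = obs, seed = seed)
  for (i in seq_along(cohort$landmarks)) {
    lm <- cohort$landmarks[[i]]
    id <- imageId(lm)
    if (render) {
      rr <- renderRadiograph(lm, seed = seed * 10000 + i)
      lm <- rr$landmarks
      cohort$landmarks[[i]] <- lm
      if (format == "png") {
        png::writePNG(rr$image, file.path(outDir, paste0(id, ".png")))
        jsonlite::write_json(
          list(image_id = id, subject_id = subjectId(lm),
               spacing = pixelSpacing(lm)),
          file.path(outDir, paste0(id, "_meta.json")),
          auto_unbox = TRUE, digits = NA)
      } else {
        writeDicom(rr$image, file.path(outDir, paste0(id, ".dcm")),
                   spacing = pixelSpacing(lm))
      }
    }
    writePoints(lm, file.path(outDir, paste0(id, ".json")))
  }
  utils::write.csv(cohort$truth, file.path(outDir, "truth.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$panel, file.path(outDir, "panel.csv"),
                   row.names = FALSE)
  .writeRunConfig(outDir, "simulate",
                  list(seed = seed, format = format,
                       n_subjects = spec$nSubjects,
                       severity_mix = as.list(spec$severityMix),
                       spacing_range = spec$spacingRange,
                       n_observers = obs$nObservers))
  invisible(cohort)
}

#' Measure a directory (or list) of landmark annotations
#'
#' One CSV row per image with ct_deg, ch_mm, ma_deg, severity and a flag
#' column; per-image geometry failures are flagged and non-fatal.
#'
#' @param input a directory containing .json/.pts annotation files, a
#'   character vector of files, or a list of LandmarkSets.
#' @param outCsv optional CSV path.
#' @param spacing spacing override for text-dialect files.
#' @param scheme the landmark scheme.
#' @return data.frame of measurements (invisibly written to outCsv if given).
#' @export
runMeasure <- function(input, outCsv = NULL, spacing = 1, scheme = footScheme()) {
  lms <- if (is.list(input) && !is.character(input)) {
    input
  } else {
    files <- if (length(input) == 1 && dir.exists(input)) {
      list.files(input, pattern = "\\.(json|pts)$", full.names = TRUE)
    } else input
    files <- files[!grepl("_meta\\.json$|^run_config", basename(files))]
    if (length(files) == 0) fmStop("fm_usage_error", "no annotation inputs found")
    lapply(files, readPoints, scheme = scheme, spacing = spacing)
  }
  rows <- lapply(lms, function(lm) {
    m <- tryCatch(measureAll(lm, scheme), footmark_error = function(e) e)
    if (inherits(m, "error")) {
      data.frame(image_id = imageId(lm), subject_id = subjectId(lm),
                 ct_deg = NA_real_, ch_mm = NA_real_, ma_deg = NA_real_,
                 severity = NA_character_, flag = "geometry_error",
                 stringsAsFactors = FALSE)
    } else {
      data.frame(image_id = imageId(lm), subject_id = subjectId(lm),
                 ct_deg = m[["ct_deg"]], ch_mm = m[["ch_mm"]],
                 ma_deg = m[["ma_deg"]],
                 severity = as.character(classifyMearys(m[["ma_deg"]])),
                 flag = "", stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(outCsv)) utils::write.csv(out, outCsv, row.names = FALSE)
  invisible(out)
}

# derived measurements -> AUTO panel rows
.autoRows <- function(meas) {
  do.call(rbind, lapply(names(.measNames), function(k) {
    data.frame(image_id = meas$image_id, subject_id = meas$subject_id,
               observer_id = "AUTO", measurement = k,
               value = meas[[.measNames[[k]]]],
               missing = is.na(meas[[.measNames[[k]]]]),
               stringsAsFactors = FALSE)
  }))
}

.loadPointsDir <- function(dir, scheme) {
  files <- list.files(dir, pattern = "\\.(json|pts)$", full.names = TRUE)
  files <- files[!grepl("_meta\\.json$", basename(files))]
  lms <- lapply(files, readPoints, scheme = scheme)
  names(lms) <- vapply(lms, imageId, "")
  lms
}

#' Evaluate automatic results against truth points and an observer panel
#'
#' Produces the full statistics suite: per-image point-to-point and
#' point-to-curve errors with CDF summaries, manual inter-observer agreement
#' (ICC(2,1), IOV, IIV, POV) per measurement, and the automatic-vs-manual
#' comparison (bias mixed model, bootstrap Pearson correlation, percentage
#' within observer range), overall and per severity class. The exclusion rule
#' (\code{\link{filterComplete}}) is honoured before any panel statistic.
#'
#' @param auto named list of automatic LandmarkSets, or a directory of files.
#' @param truth named list of truth LandmarkSets, or a directory of files.
#' @param panel long observer panel data.frame, or a panel CSV path.
#' @param outDir optional directory for the report CSVs.
#' @param scheme the landmark scheme.
#' @param seed bootstrap seed.
#' @return list: errors (per-image data.frame), cdf (point-to-point
#'   \code{\link{errorCdf}}), agreement, comparison, perSeverity, nExcluded.
#' @export
runEvaluate <- function(auto, truth, panel, outDir = NULL,
                        scheme = footScheme(), seed = 1) {
  if (is.character(auto)) auto <- .loadPointsDir(auto, scheme)
  if (is.character(truth)) truth <- .loadPointsDir(truth, scheme)
  if (is.character(panel)) panel <- utils::read.csv(panel)
  panel$missing <- as.logical(panel$missing)
  ids <- names(truth)
  missing_auto <- setdiff(ids, names(auto))
  extra_auto <- setdiff(names(auto), ids)
  if (length(missing_auto) || length(extra_auto)) {
    fmStop("fm_alignment_error", "image-id mismatch (missing: %s; extra: %s)",
           paste(missing_auto, collapse = ","), paste(extra_auto, collapse = ","))
  }
  errors <- data.frame(
    image_id = ids,
    subject_id = vapply(truth, subjectId, ""),
    p2p_mm = vapply(ids, function(i) pointToPointError(auto[[i]], truth[[i]]), 0),
    p2c_mm = vapply(ids, function(i) pointToCurveError(auto[[i]], truth[[i]], scheme), 0),
    stringsAsFactors = FALSE)
  rownames(errors) <- NULL

  fc <- filterComplete(panel)
  kept <- fc$panel
  autoMeas <- runMeasure(auto[unique(kept$image_id)], scheme = scheme)
  full <- rbind(kept[, c("image_id", "subject_id", "observer_id",
                         "measurement", "value", "missing")],
                .autoRows(autoMeas))
  meas <- names(.measNames)
  agreement <- lapply(stats::setNames(meas, meas),
                      function(m) icc2Panel(kept, m))
  cmpOne <- function(p, tag) {
    lapply(stats::setNames(meas, meas), function(m) {
      wr <- withinRange(p, m)
      b <- biasModel(p, m)
      pc <- pccBootstrap(p, m, seed = seed)
      list(bias = b$bias, p.value = b$p.value, pcc = pc$pcc, ci = pc$ci,
           within_pct = wr$percent, n = wr$n, stratum = tag)
    })
  }
  comparison <- cmpOne(full, "all")
  # severity from the mean manual Meary's angle per image
  ma <- kept[kept$measurement == "MA" & kept$observer_id != "AUTO", ]
  mma <- tapply(ma$value, ma$image_id, mean)
  sev <- classifyMearys(as.numeric(mma))
  names(sev) <- names(mma)
  perSeverity <- list()
  for (cl in severityLevels()) {
    idsCl <- names(sev)[sev == cl]
    if (length(idsCl) >= 3) {
      perSeverity[[cl]] <- tryCatch(
        cmpOne(full[full$image_id %in% idsCl, ], cl),
        footmark_error = function(e) NULL)
    }
  }
  res <- list(errors = errors, cdf = errorCdf(errors$p2p_mm),
              agreement = agreement, comparison = comparison,
              perSeverity = perSeverity, severity = sev,
              nExcluded = fc$nExcluded)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(errors, file.path(outDir, "point_errors.csv"),
                     row.names = FALSE)
    agr <- do.call(rbind, lapply(meas, function(m) {
      a <- agreement[[m]]
      data.frame(measurement = m, icc2 = a$icc2, ci_lo = a$ci[1],
                 ci_hi = a$ci[2], iov = a$iov, iiv = a$iiv,
                 residual = a$residual, pov = a$pov, n = a$n)
    }))
    utils::write.csv(agr, file.path(outDir, "agreement.csv"), row.names = FALSE)
    cmpRows <- function(cmp) do.call(rbind, lapply(meas, function(m) {
      x <- cmp[[m]]
      data.frame(stratum = x$stratum, measurement = m, bias = x$bias,
                 p_value = x$p.value, pcc = x$pcc, pcc_ci_lo = x$ci[1],
                 pcc_ci_hi = x$ci[2], within_pct = x$within_pct, n = x$n)
    }))
    cmpAll <- rbind(cmpRows(comparison),
                    do.call(rbind, lapply(perSeverity, cmpRows)))
    utils::write.csv(cmpAll, file.path(outDir, "comparison.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(p2p_mm = res$cdf$x, F = res$cdf$F),
                     file.path(outDir, "p2p_cdf.csv"), row.names = FALSE)
    .writeRunConfig(outDir, "evaluate",
                    list(seed = seed, n_images = length(ids),
                         n_excluded = fc$nExcluded))
  }
  res
}

#' Cross-validated end-to-end pipeline
#'
#' Renders (or loads) a synthetic dataset, runs subject-grouped k-fold
#' cross-validated landmark localization, measures the automatic points and
#' evaluates them against the truth points and observer panel.
#'
#' @param dataset either a directory written by \code{\link{runSimulate}}
#'   (PNG format) or an in-memory list with elements \code{images} (named list
#'   of matrices), \code{truths} (named list of LandmarkSets) and \code{panel}.
#' @param k folds.
#' @param seed fold and training seed.
#' @param outDir optional output directory for points, reports and manifest.
#' @param config a \code{\link{pointFinderConfig}}.
#' @param verbose print fold progress.
#' @return list: auto, folds, evaluation (from \code{\link{runEvaluate}}).
#' @export
runCrossval <- function(dataset, k = 10, seed = 1, outDir = NULL,
                        config = pointFinderConfig(), verbose = FALSE) {
  if (is.character(dataset)) {
    dir <- dataset
    truths <- .loadPointsDir(dir, footScheme())
    imgs <- lapply(names(truths), function(id) {
      png::readPNG(file.path(dir, paste0(id, ".png")))
    })
    names(imgs) <- names(truths)
    panel <- utils::read.csv(file.path(dir, "panel.csv"))
    dataset <- list(images = imgs, truths = truths, panel = panel)
  }
  cv <- crossvalPointFinder(dataset$images, dataset$truths, k = k, seed = seed,
                            config = config, verbose = verbose)
  ev <- runEvaluate(cv$auto, dataset$truths, dataset$panel, outDir = outDir,
                    seed = seed)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(cv$folds, file.path(outDir, "fold_manifest.csv"),
                     row.names = FALSE)
    for (id in names(cv$auto)) {
      writePoints(cv$auto[[id]], file.path(outDir, paste0(id, "_auto.json")))
    }
    .writeRunConfig(outDir, "crossval", list(seed = seed, k = k))
  }
  list(auto = cv$auto, folds = cv$folds, evaluation = ev)
}
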