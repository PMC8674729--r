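#' Read a landmark annotation file
#'
#' Two dialects are supported and auto-detected from the extension: a minimal
#' text format (header line `n_points: 61`, then one `x y` pair per line in
#' index order, optionally wrapped in `{ ... }`) and a JSON twin with keys
#' `image_id`, `subject_id`, `spacing`, `points`.
#'
#' @param path file to read.
#' @param scheme LandmarkScheme the file must conform to.
#' @param spacing mm-per-pixel override for the text dialect (which carries no
#'   spacing itself); ignored for JSON files that state their own spacing.
#' @param imageId,subjectId,source metadata overrides for the text dialect.
#' @return A \linkS4class{LandmarkSet}.
#' @export
readPoints <- function(path, scheme = footScheme(), spacing = 1,
                       imageId = sub("\\.(pts|txt|json)$", "", basename(path)),
                       subjectId = imageId, source = "manual") {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    d <- jsonlite::read_json(path, simplifyVector = TRUE)
    pts <- matrix(as.numeric(unlist(d$points)), ncol = 2, byrow = is.list(d$points))
    if (!is.null(dim(d$points))) pts <- as.matrix(d$points)
    return(landmarkSet(pts, spacing = as.numeric(d$spacing),
                       imageId = d$image_id %||% imageId,
                       subjectId = d$subject_id %||% subjectId,
                       source = d$source %||% source, scheme = scheme))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  hdr <- grep("^n_points\\s*:", lines)
  if (length(hdr) != 1L) {
    fmStop("fm_parse_error", "%s: missing 'n_points:' header", path)
  }
  n <- suppressWarnings(as.integer(sub("^n_points\\s*:\\s*", "", lines[hdr])))
  if (is.na(n)) fmStop("fm_parse_error", "%s: bad n_points header", path)
  body <- lines[-seq_len(hdr)]
  body <- body[!(body %in% c("", "{", "}"))]
  if (length(body) != n) {
    fmStop("fm_scheme_mismatch", "%s: header says %d points, file has %d",
           path, n, length(body))
  }
  if (n != scheme@nPoints) {
    fmStop("fm_scheme_mismatch", "%s: file has %d points, scheme expects %d",
           path, n, scheme@nPoints)
  }
  pts <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    tok <- strsplit(body[i], "\\s+")[[1]]
    val <- suppressWarnings(as.numeric(tok))
    if (length(val) != 2L || any(is.na(val))) {
      fmStop("fm_parse_error", "%s: non-numeric coordinates on point line %d",
             path, i)
    }
    pts[i, ] <- val
  }
  landmarkSet(pts, spacing = spacing, imageId = imageId,
              subjectId = subjectId, source = source, scheme = scheme)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a landmark annotation file
#'
#' Canonical formatting: text dialect with 6-decimal coordinates (lossless
#' round trip with \code{readPoints} at that precision), or the JSON twin when
#' the path ends in \code{.json}.
#'
#' @param lm a LandmarkSet.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writePoints <- function(lm, path) {
  pts <- lm@points
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(
      image_id = lm@imageId, subject_id = lm@subjectId,
      spacing = lm@spacing, source = lm@source,
      points = unname(apply(pts, 1, function(r) round(r, 6), simplify = FALSE))
    ), path, auto_unbox = TRUE, digits = NA)
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("n_points: %d", nrow(pts)), con)
  writeLines("{", con)
  writeLines(sprintf("%.6f %.6f", pts[, 1], pts[, 2]), con)
  writeLines("}", con)
  invisible(path)
}

#' Canonicalize landmark orientation (toes toward +x)
#'
#' Lateral radiographs come in both lateralities. The canonical form has the
#' toes toward +x: if the mean x of the metatarsal indices (20-28) is less
#' than the mean x of the calcaneal indices (10, 11, 12), all points are
#' mirrored about the vertical midline of the point bounding box. Idempotent;
#' applying it to a mirrored set recovers the original geometry.
#'
#' @param lm a LandmarkSet.
#' @param scheme LandmarkScheme supplying the index sets.
#' @return list with elements \code{landmarks} (canonical LandmarkSet) and
#'   \code{flipped} (logical).
#' @export
normalizeOrientation <- function(lm, scheme = footScheme()) {
  pts <- lm@points
  mx_met <- mean(pts[20:28, 1])
  mx_cal <- mean(pts[c(10, 11, 12), 1])
  flipped <- mx_met < mx_cal
  if (flipped) {
    mid <- (min(pts[, 1]) + max(pts[, 1]))
    pts[, 1] <- mid - pts[, 1]
    lm <- landmarkSet(pts, lm@spacing, lm@imageId, lm@subjectId, lm@source,
                      scheme = NULL)
  }
  list(landmarks = lm, flipped = flipped)
}

#' Mirror a landmark set about its vertical midline
#'
#' Utility used in tests and by the synthetic generator to produce the
#' opposite laterality.
#'
#' @param lm a LandmarkSet.
#' @return the mirrored LandmarkSet.
#' @export
mirrorLandmarks <- function(lm) {
  pts <- lm@points
  mid <- (min(pts[, 1]) + max(pts[, 1]))
  pts[, 1] <- mid - pts[, 1]
  landmarkSet(pts, lm@spacing, lm@imageId, lm@subjectId, lm@source, scheme = NULL)
}
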