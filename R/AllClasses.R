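#' @import methods
NULL

fmStop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "footmark_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

#' Landmark scheme for lateral foot radiographs
#'
#' Describes the ordered landmark model: how many points there are, which
#' ordered index runs define the piecewise cubic splines used by the geometry
#' calculator, which index pairs define straight construction lines, and which
#' ordered index sets outline each bone (used by the point-to-curve error).
#' Indices are 1-based throughout the public API.
#'
#' @slot nPoints integer, number of landmarks per image.
#' @slot splineDefs named list of integer vectors (ordered, length >= 3).
#' @slot lineDefs named list of integer pairs.
#' @slot boneGroups named list of ordered integer vectors outlining each bone.
#' @slot blocks named list of integer vectors giving anatomical block
#'   membership (used by the synthetic deformation model).
#' @export
setClass("LandmarkScheme", representation(
  nPoints = "integer",
  splineDefs = "list",
  lineDefs = "list",
  boneGroups = "list",
  blocks = "list"
))

setValidity("LandmarkScheme", function(object) {
  n <- object@nPoints
  if (length(n) != 1L || is.na(n) || n < 1L) {
    return("nPoints must be a single positive integer")
  }
  chk <- function(defs, what, minlen) {
    for (nm in names(defs)) {
      idx <- defs[[nm]]
      if (any(idx < 1L | idx > n)) {
        return(sprintf("%s '%s' has indices outside [1, %d]", what, nm, n))
      }
      if (length(idx) < minlen) {
        return(sprintf("%s '%s' needs >= %d indices", what, nm, minlen))
      }
      if (what == "splineDefs" && anyDuplicated(idx)) {
        return(sprintf("spline '%s' repeats an index", nm))
      }
      if (what == "lineDefs" && length(idx) != 2L) {
        return(sprintf("line '%s' must have exactly 2 indices", nm))
      }
    }
    TRUE
  }
  for (args in list(list(object@splineDefs, "splineDefs", 3L),
                    list(object@lineDefs, "lineDefs", 2L),
                    list(object@boneGroups, "boneGroups", 1L))) {
    res <- chk(args[[1]], args[[2]], args[[3]])
    if (!isTRUE(res)) return(res)
  }
  TRUE
})

#' One annotated image: 61 ordered 2-D landmark points
#'
#' Coordinates are image pixel coordinates: x = column, y = row, origin at the
#' top-left, y increasing downward (inferiorly). Pixel spacing is mm per pixel
#' (row, col) and must be near-isotropic, since angles are computed in pixel
#' space.
#'
#' @slot imageId character image identifier.
#' @slot subjectId character subject identifier.
#' @slot points numeric n x 2 matrix of (x, y) pixel coordinates.
#' @slot spacing numeric length-2 (row, col) mm-per-pixel.
#' @slot source one of "manual", "automatic", "synthetic_truth".
#' @export
setClass("LandmarkSet", representation(
  imageId = "character",
  subjectId = "character",
  points = "matrix",
  spacing = "numeric",
  source = "character"
))

setValidity("LandmarkSet", function(object) {
  p <- object@points
  if (!is.numeric(p) || ncol(p) != 2L) return("points must be an n x 2 numeric matrix")
  if (!all(is.finite(p))) return("all coordinates must be finite")
  sp <- object@spacing
  if (length(sp) != 2L || any(!is.finite(sp)) || any(sp <= 0)) {
    return("spacing must be two positive numbers (row, col) in mm/px")
  }
  if (abs(sp[1] - sp[2]) / sp[1] >= 0.01) {
    return("anisotropic pixel spacing (row vs col differ by >= 1%); angles in pixel space require isotropy")
  }
  if (!object@source %in% c("manual", "automatic", "synthetic_truth")) {
    return("source must be manual, automatic or synthetic_truth")
  }
  TRUE
})

#' Construct a LandmarkSet
#'
#' @param points n x 2 numeric matrix of (x, y) pixel coordinates.
#' @param spacing mm-per-pixel; a single number or (row, col) pair.
#' @param imageId,subjectId identifiers.
#' @param source annotation source ("manual", "automatic", "synthetic_truth").
#' @param scheme LandmarkScheme the set must conform to, or NULL to skip the
#'   point-count check.
#' @return A \linkS4class{LandmarkSet}.
#' @export
landmarkSet <- function(points, spacing, imageId = "img", subjectId = imageId,
                        source = "manual", scheme = footScheme()) {
  points <- as.matrix(points)
  dimnames(points) <- NULL
  if (length(spacing) == 1L) spacing <- c(spacing, spacing)
  if (!is.null(scheme) && nrow(points) != scheme@nPoints) {
    fmStop("fm_scheme_mismatch", "expected %d points, got %d",
           scheme@nPoints, nrow(points))
  }
  new("LandmarkSet", imageId = as.character(imageId),
      subjectId = as.character(subjectId), points = points,
      spacing = as.numeric(spacing), source = source)
}

#' @rdname LandmarkSet-accessors
#' @param object a LandmarkSet.
#' @export
setGeneric("landmarkPoints", function(object) standardGeneric("landmarkPoints"))
#' Accessors for LandmarkSet
#'
#' @param object a LandmarkSet.
#' @name LandmarkSet-accessors
#' @aliases landmarkPoints,LandmarkSet-method
#' @export
setMethod("landmarkPoints", "LandmarkSet", function(object) object@points)

#' @rdname LandmarkSet-accessors
#' @export
setGeneric("pixelSpacing", function(object) standardGeneric("pixelSpacing"))
#' @rdname LandmarkSet-accessors
#' @export
setMethod("pixelSpacing", "LandmarkSet", function(object) object@spacing)

#' @rdname LandmarkSet-accessors
#' @export
setGeneric("imageId", function(object) standardGeneric("imageId"))
#' @rdname LandmarkSet-accessors
#' @export
setMethod("imageId", "LandmarkSet", function(object) object@imageId)

#' @rdname LandmarkSet-accessors
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))
#' @rdname LandmarkSet-accessors
#' @export
setMethod("subjectId", "LandmarkSet", function(object) object@subjectId)

#' @rdname LandmarkSet-accessors
#' @export
setGeneric("landmarkSource", function(object) standardGeneric("landmarkSource"))
#' @rdname LandmarkSet-accessors
#' @export
setMethod("landmarkSource", "LandmarkSet", function(object) object@source)

setMethod("show", "LandmarkSet", function(object) {
  cat(sprintf("LandmarkSet '%s' (subject '%s', %s)\n", object@imageId,
              object@subjectId, object@source))
  cat(sprintf("  %d points, spacing %.4g mm/px\n", nrow(object@points),
              object@spacing[1]))
  rng <- apply(object@points, 2, range)
  cat(sprintf("  x in [%.1f, %.1f], y in [%.1f, %.1f]\n",
              rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2]))
})

setMethod("show", "LandmarkScheme", function(object) {
  cat(sprintf("LandmarkScheme: %d points, %d splines, %d lines, %d bone groups\n",
              object@nPoints, length(object@splineDefs),
              length(object@lineDefs), length(object@boneGroups)))
})

#' Shape-constrained random-forest landmark localizer model
#'
#' @slot shape list: PCA shape model (mean, modes, mode SDs, reference shape).
#' @slot stages list of per-resolution-stage regressor banks.
#' @slot config list of training hyperparameters.
#' @export
setClass("PointFinderModel", representation(
  shape = "list",
  stages = "list",
  config = "list"
))

setMethod("show", "PointFinderModel", function(object) {
  cat(sprintf("PointFinderModel: %d landmarks, %d stages, %d shape modes\n",
              nrow(object@shape$mean), length(object@stages),
              ncol(object@shape$modes)))
})
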