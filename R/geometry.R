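# Geometry calculator: calcaneal tilt, cuboid height, Meary's angle from a
# LandmarkSet via natural cubic splines, centre lines and line/curve distances.
# All operations work in image coordinates (y down); angles are computed in
# pixel space (valid because LandmarkSet enforces near-isotropic spacing) and
# distances are converted to mm via the pixel spacing.

#' Fit an interpolating natural cubic spline through ordered 2-D points
#'
#' Chord-length parameterized (cumulative chord length normalized to [0, 1]),
#' natural boundary conditions (zero second derivative). The curve
#' interpolates every control point exactly.
#'
#' @param pts m x 2 matrix of ordered control points (m >= 3).
#' @return A \code{FootCurve} object: evaluate with \code{evalCurve}.
#' @export
fitSpline <- function(pts) {
  pts <- as.matrix(pts)
  if (nrow(pts) < 3) fmStop("fm_degenerate_geometry", "spline needs >= 3 points")
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  if (any(seg < 1e-12)) {
    fmStop("fm_degenerate_knot", "coincident consecutive spline control points")
  }
  tt <- c(0, cumsum(seg)) / sum(seg)
  structure(list(
    fx = stats::splinefun(tt, pts[, 1], method = "natural"),
    fy = stats::splinefun(tt, pts[, 2], method = "natural"),
    knots = tt, control = pts
  ), class = "FootCurve")
}

#' Evaluate a FootCurve at parameter values
#'
#' @param curve a FootCurve from \code{fitSpline}.
#' @param t parameter values in [0, 1].
#' @return length(t) x 2 matrix of curve points.
#' @export
evalCurve <- function(curve, t) {
  cbind(curve$fx(t), curve$fy(t))
}

# Parameters at m uniform normalized-arc-length fractions.
.arcLengthParams <- function(curve, m, dense = max(2000L, 10L * m)) {
  tt <- seq(0, 1, length.out = dense)
  p <- evalCurve(curve, tt)
  al <- c(0, cumsum(sqrt(rowSums(diff(p)^2))))
  al <- al / al[length(al)]
  stats::approx(al, tt, xout = seq(0, 1, length.out = m), ties = "ordered")$y
}

#' @rdname evalCurve
#' @export
curveDeriv <- function(curve, t) {
  cbind(curve$fx(t, deriv = 1), curve$fy(t, deriv = 1))
}

# Minimize a scalar function of the curve point over the curve: dense sampling,
# then local refinement -- by root finding on the analytic objective derivative
# when available (machine-precision extrema), golden section otherwise.
.minimizeOnCurve <- function(curve, f, df = NULL, m = 1000L) {
  tt <- seq(0, 1, length.out = m)
  v <- f(evalCurve(curve, tt))
  i <- which.min(v)
  lo <- tt[max(1L, i - 1L)]; hi <- tt[min(m, i + 1L)]
  best_t <- tt[i]; best_v <- v[i]
  refined <- FALSE
  if (!is.null(df) && lo < hi) {
    dlo <- df(lo); dhi <- df(hi)
    if (is.finite(dlo) && is.finite(dhi) && dlo < 0 && dhi > 0) {
      rt <- stats::uniroot(df, c(lo, hi), tol = 1e-14)$root
      rv <- f(evalCurve(curve, rt))
      if (rv <= best_v) { best_t <- rt; best_v <- rv; refined <- TRUE }
    }
  }
  if (!refined && lo < hi) {
    opt <- stats::optimize(function(t) f(evalCurve(curve, t)), c(lo, hi),
                           tol = 1e-10)
    if (opt$objective < best_v) { best_t <- opt$minimum; best_v <- opt$objective }
  }
  list(t = best_t, value = best_v, point = drop(evalCurve(curve, best_t)))
}

.angleDeg <- function(u, v) {
  cosang <- sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

#' @rdname measureAll
#' @export
setGeneric("calcanealTilt", function(lm, ...) standardGeneric("calcanealTilt"))

#' @rdname measureAll
#' @export
setMethod("calcanealTilt", "LandmarkSet", function(lm, scheme = footScheme()) {
  p <- lm@points
  u <- p[scheme@lineDefs$ct_base[2], ] - p[scheme@lineDefs$ct_base[1], ]
  v <- p[scheme@lineDefs$ct_ramp[2], ] - p[scheme@lineDefs$ct_ramp[1], ]
  if (sum(u^2) < 1e-18 || sum(v^2) < 1e-18) {
    fmStop("fm_degenerate_geometry", "calcaneal tilt: coincident defining points")
  }
  a <- .angleDeg(u, v)
  if (a > 90) a <- 180 - a
  a
})

# Unit normal of the line a->b pointing to the superior side (smaller y).
.superiorNormal <- function(a, b) {
  d <- (b - a) / sqrt(sum((b - a)^2))
  n <- c(d[2], -d[1])
  if (n[2] > 0) n <- -n
  if (n[2] == 0 && n[1] < 0) n <- -n
  n
}

# Signed perpendicular distance (px) of points q to the infinite line through
# a and b, positive on the superior side.
.signedLineDist <- function(q, a, b) {
  drop(sweep(q, 2, a) %*% .superiorNormal(a, b))
}

#' @rdname measureAll
#' @export
setGeneric("cuboidHeight", function(lm, ...) standardGeneric("cuboidHeight"))

#' @rdname measureAll
#' @export
setMethod("cuboidHeight", "LandmarkSet", function(lm, scheme = footScheme()) {
  p <- lm@points
  a <- p[scheme@lineDefs$ch_base[1], ]; b <- p[scheme@lineDefs$ch_base[2], ]
  if (sum((b - a)^2) < 1e-18) {
    fmStop("fm_degenerate_geometry", "cuboid height: degenerate baseline")
  }
  curve <- fitSpline(p[scheme@splineDefs$cuboid_inferior, ])
  nrm <- .superiorNormal(a, b)
  res <- .minimizeOnCurve(curve,
                          function(q) .signedLineDist(q, a, b),
                          df = function(t) drop(curveDeriv(curve, t) %*% nrm))
  res$value * mean(lm@spacing)
})

.tlsAxis <- function(pts) {
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr))
  dir <- sv$v[, 1]
  if (sv$d[1] < 1e-9) {
    fmStop("fm_degenerate_axis", "axis fit: no spread in midpoints")
  }
  if (dir[1] < 0 || (dir[1] == 0 && dir[2] < 0)) dir <- -dir
  list(point = ctr, direction = dir)
}

#' @rdname measureAll
#' @param m number of matched arc-length samples for the metatarsal centre line.
#' @export
setGeneric("metatarsalAxis", function(lm, ...) standardGeneric("metatarsalAxis"))

#' @rdname measureAll
#' @export
setMethod("metatarsalAxis", "LandmarkSet", function(lm, scheme = footScheme(),
                                                    m = 200L) {
  p <- lm@points
  ca <- fitSpline(p[scheme@splineDefs$metatarsal_a, ])
  cb <- fitSpline(p[scheme@splineDefs$metatarsal_b, ])
  ta <- .arcLengthParams(ca, m); tb <- .arcLengthParams(cb, m)
  mids <- (evalCurve(ca, ta) + evalCurve(cb, tb)) / 2
  # match sampling directions: if the two splines run in opposite senses the
  # midpoints collapse toward the crossing; pick the pairing with more spread
  mids2 <- (evalCurve(ca, ta) + evalCurve(cb, rev(tb))) / 2
  if (sum(apply(mids2, 2, stats::var)) > sum(apply(mids, 2, stats::var))) {
    mids <- mids2
  }
  .tlsAxis(mids)
})

#' @rdname measureAll
#' @export
setGeneric("talarAxis", function(lm, ...) standardGeneric("talarAxis"))

#' @rdname measureAll
#' @export
setMethod("talarAxis", "LandmarkSet", function(lm, scheme = footScheme()) {
  p <- lm@points
  A <- (p[scheme@lineDefs$talus_neck[1], ] + p[scheme@lineDefs$talus_neck[2], ]) / 2
  curve <- fitSpline(p[scheme@splineDefs$talus_superior, ])
  # "most superior" is measured against the weight-bearing baseline (13->15)
  # rather than raw image y, so the construction is rigid-motion invariant;
  # on an upright radiograph the two coincide
  a <- p[scheme@lineDefs$ch_base[1], ]; b <- p[scheme@lineDefs$ch_base[2], ]
  sstar <- if (sum((b - a)^2) > 1e-18) {
    nrm <- .superiorNormal(a, b)
    .minimizeOnCurve(curve,
                     function(q) -.signedLineDist(q, a, b),
                     df = function(t) -drop(curveDeriv(curve, t) %*% nrm))$point
  } else {
    .minimizeOnCurve(curve, function(q) q[, 2],
                     df = function(t) curve$fy(t, deriv = 1))$point
  }
  B <- (p[9, ] + sstar) / 2
  if (sum((A - B)^2) < 1e-18) {
    fmStop("fm_degenerate_geometry", "talar axis: coincident centres")
  }
  dir <- A - B
  dir <- dir / sqrt(sum(dir^2))
  if (dir[1] < 0 || (dir[1] == 0 && dir[2] < 0)) dir <- -dir
  list(point = B, direction = dir)
})

#' @rdname measureAll
#' @export
setGeneric("mearysAngle", function(lm, ...) standardGeneric("mearysAngle"))

#' @rdname measureAll
#' @export
setMethod("mearysAngle", "LandmarkSet", function(lm, scheme = footScheme(),
                                                 mode = c("signed", "unsigned")) {
  mode <- match.arg(mode)
  t_ax <- talarAxis(lm, scheme)$direction
  m_ax <- metatarsalAxis(lm, scheme)$direction
  ang <- atan2(t_ax[1] * m_ax[2] - t_ax[2] * m_ax[1], sum(t_ax * m_ax)) * 180 / pi
  if (ang > 90) ang <- ang - 180
  if (ang <= -90) ang <- ang + 180
  if (mode == "unsigned") abs(ang) else ang
})

#' Measure calcaneal tilt, cuboid height and Meary's angle
#'
#' The three standard radiographic measurements of longitudinal-arch collapse,
#' computed from the 61-point landmark model:
#' \describe{
#'   \item{calcaneal tilt (deg, unsigned, in [0, 90])}{angle at point 10
#'     between the rays to points 11 and 12.}
#'   \item{cuboid height (mm, signed)}{minimum signed perpendicular distance
#'     from the spline through points 37-38-39-14-40-41-42 to the infinite
#'     line through points 13 and 15; positive when the cuboid outline is
#'     superior to the baseline, negative once it has crossed inferiorly
#'     (rocker-bottom collapse).}
#'   \item{Meary's angle (deg, signed, in (-90, 90])}{angle from the talar
#'     axis to the metatarsal axis; positive when the metatarsal axis deviates
#'     inferiorly (arch collapse).}
#' }
#' \code{measureAll} canonicalizes orientation (toes toward +x) exactly once
#' before measuring; the individual operations assume canonical orientation.
#'
#' @param lm a \linkS4class{LandmarkSet}.
#' @param scheme the \linkS4class{LandmarkScheme}.
#' @param mode for Meary's angle: "signed" (default) or "unsigned".
#' @param ... passed through to methods.
#' @return \code{measureAll}: named numeric vector
#'   \code{c(ct_deg, ch_mm, ma_deg)}. Axis functions: list(point, direction).
#' @export
setGeneric("measureAll", function(lm, ...) standardGeneric("measureAll"))

#' @rdname measureAll
#' @export
setMethod("measureAll", "LandmarkSet", function(lm, scheme = footScheme(),
                                                mode = c("signed", "unsigned")) {
  mode <- match.arg(mode)
  lm <- normalizeOrientation(lm, scheme)$landmarks
  c(ct_deg = calcanealTilt(lm, scheme),
    ch_mm = cuboidHeight(lm, scheme),
    ma_deg = mearysAngle(lm, scheme, mode = mode))
})
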