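# Schematic pseudo-radiograph rendering: filled bone polygons with brighter
# cortical rims on a soft-tissue background gradient, then Gaussian blur and
# additive noise. Deliberately not a physical DRR; just enough appearance
# structure for the landmark localizer to learn from.

# even-odd scanline polygon fill into a logical matrix (rows = y, cols = x)
.fillPolygon <- function(nr, nc, poly) {
  mask <- matrix(FALSE, nr, nc)
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  for (r in max(1L, floor(min(y))):min(nr, ceiling(max(y)))) {
    cross <- (y <= r) != (y2 <= r)
    if (!any(cross)) next
    xs <- x[cross] + (r - y[cross]) / (y2[cross] - y[cross]) * (x2[cross] - x[cross])
    xs <- sort(xs)
    for (i in seq(1, length(xs) - 1, by = 2)) {
      c1 <- max(1L, ceiling(xs[i])); c2 <- min(nc, floor(xs[i + 1]))
      if (c1 <= c2) mask[r, c1:c2] <- TRUE
    }
  }
  mask
}

# mark pixels within ~radius of the densely sampled polyline
.strokePath <- function(nr, nc, path, radius = 1, closed = TRUE) {
  mask <- matrix(FALSE, nr, nc)
  if (closed) path <- rbind(path, path[1, ])
  pts <- NULL
  for (i in seq_len(nrow(path) - 1)) {
    a <- path[i, ]; b <- path[i + 1, ]
    m <- max(2L, ceiling(sqrt(sum((b - a)^2))))
    pts <- rbind(pts, cbind(seq(a[1], b[1], length.out = m),
                            seq(a[2], b[2], length.out = m)))
  }
  off <- expand.grid(dx = -radius:radius, dy = -radius:radius)
  for (k in seq_len(nrow(off))) {
    cc <- round(pts[, 1]) + off$dx[k]; rr <- round(pts[, 2]) + off$dy[k]
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    mask[cbind(rr[ok], cc[ok])] <- TRUE
  }
  mask
}

.gaussKernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k / sum(k)
}

# separable Gaussian blur with replicated edges
.gblur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- .gaussKernel(sigma)
  r <- (length(k) - 1L) / 2L
  pad <- function(m, r) m[c(rep(1, r), seq_len(nrow(m)), rep(nrow(m), r)), , drop = FALSE]
  conv1 <- function(m) { # along rows (dimension 1)
    mp <- pad(m, r)
    out <- matrix(0, nrow(m), ncol(m))
    for (i in seq_along(k)) out <- out + k[i] * mp[i:(i + nrow(m) - 1L), , drop = FALSE]
    out
  }
  t(conv1(t(conv1(img))))
}

#' Render a landmark set as a schematic pseudo-radiograph
#'
#' The landmarks are shifted so the foot sits inside the canvas with a margin;
#' the returned LandmarkSet carries the shifted (image) coordinates, so the
#' truth points index directly into the image matrix (x = column, y = row).
#'
#' @param lm a LandmarkSet in canonical orientation.
#' @param scheme the landmark scheme (bone groups drive the polygons).
#' @param margin canvas margin in px around the landmark bounding box.
#' @param canvas optional c(nrow, ncol); expanded with a warning if the
#'   landmarks (plus margin) do not fit.
#' @param blurSigma Gaussian blur SD in px.
#' @param noiseSd additive Gaussian noise SD (intensity units, image in [0,1]).
#' @param seed seed for the noise; same seed, same image.
#' @return list: \code{image} (matrix in [0,1], rows = y), \code{landmarks}
#'   (LandmarkSet in image coordinates).
#' @export
renderRadiograph <- function(lm, scheme = footScheme(), margin = 15,
                             canvas = NULL, blurSigma = 1.2, noiseSd = 0.03,
                             seed = NULL) {
  pts <- lm@points
  shift <- c(margin + 1 - floor(min(pts[, 1])), margin + 1 - floor(min(pts[, 2])))
  pts <- sweep(pts, 2, shift, "+")
  need <- c(ceiling(max(pts[, 2])) + margin, ceiling(max(pts[, 1])) + margin)
  if (is.null(canvas)) {
    canvas <- need
  } else if (any(canvas < need)) {
    warning("landmarks outside canvas; expanding")
    canvas <- pmax(canvas, need)
  }
  nr <- canvas[1]; nc <- canvas[2]

  # soft-tissue background: gentle vertical gradient
  img <- matrix(rep(seq(0.12, 0.30, length.out = nr), nc), nr, nc)
  polys <- list(
    scheme@boneGroups$calcaneus, scheme@boneGroups$talus,
    scheme@boneGroups$cuboid,
    c(20L, 21L, 22L, 23L, 24L, 55L, 54L, 28L, 27L, 26L, 25L),
    scheme@boneGroups$navicular, scheme@boneGroups$cuneiform,
    scheme@boneGroups$tibia
  )
  for (g in polys) {
    poly <- pts[g, , drop = FALSE]
    img[.fillPolygon(nr, nc, poly)] <- 0.55
    img[.strokePath(nr, nc, poly, radius = 1, closed = TRUE)] <- 0.85
  }
  # fifth metatarsal rendered as a thick shaft
  m5 <- pts[scheme@boneGroups$met5, , drop = FALSE]
  img[.strokePath(nr, nc, m5, radius = 3, closed = FALSE)] <- 0.55
  img[.strokePath(nr, nc, m5, radius = 1, closed = FALSE)] <- 0.85

  img <- .gblur(img, blurSigma)
  if (noiseSd > 0) {
    if (!is.null(seed)) set.seed(seed)
    img <- img + matrix(stats::rnorm(nr * nc, 0, noiseSd), nr, nc)
  }
  img <- pmin(pmax(img, 0), 1)
  list(image = img,
       landmarks = landmarkSet(pts, lm@spacing, lm@imageId, lm@subjectId,
                               lm@source, scheme = NULL))
}
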