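# Simplified shape-constrained regression-voting landmark localizer: per
# landmark, random-forest regressors predict the displacement from a sampled
# patch to the landmark; votes are accumulated over a search grid and the
# voted positions are regularized by a PCA shape model (similarity pose +
# bounded modes), iterated coarse-to-fine. A functional stand-in for full
# regression-voting constrained local models, sized for a single CPU.

#' Localizer hyperparameters
#'
#' @param patchHalf half-width of the square intensity patch (patch is
#'   (2*patchHalf+1)^2 normalized raw intensities).
#' @param trees trees per displacement forest.
#' @param minNode,sampleFraction forest growth controls (ranger
#'   min.node.size and per-tree sample fraction).
#' @param samplesPerImage random displacement samples per landmark per
#'   training image (plus one centered sample); one value per stage
#'   (recycled), since the fine stage needs the most supervision.
#' @param stageFactors integer downscale factor per resolution stage
#'   (coarse to fine).
#' @param searchRange per-stage displacement/search radius in stage px.
#' @param gridStep per-stage search grid step in stage px.
#' @param patchSpacing per-stage spacing (stage px) between patch samples;
#'   values > 1 widen the spatial context seen by the regressors.
#' @param maxIter,moveTol iteration cap and mean-movement stopping tolerance (px).
#' @param refinePasses unconstrained confidence-blended vote passes after the
#'   final constrained stage.
#' @param priorPrecision shape-prior precision (1/px^2) balancing the vote
#'   precision in the final blend.
#' @param augmentRot,augmentScale training augmentation: patch-grid rotation
#'   range (deg) and scale range (fraction).
#' @param augmentReps augmentation replicates per training image (the first
#'   replicate is always unaugmented).
#' @param modeVarFrac shape-model variance fraction retained.
#' @param modeLimit shape-mode clamp in SDs.
#' @param irlsRounds robust reweighting rounds inside each shape fit (1 = no
#'   reweighting).
#' @param seed training seed.
#' @return list of class "PointFinderConfig".
#' @export
pointFinderConfig <- function(patchHalf = 3L, trees = 14L, samplesPerImage = 9L,
                              stageFactors = c(4L, 2L, 1L),
                              searchRange = c(12L, 6L, 5L),
                              gridStep = c(4L, 2L, 1L),
                              patchSpacing = c(2, 2, 1),
                              maxIter = 3L, moveTol = 0.5, refinePasses = 2L,
                              priorPrecision = 0.1,
                              augmentRot = 15, augmentScale = 0.1,
                              augmentReps = 3L,
                              modeVarFrac = 0.998, modeLimit = 3,
                              irlsRounds = 2L, minNode = 8L,
                              sampleFraction = 0.7, seed = 1L) {
  structure(as.list(environment()), class = "PointFinderConfig")
}

.downscale <- function(img, f) {
  if (f == 1L) return(img)
  nr <- (nrow(img) %/% f) * f; nc <- (ncol(img) %/% f) * f
  img <- img[seq_len(nr), seq_len(nc)]
  m <- matrix(colMeans(matrix(img, f)), nr %/% f) # average rows in blocks of f
  t(matrix(colMeans(matrix(t(m), f)), nc %/% f))
}

# sample square patches centered at `centers` (m x 2, (x, y)) with bilinear
# interpolation (sub-pixel accuracy matters for the displacement votes); the
# sampling grid may be rotated/scaled (training augmentation). Per-patch
# normalized.
.extractPatches <- function(img, centers, patchHalf, angle = 0, scale = 1) {
  g <- as.matrix(expand.grid(dx = -patchHalf:patchHalf, dy = -patchHalf:patchHalf))
  th <- angle * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  g <- g %*% t(R) * scale
  nr <- nrow(img); nc <- ncol(img)
  xs <- pmin(pmax(outer(centers[, 1], g[, 1], "+"), 1), nc)
  ys <- pmin(pmax(outer(centers[, 2], g[, 2], "+"), 1), nr)
  x0 <- pmin(floor(xs), nc - 1L); y0 <- pmin(floor(ys), nr - 1L)
  fx <- xs - x0; fy <- ys - y0
  at <- function(r, c) matrix(img[cbind(as.vector(r), as.vector(c))],
                              nrow(centers))
  v <- (1 - fx) * (1 - fy) * at(y0, x0) + fx * (1 - fy) * at(y0, x0 + 1) +
    (1 - fx) * fy * at(y0 + 1, x0) + fx * fy * at(y0 + 1, x0 + 1)
  mu <- rowMeans(v)
  sdv <- sqrt(pmax(rowMeans(v^2) - mu^2, 0)) + 1e-6
  v <- (v - mu) / sdv
  colnames(v) <- paste0("p", seq_len(ncol(v)))
  v
}

# Generalized Procrustes alignment + PCA shape model
.buildShapeModel <- function(shapes, varFrac) {
  norm1 <- function(p) {
    p <- sweep(p, 2, colMeans(p))
    p / sqrt(sum(p^2))
  }
  sizes <- vapply(shapes, function(p) {
    sqrt(sum(sweep(p, 2, colMeans(p))^2))
  }, 0)
  aligned <- lapply(shapes, norm1)
  mu <- norm1(Reduce(`+`, aligned) / length(aligned))
  for (it in 1:3) {
    aligned <- lapply(aligned, function(p) {
      M <- t(p) %*% mu
      sv <- svd(M)
      R <- sv$u %*% t(sv$v)
      if (det(R) < 0) { sv$u[, 2] <- -sv$u[, 2]; R <- sv$u %*% t(sv$v) }
      p %*% R
    })
    mu <- norm1(Reduce(`+`, aligned) / length(aligned))
  }
  X <- do.call(rbind, lapply(aligned, as.vector))
  pc <- stats::prcomp(X, center = TRUE)
  v <- pc$sdev^2
  nm <- if (sum(v) <= 0) 1L else max(1L, which(cumsum(v) / sum(v) >= varFrac)[1])
  list(mean = matrix(pc$center, ncol = 2), modes = pc$rotation[, seq_len(nm), drop = FALSE],
       sdev = pc$sdev[seq_len(nm)], meanSize = mean(sizes))
}

# similarity-align the model mean to candidate points (Y ~ s * mu %*% R + t),
# clamp mode weights, reconstruct in image coordinates. Candidates can carry
# per-landmark 2x2 vote precision matrices (list `prec`): the pose uses their
# traces as scalar weights, while the mode fit is an anisotropic generalized
# least squares, so an edge landmark whose votes are concentrated across the
# edge but smeared along it still contributes its reliable direction, and is
# placed along the ambiguous direction by the shape model.
.fitShape <- function(shape, Y, modeLimit, prec = NULL, w = NULL, irls = 1L) {
  n <- nrow(Y)
  wExt <- if (is.null(w)) rep(1, n) else w
  base <- wExt * (if (is.null(prec)) rep(1, n) else
    vapply(prec, function(p) p[1, 1] + p[2, 2], 0))
  rho <- rep(1, n)
  fit <- Y
  for (round in seq_len(max(1L, irls))) {
    ww <- base * rho
    ww <- ww / sum(ww)
    mu <- sweep(shape$mean, 2, colSums(shape$mean * ww))
    Yc <- sweep(Y, 2, colSums(Y * ww))
    M <- t(mu * ww) %*% Yc
    sv <- svd(M)
    R <- sv$u %*% t(sv$v)
    if (det(R) < 0) { sv$u[, 2] <- -sv$u[, 2]; R <- sv$u %*% t(sv$v) }
    s <- sum(diag(t(R) %*% M)) / sum(ww * rowSums(mu^2))
    Ym <- (Yc %*% t(R)) / s # candidates in the model frame
    P <- shape$modes
    r <- as.vector(Ym) - as.vector(mu)
    if (is.null(prec)) {
      W <- rep(ww, 2)
      A <- t(P) %*% (W * P) + diag(1e-9, ncol(P))
      b <- as.vector(solve(A, t(P) %*% (W * r)))
    } else {
      # rotate each vote precision into the model frame; overall scale cancels
      W <- matrix(0, 2 * n, 2 * n)
      for (l in seq_len(n)) {
        pm <- (rho[l] * wExt[l]) * (t(R) %*% prec[[l]] %*% R)
        W[c(l, l + n), c(l, l + n)] <- pm
      }
      A <- t(P) %*% W %*% P + diag(1e-9, ncol(P))
      b <- as.vector(solve(A, t(P) %*% (W %*% r)))
    }
    b <- pmin(pmax(b, -modeLimit * shape$sdev), modeLimit * shape$sdev)
    rec <- matrix(as.vector(mu) + P %*% b, ncol = 2)
    fit <- sweep(s * rec %*% R, 2, colSums(Y * ww), "+")
    # robust reweighting: candidates far from the fitted shape, relative to
    # the current residual level, are outliers (self-scaling threshold so
    # genuine bulk movement early in the search is not rejected)
    res <- sqrt(rowSums((Y - fit)^2))
    cth <- 2 * stats::median(res) + 3
    rho <- 1 / (1 + (res / cth)^2)
  }
  fit
}

#' Train the landmark point-finder
#'
#' Builds the PCA shape model from Procrustes-aligned truth shapes and, per
#' landmark and resolution stage, trains two random-forest regressors (dx, dy)
#' on normalized intensity patches sampled at random displacements from the
#' truth, with rotation/scale patch-grid augmentation.
#'
#' @param images list of grayscale image matrices.
#' @param truths matching list of truth LandmarkSets (image coordinates).
#' @param config a \code{\link{pointFinderConfig}}.
#' @return A \linkS4class{PointFinderModel}.
#' @export
trainPointFinder <- function(images, truths, config = pointFinderConfig()) {
  if (length(images) < 10) {
    fmStop("fm_insufficient_data", "need >= 10 training images, got %d",
           length(images))
  }
  set.seed(config$seed)
  shapes <- lapply(truths, function(t) t@points)
  nL <- nrow(shapes[[1]])
  shape <- .buildShapeModel(shapes, config$modeVarFrac)
  shape$refShape <- sweep(Reduce(`+`, shapes) / length(shapes), 2,
                          colMeans(Reduce(`+`, shapes) / length(shapes)))
  factors <- config$stageFactors
  stages <- vector("list", length(factors))
  for (si in seq_along(factors)) {
    f <- factors[si]
    r <- config$searchRange[si]
    psp <- config$patchSpacing[si]
    ns <- rep_len(config$samplesPerImage, length(factors))[si]
    imgsS <- lapply(images, .downscale, f = f)
    feats <- list()
    labs <- list()
    for (ii in seq_along(images)) {
      pts <- shapes[[ii]] / f
      for (rep in seq_len(config$augmentReps)) {
        d <- matrix(stats::runif(nL * ns * 2, -r, r), ncol = 2)
        d <- rbind(d, matrix(0, nL, 2)) # one centered sample per landmark
        lidx <- c(rep(seq_len(nL), each = ns), seq_len(nL))
        centers <- pts[lidx, ] + d
        ang <- if (rep == 1) 0 else
          stats::runif(1, -config$augmentRot, config$augmentRot)
        scl <- if (rep == 1) 1 else
          stats::runif(1, 1 - config$augmentScale, 1 + config$augmentScale)
        feats[[length(feats) + 1L]] <- .extractPatches(
          imgsS[[ii]], centers, config$patchHalf, angle = ang, scale = scl * psp)
        labs[[length(labs) + 1L]] <- cbind(lidx, -d)
      }
    }
    X <- do.call(rbind, feats)
    L <- do.call(rbind, labs)
    dxF <- vector("list", nL); dyF <- vector("list", nL)
    for (l in seq_len(nL)) {
      sel <- L[, 1] == l
      dxF[[l]] <- ranger::ranger(x = X[sel, , drop = FALSE], y = L[sel, 2],
                                 num.trees = config$trees, num.threads = 1,
                                 min.node.size = config$minNode,
                                 sample.fraction = config$sampleFraction,
                                 seed = config$seed + l)
      dyF[[l]] <- ranger::ranger(x = X[sel, , drop = FALSE], y = L[sel, 3],
                                 num.trees = config$trees, num.threads = 1,
                                 min.node.size = config$minNode,
                                 sample.fraction = config$sampleFraction,
                                 seed = config$seed + 1000 + l)
    }
    stages[[si]] <- list(factor = f, range = r, step = config$gridStep[si],
                         spacing = psp, dx = dxF, dy = dyF)
  }
  new("PointFinderModel", shape = shape, stages = stages,
      config = unclass(config))
}

.predictDisp <- function(stage, l, feats) {
  cbind(stats::predict(stage$dx[[l]], data = feats, num.threads = 1)$predictions,
        stats::predict(stage$dy[[l]], data = feats, num.threads = 1)$predictions)
}

# Hough-style coarse initialization: a landmark subset votes for the shape
# centroid over a translation grid; the densest vote bin wins.
.coarseInit <- function(model, img, stage) {
  cfg <- model@config
  ref <- model@shape$refShape / stage$factor
  nL <- nrow(ref)
  lsub <- seq(1L, nL, by = 6L)
  gx <- seq(1, ncol(img), by = 6)
  gy <- seq(1, nrow(img), by = 6)
  grid <- as.matrix(expand.grid(x = gx, y = gy))
  feats <- .extractPatches(img, grid, cfg$patchHalf, scale = stage$spacing)
  votes <- NULL
  for (l in lsub) {
    d <- .predictDisp(stage, l, feats)
    tau <- grid + d - matrix(ref[l, ], nrow(grid), 2, byrow = TRUE)
    votes <- rbind(votes, tau)
  }
  bin <- 8
  key <- paste(round(votes[, 1] / bin), round(votes[, 2] / bin))
  top <- names(which.max(table(key)))
  sel <- key == top
  colMeans(votes[sel, , drop = FALSE])
}

# After the translation vote, grid-search the leading shape modes: at the
# correct configuration the displacement regressors predict near-zero
# displacements, so the summed predicted displacement magnitude scores a
# candidate shape. Gives the iterative search a capture range covering the
# full deformity spectrum (e.g. metatarsal rotation), which translation-only
# initialization at the mean shape does not.
.coarseModeSearch <- function(model, img, stage, ctr, nModes = 2L) {
  cfg <- model@config
  sh <- model@shape
  s <- sh$meanSize / stage$factor
  b <- rep(0, length(sh$sdev))
  grid <- seq(-2.5, 2.5, length.out = 9)
  place <- function(bb) {
    rec <- matrix(as.vector(sh$mean) + sh$modes %*% bb, ncol = 2)
    sweep(s * rec, 2, ctr, "+")
  }
  for (m in seq_len(min(nModes, length(sh$sdev)))) {
    cands <- grid * sh$sdev[m]
    pos <- lapply(cands, function(cc) { bb <- b; bb[m] <- cc; place(bb) })
    tot <- numeric(length(cands))
    for (l in seq_len(nrow(sh$mean))) {
      centers <- do.call(rbind, lapply(pos, function(p) p[l, ]))
      feats <- .extractPatches(img, centers, cfg$patchHalf,
                               scale = stage$spacing)
      d <- .predictDisp(stage, l, feats)
      tot <- tot + pmin(sqrt(rowSums(d^2)), stage$range)
    }
    b[m] <- cands[which.min(tot)]
  }
  place(b)
}

#' Locate the 61 landmarks in an image
#'
#' Initializes the mean shape at the best coarse whole-shape vote position,
#' then alternates regression-voting (per landmark, predicted displacements
#' over a search grid vote for the landmark position) with bounded shape-model
#' fits, over two resolution stages, until the mean point movement falls below
#' the tolerance.
#'
#' @param model a trained \linkS4class{PointFinderModel}.
#' @param img grayscale image matrix.
#' @param spacing pixel spacing (mm/px) recorded on the output.
#' @param imageId,subjectId identifiers for the output LandmarkSet.
#' @return A \linkS4class{LandmarkSet} with source "automatic".
#' @export
findPoints <- function(model, img, spacing, imageId = "img",
                       subjectId = imageId) {
  if (stats::sd(img) < 1e-9) {
    fmStop("fm_localization_failure", "blank image: no appearance signal")
  }
  cfg <- model@config
  # the consensus search samples subsets; keep the call deterministic
  haveSeed <- exists(".Random.seed", .GlobalEnv)
  if (haveSeed) oldSeed <- get(".Random.seed", .GlobalEnv)
  on.exit(if (haveSeed) assign(".Random.seed", oldSeed, .GlobalEnv))
  set.seed(cfg$seed)
  nL <- nrow(model@shape$refShape)
  pts <- NULL
  for (si in seq_along(model@stages)) {
    stage <- model@stages[[si]]
    imgS <- .downscale(img, stage$factor)
    if (si == 1) {
      ctr <- .coarseInit(model, imgS, stage)
      pts <- .coarseModeSearch(model, imgS, stage, ctr)
    } else {
      pts <- pts * model@stages[[si - 1]]$factor / stage$factor
    }
    g <- as.matrix(expand.grid(dx = seq(-stage$range, stage$range, by = stage$step),
                               dy = seq(-stage$range, stage$range, by = stage$step)))
    vote <- function(l, grid) {
      centers <- sweep(grid, 2, pts[l, ], "+")
      feats <- .extractPatches(imgS, centers, cfg$patchHalf,
                               scale = stage$spacing)
      v <- centers + .predictDisp(stage, l, feats)
      # density peak of the votes: the candidate is the densest vote cluster,
      # which ignores stray votes from off-structure patches; the cluster's
      # 2x2 covariance tracks per-direction reliability (edge landmarks are
      # concentrated across the edge but smeared along it), and sparse
      # clusters get proportionally less precision
      D <- as.matrix(stats::dist(v))
      cnt <- rowSums(D < 3)
      sel <- D[which.max(cnt), ] < 3
      vc <- v[sel, , drop = FALSE]
      C <- if (nrow(vc) > 2) stats::cov(vc) else diag(2)
      # clamp covariance eigenvalues so no landmark can dominate the shape
      # fit with a spuriously tight (self-confirming) vote cluster
      ei <- eigen(C + diag(0.5, 2), symmetric = TRUE)
      ev <- pmin(pmax(ei$values, 0.75), 50)
      Cc <- ei$vectors %*% diag(ev) %*% t(ei$vectors)
      list(cand = colMeans(vc), prec = solve(Cc) * mean(sel),
           conf = mean(sel) / (1 + sum(diag(C))))
    }
    cand <- matrix(0, nL, 2); prec <- vector("list", nL); conf <- numeric(nL)
    tau <- cfg$priorPrecision
    for (it in seq_len(cfg$maxIter)) {
      for (l in seq_len(nL)) {
        vl <- vote(l, g)
        cand[l, ] <- vl$cand
        prec[[l]] <- vl$prec
        conf[l] <- vl$conf
      }
      fit <- .fitShape(model@shape, cand, cfg$modeLimit, prec = prec,
                       irls = cfg$irlsRounds)
      # per-landmark precision blend: reliable vote directions lead, the
      # shape fit fills in the ambiguous ones
      newPts <- pts
      for (l in seq_len(nL)) {
        newPts[l, ] <- solve(prec[[l]] + diag(tau, 2),
                             prec[[l]] %*% cand[l, ] + tau * fit[l, ])
      }
      move <- mean(sqrt(rowSums((newPts - pts)^2)))
      pts <- newPts
      if (move < cfg$moveTol) break
    }
    if (si == length(model@stages)) {
      # final refinement: unconstrained local vote passes, blending the voted
      # position with the shape-constrained one per direction according to
      # the vote precision (reliable directions follow the votes, ambiguous
      # ones stay where the shape model put them)
      g2 <- as.matrix(expand.grid(dx = -3:3, dy = -3:3))
      tau <- cfg$priorPrecision
      for (pass in seq_len(cfg$refinePasses)) {
        for (l in seq_len(nL)) {
          vl <- vote(l, g2)
          pts[l, ] <- solve(vl$prec + diag(tau, 2),
                            vl$prec %*% vl$cand + tau * pts[l, ])
        }
      }
    }
  }
  landmarkSet(pts, spacing, imageId, subjectId, source = "automatic",
              scheme = NULL)
}

#' Save / load a point-finder model
#'
#' Single-archive serialization with a format version tag; a reloaded model
#' makes identical predictions.
#'
#' @param model a PointFinderModel.
#' @param path archive path.
#' @return \code{loadPointFinder}: the model.
#' @export
savePointFinder <- function(model, path) {
  saveRDS(list(format = "footmark-pointfinder-1", shape = model@shape,
               stages = model@stages, config = model@config), path)
  invisible(path)
}

#' @rdname savePointFinder
#' @export
loadPointFinder <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "footmark-pointfinder-1")) {
    fmStop("fm_parse_error", "%s: not a point-finder archive", path)
  }
  new("PointFinderModel", shape = obj$shape, stages = obj$stages,
      config = obj$config)
}

#' Subject-grouped cross-validated landmark localization
#'
#' Assigns subject-grouped folds (\code{\link{assignFolds}}), trains a model
#' on each k-1 fold complement, and predicts the held-out images, so every
#' image's automatic points come from a model that never saw that subject.
#'
#' @param images named list of image matrices.
#' @param truths matching named list of truth LandmarkSets.
#' @param k number of folds.
#' @param seed fold/shuffle + training seed.
#' @param config a \code{\link{pointFinderConfig}}.
#' @param verbose print per-fold progress.
#' @return list: auto (named list of automatic LandmarkSets), folds
#'   (data.frame image_id, subject_id, fold).
#' @export
crossvalPointFinder <- function(images, truths, k = 10, seed = 1,
                                config = pointFinderConfig(), verbose = FALSE) {
  ids <- names(images)
  subs <- vapply(truths, subjectId, "")
  folds <- assignFolds(ids, unname(subs), k, seed = seed)
  auto <- vector("list", length(ids)); names(auto) <- ids
  for (f in seq_len(k)) {
    test <- folds$image_id[folds$fold == f]
    train <- setdiff(ids, test)
    cfgf <- config; cfgf$seed <- config$seed + f
    model <- trainPointFinder(images[train], truths[train], cfgf)
    if (verbose) message(sprintf("fold %d: trained on %d, predicting %d",
                                 f, length(train), length(test)))
    for (id in test) {
      auto[[id]] <- findPoints(model, images[[id]],
                               spacing = pixelSpacing(truths[[id]]),
                               imageId = id, subjectId = subs[[id]])
    }
  }
  list(auto = auto, folds = folds)
}
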