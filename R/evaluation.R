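# Agreement and error statistics: landmark error metrics, ICC(2,1) with
# variance components, the automatic-vs-manual bias mixed model, cluster
# bootstrap Pearson correlation, within-observer-range rates, the exclusion
# rule and subject-grouped cross-validation folds.

#' Mean point-to-point landmark error
#'
#' Mean over the per-landmark Euclidean distances between an automatic and a
#' ground-truth annotation of the same image, in mm.
#'
#' @param auto,gt LandmarkSets for the same image with equal spacing.
#' @return error in mm.
#' @export
pointToPointError <- function(auto, gt) {
  if (max(abs(auto@spacing - gt@spacing)) > 1e-9) {
    fmStop("fm_unit_error", "pixel spacings differ between annotations")
  }
  mean(sqrt(rowSums((auto@points - gt@points)^2))) * mean(gt@spacing)
}

.distToCurve <- function(curve, q) {
  res <- .minimizeOnCurve(
    curve,
    function(p) (p[, 1] - q[1])^2 + (p[, 2] - q[2])^2,
    df = function(t) {
      p <- evalCurve(curve, t)
      2 * sum((p - rbind(q)) * curveDeriv(curve, t))
    })
  sqrt(res$value)
}

#' Mean point-to-curve landmark error
#'
#' For each automatic point belonging to a bone-group outline, the distance to
#' the nearest point of the spline through the ground-truth points of that
#' group (forgiving tangential slippage along the outline); points in no group
#' (or in groups with fewer than 3 points) fall back to the point-to-point
#' distance. Mean over all landmarks, in mm.
#'
#' @param auto,gt LandmarkSets for the same image with equal spacing.
#' @param scheme the landmark scheme supplying the bone groups.
#' @return error in mm.
#' @export
pointToCurveError <- function(auto, gt, scheme = footScheme()) {
  if (max(abs(auto@spacing - gt@spacing)) > 1e-9) {
    fmStop("fm_unit_error", "pixel spacings differ between annotations")
  }
  n <- nrow(gt@points)
  groupOf <- rep(NA_integer_, n)
  curves <- vector("list", length(scheme@boneGroups))
  for (gi in seq_along(scheme@boneGroups)) {
    g <- scheme@boneGroups[[gi]]
    if (length(g) < 3L) {
      warning("bone group with < 3 points; falling back to point-to-point")
      next
    }
    curves[[gi]] <- fitSpline(gt@points[g, ])
    groupOf[g] <- gi
  }
  d <- numeric(n)
  for (i in seq_len(n)) {
    direct <- sqrt(sum((auto@points[i, ] - gt@points[i, ])^2))
    if (is.na(groupOf[i]) || is.null(curves[[groupOf[i]]])) {
      d[i] <- direct
    } else {
      # the matching ground-truth point lies on the curve, so the direct
      # distance is always an upper bound for the search
      d[i] <- min(.distToCurve(curves[[groupOf[i]]], auto@points[i, ]), direct)
    }
  }
  mean(d) * mean(gt@spacing)
}

# long panel -> images x observers matrix for one measurement (manual only)
.panelWide <- function(panel, measurement, includeAuto = FALSE) {
  p <- panel[panel$measurement == measurement, ]
  if (!includeAuto) p <- p[p$observer_id != "AUTO", ]
  if (nrow(p) == 0) fmStop("fm_config_error", "no rows for measurement %s", measurement)
  imgs <- unique(p$image_id); obsv <- sort(unique(p$observer_id))
  M <- matrix(NA_real_, length(imgs), length(obsv),
              dimnames = list(imgs, obsv))
  M[cbind(match(p$image_id, imgs), match(p$observer_id, obsv))] <- p$value
  M
}

.twoWayMS <- function(M) {
  n <- nrow(M); k <- ncol(M)
  mu <- mean(M)
  rm <- rowMeans(M); cm <- colMeans(M)
  msr <- k * sum((rm - mu)^2) / (n - 1)
  msc <- n * sum((cm - mu)^2) / (k - 1)
  sse <- sum((M - outer(rm, rep(1, k)) - outer(rep(1, n), cm) + mu)^2)
  mse <- sse / ((n - 1) * (k - 1))
  list(msr = msr, msc = msc, mse = mse, n = n, k = k)
}

#' ICC(2,1) agreement and variance components for an observer panel
#'
#' Intraclass correlation from the two-way random-effects model with images
#' and observers both random (single rater, absolute agreement), computed from
#' the ANOVA mean squares, with the F-distribution 95% CI (McGraw-Wong) or a
#' cluster bootstrap over images. Variance components by method of moments
#' (negative estimates truncated at zero): inter-image variance
#' IIV = (MSR - MSE)/k, inter-observer variance IOV = (MSC - MSE)/n, residual
#' = MSE, and the proportion of variance explained by observers
#' POV = IOV / (IOV + IIV + residual).
#'
#' @param panel long measurement panel (image_id, observer_id, measurement,
#'   value, missing); AUTO rows are ignored.
#' @param measurement one of "CT", "CH", "MA".
#' @param ciMethod "f" (default) or "bootstrap".
#' @param level confidence level.
#' @param nBoot,seed bootstrap settings.
#' @return list: icc2, ci, iov, iiv, residual, pov, n, k.
#' @export
icc2Panel <- function(panel, measurement, ciMethod = c("f", "bootstrap"),
                      level = 0.95, nBoot = 1000, seed = 1) {
  ciMethod <- match.arg(ciMethod)
  M <- .panelWide(panel, measurement)
  if (anyNA(M)) {
    fmStop("fm_exclusion_violation",
           "panel has missing cells; apply filterComplete first")
  }
  if (nrow(M) < 2 || ncol(M) < 2) {
    fmStop("fm_config_error", "need >= 2 images and >= 2 observers")
  }
  res <- .iccFromMatrix(M)
  if (ciMethod == "f") {
    res$ci <- .iccFCI(M, level)
  } else {
    set.seed(seed)
    boot <- replicate(nBoot, {
      idx <- sample(nrow(M), replace = TRUE)
      .iccFromMatrix(M[idx, , drop = FALSE])$icc2
    })
    res$ci <- unname(stats::quantile(boot, c((1 - level) / 2, (1 + level) / 2),
                                     na.rm = TRUE))
  }
  res
}

.iccFromMatrix <- function(M) {
  ms <- .twoWayMS(M)
  with(ms, {
    tot <- msr + (k - 1) * mse + k * (msc - mse) / n
    if (abs(tot) < 1e-300) fmStop("fm_undefined_icc", "zero total variance")
    icc <- (msr - mse) / tot
    iiv <- max(0, (msr - mse) / k)
    iov <- max(0, (msc - mse) / n)
    denom <- iov + iiv + mse
    list(icc2 = icc, iov = iov, iiv = iiv, residual = mse,
         pov = if (denom > 0) iov / denom else 0, n = n, k = k)
  })
}

# McGraw & Wong F-based CI for ICC(2,1)
.iccFCI <- function(M, level = 0.95) {
  ms <- .twoWayMS(M)
  n <- ms$n; k <- ms$k
  icc <- .iccFromMatrix(M)$icc2
  if (ms$mse <= 0) return(c(icc, icc))
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * ms$msc + b * ms$mse)^2 /
    ((a * ms$msc)^2 / (k - 1) + (b * ms$mse)^2 / ((n - 1) * (k - 1)))
  alpha <- 1 - level
  fl <- stats::qf(1 - alpha / 2, n - 1, v)
  fu <- stats::qf(1 - alpha / 2, v, n - 1)
  lo <- n * (ms$msr - fl * ms$mse) /
    (fl * (k * ms$msc + (k * n - k - n) * ms$mse) + n * ms$msr)
  hi <- n * (fu * ms$msr - ms$mse) /
    (k * ms$msc + (k * n - k - n) * ms$mse + n * fu * ms$msr)
  c(max(-1, lo), min(1, hi))
}

# images x observers matrix of derived-minus-manual differences
.diffMatrix <- function(panel, measurement) {
  M <- .panelWide(panel, measurement)
  A <- panel[panel$measurement == measurement & panel$observer_id == "AUTO", ]
  if (nrow(A) == 0) fmStop("fm_config_error", "panel has no AUTO rows")
  a <- A$value[match(rownames(M), A$image_id)]
  if (anyNA(M) || anyNA(a)) {
    fmStop("fm_exclusion_violation",
           "panel has missing cells; apply filterComplete first")
  }
  a - M
}

#' Bias of derived measurements against the observer panel
#'
#' Fits the balanced two-way random-effects model to the per-cell differences
#' derived - manual; the bias estimate is the model intercept (the grand mean
#' of the differences for complete balanced data). The standard error combines
#' the method-of-moments variance components, and the Wald statistic is
#' referred to a t distribution with Satterthwaite degrees of freedom (with
#' only a handful of observers a normal reference would be anti-conservative).
#'
#' @param panel long panel including AUTO rows.
#' @param measurement one of "CT", "CH", "MA".
#' @return list: bias, se, df, p.value, n, k.
#' @export
biasModel <- function(panel, measurement) {
  D <- .diffMatrix(panel, measurement)
  ms <- .twoWayMS(D)
  n <- ms$n; k <- ms$k
  bias <- mean(D)
  v <- (ms$msr + ms$msc - ms$mse) / (n * k)
  if (v <= 1e-24) {
    p <- if (abs(bias) < 1e-12) 1 else 0
    return(list(bias = bias, se = 0, df = Inf, p.value = p, n = n, k = k))
  }
  df <- (ms$msr + ms$msc - ms$mse)^2 /
    (ms$msr^2 / (n - 1) + ms$msc^2 / (k - 1) + ms$mse^2 / ((n - 1) * (k - 1)))
  se <- sqrt(v)
  p <- 2 * stats::pt(-abs(bias / se), df)
  list(bias = bias, se = se, df = df, p.value = p, n = n, k = k)
}

#' Pearson correlation of derived vs manual measurements, cluster bootstrap CI
#'
#' Pairing "mean" (default) correlates the derived value with the per-image
#' mean over observers; "pooled" correlates the derived value with every
#' observer's value (pairs pooled over observers). The percentile CI resamples
#' images (clusters), respecting the repeated-measures structure.
#'
#' @param panel long panel including AUTO rows.
#' @param measurement one of "CT", "CH", "MA".
#' @param pairing "mean" or "pooled".
#' @param nBoot bootstrap repeats.
#' @param seed bootstrap seed.
#' @return list: pcc, ci (length 2), pairing, n.
#' @export
pccBootstrap <- function(panel, measurement, pairing = c("mean", "pooled"),
                         nBoot = 1000, seed = 1) {
  pairing <- match.arg(pairing)
  D <- .panelWide(panel, measurement) # manual
  A <- panel[panel$measurement == measurement & panel$observer_id == "AUTO", ]
  a <- A$value[match(rownames(D), A$image_id)]
  if (nrow(D) < 3) fmStop("fm_config_error", "need >= 3 images")
  pair_cor <- function(idx) {
    if (pairing == "mean") {
      x <- a[idx]; y <- rowMeans(D[idx, , drop = FALSE])
    } else {
      x <- rep(a[idx], ncol(D)); y <- as.vector(D[idx, , drop = FALSE])
    }
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      fmStop("fm_undefined_correlation", "zero variance in one series")
    }
    stats::cor(x, y)
  }
  est <- pair_cor(seq_along(a))
  set.seed(seed)
  boot <- replicate(nBoot, {
    idx <- sample(length(a), replace = TRUE)
    tryCatch(pair_cor(idx), footmark_error = function(e) NA_real_)
  })
  ci <- unname(stats::quantile(boot, c(0.025, 0.975), na.rm = TRUE))
  list(pcc = est, ci = ci, pairing = pairing, n = length(a))
}

#' Percentage of derived measurements within the observer range
#'
#' An image counts as within range iff
#' min(observers) <= derived <= max(observers) (boundaries inclusive).
#'
#' @param panel long panel including AUTO rows.
#' @param measurement one of "CT", "CH", "MA".
#' @return list: percent, within (named logical per image), n.
#' @export
withinRange <- function(panel, measurement) {
  D <- .panelWide(panel, measurement)
  A <- panel[panel$measurement == measurement & panel$observer_id == "AUTO", ]
  a <- A$value[match(rownames(D), A$image_id)]
  if (anyNA(D) || anyNA(a)) {
    fmStop("fm_exclusion_violation",
           "panel has missing cells; apply filterComplete first")
  }
  w <- a >= apply(D, 1, min) & a <= apply(D, 1, max)
  names(w) <- rownames(D)
  list(percent = 100 * mean(w), within = w, n = length(w))
}

#' Exclusion rule: drop images with any missing manual measurement
#'
#' An image is excluded when at least one observer was unable to provide at
#' least one measurement (missing flag set or value NA).
#'
#' @param panel long measurement panel.
#' @return list: panel (retained rows), nExcluded, excluded (image ids).
#' @export
filterComplete <- function(panel) {
  man <- panel[panel$observer_id != "AUTO", ]
  bad <- unique(man$image_id[is.na(man$value) | man$missing])
  # also drop images lacking any expected (observer, measurement) cell
  obsv <- unique(man$observer_id); meas <- unique(man$measurement)
  cnt <- table(man$image_id)
  bad <- union(bad, names(cnt)[cnt < length(obsv) * length(meas)])
  keep <- !(panel$image_id %in% bad)
  list(panel = panel[keep, ], nExcluded = length(bad), excluded = bad)
}

#' Subject-grouped cross-validation fold assignment
#'
#' Seeded randomized greedy packing: subjects are shuffled, then each subject
#' (with all of its images) is assigned to the currently smallest fold by
#' image count, ties broken by subject count and then fold index. All images
#' of a subject always share one fold.
#'
#' @param imageIds character vector of image ids.
#' @param subjectIds matching subject ids.
#' @param k number of folds.
#' @param seed shuffle seed.
#' @return data.frame(image_id, subject_id, fold).
#' @export
assignFolds <- function(imageIds, subjectIds, k, seed = 1) {
  subs <- unique(subjectIds)
  if (k > length(subs)) {
    fmStop("fm_config_error", "k = %d exceeds the %d subjects", k, length(subs))
  }
  set.seed(seed)
  subs <- sample(subs)
  nImg <- integer(k); nSub <- integer(k)
  foldOf <- integer(length(subs)); names(foldOf) <- subs
  for (s in subs) {
    cand <- which(nImg == min(nImg))
    if (length(cand) > 1) cand <- cand[nSub[cand] == min(nSub[cand])]
    f <- cand[1]
    foldOf[s] <- f
    nImg[f] <- nImg[f] + sum(subjectIds == s)
    nSub[f] <- nSub[f] + 1L
  }
  data.frame(image_id = imageIds, subject_id = subjectIds,
             fold = unname(foldOf[subjectIds]), stringsAsFactors = FALSE)
}

#' Empirical CDF summary of per-image errors
#'
#' @param errors numeric vector of per-image error values.
#' @return list: x (sorted values), F (cumulative proportions), median,
#'   quantile(p), fractionBelow(threshold).
#' @export
errorCdf <- function(errors) {
  if (length(errors) == 0) fmStop("fm_config_error", "no error values")
  x <- sort(errors)
  list(
    x = x,
    F = seq_along(x) / length(x),
    median = stats::median(x),
    quantile = function(p) unname(stats::quantile(x, p, type = 7)),
    fractionBelow = function(th) mean(x < th)
  )
}
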