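# Independent reference implementations used as oracles. Kept deliberately
# naive and separate from the package's code paths.

# Natural cubic spline through (t, y): solve the tridiagonal second-derivative
# system directly and evaluate piecewise.
refNaturalSpline <- function(t, y, tout) {
  n <- length(t)
  h <- diff(t)
  A <- matrix(0, n, n)
  rhs <- numeric(n)
  A[1, 1] <- 1; A[n, n] <- 1
  for (i in 2:(n - 1)) {
    A[i, i - 1] <- h[i - 1]
    A[i, i] <- 2 * (h[i - 1] + h[i])
    A[i, i + 1] <- h[i]
    rhs[i] <- 6 * ((y[i + 1] - y[i]) / h[i] - (y[i] - y[i - 1]) / h[i - 1])
  }
  m <- solve(A, rhs) # second derivatives at knots
  vapply(tout, function(x) {
    i <- max(1L, min(n - 1L, findInterval(x, t)))
    dt <- t[i + 1] - t[i]
    a <- (t[i + 1] - x) / dt
    b <- (x - t[i]) / dt
    a * y[i] + b * y[i + 1] +
      ((a^3 - a) * m[i] + (b^3 - b) * m[i + 1]) * dt^2 / 6
  }, 0)
}

# chord-length parameters matching the package's convention
refChordParams <- function(pts) {
  seg <- sqrt(rowSums(diff(pts)^2))
  c(0, cumsum(seg)) / sum(seg)
}

# a smooth random 2-D configuration for brute-force distance checks
randomSmoothCurvePoints <- function(n = 7, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- sort(runif(n, 0, 100))
  y <- 50 + cumsum(rnorm(n, 0, 6))
  cbind(x, y)
}

# template with selected points overridden (keeps a valid 61-point set)
templateWith <- function(overrides) {
  lm <- footTemplate()
  p <- landmarkPoints(lm)
  for (nm in names(overrides)) p[as.integer(nm), ] <- overrides[[nm]]
  landmarkSet(p, pixelSpacing(lm), "test", "test", "synthetic_truth")
}

rotatePts <- function(p, deg, pivot = c(0, 0)) {
  th <- deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  sweep(sweep(p, 2, pivot) %*% t(R), 2, pivot, "+")
}

# tiny rendered cohort shared by localizer/pipeline tests (built lazily once)
.tinyCohortCache <- new.env()
tinyRenderedCohort <- function(nSubjects = 12, seed = 5) {
  key <- paste0("c", nSubjects, "_", seed)
  if (!is.null(.tinyCohortCache[[key]])) return(.tinyCohortCache[[key]])
  co <- generateCohort(cohortSpec(nSubjects = nSubjects,
                                  imagesPerSubject = 2), seed = seed)
  imgs <- list(); tru <- list()
  for (i in seq_along(co$landmarks)) {
    id <- names(co$landmarks)[i]
    rr <- renderRadiograph(co$landmarks[[id]], seed = seed * 1000 + i)
    imgs[[id]] <- rr$image
    tru[[id]] <- rr$landmarks
  }
  out <- list(images = imgs, truths = tru, panel = co$panel, truth = co$truth)
  .tinyCohortCache[[key]] <- out
  out
}
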