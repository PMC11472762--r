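# Internal numeric helpers shared across modules.

# Bilinear interpolation at continuous 0-based (x = column, y = row)
# positions at pixel centers. Errors name the side that overflows so
# region-construction failures are diagnosable.
bilinearSample <- function(px, x, y, context = "sample") {
  nr <- nrow(px)
  nc <- ncol(px)
  eps <- 1e-9
  if (any(x < -eps)) stop(context, ": region exits image bounds on the left")
  if (any(x > nc - 1 + eps)) {
    stop(context, ": region exits image bounds on the right")
  }
  if (any(y < -eps)) stop(context, ": region exits image bounds on the top")
  if (any(y > nr - 1 + eps)) {
    stop(context, ": region exits image bounds on the bottom")
  }
  x <- pmin(pmax(x, 0), nc - 1)
  y <- pmin(pmax(y, 0), nr - 1)
  x0 <- pmin(floor(x), nc - 2)
  y0 <- pmin(floor(y), nr - 2)
  fx <- x - x0
  fy <- y - y0
  i00 <- px[cbind(y0 + 1, x0 + 1)]
  i01 <- px[cbind(y0 + 1, x0 + 2)]
  i10 <- px[cbind(y0 + 2, x0 + 1)]
  i11 <- px[cbind(y0 + 2, x0 + 2)]
  (1 - fy) * ((1 - fx) * i00 + fx * i01) + fy * ((1 - fx) * i10 + fx * i11)
}

# Trapezoidal integral of y over x.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) stop("need at least two points to integrate")
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

segmentLength <- function(seg) {
  sqrt(sum((seg[2, ] - seg[1, ])^2))
}

# Distance from point p to segment (a, b).
pointSegmentDistance <- function(p, a, b) {
  ab <- b - a
  denom <- sum(ab^2)
  t <- if (denom == 0) 0 else sum((p - a) * ab) / denom
  t <- min(max(t, 0), 1)
  proj <- a + t * ab
  sqrt(sum((p - proj)^2))
}

# Draw n rows from N(0, R) given a correlation matrix R, via Cholesky.
# Optional 'given' fixes the first component (conditional simulation).
rmvnormChol <- function(n, R, given = NULL) {
  L <- tryCatch(t(chol(R)), error = function(e) {
    stop("correlation matrix is not positive definite")
  })
  k <- ncol(R)
  e <- matrix(stats::rnorm(n * k), nrow = n, ncol = k)
  if (!is.null(given)) e[, 1] <- given
  e %*% t(L)
}

# Rotate a radiograph 90 degrees counter-clockwise together with 0-based
# pixel-center coordinates: (x, y) -> (y, W - 1 - x). Used by equivariance
# tests; the pixel grid maps onto itself exactly.
rotateRadiograph90 <- function(image) {
  px <- pixels(image)
  # (x, y) -> (y, W - 1 - x): new[W - x, y + 1] = old[y + 1, x + 1]
  rotated <- t(px)[seq(ncol(px), 1), , drop = FALSE]
  Radiograph(rotated, mmPerPx = mmPerPx(image), birdId = birdId(image),
             timepoint = timepoint(image),
             photometricNormalized = image@photometricNormalized)
}

rotatePoint90 <- function(pts, imageWidth) {
  pts <- rbind(pts)
  cbind(pts[, 2], imageWidth - 1 - pts[, 1])
}

rotateAnnotation90 <- function(ann, imageWidth) {
  rot <- function(m) rotatePoint90(m, imageWidth)
  br <- ann@backgroundRegion
  if (length(br) == 4) {
    corners <- rot(rbind(c(br[1], br[2]), c(br[3], br[4])))
    br <- c(min(corners[, 1]), min(corners[, 2]),
            max(corners[, 1]), max(corners[, 2]))
  }
  KeelAnnotation(
    imageId = ann@imageId,
    tibiotarsalLine = rot(ann@tibiotarsalLine),
    keelPolyline = rot(ann@keelPolyline),
    middepthLine = rot(ann@middepthLine),
    cranialdepthLine = rot(ann@cranialdepthLine),
    densityAnchor = list(
      point = as.numeric(rot(ann@densityAnchor$point)),
      direction = c(ann@densityAnchor$direction[2],
                    -ann@densityAnchor$direction[1])),
    backgroundRegion = br)
}
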