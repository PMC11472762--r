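# Phantom radiographs with analytic ground truth.
#
# Phantoms use additive attenuation: a bone element contributes its level to
# every pixel whose center lies inside it, plus an optional uniform haze and
# Gaussian noise. Band edges are placed on half-pixel boundaries so the
# trapezoidal profile AUC of the bilinear reconstruction equals the analytic
# attenuation integral (level x band width) exactly; measurement error then
# reflects only noise and interpolation, which is what the recovery tests
# are meant to see.
#
# Layout (0-based x = column, y = row):
#   - a vertical tibiotarsal band at tibioCenterX, full width 2 x halfWidth;
#   - a keel band along a centerline that runs straight down the cranial
#     ridge (the pila carinae) and then bends caudally to the keel tip via a
#     quadratic Bezier, constant half-width;
#   - an off-bone background rectangle for the haze/pedestal correction.

#' Phantom specification
#'
#' @param imageSize c(width, height) in px.
#' @param mmPerPx pixel spacing written into the phantom.
#' @param tibioCenterX integer x of the tibiotarsal band center.
#' @param tibioHalfWidth half width in px; use k + 0.5 so band edges fall on
#'   half-pixel boundaries.
#' @param tibioLevel attenuation level (a.u.).
#' @param keelCranialX integer x of the straight cranial ridge.
#' @param keelCranialTop,keelCranialBottom y extent of the straight ridge.
#' @param keelControl,keelTip Bezier control point and keel tip (x, y).
#' @param keelHalfWidth half width in px (k + 0.5).
#' @param keelLevel attenuation level (a.u.).
#' @param anchorY y of the keel-density anchor on the cranial ridge.
#' @param haze uniform background pedestal added everywhere (a.u.).
#' @param noiseSd Gaussian pixel noise standard deviation (a.u.).
#' @param seed RNG seed; identical specs with identical seeds render
#'   bit-identical images.
#' @return a validated \code{PhantomSpec} list.
#' @export
phantomSpec <- function(imageSize = c(320, 320), mmPerPx = 0.2,
                        tibioCenterX = 60, tibioHalfWidth = 19.5,
                        tibioLevel = 30,
                        keelCranialX = 230, keelCranialTop = 40,
                        keelCranialBottom = 110,
                        keelControl = c(230, 200), keelTip = c(150, 285),
                        keelHalfWidth = 19.5, keelLevel = 20,
                        anchorY = 70, haze = 0, noiseSd = 0, seed = 1) {
  spec <- list(imageSize = imageSize, mmPerPx = mmPerPx,
               tibioCenterX = tibioCenterX, tibioHalfWidth = tibioHalfWidth,
               tibioLevel = tibioLevel, keelCranialX = keelCranialX,
               keelCranialTop = keelCranialTop,
               keelCranialBottom = keelCranialBottom,
               keelControl = keelControl, keelTip = keelTip,
               keelHalfWidth = keelHalfWidth, keelLevel = keelLevel,
               anchorY = anchorY, haze = haze, noiseSd = noiseSd,
               seed = seed)
  if (any(c(spec$tibioLevel, spec$keelLevel) < 0)) {
    stop("attenuation levels must be >= 0")
  }
  w <- imageSize[1]
  h <- imageSize[2]
  if (tibioCenterX + tibioHalfWidth >= w || tibioCenterX - tibioHalfWidth < 0) {
    stop("tibiotarsal band outside image bounds")
  }
  if (keelTip[1] < 0 || keelTip[1] >= w || keelTip[2] < 0 || keelTip[2] >= h ||
      keelCranialX + keelHalfWidth >= w) {
    stop("keel element outside image bounds")
  }
  class(spec) <- "PhantomSpec"
  spec
}

#' Random phantom specification
#'
#' Varies band widths, levels and keel shape across seeds so recovery and
#' test-retest batches have between-phantom variance.
#'
#' @param seed RNG seed (also stored in the spec).
#' @return a \code{PhantomSpec}.
#' @export
randomPhantomSpec <- function(seed) {
  set.seed(seed)
  phantomSpec(
    tibioHalfWidth = sample(15:23, 1) + 0.5,
    tibioLevel = stats::runif(1, 20, 40),
    keelHalfWidth = sample(14:23, 1) + 0.5,
    keelLevel = stats::runif(1, 15, 30),
    keelControl = c(230, stats::runif(1, 180, 220)),
    keelTip = c(stats::runif(1, 140, 165), stats::runif(1, 270, 295)),
    noiseSd = 1,
    seed = seed)
}

# Dense keel centerline: straight ridge + quadratic Bezier to the tip.
.keelCenterline <- function(spec, nBezier = 400) {
  p0 <- c(spec$keelCranialX, spec$keelCranialBottom)
  p1 <- spec$keelControl
  p2 <- spec$keelTip
  tt <- seq(0, 1, length.out = nBezier)
  bez <- cbind((1 - tt)^2 * p0[1] + 2 * (1 - tt) * tt * p1[1] + tt^2 * p2[1],
               (1 - tt)^2 * p0[2] + 2 * (1 - tt) * tt * p1[2] + tt^2 * p2[2])
  straight <- cbind(spec$keelCranialX,
                    seq(spec$keelCranialTop, spec$keelCranialBottom,
                        length.out = 80))
  rbind(straight[-nrow(straight), ], bez)
}

.polylineArc <- function(pts) {
  seg <- sqrt(rowSums(diff(pts)^2))
  list(seg = seg, cum = c(0, cumsum(seg)), total = sum(seg))
}

.pointAtArc <- function(pts, arc, s) {
  i <- findInterval(s, arc$cum, rightmost.closed = TRUE)
  i <- min(max(i, 1), nrow(pts) - 1)
  f <- (s - arc$cum[i]) / max(arc$seg[i], 1e-12)
  pts[i, ] + f * (pts[i + 1, ] - pts[i, ])
}

# Minimum distance from a grid of pixel centers to a polyline, restricted to
# the polyline's bounding box padded by `pad`.
.distanceMask <- function(w, h, pts, pad) {
  xr <- range(pts[, 1]) + c(-pad, pad)
  yr <- range(pts[, 2]) + c(-pad, pad)
  xs <- max(0, floor(xr[1])):min(w - 1, ceiling(xr[2]))
  ys <- max(0, floor(yr[1])):min(h - 1, ceiling(yr[2]))
  gx <- rep(xs, times = length(ys))
  gy <- rep(ys, each = length(xs))
  dmin <- rep(Inf, length(gx))
  for (i in seq_len(nrow(pts) - 1)) {
    a <- pts[i, ]
    b <- pts[i + 1, ]
    ab <- b - a
    denom <- sum(ab^2)
    t <- ((gx - a[1]) * ab[1] + (gy - a[2]) * ab[2]) / max(denom, 1e-12)
    t <- pmin(pmax(t, 0), 1)
    dx <- gx - (a[1] + t * ab[1])
    dy <- gy - (a[2] + t * ab[2])
    dmin <- pmin(dmin, dx * dx + dy * dy)
  }
  list(x = gx, y = gy, dist = sqrt(dmin))
}

#' Render a phantom radiograph with its annotation and ground truth
#'
#' @param spec a \code{\link{phantomSpec}}.
#' @return list with \code{image} (a \linkS4class{Radiograph}),
#'   \code{annotation} (a \linkS4class{KeelAnnotation} whose keypoints lie on
#'   the true centerlines) and \code{truth}: the analytic values the
#'   measurement stage should recover (tibiotarsal and keel density as
#'   level x band width in the profile's unit, keel length in px, mid and
#'   cranial depth in px, xlm, plus the rendering parameters).
#' @export
makePhantom <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"))
  set.seed(spec$seed)
  w <- spec$imageSize[1]
  h <- spec$imageSize[2]
  img <- matrix(0, nrow = h, ncol = w)

  # tibiotarsal band: vertical, rows 20 .. h - 20
  tibioRows <- 20:(h - 21)
  xs <- 0:(w - 1)
  inBand <- abs(xs - spec$tibioCenterX) < spec$tibioHalfWidth
  img[tibioRows + 1, which(inBand)] <-
    img[tibioRows + 1, which(inBand)] + spec$tibioLevel

  # keel band around the centerline
  center <- .keelCenterline(spec)
  # decimated centerline for rendering (sag error ~1e-2 px, far below the
  # half-pixel edge placement); full resolution kept for the arc-length truth
  maskPts <- center[unique(c(seq(1, nrow(center), by = 4), nrow(center))), ]
  msk <- .distanceMask(w, h, maskPts, pad = spec$keelHalfWidth + 2)
  inside <- msk$dist < spec$keelHalfWidth
  idx <- cbind(msk$y[inside] + 1, msk$x[inside] + 1)
  img[idx] <- img[idx] + spec$keelLevel

  if (spec$haze > 0) img <- img + spec$haze
  if (spec$noiseSd > 0) {
    img <- img + matrix(stats::rnorm(w * h, 0, spec$noiseSd), h, w)
  }

  arc <- .polylineArc(center)
  mid <- .pointAtArc(center, arc, arc$total / 2)
  # unit normal at the midpoint
  eps <- arc$total / 1000
  pA <- .pointAtArc(center, arc, arc$total / 2 - eps)
  pB <- .pointAtArc(center, arc, arc$total / 2 + eps)
  tang <- (pB - pA) / sqrt(sum((pB - pA)^2))
  nrm <- c(-tang[2], tang[1])
  hwK <- spec$keelHalfWidth

  # 9 annotation clicks at equal arc length along the true centerline
  clicks <- t(vapply(seq(0, 1, length.out = 9), function(f) {
    .pointAtArc(center, arc, f * arc$total)
  }, numeric(2)))

  margin <- 3  # measurement lines extend past the band edges
  tibioY <- round(h / 2)
  ann <- KeelAnnotation(
    imageId = sprintf("phantom-%d", spec$seed),
    tibiotarsalLine = rbind(
      c(spec$tibioCenterX - spec$tibioHalfWidth - margin, tibioY),
      c(spec$tibioCenterX + spec$tibioHalfWidth + margin, tibioY)),
    keelPolyline = clicks,
    middepthLine = rbind(mid - hwK * nrm, mid + hwK * nrm),
    cranialdepthLine = rbind(
      c(spec$keelCranialX - hwK, spec$keelCranialTop + 10),
      c(spec$keelCranialX + hwK, spec$keelCranialTop + 10)),
    densityAnchor = list(
      point = c(spec$keelCranialX - (10 / spec$mmPerPx) / 2, spec$anchorY),
      direction = c(1, 0)),
    backgroundRegion = c(275, 5, 315, 45))

  unitScale <- spec$mmPerPx  # profiles report mm positions
  truth <- list(
    tibiotarsalDensity = spec$tibioLevel * 2 * spec$tibioHalfWidth *
      unitScale,
    keelDensity = spec$keelLevel * 2 * hwK * unitScale,
    keelLength = arc$total,
    keelMidDepth = 2 * hwK,
    keelCranialDepth = 2 * hwK,
    xlm = arc$total / (2 * hwK),
    tibioLevel = spec$tibioLevel, keelLevel = spec$keelLevel,
    haze = spec$haze, noiseSd = spec$noiseSd, seed = spec$seed)

  image <- Radiograph(img, mmPerPx = spec$mmPerPx,
                      birdId = sprintf("phantom-%d", spec$seed),
                      timepoint = "PMD")
  list(image = image, annotation = ann, truth = truth)
}

#' Phantom recovery report
#'
#' Renders a batch of randomized phantoms, measures them with the standard
#' pipeline and reports relative recovery errors against the analytic
#' truths.
#'
#' @param nPhantoms batch size.
#' @param seed base seed; phantom i uses seed + i.
#' @return data.frame with one row per phantom: relative errors (fractions)
#'   for keel length, mid-depth, cranial depth, tibiotarsal and keel
#'   density.
#' @export
phantomCheck <- function(nPhantoms = 50, seed = 1) {
  rows <- lapply(seq_len(nPhantoms), function(i) {
    ph <- makePhantom(randomPhantomSpec(seed + i))
    m <- measureRadiograph(ph$image, ph$annotation)
    tr <- ph$truth
    data.frame(
      seed = tr$seed,
      keel_length_relerr = m$keel_length_px / tr$keelLength - 1,
      mid_depth_relerr = m$keel_mid_depth_px / tr$keelMidDepth - 1,
      cranial_depth_relerr = m$keel_cranial_depth_px / tr$keelCranialDepth - 1,
      tibio_density_relerr = m$tibiotarsal_density / tr$tibiotarsalDensity - 1,
      keel_density_relerr = m$keel_density / tr$keelDensity - 1)
  })
  do.call(rbind, rows)
}
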