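# Radiographic measurements: wide-line intensity profiles, their AUC density
# proxies, and keel spline geometry.
#
# A "profile" follows ImageJ's wide-line plot-profile semantics: at each
# position along the axis from start to end, the value is the average of the
# bilinear interpolant across the perpendicular width. The perpendicular
# average is taken at fine (0.1 px) sub-pixel spacing, i.e. it approximates
# the continuous width-average rather than a coarse per-pixel sum; closed
# forms (constant fields, bands with edges on half-pixel boundaries) are
# reproduced exactly by the axis-direction trapezoid.

#' Wide-line intensity profile
#'
#' @param image a \linkS4class{Radiograph}.
#' @param start,end numeric length-2 points (x, y) in 0-based pixel-center
#'   coordinates; the profile axis runs from start to end.
#' @param widthPx full width of the averaged band perpendicular to the axis
#'   (>= 1).
#' @param stepPx sampling step along the axis, in px.
#' @param perpSpacingPx sub-pixel spacing of the perpendicular average.
#' @return an object of class \code{IntensityProfile}: list with
#'   \code{positions} (px, or mm when the image has spacing), \code{values},
#'   \code{step} and \code{unit}.
#' @export
profileCurve <- function(image, start, end, widthPx = 1, stepPx = 1,
                         perpSpacingPx = 0.1) {
  stopifnot(is(image, "Radiograph"))
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (widthPx < 1) stop("widthPx must be >= 1")
  axis <- end - start
  len <- sqrt(sum(axis^2))
  if (len == 0) stop("profile start and end must differ")
  u <- axis / len
  v <- c(-u[2], u[1])
  posPx <- seq(0, len, by = stepPx)
  if (posPx[length(posPx)] < len - 1e-9) posPx <- c(posPx, len)
  nOff <- max(2L, as.integer(round(widthPx / perpSpacingPx)) + 1L)
  offs <- seq(-widthPx / 2, widthPx / 2, length.out = nOff)
  px <- pixels(image)
  vals <- vapply(posPx, function(p) {
    cx <- start[1] + p * u[1] + offs * v[1]
    cy <- start[2] + p * u[2] + offs * v[2]
    mean(bilinearSample(px, cx, cy, context = "profileCurve"))
  }, numeric(1))
  sp <- mmPerPx(image)
  unit <- if (is.na(sp)) "px" else "mm"
  scale <- if (is.na(sp)) 1 else sp
  structure(list(positions = posPx * scale, values = vals,
                 step = stepPx * scale, unit = unit),
            class = "IntensityProfile")
}

#' Area under an intensity profile
#'
#' Trapezoidal integral of profile values over positions; the optical
#' density proxy of the measured bone region.
#'
#' @param profile an \code{IntensityProfile} from \code{\link{profileCurve}}.
#' @return numeric AUC in intensity x position units.
#' @export
profileAuc <- function(profile) {
  stopifnot(inherits(profile, "IntensityProfile"))
  if (length(profile$positions) < 2) stop("profile needs >= 2 positions")
  if (any(!is.finite(profile$values))) stop("profile values must be finite")
  trapz(profile$positions, profile$values)
}

#' Background correction of a density AUC
#'
#' Subtracts the off-bone background pedestal: the median intensity of the
#' annotated background rectangle times the profile's position span, clamped
#' at zero. With no background region the raw value is returned with a
#' warning.
#'
#' @param rawAuc uncorrected AUC.
#' @param image the \linkS4class{Radiograph} measured.
#' @param ann the \linkS4class{KeelAnnotation} (its \code{backgroundRegion}
#'   is used).
#' @param regionLength position span of the measured profile, in the same
#'   unit as the AUC positions.
#' @return corrected AUC with attribute \code{backgroundLevel} (median
#'   background intensity, or NA when no region was annotated).
#' @export
backgroundCorrect <- function(rawAuc, image, ann, regionLength) {
  br <- ann@backgroundRegion
  if (length(br) != 4) {
    warning("no background region annotated; returning uncorrected AUC")
    return(structure(rawAuc, backgroundLevel = NA_real_))
  }
  px <- pixels(image)
  x0 <- max(0L, as.integer(floor(br[1])))
  y0 <- max(0L, as.integer(floor(br[2])))
  x1 <- min(ncol(px) - 1L, as.integer(ceiling(br[3])))
  y1 <- min(nrow(px) - 1L, as.integer(ceiling(br[4])))
  med <- stats::median(px[(y0:y1) + 1L, (x0:x1) + 1L])
  structure(max(0, rawAuc - med * regionLength), backgroundLevel = med)
}

#' Tibiotarsal mid-shaft radiographic optical density
#'
#' Profile AUC over a region whose axis is the user-drawn line across the
#' tibiotarsal mid-shaft (so the axis length equals the drawn bone width) and
#' whose width is 100 px along the bone axis. The measure deliberately scales
#' with bone width; set \code{widthNormalized = TRUE} for AUC divided by the
#' drawn line length.
#'
#' @param image a \linkS4class{Radiograph}.
#' @param ann a \linkS4class{KeelAnnotation} with \code{tibiotarsalLine}.
#' @param bandWidthPx width of the averaged band (default 100 px).
#' @param correctBackground subtract the background pedestal when a
#'   background region is annotated.
#' @param widthNormalized divide the AUC by the axis length.
#' @return numeric density (a.u. x px, or a.u. x mm when spacing is known),
#'   with attributes \code{raw} and \code{backgroundLevel}.
#' @export
tibiotarsalDensity <- function(image, ann, bandWidthPx = 100,
                               correctBackground = TRUE,
                               widthNormalized = FALSE) {
  seg <- ann@tibiotarsalLine
  prof <- profileCurve(image, seg[1, ], seg[2, ], widthPx = bandWidthPx)
  raw <- profileAuc(prof)
  span <- max(prof$positions) - min(prof$positions)
  bg <- NA_real_
  val <- raw
  if (correctBackground && length(ann@backgroundRegion) == 4) {
    val <- backgroundCorrect(raw, image, ann, span)
    bg <- attr(val, "backgroundLevel")
    val <- as.numeric(val)
  }
  if (widthNormalized) val <- val / span
  structure(val, raw = raw, backgroundLevel = bg)
}

#' Cranial keel radiographic optical density
#'
#' Profile AUC over a band of width 25 px and axis length 10 mm, anchored at
#' the keel edge and directed across the pila carinae (the cranial keel
#' ridge, rarely fractured and therefore free of callus over-mineralization).
#'
#' @param image a \linkS4class{Radiograph}; needs pixel spacing (or
#'   \code{fallbackMmPerPx}) to realize the 10 mm length.
#' @param ann a \linkS4class{KeelAnnotation} with \code{densityAnchor}.
#' @param lengthMm axis length in mm (default 10).
#' @param bandWidthPx band width (default 25 px).
#' @param fallbackMmPerPx spacing used when the image has none.
#' @param correctBackground subtract the background pedestal when annotated.
#' @return numeric density (a.u. x mm) with attributes \code{raw} and
#'   \code{backgroundLevel}.
#' @export
keelDensity <- function(image, ann, lengthMm = 10, bandWidthPx = 25,
                        fallbackMmPerPx = NA, correctBackground = TRUE) {
  sp <- mmPerPx(image)
  if (is.na(sp)) sp <- as.numeric(fallbackMmPerPx)
  if (is.na(sp)) {
    stop("cannot realize ", lengthMm, " mm: no pixel spacing and no fallback")
  }
  img <- image
  if (is.na(mmPerPx(image))) {
    img <- Radiograph(pixels(image), mmPerPx = sp, birdId = birdId(image),
                      timepoint = timepoint(image))
  }
  anchor <- ann@densityAnchor
  lenPx <- lengthMm / sp
  start <- anchor$point
  end <- anchor$point + anchor$direction * lenPx
  prof <- profileCurve(img, start, end, widthPx = bandWidthPx)
  raw <- profileAuc(prof)
  span <- max(prof$positions) - min(prof$positions)
  bg <- NA_real_
  val <- raw
  if (correctBackground && length(ann@backgroundRegion) == 4) {
    val <- backgroundCorrect(raw, img, ann, span)
    bg <- attr(val, "backgroundLevel")
    val <- as.numeric(val)
  }
  structure(val, raw = raw, backgroundLevel = bg)
}

#' Keel spline length and midpoint
#'
#' Natural cubic spline through the clicked centerline points (chord-length
#' parameterization), arc length by 1000-segment quadrature, and the point at
#' half arc length (the spline midpoint the mid-depth line must cross).
#'
#' @param polyline n x 2 matrix of ordered points, n >= 2, no consecutive
#'   duplicates.
#' @return list with \code{length} (px) and \code{midpoint} (x, y).
#' @export
keelSplineLength <- function(polyline) {
  pts <- .asPointMatrix(polyline)
  if (nrow(pts) < 2) stop("keel polyline needs at least 2 points")
  chord <- sqrt(rowSums(diff(pts)^2))
  if (any(chord == 0)) stop("keel polyline has duplicate consecutive points")
  tknots <- c(0, cumsum(chord))
  sx <- stats::splinefun(tknots, pts[, 1], method = "natural")
  sy <- stats::splinefun(tknots, pts[, 2], method = "natural")
  tt <- seq(0, tknots[length(tknots)], length.out = 1001)
  xy <- cbind(sx(tt), sy(tt))
  seg <- sqrt(rowSums(diff(xy)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  tHalf <- stats::approx(cum, tt, xout = total / 2, ties = "ordered")$y
  list(length = total, midpoint = c(sx(tHalf), sy(tHalf)))
}

#' Keel geometry: length, depths and the length to mid-depth ratio
#'
#' Length from the centerline spline; mid-depth and cranial depth as the
#' Euclidean lengths of their annotated lines; xlm = length / mid-depth (for
#' an undamaged keel the ratio is expected near 5). Warns when the annotated
#' mid-depth line misses the computed spline midpoint by more than
#' \code{warnTolPx}.
#'
#' @param image a \linkS4class{Radiograph} (unused numerically; kept so the
#'   call mirrors the other measurements and for bounds context).
#' @param ann a \linkS4class{KeelAnnotation}.
#' @param warnTolPx tolerance (px) for the mid-depth line's nearest approach
#'   to the spline midpoint.
#' @return list with \code{length}, \code{midDepth}, \code{cranialDepth},
#'   \code{xlm} (all px except the unitless ratio) and \code{midpoint}.
#' @export
keelGeometry <- function(image, ann, warnTolPx = 10) {
  sp <- keelSplineLength(ann@keelPolyline)
  midDepth <- segmentLength(ann@middepthLine)
  cranialDepth <- segmentLength(ann@cranialdepthLine)
  if (midDepth == 0) stop("mid-depth line has zero length; cannot form ratio")
  d <- pointSegmentDistance(sp$midpoint, ann@middepthLine[1, ],
                            ann@middepthLine[2, ])
  if (d > warnTolPx) {
    warning(sprintf(
      "mid-depth line passes %.1f px from the spline midpoint (> %g px)",
      d, warnTolPx))
  }
  list(length = sp$length, midDepth = midDepth,
       cranialDepth = cranialDepth, xlm = sp$length / midDepth,
       midpoint = sp$midpoint)
}

#' All six radiographic measurements of one image
#'
#' Runs the tibiotarsal density, keel density and keel geometry measurements
#' and returns one morphometric record. At week 16 the keel is only partly
#' ossified, so the length refers to the ossified portion; such records carry
#' \code{ossified_only = TRUE}.
#'
#' @param image a \linkS4class{Radiograph}.
#' @param ann a \linkS4class{KeelAnnotation}.
#' @param fallbackMmPerPx spacing fallback for the 10 mm keel density line.
#' @param widthNormalized use the width-normalized tibiotarsal variant.
#' @return one-row data.frame with bird_id, timepoint, tibiotarsal_density,
#'   keel_density, keel_length_px, keel_mid_depth_px, keel_cranial_depth_px,
#'   xlm, background_level, unit, ossified_only.
#' @export
measureRadiograph <- function(image, ann, fallbackMmPerPx = NA,
                              widthNormalized = FALSE) {
  td <- tibiotarsalDensity(image, ann, widthNormalized = widthNormalized)
  kd <- keelDensity(image, ann, fallbackMmPerPx = fallbackMmPerPx)
  geo <- keelGeometry(image, ann)
  bg <- attr(td, "backgroundLevel")
  data.frame(
    bird_id = birdId(image),
    timepoint = timepoint(image),
    tibiotarsal_density = as.numeric(td),
    keel_density = as.numeric(kd),
    keel_length_px = geo$length,
    keel_mid_depth_px = geo$midDepth,
    keel_cranial_depth_px = geo$cranialDepth,
    xlm = geo$xlm,
    background_level = if (is.null(bg)) NA_real_ else bg,
    unit = if (is.na(mmPerPx(image))) "px" else "mm",
    ossified_only = identical(timepoint(image), "wk16"),
    stringsAsFactors = FALSE
  )
}
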