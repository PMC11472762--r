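#' @import methods
NULL

TIMEPOINTS <- c("wk16", "wk29", "wk42", "wk55", "wk68", "PM", "PMD")

#' Radiograph: a calibrated radiographic image
#'
#' Container for one radiographic image after loading: a real-valued pixel
#' matrix in canonical photometric orientation (larger value = denser tissue),
#' optional physical pixel spacing, and identifying metadata.
#'
#' Coordinates throughout the package are 0-based with x = column and
#' y = row, continuous positions measured at pixel centers.
#'
#' @slot pixels numeric matrix (rows x columns) of intensities, arbitrary
#'   units; finite, at least 64 x 64.
#' @slot mmPerPx physical size of one pixel in mm, or \code{NA_real_} when the
#'   source carried no spacing ("px-units-only" records).
#' @slot birdId bird identifier (may be \code{NA}).
#' @slot timepoint one of \code{"wk16","wk29","wk42","wk55","wk68","PM","PMD"}
#'   or \code{NA}.
#' @slot photometricNormalized \code{TRUE} once the polarity convention
#'   (denser = brighter) has been applied.
#' @exportClass Radiograph
setClass("Radiograph",
  slots = c(
    pixels = "matrix",
    mmPerPx = "numeric",
    birdId = "character",
    timepoint = "character",
    photometricNormalized = "logical"
  )
)

setValidity("Radiograph", function(object) {
  px <- object@pixels
  if (!is.numeric(px)) return("pixels must be a numeric matrix")
  if (nrow(px) < 64 || ncol(px) < 64) {
    return("pixels must be at least 64 x 64 after load")
  }
  if (!all(is.finite(px))) return("pixels must be finite")
  if (length(object@mmPerPx) != 1) return("mmPerPx must be length 1")
  if (!is.na(object@mmPerPx) && object@mmPerPx <= 0) {
    return("mmPerPx must be strictly positive when present")
  }
  if (!is.na(object@timepoint) && !(object@timepoint %in% TIMEPOINTS)) {
    return(sprintf("timepoint must be one of: %s",
                   paste(TIMEPOINTS, collapse = ", ")))
  }
  if (length(object@photometricNormalized) != 1 ||
      is.na(object@photometricNormalized)) {
    return("photometricNormalized must be TRUE or FALSE")
  }
  TRUE
})

#' Construct a Radiograph
#'
#' @param pixels numeric matrix of intensities.
#' @param mmPerPx mm per pixel, or \code{NA}.
#' @param birdId bird identifier.
#' @param timepoint measurement occasion code.
#' @param photometricNormalized whether polarity is already canonical.
#' @return a \linkS4class{Radiograph}.
#' @export
Radiograph <- function(pixels, mmPerPx = NA_real_, birdId = NA_character_,
                       timepoint = NA_character_,
                       photometricNormalized = TRUE) {
  new("Radiograph",
      pixels = pixels,
      mmPerPx = as.numeric(mmPerPx),
      birdId = as.character(birdId),
      timepoint = as.character(timepoint),
      photometricNormalized = photometricNormalized)
}

#' KeelAnnotation: keypoints standing in for manual on-image drawings
#'
#' Named user-placed points and polylines per image: the tibiotarsal
#' mid-shaft line (drawn across the bone, i.e. its length is the bone width),
#' the keel centerline polyline from the pila carinae to the keel tip, the
#' mid-depth and cranial-depth lines, the anchor + direction of the 10 mm
#' keel density line across the pila carinae, and an optional off-bone
#' background rectangle.
#'
#' All point matrices are n x 2 with columns (x, y) in 0-based pixel-center
#' coordinates.
#'
#' @slot imageId image identifier the annotation refers to.
#' @slot tibiotarsalLine 2 x 2 matrix, endpoints of the mid-shaft line.
#' @slot keelPolyline n x 2 matrix (n >= 2), ordered, no consecutive
#'   duplicates.
#' @slot middepthLine 2 x 2 matrix.
#' @slot cranialdepthLine 2 x 2 matrix.
#' @slot densityAnchor list with \code{point} (length-2) and \code{direction}
#'   (length-2 unit vector).
#' @slot backgroundRegion length-4 numeric \code{c(x0, y0, x1, y1)} or
#'   length-0 when absent.
#' @exportClass KeelAnnotation
setClass("KeelAnnotation",
  slots = c(
    imageId = "character",
    tibiotarsalLine = "matrix",
    keelPolyline = "matrix",
    middepthLine = "matrix",
    cranialdepthLine = "matrix",
    densityAnchor = "list",
    backgroundRegion = "numeric"
  )
)

.checkSegment <- function(m, what) {
  if (!is.numeric(m) || !identical(dim(m), c(2L, 2L))) {
    return(sprintf("%s must be a 2 x 2 numeric matrix", what))
  }
  if (!all(is.finite(m))) return(sprintf("%s must be finite", what))
  NULL
}

setValidity("KeelAnnotation", function(object) {
  for (nm in c("tibiotarsalLine", "middepthLine", "cranialdepthLine")) {
    msg <- .checkSegment(slot(object, nm), nm)
    if (!is.null(msg)) return(msg)
  }
  kp <- object@keelPolyline
  if (!is.numeric(kp) || ncol(kp) != 2 || nrow(kp) < 2) {
    return("keelPolyline must be an n x 2 matrix with n >= 2")
  }
  if (!all(is.finite(kp))) return("keelPolyline must be finite")
  d <- diff(kp)
  if (any(rowSums(d * d) == 0)) {
    return("keelPolyline has consecutive duplicate points")
  }
  da <- object@densityAnchor
  if (!all(c("point", "direction") %in% names(da))) {
    return("densityAnchor must have elements 'point' and 'direction'")
  }
  if (length(da$point) != 2 || length(da$direction) != 2 ||
      !all(is.finite(c(da$point, da$direction)))) {
    return("densityAnchor point/direction must be finite length-2 vectors")
  }
  if (sum(da$direction^2) == 0) {
    return("densityAnchor direction must be nonzero")
  }
  br <- object@backgroundRegion
  if (length(br) != 0 && length(br) != 4) {
    return("backgroundRegion must be absent or c(x0, y0, x1, y1)")
  }
  if (length(br) == 4 && (br[1] > br[3] || br[2] > br[4])) {
    return("backgroundRegion must have x0 <= x1 and y0 <= y1")
  }
  TRUE
})

#' Construct a KeelAnnotation
#'
#' @param imageId image identifier.
#' @param tibiotarsalLine,middepthLine,cranialdepthLine 2 x 2 point matrices
#'   (rows are endpoints, columns x and y).
#' @param keelPolyline n x 2 matrix of ordered keel centerline points.
#' @param densityAnchor list with \code{point} and \code{direction}; the
#'   direction is normalized to unit length.
#' @param backgroundRegion optional \code{c(x0, y0, x1, y1)} rectangle.
#' @return a \linkS4class{KeelAnnotation}.
#' @export
KeelAnnotation <- function(imageId, tibiotarsalLine, keelPolyline,
                           middepthLine, cranialdepthLine, densityAnchor,
                           backgroundRegion = numeric(0)) {
  dir <- as.numeric(densityAnchor$direction)
  nrm <- sqrt(sum(dir^2))
  if (is.finite(nrm) && nrm > 0) dir <- dir / nrm
  new("KeelAnnotation",
      imageId = as.character(imageId),
      tibiotarsalLine = .asPointMatrix(tibiotarsalLine),
      keelPolyline = .asPointMatrix(keelPolyline),
      middepthLine = .asPointMatrix(middepthLine),
      cranialdepthLine = .asPointMatrix(cranialdepthLine),
      densityAnchor = list(point = as.numeric(densityAnchor$point),
                           direction = dir),
      backgroundRegion = as.numeric(backgroundRegion))
}

.asPointMatrix <- function(x) {
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  m
}

#' CorrelationEstimate: a correlation with its standard error
#'
#' Result container for polychoric, polyserial and Pearson correlations.
#'
#' @slot rho estimated correlation in [-1, 1].
#' @slot se standard error (NA when the estimate hit the boundary).
#' @slot method one of \code{"polychoric"}, \code{"polyserial"},
#'   \code{"pearson"}.
#' @slot n number of complete observation pairs used.
#' @slot thresholdsX,thresholdsY estimated latent thresholds for ordinal
#'   margins (empty for continuous margins).
#' @slot boundary \code{TRUE} when |rho| was capped at 0.9999.
#' @exportClass CorrelationEstimate
setClass("CorrelationEstimate",
  slots = c(
    rho = "numeric",
    se = "numeric",
    method = "character",
    n = "integer",
    thresholdsX = "numeric",
    thresholdsY = "numeric",
    boundary = "logical"
  )
)

setValidity("CorrelationEstimate", function(object) {
  if (abs(object@rho) > 1) return("|rho| must be <= 1")
  if (!object@method %in% c("polychoric", "polyserial", "pearson")) {
    return("method must be polychoric, polyserial or pearson")
  }
  if (length(object@thresholdsX) > 1 &&
      any(diff(object@thresholdsX) <= 0)) {
    return("thresholdsX must be strictly increasing")
  }
  if (length(object@thresholdsY) > 1 &&
      any(diff(object@thresholdsY) <= 0)) {
    return("thresholdsY must be strictly increasing")
  }
  if (!is.na(object@se) && object@se < 0) return("se must be >= 0")
  TRUE
})

.CorrelationEstimate <- function(rho, se, method, n,
                                 thresholdsX = numeric(0),
                                 thresholdsY = numeric(0),
                                 boundary = FALSE) {
  new("CorrelationEstimate", rho = rho, se = se, method = method,
      n = as.integer(n), thresholdsX = thresholdsX,
      thresholdsY = thresholdsY, boundary = boundary)
}

#' RegressionFit: a fitted association model
#'
#' Tidy container for the per-age damage regressions and the pelvic-dimension
#' models: coefficient table, family, log-likelihood (ML families), residuals
#' and convergence status.
#'
#' @slot coefficients data.frame with columns term, estimate, se, statistic,
#'   p.value.
#' @slot family \code{"linear"}, \code{"logistic"} or
#'   \code{"censored_poisson"}.
#' @slot n number of observations used.
#' @slot logLik maximized log-likelihood.
#' @slot residuals response residuals (working scale for ML families).
#' @slot converged convergence / regularity flag (FALSE e.g. under perfect
#'   separation).
#' @slot meta list of free-form metadata (response, timepoint, ...).
#' @exportClass RegressionFit
setClass("RegressionFit",
  slots = c(
    coefficients = "data.frame",
    family = "character",
    n = "integer",
    logLik = "numeric",
    residuals = "numeric",
    converged = "logical",
    meta = "list"
  )
)

setValidity("RegressionFit", function(object) {
  cf <- object@coefficients
  need <- c("term", "estimate", "se", "statistic", "p.value")
  if (!all(need %in% names(cf))) {
    return(sprintf("coefficients must have columns: %s",
                   paste(need, collapse = ", ")))
  }
  p <- cf$p.value
  if (any(!is.na(p) & (p < 0 | p > 1))) return("p-values must lie in [0, 1]")
  if (!object@family %in% c("linear", "logistic", "censored_poisson")) {
    return("unknown family")
  }
  TRUE
})
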