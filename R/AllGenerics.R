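#' Accessors
#'
#' Accessor generics for the package's S4 containers.
#'
#' @param object an object of the relevant class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))

#' @rdname accessors
#' @export
setGeneric("mmPerPx", function(object) standardGeneric("mmPerPx"))

#' @rdname accessors
#' @export
setGeneric("birdId", function(object) standardGeneric("birdId"))

#' @rdname accessors
#' @export
setGeneric("timepoint", function(object) standardGeneric("timepoint"))

#' @rdname accessors
#' @export
setGeneric("imageId", function(object) standardGeneric("imageId"))

#' @rdname accessors
#' @export
setGeneric("corRho", function(object) standardGeneric("corRho"))

#' @rdname accessors
#' @export
setGeneric("corSe", function(object) standardGeneric("corSe"))

#' @rdname accessors
#' @export
setMethod("pixels", "Radiograph", function(object) object@pixels)

#' @rdname accessors
#' @export
setMethod("mmPerPx", "Radiograph", function(object) object@mmPerPx)

#' @rdname accessors
#' @export
setMethod("birdId", "Radiograph", function(object) object@birdId)

#' @rdname accessors
#' @export
setMethod("timepoint", "Radiograph", function(object) object@timepoint)

#' @rdname accessors
#' @export
setMethod("imageId", "KeelAnnotation", function(object) object@imageId)

#' @rdname accessors
#' @export
setMethod("corRho", "CorrelationEstimate", function(object) object@rho)

#' @rdname accessors
#' @export
setMethod("corSe", "CorrelationEstimate", function(object) object@se)

#' @describeIn accessors dimensions (rows, columns) of the pixel matrix.
#' @export
setMethod("dim", "Radiograph", function(x) dim(x@pixels))

#' Coefficient table of a RegressionFit
#'
#' @param object a \linkS4class{RegressionFit}.
#' @param ... ignored.
#' @return named numeric vector of estimates (use \code{tidyCoef} for the
#'   full table).
#' @export
setMethod("coef", "RegressionFit", function(object, ...) {
  stats::setNames(object@coefficients$estimate, object@coefficients$term)
})

#' Full coefficient table
#'
#' @param fit a \linkS4class{RegressionFit}.
#' @return data.frame with term, estimate, se, statistic, p.value.
#' @export
tidyCoef <- function(fit) {
  stopifnot(is(fit, "RegressionFit"))
  fit@coefficients
}

#' @describeIn accessors log-likelihood of an ML fit.
#' @param object a \linkS4class{RegressionFit}.
#' @export
setMethod("logLik", "RegressionFit", function(object) object@logLik)

setMethod("show", "Radiograph", function(object) {
  sp <- if (is.na(object@mmPerPx)) "px-units-only" else {
    sprintf("%.4g mm/px", object@mmPerPx)
  }
  cat(sprintf("Radiograph %d x %d [%s] bird=%s timepoint=%s\n",
              nrow(object@pixels), ncol(object@pixels), sp,
              object@birdId, object@timepoint))
  cat(sprintf("  intensity range [%.4g, %.4g], photometric %s\n",
              min(object@pixels), max(object@pixels),
              if (object@photometricNormalized) "canonical (denser = brighter)"
              else "raw"))
})

setMethod("show", "KeelAnnotation", function(object) {
  cat(sprintf("KeelAnnotation for image '%s'\n", object@imageId))
  cat(sprintf("  keel polyline: %d points; background region: %s\n",
              nrow(object@keelPolyline),
              if (length(object@backgroundRegion)) "yes" else "no"))
})

setMethod("show", "CorrelationEstimate", function(object) {
  cat(sprintf("%s correlation: %.4f +/- %s (n = %d)%s\n",
              object@method, object@rho,
              if (is.na(object@se)) "NA" else sprintf("%.4f", object@se),
              object@n,
              if (object@boundary) " [boundary]" else ""))
})

setMethod("show", "RegressionFit", function(object) {
  cat(sprintf("RegressionFit [%s], n = %d, logLik = %.3f%s\n",
              object@family, object@n, object@logLik,
              if (!object@converged) " (NOT converged)" else ""))
  print(object@coefficients, row.names = FALSE, digits = 4)
})
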