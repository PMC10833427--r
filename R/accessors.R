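#' Accessors for tomography objects
#'
#' Small generic accessors: projection angles, detector dimensions,
#' rotation-center offset, raw arrays, traces and affine-match parameters.
#'
#' @param x the object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("angles", function(x) standardGeneric("angles"))
#' @rdname accessors
#' @export
setMethod("angles", "ScanGeometry", function(x) x@angles)
#' @rdname accessors
#' @export
setMethod("angles", "Sinogram", function(x) x@geometry@angles)

#' @rdname accessors
#' @export
setGeneric("numColumns", function(x) standardGeneric("numColumns"))
#' @rdname accessors
#' @export
setMethod("numColumns", "ScanGeometry", function(x) x@numColumns)
#' @rdname accessors
#' @export
setMethod("numColumns", "Sinogram", function(x) x@geometry@numColumns)

#' @rdname accessors
#' @export
setGeneric("numSlices", function(x) standardGeneric("numSlices"))
#' @rdname accessors
#' @export
setMethod("numSlices", "ScanGeometry", function(x) x@numSlices)
#' @rdname accessors
#' @export
setMethod("numSlices", "Sinogram", function(x) x@geometry@numSlices)
#' @rdname accessors
#' @export
setMethod("numSlices", "Volume", function(x) dim(x@data)[1L])

#' @rdname accessors
#' @export
setGeneric("centerOffset", function(x) standardGeneric("centerOffset"))
#' @rdname accessors
#' @export
setMethod("centerOffset", "ScanGeometry", function(x) x@centerOffset)
#' @rdname accessors
#' @export
setMethod("centerOffset", "Sinogram", function(x) x@geometry@centerOffset)

#' @rdname accessors
#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))
#' @rdname accessors
#' @export
setMethod("geometry", "Sinogram", function(x) x@geometry)
#' @rdname accessors
#' @export
setMethod("geometry", "OperatorPlan", function(x) x@geometry)

#' @rdname accessors
#' @export
sinogramData <- function(x) x@data

#' @rdname accessors
#' @export
volumeData <- function(x) x@data

#' @rdname accessors
#' @export
gridSide <- function(x) dim(x@data)[2L]

#' @rdname accessors
#' @export
reconVolume <- function(x) x@volume

#' @rdname accessors
#' @export
objectiveTrace <- function(x) x@objectiveTrace

#' @rdname accessors
#' @export
dataTermTrace <- function(x) x@dataTermTrace

#' @rdname accessors
#' @export
iterationsRun <- function(x) x@iterationsRun

#' @rdname accessors
#' @export
configEcho <- function(x) x@configEcho

#' @rdname accessors
#' @export
matchScale <- function(x) x@scale

#' @rdname accessors
#' @export
matchShift <- function(x) x@shift

#' @rdname accessors
#' @export
dataTerm <- function(x) x@dataTerm

#' @rdname accessors
#' @export
priorTerm <- function(x) x@priorTerm

#' @rdname accessors
#' @export
objectiveTotal <- function(x) x@total

setMethod("show", "ScanGeometry", function(object) {
  cat(sprintf("ScanGeometry: %d angles in [%.4f, %.4f] rad, %d columns x %d slices, center offset %+.3f px\n",
              length(object@angles), min(object@angles), max(object@angles),
              object@numColumns, object@numSlices, object@centerOffset))
})

setMethod("show", "Sinogram", function(object) {
  d <- dim(object@data)
  cat(sprintf("Sinogram: %d angles x %d slices x %d columns, range [%.4g, %.4g]\n",
              d[1L], d[2L], d[3L], min(object@data), max(object@data)))
})

setMethod("show", "Volume", function(object) {
  d <- dim(object@data)
  cat(sprintf("Volume: %d slices x %d x %d, range [%.4g, %.4g]\n",
              d[1L], d[2L], d[3L], min(object@data), max(object@data)))
})

setMethod("show", "QGGMRFParams", function(object) {
  cat(sprintf("QGGMRFParams: p = %g, q = 2, c = %g, sigma = %g (26-neighbor prior)\n",
              object@p, object@c, object@sigma))
})

setMethod("show", "OperatorPlan", function(object) {
  cat(sprintf("OperatorPlan: %d views x %d radial bins, fine grid %d^2, kernel %s w = %d (tol %.1e)\n",
              length(object@geometry@angles), object@polar@radialCount,
              object@fineSize, object@kernel@family, object@kernel@width,
              object@kernel@tolerance))
})

setMethod("show", "ReconResult", function(object) {
  cat(sprintf("ReconResult: %d iterations, final objective %.6g (data %.6g)\n",
              object@iterationsRun,
              utils::tail(object@objectiveTrace, 1L),
              utils::tail(object@dataTermTrace, 1L)))
  show(object@volume)
})

setMethod("show", "AffineMatch", function(object) {
  cat(sprintf("AffineMatch: scale = %.6g, shift = %.6g\n", object@scale, object@shift))
})

setMethod("show", "ObjectiveBreakdown", function(object) {
  cat(sprintf("Objective: total %.6g = data %.6g + prior %.6g\n",
              object@total, object@dataTerm, object@priorTerm))
})
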