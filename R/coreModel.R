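#' Construct a scan geometry
#'
#' @param angles projection angles in radians, strictly increasing in
#'   \eqn{[0, 2\pi)}.
#' @param numColumns detector width in pixels (>= 2).
#' @param numSlices number of detector rows along the rotation axis.
#' @param centerOffset signed rotation-axis offset in pixels (fractional
#'   allowed) from the detector midpoint \code{(numColumns - 1)/2}.
#' @param pixelSize physical length per pixel (arbitrary units).
#' @return a \linkS4class{ScanGeometry}.
#' @examples
#' g <- scanGeometry(seq(0, pi, length.out = 9)[1:8], 32)
#' numColumns(g)
#' @export
scanGeometry <- function(angles, numColumns, numSlices = 1L,
                         centerOffset = 0, pixelSize = 1) {
  new("ScanGeometry", angles = as.numeric(angles),
      numColumns = as.integer(numColumns), numSlices = as.integer(numSlices),
      centerOffset = as.numeric(centerOffset), pixelSize = as.numeric(pixelSize))
}

#' Construct a sinogram
#'
#' @param data 3-D numeric array indexed \code{[angle, slice, column]}.
#' @param geometry the matching \linkS4class{ScanGeometry}.
#' @return a \linkS4class{Sinogram}.
#' @export
sinogram <- function(data, geometry) {
  storage.mode(data) <- "double"
  new("Sinogram", data = data, geometry = geometry)
}

#' Construct a volume
#'
#' @param data 3-D numeric array indexed \code{[slice, y, x]} (square in
#'   y, x), or a 2-D matrix treated as a single slice.
#' @param voxelSize physical length per voxel.
#' @return a \linkS4class{Volume}.
#' @export
tomoVolume <- function(data, voxelSize = 1) {
  if (is.matrix(data)) data <- array(data, c(1L, nrow(data), ncol(data)))
  storage.mode(data) <- "double"
  new("Volume", data = data, voxelSize = as.numeric(voxelSize))
}

#' Zero volume matching a geometry
#'
#' @param geometry a \linkS4class{ScanGeometry}.
#' @param voxelSize physical length per voxel.
#' @return a \linkS4class{Volume} of zeros with grid side \code{numColumns}.
#' @export
zeroVolume <- function(geometry, voxelSize = geometry@pixelSize) {
  n <- geometry@numColumns
  tomoVolume(array(0, c(geometry@numSlices, n, n)), voxelSize)
}

#' Check that a sinogram and a volume are mutually consistent
#'
#' Verifies that the detector column count matches the volume grid side and
#' that slice counts agree, raising a shape-mismatch error naming the
#' offending dimension otherwise.
#'
#' @param sino a \linkS4class{Sinogram}.
#' @param volume a \linkS4class{Volume}.
#' @return \code{TRUE} (invisibly errors otherwise).
#' @export
validatePair <- function(sino, volume) {
  g <- sino@geometry
  dv <- dim(volume@data)
  if (dv[2L] != g@numColumns)
    stop(sprintf("shape mismatch: volume grid side %d != detector columns %d",
                 dv[2L], g@numColumns))
  if (dv[1L] != g@numSlices)
    stop(sprintf("shape mismatch: volume slices %d != sinogram slices %d",
                 dv[1L], g@numSlices))
  TRUE
}

#' Solver configuration constructor
#'
#' @param maxIterations iteration budget (>= 1).
#' @param stepSize positive step length, or \code{"auto"}/\code{NA} for the
#'   power-iteration estimate \code{0.9 / L}.
#' @param restart reset momentum when the objective increases.
#' @param monotone enforce a non-increasing objective trace.
#' @param accelerate use Nesterov momentum (FALSE: plain gradient descent).
#' @param stopTolerance relative objective-change stopping threshold
#'   (0 = run all iterations).
#' @param seed integer seed for randomized initialization (power iteration).
#' @return a \linkS4class{SolverConfig}.
#' @export
solverConfig <- function(maxIterations = 100L, stepSize = "auto",
                         restart = TRUE, monotone = TRUE, accelerate = TRUE,
                         stopTolerance = 0, seed = 1L) {
  if (identical(stepSize, "auto")) stepSize <- NA_real_
  new("SolverConfig", maxIterations = as.integer(maxIterations),
      stepSize = as.numeric(stepSize), restart = isTRUE(restart),
      monotone = isTRUE(monotone), accelerate = isTRUE(accelerate),
      stopTolerance = as.numeric(stopTolerance),
      seed = as.integer(seed))
}

#' Affine match constructor
#' @param scale scale \code{s}.
#' @param shift shift \code{delta}.
#' @return an \linkS4class{AffineMatch}.
#' @export
affineMatchValues <- function(scale, shift) {
  new("AffineMatch", scale = as.numeric(scale), shift = as.numeric(shift))
}

#' Serialize a configuration object to a plain list
#'
#' Round-trippable plain-field representation: calling the matching
#' constructor with \code{do.call} on the result reproduces the object.
#'
#' @param x a configuration object (geometry, solver config, prior
#'   parameters, filter, phantom or acquisition spec, kernel, schedule).
#' @return a named list of plain fields.
#' @export
setGeneric("toConfig", function(x) standardGeneric("toConfig"))

#' @rdname toConfig
setMethod("toConfig", "ScanGeometry", function(x)
  list(angles = x@angles, numColumns = x@numColumns, numSlices = x@numSlices,
       centerOffset = x@centerOffset, pixelSize = x@pixelSize))

#' @rdname toConfig
setMethod("toConfig", "SolverConfig", function(x)
  list(maxIterations = x@maxIterations,
       stepSize = if (is.na(x@stepSize)) "auto" else x@stepSize,
       restart = x@restart, monotone = x@monotone,
       accelerate = x@accelerate,
       stopTolerance = x@stopTolerance, seed = x@seed))

#' @rdname toConfig
setMethod("toConfig", "QGGMRFParams", function(x)
  list(p = x@p, c = x@c, sigma = x@sigma))

#' @rdname toConfig
setMethod("toConfig", "FilterSpec", function(x)
  list(name = x@name, order = x@order, cutoff = x@cutoff))

#' @rdname toConfig
setMethod("toConfig", "SpreadingKernel", function(x)
  list(family = x@family, tolerance = x@tolerance, width = x@width,
       oversampling = x@oversampling))

#' @rdname toConfig
setMethod("toConfig", "FoamSpec", function(x)
  list(gridSide = x@gridSide, numSlices = x@numSlices, voidCount = x@voidCount,
       radiusRange = x@radiusRange, materialDensity = x@materialDensity,
       seed = x@seed))

#' @rdname toConfig
setMethod("toConfig", "AcquisitionSpec", function(x)
  list(numAngles = x@numAngles, angleSpan = x@angleSpan, flux = x@flux,
       poissonNoise = x@poissonNoise, centerOffset = x@centerOffset,
       seed = x@seed))

#' @rdname toConfig
setMethod("toConfig", "LevelSchedule", function(x)
  list(factors = x@factors, iterations = x@iterations))
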