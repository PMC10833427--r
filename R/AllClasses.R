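#' @useDynLib nufftTomo, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

.finite <- function(x) all(is.finite(x))

#' Parallel-beam scan geometry
#'
#' Describes a parallel-beam acquisition: the projection angles (radians,
#' strictly increasing within \eqn{[0, 2\pi)}), the detector width in pixels,
#' the number of detector rows along the rotation axis, and the signed
#' rotation-center offset (in pixels, fractional allowed) measured from the
#' detector midpoint at column \eqn{(numColumns - 1)/2}.
#'
#' @slot angles numeric vector of projection angles in radians.
#' @slot numColumns integer, detector width in pixels.
#' @slot numSlices integer, number of detector rows.
#' @slot centerOffset numeric, rotation-axis offset from the detector midpoint.
#' @slot pixelSize numeric, physical length per detector pixel.
#' @export
setClass("ScanGeometry",
  representation(angles = "numeric", numColumns = "integer",
                 numSlices = "integer", centerOffset = "numeric",
                 pixelSize = "numeric"))

setValidity("ScanGeometry", function(object) {
  a <- object@angles
  if (length(a) < 1L || !.finite(a)) return("angles must be finite and non-empty")
  if (any(a < 0) || any(a >= 2 * pi)) return("angles must lie in [0, 2*pi)")
  if (length(a) > 1L && any(diff(a) <= 0)) return("angles must be strictly increasing")
  if (object@numColumns < 2L) return("numColumns must be >= 2")
  if (object@numSlices < 1L) return("numSlices must be >= 1")
  if (!is.finite(object@centerOffset) ||
      abs(object@centerOffset) >= object@numColumns / 2)
    return("centerOffset must satisfy |offset| < numColumns/2")
  if (!is.finite(object@pixelSize) || object@pixelSize <= 0)
    return("pixelSize must be positive")
  TRUE
})

#' Attenuation sinogram
#'
#' Projection line integrals indexed \code{[angle, slice, column]}, paired
#' with the geometry that produced them.
#'
#' @slot data 3-D numeric array, dimensions
#'   \code{(length(angles), numSlices, numColumns)}.
#' @slot geometry a \linkS4class{ScanGeometry}.
#' @export
setClass("Sinogram",
  representation(data = "array", geometry = "ScanGeometry"))

setValidity("Sinogram", function(object) {
  d <- dim(object@data)
  g <- object@geometry
  if (length(d) != 3L) return("sinogram data must be a 3-D array [angle, slice, column]")
  if (d[1L] != length(g@angles)) return("first dimension must equal the number of angles")
  if (d[2L] != g@numSlices) return("second dimension must equal numSlices")
  if (d[3L] != g@numColumns) return("third dimension must equal numColumns")
  if (!.finite(object@data)) return("sinogram values must all be finite")
  TRUE
})

#' Reconstruction volume
#'
#' Sample density on a Cartesian grid, indexed \code{[slice, y, x]} with a
#' square per-slice grid.
#'
#' @slot data 3-D numeric array \code{[slice, y, x]} with \code{dim[2] == dim[3]}.
#' @slot voxelSize numeric, physical length per voxel.
#' @export
setClass("Volume",
  representation(data = "array", voxelSize = "numeric"))

setValidity("Volume", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L) return("volume data must be a 3-D array [slice, y, x]")
  if (d[2L] != d[3L]) return("per-slice grid must be square")
  if (!.finite(object@data)) return("volume values must all be finite")
  if (!is.finite(object@voxelSize) || object@voxelSize <= 0)
    return("voxelSize must be positive")
  TRUE
})

#' Polar frequency grid
#'
#' The non-uniform polar sampling of 2-D frequency space used by the central
#' slice theorem: one radial line of 1-D DFT frequencies per projection angle.
#' Points are stored in grid-frequency units (radians per pixel, each
#' coordinate in \eqn{[-\pi, \pi)}).
#'
#' @slot points numeric matrix (totalCount x 2) of \eqn{(k_x, k_y)} pairs.
#' @slot radialCount integer, radial samples per view.
#' @slot totalCount integer, total number of points.
#' @slot angles numeric, the view angles the grid was built from.
#' @slot radialIndex integer, signed DFT bin index of each radial sample.
#' @export
setClass("PolarFrequencyGrid",
  representation(points = "matrix", radialCount = "integer",
                 totalCount = "integer", angles = "numeric",
                 radialIndex = "integer"))

setValidity("PolarFrequencyGrid", function(object) {
  if (object@totalCount != object@radialCount * length(object@angles))
    return("totalCount must equal radialCount * number of angles")
  if (nrow(object@points) != object@totalCount || ncol(object@points) != 2L)
    return("points must be a totalCount x 2 matrix")
  if (any(object@points < -pi - 1e-12) || any(object@points >= pi + 1e-12))
    return("frequencies must lie in [-pi, pi)^2 grid-frequency units")
  # radial coordinates symmetric about zero (modulo 2*pi: -Nyquist pairs itself)
  r <- sort(unique(round(object@radialIndex %% object@radialCount, 9)))
  rn <- sort(unique(round((-object@radialIndex) %% object@radialCount, 9)))
  if (!isTRUE(all.equal(r, rn))) return("radial frequencies must be symmetric about zero")
  TRUE
})

#' Spreading kernel settings
#'
#' Accuracy contract of the NUFFT gridding step: a compactly supported
#' spreading kernel of per-dimension width \code{width} on a fine grid
#' oversampled by \code{oversampling}, targeting relative accuracy
#' \code{tolerance}.
#'
#' @slot family character, kernel identifier (\code{"exp-semicircle"}).
#' @slot tolerance numeric, target NUFFT accuracy in (0, 1).
#' @slot width integer, kernel support in fine-grid points per dimension.
#' @slot oversampling numeric, fine-grid upsampling factor (>= 1.25).
#' @export
setClass("SpreadingKernel",
  representation(family = "character", tolerance = "numeric",
                 width = "integer", oversampling = "numeric"))

setValidity("SpreadingKernel", function(object) {
  if (object@tolerance <= 0 || object@tolerance >= 1)
    return("tolerance must lie in (0, 1)")
  if (object@width < 2L) return("width must be >= 2")
  if (object@oversampling < 1.25) return("oversampling must be >= 1.25")
  TRUE
})

#' qGGMRF prior hyper-parameters
#'
#' The q-generalized Gaussian Markov random field potential
#' \eqn{\rho(\Delta) = |\Delta/\sigma|^2 / (c + |\Delta/\sigma|^{2-p})}
#' over the 26-neighbor 1-hop 3-D neighborhood, with partition-of-unity
#' weights inversely proportional to neighbor distance. \code{q} is fixed
#' at 2; \code{p}, \code{c} and \code{sigma} control the penalty strength
#' and its edge-preserving transition.
#'
#' @slot p numeric shape exponent, \eqn{1 \le p < 2}.
#' @slot c numeric transition constant, > 0.
#' @slot sigma numeric regularization scale, > 0.
#' @slot q numeric, fixed at 2.
#' @slot neighborhood integer matrix (26 x 3) of (dz, dy, dx) offsets.
#' @slot weights numeric vector of 26 positive weights summing to 1.
#' @export
setClass("QGGMRFParams",
  representation(p = "numeric", c = "numeric", sigma = "numeric",
                 q = "numeric", neighborhood = "matrix", weights = "numeric"))

setValidity("QGGMRFParams", function(object) {
  if (object@q != 2) return("q is fixed at 2")
  if (object@p < 1 || object@p >= object@q) return("p must satisfy 1 <= p < q = 2")
  if (object@c <= 0) return("c must be > 0")
  if (object@sigma <= 0) return("sigma must be > 0")
  if (nrow(object@neighborhood) != 26L || ncol(object@neighborhood) != 3L)
    return("neighborhood must be the 26 offsets of the 1-hop 3-D neighborhood")
  if (length(object@weights) != 26L || any(object@weights <= 0))
    return("weights must be 26 strictly positive values")
  if (abs(sum(object@weights) - 1) > 1e-12) return("weights must sum to 1")
  d <- sqrt(rowSums(object@neighborhood^2))
  ratio <- object@weights * d
  if (max(abs(ratio - ratio[1L])) > 1e-12)
    return("weights must be inversely proportional to offset length")
  TRUE
})

#' Solver configuration
#'
#' Settings for the monotone accelerated gradient method with restart.
#' \code{stepSize} is a positive scalar or \code{NA} for the automatic
#' power-iteration estimate; \code{stopTolerance} is the relative
#' objective-change threshold (0 runs all \code{maxIterations}).
#'
#' @slot maxIterations integer >= 1.
#' @slot stepSize numeric, positive scalar or \code{NA} ("auto").
#' @slot restart logical, reset momentum when the objective increases.
#' @slot monotone logical, enforce a non-increasing objective trace.
#' @slot accelerate logical; FALSE gives plain (unaccelerated) gradient
#'   descent.
#' @slot stopTolerance numeric >= 0.
#' @slot seed integer used for any randomized initialization (power iteration).
#' @export
setClass("SolverConfig",
  representation(maxIterations = "integer", stepSize = "numeric",
                 restart = "logical", monotone = "logical",
                 accelerate = "logical",
                 stopTolerance = "numeric", seed = "integer"))

setValidity("SolverConfig", function(object) {
  if (object@maxIterations < 1L) return("maxIterations must be >= 1")
  if (!is.na(object@stepSize) && object@stepSize <= 0)
    return("stepSize must be positive or NA (auto)")
  if (is.na(object@stopTolerance) || object@stopTolerance < 0)
    return("stopTolerance must be >= 0")
  TRUE
})

#' Reconstruction result
#'
#' The reconstructed volume together with the per-iteration objective and
#' data-term traces and an echo of the configuration actually used.
#'
#' @slot volume a \linkS4class{Volume}.
#' @slot objectiveTrace numeric, objective value after each iteration.
#' @slot dataTermTrace numeric, data misfit \eqn{\frac12\|Rf-b\|^2} per iteration.
#' @slot iterationsRun integer.
#' @slot configEcho list with elements \code{solver} and \code{prior} (and,
#'   for hierarchical runs, the per-level schedule and sigmas).
#' @export
setClass("ReconResult",
  representation(volume = "Volume", objectiveTrace = "numeric",
                 dataTermTrace = "numeric", iterationsRun = "integer",
                 configEcho = "list"))

setValidity("ReconResult", function(object) {
  if (length(object@objectiveTrace) != object@iterationsRun)
    return("objectiveTrace length must equal iterationsRun")
  if (length(object@dataTermTrace) != object@iterationsRun)
    return("dataTermTrace length must equal iterationsRun")
  mono <- isTRUE(object@configEcho$solver$monotone) &&
    !isTRUE(object@configEcho$hierarchical)   # traces jump between levels
  if (mono && object@iterationsRun > 1L) {
    tr <- object@objectiveTrace
    if (any(diff(tr) > 1e-9 * pmax(abs(tr[-length(tr)]), 1)))
      return("objectiveTrace must be non-increasing when monotone is enabled")
  }
  TRUE
})

#' Affine intensity match
#'
#' Least-squares scale \code{s} and shift \code{delta} mapping a candidate
#' image onto a reference, used by the affine-matched rRMSE protocol.
#'
#' @slot scale numeric.
#' @slot shift numeric.
#' @export
setClass("AffineMatch", representation(scale = "numeric", shift = "numeric"))

setValidity("AffineMatch", function(object) {
  if (!is.finite(object@scale) || !is.finite(object@shift))
    return("scale and shift must be finite")
  TRUE
})

#' Objective breakdown
#'
#' @slot dataTerm numeric, \eqn{\frac12\|Rf - b\|_2^2}.
#' @slot priorTerm numeric, weighted qGGMRF penalty.
#' @slot total numeric, their sum.
#' @export
setClass("ObjectiveBreakdown",
  representation(dataTerm = "numeric", priorTerm = "numeric", total = "numeric"))

setValidity("ObjectiveBreakdown", function(object) {
  if (object@dataTerm < 0 || object@priorTerm < 0) return("terms must be >= 0")
  if (abs(object@total - (object@dataTerm + object@priorTerm)) >
      1e-9 * max(1, object@total))
    return("total must equal dataTerm + priorTerm")
  TRUE
})

#' NUFFT operator plan
#'
#' Precomputed state shared by the forward Radon transform and its adjoint:
#' the polar frequency grid, the spreading kernel, the deapodization profile
#' (reciprocal of the kernel Fourier transform on the image grid), and the
#' combined per-point phase (image-center phase, detector-center phase and
#' rotation-center offset ramp).
#'
#' @slot geometry a \linkS4class{ScanGeometry}.
#' @slot kernel a \linkS4class{SpreadingKernel}.
#' @slot polar a \linkS4class{PolarFrequencyGrid}.
#' @slot deapodization numeric, per-axis deapodization profile (length n).
#' @slot fineSize integer, oversampled fine-grid side.
#' @slot beta numeric, kernel shape parameter.
#' @slot xiX,xiY numeric, polar points in fine-grid frequency units.
#' @slot phase complex, combined unit-modulus phase per polar point.
#' @slot radialFreq numeric, Nyquist-normalized |k| in [0, 0.5] per radial bin.
#' @slot pad integer, detector embedding offset when radialCount > numColumns.
#' @export
setClass("OperatorPlan",
  representation(geometry = "ScanGeometry", kernel = "SpreadingKernel",
                 polar = "PolarFrequencyGrid", deapodization = "numeric",
                 fineSize = "integer", beta = "numeric",
                 xiX = "numeric", xiY = "numeric", phase = "complex",
                 radialFreq = "numeric", pad = "integer"))

setValidity("OperatorPlan", function(object) {
  if (!.finite(object@deapodization) || any(object@deapodization == 0))
    return("deapodization values must be finite and nonzero")
  if (object@polar@totalCount != length(object@xiX))
    return("polar grid inconsistent with plan state")
  if (length(object@polar@angles) != length(object@geometry@angles) ||
      any(object@polar@angles != object@geometry@angles))
    return("polar grid inconsistent with geometry")
  TRUE
})

#' Filtered back-projection filter
#'
#' @slot name character: \code{"ram-lak"}, \code{"shepp-logan"},
#'   \code{"butterworth"} or \code{"none"}.
#' @slot order numeric Butterworth order (>= 1).
#' @slot cutoff numeric normalized cutoff in (0, 0.5].
#' @export
setClass("FilterSpec",
  representation(name = "character", order = "numeric", cutoff = "numeric"))

setValidity("FilterSpec", function(object) {
  if (!object@name %in% c("ram-lak", "shepp-logan", "butterworth", "none"))
    return(sprintf("unknown filter '%s' (supported: ram-lak, shepp-logan, butterworth, none)",
                   object@name))
  if (object@name == "butterworth") {
    if (object@cutoff <= 0 || object@cutoff > 0.5)
      return("butterworth cutoff must lie in (0, 0.5]")
    if (object@order < 1) return("butterworth order must be >= 1")
  }
  TRUE
})

#' Foam phantom specification
#'
#' A uniform cylinder of bulk material with non-overlapping spherical voids,
#' emulating foam-like micro-CT specimens.
#'
#' @slot gridSide integer, per-slice grid side in pixels.
#' @slot numSlices integer.
#' @slot voidCount integer, target number of voids (fewer may be placed).
#' @slot radiusRange numeric length-2, (min, max) void radius in pixels.
#' @slot materialDensity numeric, attenuation of the bulk.
#' @slot seed integer.
#' @export
setClass("FoamSpec",
  representation(gridSide = "integer", numSlices = "integer",
                 voidCount = "integer", radiusRange = "numeric",
                 materialDensity = "numeric", seed = "integer"))

setValidity("FoamSpec", function(object) {
  r <- object@radiusRange
  if (length(r) != 2L || any(r <= 0) || r[2L] < r[1L])
    return("radiusRange must be positive (min, max)")
  if (r[2L] >= object@gridSide / 4) return("max void radius must be < gridSide/4")
  if (object@voidCount < 0L) return("voidCount must be >= 0")
  if (object@numSlices < 1L) return("numSlices must be >= 1")
  TRUE
})

#' Acquisition specification
#'
#' Beer-Lambert acquisition simulation settings: number of views over the
#' angular span, incident flux (mean photons per detector pixel), optional
#' Poisson counting noise, and a rotation-center offset applied as a
#' sub-pixel detector shift.
#'
#' @slot numAngles integer >= 1.
#' @slot angleSpan numeric, pi or 2*pi.
#' @slot flux numeric > 0, incident photons per pixel.
#' @slot poissonNoise logical.
#' @slot centerOffset numeric, pixels.
#' @slot seed integer.
#' @export
setClass("AcquisitionSpec",
  representation(numAngles = "integer", angleSpan = "numeric",
                 flux = "numeric", poissonNoise = "logical",
                 centerOffset = "numeric", seed = "integer"))

setValidity("AcquisitionSpec", function(object) {
  if (object@numAngles < 1L) return("numAngles must be >= 1")
  if (!is.finite(object@flux) || object@flux <= 0) return("flux must be > 0")
  if (!isTRUE(all.equal(object@angleSpan, pi)) &&
      !isTRUE(all.equal(object@angleSpan, 2 * pi)))
    return("angleSpan must be pi or 2*pi")
  TRUE
})

#' Multiresolution level schedule
#'
#' Ordered (downsampleFactor, iterations) pairs for coarse-to-fine
#' reconstruction; factors are powers of two, non-increasing, ending at 1.
#'
#' @slot factors integer vector.
#' @slot iterations integer vector.
#' @export
setClass("LevelSchedule",
  representation(factors = "integer", iterations = "integer"))

setValidity("LevelSchedule", function(object) {
  f <- object@factors
  if (length(f) < 1L || length(f) != length(object@iterations))
    return("factors and iterations must have equal positive length")
  if (any(bitwAnd(f, f - 1L) != 0L) || any(f < 1L))
    return("factors must be powers of 2")
  if (any(diff(f) > 0L)) return("factors must be non-increasing")
  if (f[length(f)] != 1L) return("last factor must be 1")
  if (any(object@iterations < 1L)) return("iterations must be >= 1 per level")
  TRUE
})
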