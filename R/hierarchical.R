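#' Multiresolution schedule constructor
#'
#' @param factors downsampling factors (powers of 2, non-increasing,
#'   ending at 1). Default \code{c(4, 2, 1)}.
#' @param iterations iteration budget per level. Default
#'   \code{c(60, 30, 15)}.
#' @return a \linkS4class{LevelSchedule}.
#' @export
levelSchedule <- function(factors = c(4L, 2L, 1L),
                          iterations = c(60L, 30L, 15L)) {
  new("LevelSchedule", factors = as.integer(factors),
      iterations = as.integer(iterations))
}

#' Downsample a sinogram along the detector
#'
#' Block-averages detector columns with a window equal to \code{factor};
#' angles and slices are unchanged, the rotation-center offset is divided
#' by the factor and the pixel size multiplied by it.
#'
#' @param sino a \linkS4class{Sinogram}.
#' @param factor power of 2 dividing \code{numColumns}.
#' @return a \linkS4class{Sinogram} of width \code{numColumns / factor}.
#' @export
downsampleSinogram <- function(sino, factor) {
  factor <- as.integer(factor)
  if (factor == 1L) return(sino)
  g <- sino@geometry
  n <- g@numColumns
  if (n %% factor != 0L)
    stop(sprintf("numColumns %d not divisible by factor %d", n, factor))
  d <- sino@data
  nc <- n %/% factor
  dn <- array(0, c(dim(d)[1L], dim(d)[2L], nc))
  for (j in seq_len(factor))
    dn <- dn + d[, , seq(j, n, by = factor), drop = FALSE]
  dn <- dn / factor
  geomOut <- scanGeometry(g@angles, nc, g@numSlices,
                          g@centerOffset / factor, g@pixelSize * factor)
  sinogram(dn, geomOut)
}

# per-axis bilinear interpolation matrix (center-aligned, linear
# extrapolation at the borders so affine profiles are reproduced exactly)
.upsampleMatrix <- function(nCoarse, factor) {
  nFine <- nCoarse * factor
  u <- (seq_len(nFine) - 0.5) / factor - 0.5      # coarse coordinates, 0-based
  i0 <- pmin(pmax(floor(u), 0), nCoarse - 2)
  t <- u - i0
  w <- matrix(0, nFine, nCoarse)
  w[cbind(seq_len(nFine), i0 + 1)] <- 1 - t
  w[cbind(seq_len(nFine), i0 + 2)] <- t
  w
}

#' Upsample a volume by bilinear interpolation
#'
#' Per-slice bilinear interpolation to a \code{factor}-times finer grid,
#' density-scale preserving (constants map to constants; affine ramps are
#' reproduced exactly).
#'
#' @param volume a \linkS4class{Volume}.
#' @param factor integer upsampling factor (>= 1).
#' @return a \linkS4class{Volume} with side \code{factor * gridSide}.
#' @export
upsampleVolume <- function(volume, factor) {
  factor <- as.integer(factor)
  if (factor == 1L) return(volume)
  n <- gridSide(volume)
  w <- .upsampleMatrix(n, factor)
  ns <- numSlices(volume)
  out <- array(0, c(ns, n * factor, n * factor))
  for (s in seq_len(ns))
    out[s, , ] <- w %*% matrix(volume@data[s, , ], n, n) %*% t(w)
  tomoVolume(out, volume@voxelSize / factor)
}

#' Coarse-to-fine hierarchical reconstruction
#'
#' Solves the MBIR problem on a detector-downsampled version of the data,
#' upsamples the solution, and uses it as the initial iterate for the next
#' (finer) level, ending at full resolution. Coarse-level data are
#' rescaled to coarse-pixel path-length units internally so each level
#' reconstructs the same physical density; sigma is constant across levels
#' unless per-level multipliers are supplied.
#'
#' @param sino full-resolution projection data.
#' @param params a \linkS4class{QGGMRFParams}.
#' @param config a \linkS4class{SolverConfig} (its \code{maxIterations} is
#'   superseded by the schedule).
#' @param schedule a \linkS4class{LevelSchedule};
#'   default \code{(4 x 60, 2 x 30, 1 x 15)}.
#' @param kernel a \linkS4class{SpreadingKernel} for the per-level plans.
#' @param sigmaScale optional per-level multipliers on \code{sigma}
#'   (default all 1).
#' @return the finest-level \linkS4class{ReconResult} with concatenated
#'   per-level traces; \code{configEcho} records the schedule and the
#'   per-level sigmas actually used.
#' @export
hierarchicalReconstruct <- function(sino, params, config = solverConfig(),
                                    schedule = levelSchedule(),
                                    kernel = spreadingKernel(),
                                    sigmaScale = NULL) {
  validObject(schedule)
  nLev <- length(schedule@factors)
  if (is.null(sigmaScale)) sigmaScale <- rep(1, nLev)
  stopifnot(length(sigmaScale) == nLev)
  n <- sino@geometry@numColumns
  if (any(n %% schedule@factors != 0L))
    stop("detector width must be divisible by every schedule factor")

  traces <- list(); dtraces <- list()
  prev <- NULL; prevFactor <- NULL
  res <- NULL
  sigmasUsed <- numeric(nLev)
  for (l in seq_len(nLev)) {
    f <- schedule@factors[l]
    sl <- downsampleSinogram(sino, f)
    if (f > 1L) sl@data <- sl@data / f     # coarse-pixel path-length units
    plan <- operatorPlan(sl@geometry, kernel)
    sigmasUsed[l] <- params@sigma * sigmaScale[l]
    pl <- qggmrfParams(sigma = sigmasUsed[l], p = params@p, c = params@c)
    cfg <- solverConfig(maxIterations = schedule@iterations[l],
                        stepSize = if (is.na(config@stepSize)) "auto"
                                   else config@stepSize,
                        restart = config@restart, monotone = config@monotone,
                        accelerate = config@accelerate,
                        stopTolerance = config@stopTolerance,
                        seed = config@seed)
    init <- if (is.null(prev)) NULL else upsampleVolume(prev, prevFactor %/% f)
    res <- solveMBIR(sl, plan, pl, cfg, init = init)
    traces[[l]] <- res@objectiveTrace
    dtraces[[l]] <- res@dataTermTrace
    prev <- res@volume
    prevFactor <- f
  }
  echo <- res@configEcho
  echo$hierarchical <- TRUE
  echo$schedule <- toConfig(schedule)
  echo$sigmaPerLevel <- sigmasUsed
  new("ReconResult", volume = res@volume,
      objectiveTrace = unlist(traces), dataTermTrace = unlist(dtraces),
      iterationsRun = length(unlist(traces)), configEcho = echo)
}
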