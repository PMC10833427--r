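#' Sparse-angle foam benchmark: FBP versus MBIR
#'
#' The package's reference evaluation protocol on synthetic foam data. For
#' each seed: generate a foam phantom (attenuation per voxel
#' \code{6/gridSide}, so the peak optical depth is around 3-4, a typical
#' synchrotron transmission of a few percent), simulate a noisy
#' Beer-Lambert acquisition over half a turn with a 16:1
#' detector-column-to-view undersampling ratio (128 views at the full
#' 2048-column scale; 32 views at the 512-column desk scale, preserving
#' the sparse-view regime the protocol probes), then reconstruct with
#' (a) FBP under a Butterworth filter (order 2, cutoff 0.25) and
#' (b) MBIR (p = 1.2, c = 1e-4) for \code{iterations} iterations with
#' sigma selected by a sweep on a single slice of the first seed's data.
#' Both reconstructions are scored by affine-matched relative RMSE against
#' the phantom inside the inscribed circle. The sigma grid spans
#' \code{materialDensity * c(0.25, 0.5, 1, 2, 4)} (the phantom's only
#' intensity step is \code{materialDensity}); sigma is chosen to minimize
#' the sweep slice's rRMSE against the known ground truth.
#'
#' @param seeds integer vector of study seeds.
#' @param gridSide detector width / grid side (default 512).
#' @param numSlices slices per volume (default 4).
#' @param numAngles projections over pi (default \code{gridSide/16}: the
#'   sparse-angle regime, proportionally scaled).
#' @param flux incident photons per pixel (default 1e4).
#' @param iterations MBIR iteration budget (default 100).
#' @param sweepSigmas sigma grid for the selection sweep.
#' @param sweepIterations iteration budget per sweep point.
#' @param tolerance NUFFT accuracy.
#' @param verbose print progress messages.
#' @return data.frame with one row per seed: \code{seed}, \code{fbpRrmse},
#'   \code{mbirRrmse}, \code{sigma}; the chosen sigma and the sweep table
#'   are attached as attributes.
#' @export
foamStudy <- function(seeds = 1:3, gridSide = 512L, numSlices = 4L,
                      numAngles = as.integer(round(gridSide / 16)),
                      flux = 1e4, iterations = 100L,
                      sweepSigmas = NULL, sweepIterations = 60L,
                      tolerance = 1e-6, verbose = interactive()) {
  density <- 6 / gridSide
  if (is.null(sweepSigmas)) sweepSigmas <- density * c(0.25, 0.5, 1, 2, 4)
  kern <- spreadingKernel(tolerance)
  mask <- circularMask(gridSide)
  say <- function(...) if (verbose) message(sprintf(...))

  sigmaStar <- NA_real_
  sweepTable <- NULL
  rows <- list()
  for (i in seq_along(seeds)) {
    sd <- as.integer(seeds[i])
    spec <- foamSpec(gridSide, numSlices, materialDensity = density,
                     seed = sd)
    vol <- makeFoam(spec)
    acq <- acquisitionSpec(numAngles, angleSpan = pi, flux = flux,
                           poissonNoise = TRUE, seed = sd + 500000L)
    sim <- simulateAcquisition(vol, acq)
    b <- beerLambert(sim$intensity, sim$flat, geom = sim$clean@geometry)
    plan <- operatorPlan(b@geometry, kern)

    fbpVol <- fbpReconstruct(b, filter = filterSpec("butterworth", 2, 0.25),
                             kernel = kern)
    fbpErr <- relativeRmse(vol, fbpVol, mask)
    say("seed %d: FBP rRMSE %.4f", sd, fbpErr)

    if (is.na(sigmaStar)) {
      sub <- subsetSlices(b, 1L)
      subPlan <- operatorPlan(sub@geometry, kern)
      cfg <- solverConfig(maxIterations = sweepIterations, seed = sd)
      sw <- sweepSigma(sub, subPlan, sweepSigmas, qggmrfParams(1), cfg)
      refSlice <- tomoVolume(vol@data[1L, , , drop = FALSE])
      errs <- vapply(sw, function(r)
        relativeRmse(refSlice, r$result@volume, mask), numeric(1))
      sweepTable <- data.frame(sigma = sweepSigmas, rrmse = errs)
      sigmaStar <- sweepSigmas[which.min(errs)]
      say("sigma sweep: %s -> sigma* = %g",
          paste(sprintf("%.4g:%.3f", sweepSigmas, errs), collapse = " "),
          sigmaStar)
    }

    cfg <- solverConfig(maxIterations = iterations, seed = sd)
    res <- solveMBIR(b, plan, qggmrfParams(sigma = sigmaStar), cfg)
    mbirErr <- relativeRmse(vol, res@volume, mask)
    say("seed %d: MBIR rRMSE %.4f (sigma %g)", sd, mbirErr, sigmaStar)
    rows[[i]] <- data.frame(seed = sd, fbpRrmse = fbpErr,
                            mbirRrmse = mbirErr, sigma = sigmaStar)
  }
  out <- do.call(rbind, rows)
  attr(out, "sweep") <- sweepTable
  out
}
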