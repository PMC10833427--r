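#' Foam phantom specification
#'
#' Defaults describe a foam-like specimen: a cylinder filling 90% of the
#' field of view densely packed with non-overlapping spherical voids
#' (about \code{gridSide^2/400} requested, log-uniform radii between 0.4%
#' and 4% of the grid side, floored at sub-pixel scale), giving the
#' polydisperse bubble texture of real foams; the rejection sampler
#' saturates near its packing limit so the realized void count is
#' typically below the request.
#'
#' @param gridSide per-slice grid side in pixels.
#' @param numSlices number of slices.
#' @param voidCount target number of voids (fewer may be placed when the
#'   rejection sampler saturates).
#' @param radiusRange (min, max) void radius in pixels.
#' @param materialDensity attenuation of the bulk material per voxel.
#' @param seed integer seed.
#' @return a \linkS4class{FoamSpec}.
#' @export
foamSpec <- function(gridSide, numSlices = 1L,
                     voidCount = round(gridSide^2 / 400),
                     radiusRange = pmax(c(0.004, 0.04) * gridSide,
                                        c(0.75, 1.5)),
                     materialDensity = 1, seed = 1L) {
  new("FoamSpec", gridSide = as.integer(gridSide),
      numSlices = as.integer(numSlices), voidCount = as.integer(voidCount),
      radiusRange = as.numeric(radiusRange),
      materialDensity = as.numeric(materialDensity), seed = as.integer(seed))
}

#' Generate a foam phantom
#'
#' A uniform cylinder (radius 0.45 x gridSide) of \code{materialDensity},
#' minus non-overlapping spherical voids of density zero. Void centers are
#' uniform in the cylinder (z uniform across the slab), radii log-uniform
#' in \code{radiusRange}; each void must fit inside the cylinder
#' cross-section and not intersect previously placed voids (rejection
#' sampling, at most 1e4 attempts per void; fewer voids than requested is
#' allowed and reported via a message and the \code{"voids"} attribute).
#' Deterministic given the seed.
#'
#' @param spec a \linkS4class{FoamSpec}.
#' @return a \linkS4class{Volume} with a \code{"voids"} attribute (matrix
#'   of placed void centers and radii).
#' @export
makeFoam <- function(spec) {
  n <- spec@gridSide
  ns <- spec@numSlices
  cc <- (n - 1) / 2
  rcyl <- 0.45 * n
  voids <- .withSeed(spec@seed, {
    placed <- matrix(0, 0, 4, dimnames = list(NULL, c("z", "y", "x", "r")))
    for (v in seq_len(spec@voidCount)) {
      for (att in seq_len(10000L)) {
        r <- exp(stats::runif(1, log(spec@radiusRange[1L]),
                              log(spec@radiusRange[2L])))
        rad <- sqrt(stats::runif(1)) * rcyl
        ang <- stats::runif(1, 0, 2 * pi)
        cx <- cc + rad * cos(ang)
        cy <- cc + rad * sin(ang)
        cz <- stats::runif(1, 0, ns - 1)
        if (sqrt((cx - cc)^2 + (cy - cc)^2) + r > rcyl) next
        if (nrow(placed) > 0) {
          dd <- sqrt((placed[, "z"] - cz)^2 + (placed[, "y"] - cy)^2 +
                       (placed[, "x"] - cx)^2)
          if (any(dd <= placed[, "r"] + r)) next
        }
        placed <- rbind(placed, c(cz, cy, cx, r))
        break
      }
    }
    placed
  })
  if (nrow(voids) < spec@voidCount)
    message(sprintf("makeFoam: placed %d of %d requested voids",
                    nrow(voids), spec@voidCount))

  xs <- 0:(n - 1)
  diskSq <- outer((xs - cc)^2, (xs - cc)^2, "+")    # [y, x]
  slice <- spec@materialDensity * (diskSq <= rcyl^2)
  vol <- array(0, c(ns, n, n))
  for (s in seq_len(ns)) vol[s, , ] <- slice
  for (v in seq_len(nrow(voids))) {
    cz <- voids[v, "z"]; cy <- voids[v, "y"]; cx <- voids[v, "x"]
    r <- voids[v, "r"]
    zi <- max(0, ceiling(cz - r)):min(ns - 1, floor(cz + r))
    yi <- max(0, ceiling(cy - r)):min(n - 1, floor(cy + r))
    xi <- max(0, ceiling(cx - r)):min(n - 1, floor(cx + r))
    for (z in zi) {
      rz2 <- r^2 - (z - cz)^2
      if (rz2 <= 0) next
      m <- outer((yi - cy)^2, (xi - cx)^2, "+") <= rz2
      blk <- vol[z + 1L, yi + 1L, xi + 1L]
      blk[m] <- 0
      vol[z + 1L, yi + 1L, xi + 1L] <- blk
    }
  }
  out <- tomoVolume(vol)
  attr(out, "voids") <- voids
  out
}

# Toft's modified Shepp-Logan ellipse table:
# intensity, semi-axis a (x), semi-axis b (y), x0, y0, angle (deg)
.sheppLoganTable <- matrix(c(
   1.00, 0.6900, 0.9200,  0.00,  0.0000,   0,
  -0.80, 0.6624, 0.8740,  0.00, -0.0184,   0,
  -0.20, 0.1100, 0.3100,  0.22,  0.0000, -18,
  -0.20, 0.1600, 0.4100, -0.22,  0.0000,  18,
   0.10, 0.2100, 0.2500,  0.00,  0.3500,   0,
   0.10, 0.0460, 0.0460,  0.00,  0.1000,   0,
   0.10, 0.0460, 0.0460,  0.00, -0.1000,   0,
   0.10, 0.0460, 0.0230, -0.08, -0.6050,   0,
   0.10, 0.0230, 0.0230,  0.00, -0.6060,   0,
   0.10, 0.0230, 0.0460,  0.06, -0.6050,   0), ncol = 6, byrow = TRUE)

#' Standard Shepp-Logan head phantom
#'
#' The 10-ellipse modified (contrast-enhanced) Shepp-Logan slice with
#' values in [0, 1] and exact zeros outside the skull ellipse.
#'
#' @param gridSide grid side in pixels (>= 16).
#' @return a single-slice \linkS4class{Volume}.
#' @export
makeSheppLogan <- function(gridSide) {
  n <- as.integer(gridSide)
  if (n < 16L) stop("gridSide must be >= 16")
  cc <- (n - 1) / 2
  u <- ((0:(n - 1)) - cc) / (n / 2)
  x <- matrix(u, n, n, byrow = TRUE)     # [y, x]
  y <- matrix(-u, n, n)                  # standard orientation: +y superior
  img <- matrix(0, n, n)
  for (e in seq_len(nrow(.sheppLoganTable))) {
    a <- .sheppLoganTable[e, ]
    phi <- a[6L] * pi / 180
    xr <- cos(phi) * (x - a[4L]) + sin(phi) * (y - a[5L])
    yr <- -sin(phi) * (x - a[4L]) + cos(phi) * (y - a[5L])
    img <- img + a[1L] * ((xr / a[2L])^2 + (yr / a[3L])^2 <= 1)
  }
  tomoVolume(pmax(img, 0))               # clear 1e-16 float residue
}

#' Acquisition specification constructor
#'
#' @param numAngles number of projections over the span.
#' @param angleSpan \code{pi} (half turn, default) or \code{2*pi}.
#' @param flux mean incident photons per detector pixel (I0).
#' @param poissonNoise sample Poisson counting noise.
#' @param centerOffset rotation-axis offset in pixels applied to the
#'   simulated data.
#' @param seed integer seed for the noise.
#' @return an \linkS4class{AcquisitionSpec}.
#' @export
acquisitionSpec <- function(numAngles, angleSpan = pi, flux = 1e4,
                            poissonNoise = TRUE, centerOffset = 0,
                            seed = 1L) {
  new("AcquisitionSpec", numAngles = as.integer(numAngles),
      angleSpan = as.numeric(angleSpan), flux = as.numeric(flux),
      poissonNoise = isTRUE(poissonNoise),
      centerOffset = as.numeric(centerOffset), seed = as.integer(seed))
}

# Poisson sampling robust to very large rates (normal approximation above
# 1e8 where rpois would overflow integer storage)
.rpoisLarge <- function(lambda) {
  out <- numeric(length(lambda))
  big <- lambda > 1e8
  if (any(!big)) out[!big] <- stats::rpois(sum(!big), lambda[!big])
  if (any(big))
    out[big] <- round(lambda[big] + sqrt(lambda[big]) * stats::rnorm(sum(big)))
  out
}

#' Simulate a Beer-Lambert acquisition
#'
#' Forward-projects the phantom, applies the rotation-center offset as a
#' sub-pixel Fourier shift of the clean sinogram, converts to transmitted
#' intensity \eqn{I = I_0 e^{-b}} and optionally samples Poisson counting
#' noise. Attenuations so large that \eqn{e^{-b}} underflows are clamped
#' with a warning.
#'
#' @param volume the phantom \linkS4class{Volume}.
#' @param acq an \linkS4class{AcquisitionSpec}.
#' @param plan optional \linkS4class{OperatorPlan} for the zero-offset
#'   geometry (built automatically when omitted).
#' @return list with \code{intensity} (array [angle, slice, column]),
#'   \code{flat} (same shape, constant I0), \code{clean} (the noise-free
#'   attenuation \linkS4class{Sinogram}, offset applied, whose geometry
#'   records the simulated \code{centerOffset}).
#' @export
simulateAcquisition <- function(volume, acq, plan = NULL) {
  n <- gridSide(volume)
  th <- acq@angleSpan * (0:(acq@numAngles - 1L)) / acq@numAngles
  geom <- scanGeometry(th, n, numSlices(volume), centerOffset = 0,
                       pixelSize = volume@voxelSize)
  if (is.null(plan)) plan <- operatorPlan(geom)
  clean <- forwardProject(volume, plan)
  if (acq@centerOffset != 0)
    clean <- centerCorrect(clean, -acq@centerOffset)
  else
    clean@geometry <- geom
  b <- clean@data
  trans <- exp(-b)
  if (any(trans == 0)) {
    warning("attenuation so large that exp(-b) underflows; clamping")
    trans[trans == 0] <- .Machine$double.xmin
  }
  lambda <- acq@flux * trans
  intensity <- if (acq@poissonNoise)
    array(.withSeed(acq@seed, .rpoisLarge(lambda)), dim(lambda))
  else lambda
  flat <- array(acq@flux, dim(lambda))
  list(intensity = intensity, flat = flat, clean = clean)
}
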