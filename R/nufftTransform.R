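#' Spreading width for a target NUFFT accuracy
#'
#' Returns the per-dimension kernel support \code{w} (in fine-grid points)
#' used to reach relative accuracy \code{tolerance} with the
#' exponential-of-semicircle kernel at 2x oversampling. The width is
#' monotone non-increasing in the tolerance.
#'
#' @param tolerance target accuracy, in \code{[1e-14, 1e-1]}.
#' @return integer kernel width.
#' @examples
#' kernelWidth(1e-6)
#' @export
kernelWidth <- function(tolerance) {
  if (!is.finite(tolerance) || tolerance < 1e-14 || tolerance > 1e-1)
    stop("tolerance must lie in [1e-14, 1e-1]")
  max(2L, as.integer(ceiling(log10(1 / tolerance))) + 1L)
}

#' Spreading kernel constructor
#'
#' @param tolerance target NUFFT accuracy epsilon.
#' @param oversampling fine-grid upsampling factor (default 2).
#' @param width kernel support per dimension; default derived from
#'   \code{tolerance} via \code{\link{kernelWidth}}.
#' @param family kernel identifier (only \code{"exp-semicircle"}).
#' @return a \linkS4class{SpreadingKernel}.
#' @export
spreadingKernel <- function(tolerance = 1e-6, oversampling = 2,
                            width = kernelWidth(tolerance),
                            family = "exp-semicircle") {
  if (!identical(family, "exp-semicircle"))
    stop("unsupported kernel family: ", family)
  new("SpreadingKernel", family = family, tolerance = as.numeric(tolerance),
      width = as.integer(width), oversampling = as.numeric(oversampling))
}

# Kernel shape parameter; 2.30 * w is the standard choice at 2x oversampling.
.kernelBeta <- function(width) 2.30 * width

# Continuous Fourier transform of the spreading kernel,
#   phihat(nu) = int_{-w/2}^{w/2} phi(s) exp(-2i pi nu s) ds,
# via the substitution s = (w/2) sin(u), which removes the square-root
# endpoint behavior; 80-node Gauss-Legendre is then exact to machine
# precision for all |nu| <= 0.5.
.kernelFourier <- function(nu, width, beta) {
  gl <- pracma::gaussLegendre(80L, 0, pi / 2)
  halfw <- width / 2
  cu <- cos(gl$x)
  su <- sin(gl$x)
  fu <- exp(beta * (cu - 1)) * cu          # phi((w/2) sin u) * cos(u)
  # out(nu) = 2 * (w/2) * sum_k wk * fu_k * cos(2 pi nu (w/2) sin u_k)
  arg <- outer(2 * pi * nu * halfw, su)    # |nu| x nodes
  as.numeric(2 * halfw * (cos(arg) %*% (gl$w * fu)))
}

#' Build the polar frequency grid
#'
#' One radial line of 1-D DFT frequencies per projection angle:
#' \eqn{k_j = \omega_m (\cos\theta_i, \sin\theta_i)} with
#' \eqn{\omega_m = 2\pi m'/M_t} for signed DFT bins \eqn{m'}.
#'
#' @param geom a \linkS4class{ScanGeometry}.
#' @param radialCount radial samples per view, \code{>= numColumns}
#'   (default equal).
#' @return a \linkS4class{PolarFrequencyGrid}.
#' @export
buildPolarGrid <- function(geom, radialCount = geom@numColumns) {
  radialCount <- as.integer(radialCount)
  if (radialCount < 2L) stop("radialCount must be >= 2")
  if (radialCount < geom@numColumns)
    stop("radialCount must be >= numColumns")
  mm <- 0:(radialCount - 1L)
  mSigned <- as.integer(((mm + radialCount %/% 2L) %% radialCount) - radialCount %/% 2L)
  om <- 2 * pi * mSigned / radialCount
  th <- geom@angles
  kx <- as.numeric(outer(om, cos(th)))
  ky <- as.numeric(outer(om, sin(th)))
  new("PolarFrequencyGrid", points = cbind(kx, ky),
      radialCount = radialCount,
      totalCount = radialCount * length(th),
      angles = th, radialIndex = rep(mSigned, length(th)))
}

#' Build an operator plan
#'
#' Precomputes everything the NUFFT-based Radon transform and its adjoint
#' share: the polar grid, deapodization profile, fine-grid size and the
#' combined per-point phase (image half-pixel center, detector center and
#' rotation-center offset ramp).
#'
#' @param geom a \linkS4class{ScanGeometry}.
#' @param kernel a \linkS4class{SpreadingKernel}.
#' @param radialCount radial samples per view (default \code{numColumns}).
#' @return an \linkS4class{OperatorPlan}.
#' @export
operatorPlan <- function(geom, kernel = spreadingKernel(),
                         radialCount = geom@numColumns) {
  n <- geom@numColumns
  polar <- buildPolarGrid(geom, radialCount)
  mt <- polar@radialCount
  nf <- as.integer(2 * ceiling(kernel@oversampling * n / 2))
  w <- kernel@width
  beta <- .kernelBeta(w)
  s0 <- n %/% 2L
  deltaC <- (n - 1) / 2 - s0                       # -1/2 for even n, 0 for odd
  deapod <- .kernelFourier(((0:(n - 1)) - s0) / nf, w, beta)
  pad <- (mt - n) %/% 2L
  cDet <- pad + (n - 1) / 2
  om <- 2 * pi * polar@radialIndex / mt            # per polar point
  xi <- polar@points * nf / (2 * pi)
  phase <- exp(1i * (polar@points[, 1L] + polar@points[, 2L]) * deltaC) *
    exp(-1i * om * (cDet + geom@centerOffset))
  new("OperatorPlan", geometry = geom, kernel = kernel, polar = polar,
      deapodization = deapod, fineSize = nf, beta = beta,
      xiX = xi[, 1L], xiY = xi[, 2L], phase = phase,
      radialFreq = abs(polar@radialIndex) / mt, pad = as.integer(pad))
}

# integer grid shift used for the fine-grid embedding
.planShift <- function(plan) plan@geometry@numColumns %/% 2L

# Forward Radon transform of one slice. Input: n x n matrix [y, x].
# Output: numColumns x numAngles matrix [column, angle] of line integrals.
# filterWeights (per radial bin, length radialCount) is the FBP hook.
.forwardSlice <- function(img, plan, filterWeights = NULL) {
  mt <- plan@polar@radialCount
  nA <- length(plan@geometry@angles)
  n <- plan@geometry@numColumns
  vals <- cpp_nufft_type2(img, plan@deapodization, plan@xiX, plan@xiY,
                          plan@fineSize, plan@kernel@width, plan@beta,
                          .planShift(plan))
  ghat <- matrix(vals * plan@phase, nrow = mt, ncol = nA)
  if (!is.null(filterWeights)) ghat <- ghat * filterWeights
  p <- Re(mvfft(ghat, inverse = TRUE)) / mt
  p[plan@pad + seq_len(n), , drop = FALSE]
}

# Exact adjoint of .forwardSlice. Input: numColumns x numAngles matrix
# [column, angle]; output: n x n image. No |k| weighting: this is the
# unfiltered adjoint R^dagger.
.adjointSlice <- function(det, plan, filterWeights = NULL) {
  mt <- plan@polar@radialCount
  n <- plan@geometry@numColumns
  nA <- length(plan@geometry@angles)
  full <- matrix(0, nrow = mt, ncol = nA)
  full[plan@pad + seq_len(n), ] <- det
  ghat <- mvfft(matrix(as.complex(full), mt, nA)) / mt
  if (!is.null(filterWeights)) ghat <- ghat * filterWeights
  coef <- as.vector(ghat) * Conj(plan@phase)
  cpp_nufft_type1(coef, plan@deapodization, plan@xiX, plan@xiY,
                  n, plan@fineSize, plan@kernel@width, plan@beta,
                  .planShift(plan))
}

# slice-by-slice application on raw arrays (internal fast path)
.forwardArray <- function(vol, plan) {
  g <- plan@geometry
  nA <- length(g@angles)
  ns <- dim(vol)[1L]
  n <- g@numColumns
  out <- array(0, c(nA, ns, n))
  for (s in seq_len(ns)) {
    p <- .forwardSlice(matrix(vol[s, , ], n, n), plan)   # [column, angle]
    out[, s, ] <- t(p)
  }
  out
}

.adjointArray <- function(sino, plan, filterWeights = NULL) {
  g <- plan@geometry
  ns <- dim(sino)[2L]
  n <- g@numColumns
  out <- array(0, c(ns, n, n))
  for (s in seq_len(ns))
    out[s, , ] <- .adjointSlice(t(matrix(sino[, s, ], dim(sino)[1L], n)),
                                plan, filterWeights)
  out
}

#' Forward Radon transform via NUFFT
#'
#' Per slice: deapodize, oversampled 2-D FFT, kernel interpolation onto the
#' polar frequency grid (the central slice theorem), per-view inverse 1-D
#' FFT along each radial line with the rotation-center phase ramp applied.
#' Output values are line integrals in pixel units.
#'
#' @param volume a \linkS4class{Volume}.
#' @param plan an \linkS4class{OperatorPlan}.
#' @return a \linkS4class{Sinogram}.
#' @export
setGeneric("forwardProject", function(volume, plan) standardGeneric("forwardProject"))

#' @rdname forwardProject
setMethod("forwardProject", signature("Volume", "OperatorPlan"),
  function(volume, plan) {
    b <- sinogram(array(0, c(length(plan@geometry@angles),
                             plan@geometry@numSlices,
                             plan@geometry@numColumns)), plan@geometry)
    validatePair(b, volume)
    if (!all(is.finite(volume@data))) stop("non-finite volume input")
    b@data <- .forwardArray(volume@data, plan)
    b
  })

#' Adjoint back-projection via NUFFT
#'
#' The exact adjoint of \code{\link{forwardProject}}: per-view 1-D FFT along
#' detector rows, undo the rotation-center phase ramp, spread the polar
#' coefficients onto the oversampled Cartesian frequency grid with the same
#' kernel, inverse 2-D FFT and deapodize. No \eqn{|k|} density weighting is
#' applied (unfiltered adjoint \eqn{R^\dagger}).
#'
#' @param sino a \linkS4class{Sinogram}.
#' @param plan an \linkS4class{OperatorPlan}.
#' @return a \linkS4class{Volume}.
#' @export
setGeneric("backProject", function(sino, plan) standardGeneric("backProject"))

#' @rdname backProject
setMethod("backProject", signature("Sinogram", "OperatorPlan"),
  function(sino, plan) {
    if (!identical(dim(sino@data)[c(1L, 3L)],
                   c(length(plan@geometry@angles), plan@geometry@numColumns)))
      stop("shape mismatch: sinogram does not match plan geometry")
    if (!all(is.finite(sino@data))) stop("non-finite sinogram input")
    tomoVolume(.adjointArray(sino@data, plan),
               voxelSize = plan@geometry@pixelSize)
  })

# residual half-pixel center phase (polar-point-wise); with it, grid
# coordinates are centered on pixel (n-1)/2 exactly
.centerPhase <- function(plan) {
  n <- plan@geometry@numColumns
  deltaC <- (n - 1) / 2 - n %/% 2L
  exp(1i * (plan@polar@points[, 1L] + plan@polar@points[, 2L]) * deltaC)
}

# uniform image -> polar coefficients: Sum_u f[u] exp(-i k . (u - c)),
# c = (n-1)/2 per axis (kernel-accurate NUFFT evaluation)
.nufftGridToPolar <- function(img, plan) {
  cpp_nufft_type2(img, plan@deapodization, plan@xiX, plan@xiY,
                  plan@fineSize, plan@kernel@width, plan@beta,
                  .planShift(plan)) * .centerPhase(plan)
}

# polar coefficients -> uniform image (real part):
# Re Sum_j c_j exp(+i k_j . (u - c)); exact adjoint of .nufftGridToPolar
.nufftPolarToGrid <- function(coef, plan) {
  cpp_nufft_type1(coef * Conj(.centerPhase(plan)), plan@deapodization,
                  plan@xiX, plan@xiY, plan@geometry@numColumns,
                  plan@fineSize, plan@kernel@width, plan@beta,
                  .planShift(plan))
}
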