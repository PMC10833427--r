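#' Partition-of-unity neighbor weights for the 26-neighbor prior
#'
#' The 26 offsets of the 1-hop 3-D neighborhood with weights inversely
#' proportional to the Euclidean offset length, normalized to sum to one
#' (6 face, 12 edge and 8 corner neighbors).
#'
#' @return list with \code{offsets} (26 x 3 integer matrix of (dz, dy, dx))
#'   and \code{weights} (numeric, sums to 1).
#' @examples
#' w <- neighborWeights()
#' sum(w$weights)
#' @export
neighborWeights <- function() {
  off <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  d <- sqrt(rowSums(off^2))
  w <- (1 / d) / sum(1 / d)
  list(offsets = unname(off), weights = as.numeric(w))
}

#' qGGMRF parameter constructor
#'
#' @param sigma regularization scale (same units as voxel values).
#' @param p shape exponent in [1, 2); default 1.2.
#' @param c transition constant; default 1e-4.
#' @return a \linkS4class{QGGMRFParams}.
#' @export
qggmrfParams <- function(sigma, p = 1.2, c = 1e-4) {
  nw <- neighborWeights()
  new("QGGMRFParams", p = as.numeric(p), c = as.numeric(c),
      sigma = as.numeric(sigma), q = 2,
      neighborhood = nw$offsets, weights = nw$weights)
}

#' qGGMRF potential function
#'
#' \eqn{\rho(\Delta) = |\Delta/\sigma|^2 / (c + |\Delta/\sigma|^{2-p})}:
#' quadratic (scaled by \eqn{1/c}) for differences far below \eqn{\sigma},
#' growing like \eqn{|\Delta/\sigma|^p} for large differences, hence
#' edge-preserving. Even, zero at zero, strictly increasing in
#' \eqn{|\Delta|}.
#'
#' @param delta density difference(s).
#' @param params a \linkS4class{QGGMRFParams}.
#' @return penalty value(s).
#' @export
qggmrfPotential <- function(delta, params) {
  a <- abs(delta / params@sigma)
  a^2 / (params@c + a^(2 - params@p))
}

#' Derivative of the qGGMRF potential
#'
#' @inheritParams qggmrfPotential
#' @return \eqn{d\rho/d\Delta}, same length as \code{delta}.
#' @export
qggmrfPotentialDeriv <- function(delta, params) {
  a <- abs(delta / params@sigma)
  t <- a^(2 - params@p)
  delta / params@sigma^2 * (2 * params@c + params@p * t) / (params@c + t)^2
}

.asVolumeArray <- function(volume) {
  if (is(volume, "Volume")) volume@data else volume
}

#' qGGMRF prior value of a volume
#'
#' Sum over all ordered voxel pairs within the 26-neighbor neighborhood of
#' \eqn{w_{mn}\,\rho(f_m - f_n)}. Out-of-range neighbors are skipped
#' (no wrap, no reflection) and weights are not renormalized at boundaries;
#' single-slice volumes therefore degrade gracefully to the 8-neighbor
#' 2-D prior.
#'
#' @param volume a \linkS4class{Volume} or 3-D array.
#' @param params a \linkS4class{QGGMRFParams}.
#' @return scalar penalty value.
#' @export
priorValue <- function(volume, params) {
  f <- .asVolumeArray(volume)
  cpp_qggmrf_eval(f, params@sigma, params@p, params@c, FALSE)$value
}

#' Gradient of the qGGMRF prior
#'
#' Analytic gradient of \code{\link{priorValue}}; the gradient of any
#' constant volume is identically zero, and the gradient depends only on
#' voxel differences.
#'
#' @param volume a \linkS4class{Volume} or 3-D array.
#' @param params a \linkS4class{QGGMRFParams}.
#' @param accumulate optional array of the same shape; when given, the
#'   gradient is added to it (in-place accumulation semantics).
#' @return 3-D array: the gradient (plus \code{accumulate} when supplied).
#' @export
priorGradient <- function(volume, params, accumulate = NULL) {
  f <- .asVolumeArray(volume)
  g <- cpp_qggmrf_eval(f, params@sigma, params@p, params@c, TRUE)$gradient
  if (!is.null(accumulate)) {
    if (!identical(dim(accumulate), dim(f)))
      stop("shape mismatch: accumulate must match the volume shape")
    g <- accumulate + g
  }
  g
}
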