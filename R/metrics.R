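.metricArray <- function(x) if (is(x, "Volume")) x@data else as.array(x)

#' Inscribed circular mask
#'
#' Logical per-slice mask selecting the circle inscribed in the square
#' grid, the region inside which experimental reconstructions are
#' compared.
#'
#' @param gridSide grid side in pixels.
#' @param radius mask radius in pixels (default: inscribed circle).
#' @return logical \code{gridSide x gridSide} matrix.
#' @export
circularMask <- function(gridSide, radius = (gridSide - 1) / 2) {
  cc <- (gridSide - 1) / 2
  u <- (0:(gridSide - 1)) - cc
  outer(u^2, u^2, "+") <= radius^2
}

# expand a per-slice mask (or NULL) to the full index set of an array
.maskIndex <- function(arr, mask) {
  if (is.null(mask)) return(rep(TRUE, length(arr)))
  ns <- dim(arr)[1L]
  as.vector(aperm(array(mask, c(dim(arr)[2L], dim(arr)[3L], ns)),
                  c(3L, 1L, 2L)))
}

#' Least-squares affine intensity match
#'
#' Closed-form scale and shift minimizing \eqn{\|s B + \Delta - A\|_2^2}:
#' \eqn{s = \mathrm{cov}(B, A) / \mathrm{var}(B)},
#' \eqn{\Delta = \bar A - s \bar B}.
#'
#' @param reference reference volume/array A.
#' @param candidate candidate volume/array B (must be non-constant).
#' @param mask optional per-slice logical mask restricting the comparison
#'   region (e.g. \code{\link{circularMask}}).
#' @return an \linkS4class{AffineMatch}.
#' @export
affineMatch <- function(reference, candidate, mask = NULL) {
  a <- .metricArray(reference); b <- .metricArray(candidate)
  stopifnot(identical(dim(a), dim(b)))
  idx <- .maskIndex(a, mask)
  av <- a[idx]; bv <- b[idx]
  vb <- stats::var(bv)
  if (!is.finite(vb) || vb == 0)
    stop("candidate is constant: affine scale undefined")
  s <- stats::cov(bv, av) / vb
  affineMatchValues(s, mean(av) - s * mean(bv))
}

#' Affine-matched relative root-mean-square error
#'
#' \eqn{\|s B + \Delta - A\|_2 / \|A\|_2} with \eqn{(s, \Delta)} from
#' \code{\link{affineMatch}}; zero iff the candidate is an exact affine
#' rescaling of the reference.
#'
#' @inheritParams affineMatch
#' @return scalar rRMSE.
#' @export
relativeRmse <- function(reference, candidate, mask = NULL) {
  a <- .metricArray(reference); b <- .metricArray(candidate)
  stopifnot(identical(dim(a), dim(b)))
  idx <- .maskIndex(a, mask)
  av <- a[idx]; bv <- b[idx]
  na <- sqrt(sum(av^2))
  if (na == 0) stop("reference has zero norm")
  m <- affineMatch(reference, candidate, mask)
  sqrt(sum((m@scale * bv + m@shift - av)^2)) / na
}

#' Extract a line profile
#'
#' The 1-D intensity sequence along a row of one slice, optionally affine
#' matched to the corresponding profile of a reference volume.
#'
#' @param volume a \linkS4class{Volume} or array.
#' @param sliceIndex 1-based slice index.
#' @param rowIndex 1-based row (y) index.
#' @param columnRange 1-based column indices (may be empty).
#' @param reference optional reference volume; when given, the profile is
#'   affine matched to the reference's profile at the same location.
#' @return numeric vector of intensities.
#' @export
lineProfile <- function(volume, sliceIndex, rowIndex, columnRange,
                        reference = NULL) {
  v <- .metricArray(volume)
  d <- dim(v)
  if (length(columnRange) == 0L) return(numeric(0))
  if (sliceIndex < 1L || sliceIndex > d[1L] ||
      rowIndex < 1L || rowIndex > d[2L] ||
      any(columnRange < 1L) || any(columnRange > d[3L]))
    stop("profile indices out of range")
  prof <- v[sliceIndex, rowIndex, columnRange]
  if (!is.null(reference)) {
    rp <- .metricArray(reference)[sliceIndex, rowIndex, columnRange]
    m <- affineMatch(rp, prof)
    prof <- m@scale * prof + m@shift
  }
  as.numeric(prof)
}
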