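# Brute-force reference implementations, independent of the NUFFT code path.

# bilinear sample of a matrix at fractional (x, y) pixel coordinates,
# zero outside the grid
.bilinearSample <- function(img, x, y) {
  n <- nrow(img)
  ix <- floor(x); iy <- floor(y)
  fx <- x - ix; fy <- y - iy
  out <- numeric(length(x))
  for (dx in 0:1) {
    for (dy in 0:1) {
      jx <- ix + dx; jy <- iy + dy
      wgt <- (if (dx == 0) 1 - fx else fx) * (if (dy == 0) 1 - fy else fy)
      ok <- jx >= 0 & jx <= n - 1 & jy >= 0 & jy <= n - 1 & wgt > 0
      if (any(ok))
        out[ok] <- out[ok] + wgt[ok] * img[cbind(jy[ok] + 1L, jx[ok] + 1L)]
    }
  }
  out
}

#' Direct Radon transform by dense ray sampling
#'
#' Numerical line integrals by sampling each ray at \code{step}-pixel
#' intervals with pixel-center bilinear interpolation. Slow and entirely
#' independent of the NUFFT operators; intended as a test oracle on grids
#' of side <= 64.
#'
#' @param volume a \linkS4class{Volume} (grid side <= 64).
#' @param geom a \linkS4class{ScanGeometry}.
#' @param step ray sampling interval in pixels (<= 0.25).
#' @return a \linkS4class{Sinogram}.
#' @export
radonOracle <- function(volume, geom, step = 0.25) {
  n <- dim(volume@data)[2L]
  if (n > 64L) stop("radonOracle is a test oracle; grid side must be <= 64")
  if (step > 0.25) stop("step must be <= 0.25 pixel")
  stopifnot(n == geom@numColumns, dim(volume@data)[1L] == geom@numSlices)
  cc <- (n - 1) / 2
  tdet <- (0:(n - 1)) - cc - geom@centerOffset
  ell <- n / sqrt(2) + 2
  svals <- seq(-ell, ell, by = step)
  nA <- length(geom@angles)
  ns <- geom@numSlices
  out <- array(0, c(nA, ns, n))
  for (ia in seq_len(nA)) {
    th <- geom@angles[ia]
    xs <- outer(tdet, svals, function(t, s) t * cos(th) - s * sin(th)) + cc
    ys <- outer(tdet, svals, function(t, s) t * sin(th) + s * cos(th)) + cc
    for (s in seq_len(ns)) {
      v <- .bilinearSample(matrix(volume@data[s, , ], n, n),
                           as.vector(xs), as.vector(ys))
      out[ia, s, ] <- rowSums(matrix(v, nrow = n)) * step
    }
  }
  sinogram(out, geom)
}

#' Direct non-uniform DFT evaluation
#'
#' Evaluates the O(NM) sum \eqn{g(x) = \sum_j c_j \exp(i k_j \cdot x)} of
#' polar-grid Fourier coefficients at arbitrary Cartesian positions, as an
#' accuracy oracle for the NUFFT.
#'
#' @param coefficients complex coefficients, one per polar grid point.
#' @param polar a \linkS4class{PolarFrequencyGrid}.
#' @param positions numeric matrix (P x 2) of (x, y) positions in pixels
#'   (centered coordinates).
#' @return complex vector of length P.
#' @export
dftOracle <- function(coefficients, polar, positions) {
  if (length(coefficients) != polar@totalCount)
    stop("coefficients must match the polar grid size")
  np <- nrow(positions)
  if (as.double(np) * polar@totalCount > 1e7)
    stop("dftOracle guard exceeded: totalCount * positions must be <= 1e7")
  ph <- positions %*% t(polar@points)      # P x M
  as.vector(exp(1i * ph) %*% coefficients)
}

# centered pixel coordinates of an n x n grid, matching the operator
# convention (origin at pixel (n-1)/2)
.gridPositions <- function(n) {
  cc <- (n - 1) / 2
  u <- (0:(n - 1)) - cc
  cbind(x = rep(u, each = n), y = rep(u, times = n))   # [y fastest]
}
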