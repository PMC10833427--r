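#' Beer-Lambert conversion of raw intensities to attenuation
#'
#' \eqn{b = -\ln(I / I_0)} elementwise. Both inputs must be strictly
#' positive; the first offending index is named in the error.
#'
#' @param intensity raw counts \code{I} (array).
#' @param flat reference beam intensity \code{I0} (scalar or array
#'   broadcastable to \code{intensity}).
#' @param geom optional \linkS4class{ScanGeometry}; when given, a
#'   \linkS4class{Sinogram} is returned instead of a plain array.
#' @return attenuation line integrals (array or Sinogram).
#' @export
beerLambert <- function(intensity, flat, geom = NULL) {
  bad <- which(!(intensity > 0))
  if (length(bad))
    stop(sprintf("nonpositive intensity at index %d", bad[1L]))
  bad <- which(!(flat > 0))
  if (length(bad))
    stop(sprintf("nonpositive flat-field at index %d", bad[1L]))
  b <- -log(intensity / flat)
  if (is.null(geom)) b else sinogram(array(b, dim(intensity)), geom)
}

#' Rotation-center correction by Fourier shift
#'
#' Shifts every detector row so that the rotation axis, located at
#' \code{offset} pixels from the detector midpoint, moves to the midpoint:
#' output row values are the input sampled at \code{column + offset}
#' (circularly, via a linear phase ramp in the row's Fourier domain;
#' fractional offsets allowed). The small imaginary residue of the inverse
#' FFT is discarded; for fractional offsets this attenuates the (normally
#' negligible) Nyquist component by \eqn{\cos(\pi\,\mathrm{offset})}, the
#' standard behavior of a real-valued fractional delay. Integer offsets
#' are exact circular shifts.
#'
#' @param sino a \linkS4class{Sinogram}.
#' @param offset fractional pixels, \code{|offset| < numColumns/2}.
#' @return a \linkS4class{Sinogram} with \code{centerOffset} reduced by
#'   \code{offset}.
#' @export
centerCorrect <- function(sino, offset) {
  g <- sino@geometry
  n <- g@numColumns
  if (abs(offset) >= n / 2) stop("offset out of range: |offset| < numColumns/2")
  mSigned <- ((0:(n - 1) + n %/% 2L) %% n) - n %/% 2L
  ramp <- exp(2i * pi * mSigned * offset / n)
  d <- sino@data
  out <- array(0, dim(d))
  for (s in seq_len(dim(d)[2L])) {
    rows <- t(matrix(d[, s, ], dim(d)[1L], n))        # columns x angles
    sh <- Re(mvfft(mvfft(matrix(as.complex(rows), n)) * ramp,
                   inverse = TRUE)) / n
    out[, s, ] <- t(sh)
  }
  geomOut <- scanGeometry(g@angles, n, g@numSlices,
                          g@centerOffset - offset, g@pixelSize)
  sinogram(out, geomOut)
}

#' MBIR objective breakdown
#'
#' Data term \eqn{\frac12 \|Rf - b\|_2^2} plus the qGGMRF prior value.
#'
#' @param volume current estimate \code{f}.
#' @param sino projection data \code{b}.
#' @param plan an \linkS4class{OperatorPlan}.
#' @param params a \linkS4class{QGGMRFParams}.
#' @return an \linkS4class{ObjectiveBreakdown}.
#' @export
mbirObjective <- function(volume, sino, plan, params) {
  validatePair(sino, volume)
  r <- .forwardArray(volume@data, plan) - sino@data
  dt <- 0.5 * sum(r * r)
  pt <- priorValue(volume, params)
  new("ObjectiveBreakdown", dataTerm = dt, priorTerm = pt, total = dt + pt)
}

#' MBIR objective gradient
#'
#' \eqn{R^\dagger(Rf - b)} with the prior gradient accumulated into the
#' data-term gradient.
#'
#' @inheritParams mbirObjective
#' @return a \linkS4class{Volume} holding the gradient.
#' @export
mbirGradient <- function(volume, sino, plan, params) {
  validatePair(sino, volume)
  r <- .forwardArray(volume@data, plan) - sino@data
  g <- priorGradient(volume@data, params,
                     accumulate = .adjointArray(r, plan))
  tomoVolume(g, volume@voxelSize)
}

#' Step-size estimate from the operator norm
#'
#' Power iteration (20 iterations, seeded start, Rayleigh-quotient
#' estimate) for the largest eigenvalue \eqn{L} of \eqn{R^\dagger R} on one
#' slice; returns \eqn{0.9 / L}. Deterministic given the seed.
#'
#' @param plan an \linkS4class{OperatorPlan}.
#' @param seed integer.
#' @return positive scalar step size.
#' @export
estimateStep <- function(plan, seed = 1L) {
  n <- plan@geometry@numColumns
  v <- .withSeed(seed, matrix(stats::rnorm(n * n), n, n))
  lam <- 1
  for (k in 1:20) {
    u <- .adjointSlice(.forwardSlice(v, plan), plan)
    lam <- sum(v * u) / sum(v * v)
    v <- u / sqrt(sum(u * u))
  }
  0.9 / lam
}

# evaluate expr with a temporarily seeded RNG, restoring global state
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Model-based iterative reconstruction
#'
#' Minimizes \eqn{\frac12\|Rf - b\|_2^2 + h(f)} (qGGMRF prior \eqn{h}) by a
#' Nesterov-style accelerated gradient method with function-value restart
#' and a monotone safeguard: an accelerated candidate that raises the
#' objective is discarded and the momentum reset; a plain gradient step
#' that overshoots triggers backtracking (step halving on the current
#' gradient) within the iteration, so the objective trace is
#' non-increasing and the step adapts to the prior's local curvature.
#' Stops at \code{maxIterations} or when the relative objective change
#' falls below \code{stopTolerance}.
#'
#' @param sino projection data \code{b}.
#' @param plan an \linkS4class{OperatorPlan}.
#' @param params a \linkS4class{QGGMRFParams}.
#' @param config a \linkS4class{SolverConfig}.
#' @param init optional initial \linkS4class{Volume} (default: zeros).
#' @return a \linkS4class{ReconResult}.
#' @export
solveMBIR <- function(sino, plan, params, config = solverConfig(),
                      init = NULL) {
  g <- plan@geometry
  b <- sino@data
  if (is.null(init)) init <- zeroVolume(g)
  validatePair(sino, init)
  alpha <- config@stepSize
  if (is.na(alpha)) alpha <- estimateStep(plan, config@seed)

  x <- init@data
  fwdX <- .forwardArray(x, plan)
  dataX <- 0.5 * sum((fwdX - b)^2)
  fX <- dataX + priorValue(x, params)
  y <- x
  resY <- fwdX - b
  yIsX <- TRUE
  tmom <- 1
  trace <- numeric(config@maxIterations)
  dtrace <- numeric(config@maxIterations)
  iters <- 0L

  for (k in seq_len(config@maxIterations)) {
    grad <- priorGradient(y, params, accumulate = .adjointArray(resY, plan))
    xNew <- y - alpha * grad
    fwdNew <- .forwardArray(xNew, plan)
    dataNew <- 0.5 * sum((fwdNew - b)^2)
    fNew <- dataNew + priorValue(xNew, params)
    if (!is.finite(fNew))
      stop(sprintf("non-finite objective at iteration %d", k))

    rejected <- FALSE
    if (config@monotone && fNew > fX) {
      if (!yIsX) {
        # accelerated candidate rejected: reset momentum, keep the iterate
        y <- x
        resY <- fwdX - b
        yIsX <- TRUE
        tmom <- 1
        rejected <- TRUE
      } else {
        # plain step from x overshot: backtrack on the current gradient
        for (bt in 1:12) {
          alpha <- alpha / 2
          xNew <- x - alpha * grad
          fwdNew <- .forwardArray(xNew, plan)
          dataNew <- 0.5 * sum((fwdNew - b)^2)
          fNew <- dataNew + priorValue(xNew, params)
          if (fNew <= fX) break
        }
        rejected <- fNew > fX            # stuck at a stationary point
      }
    }

    if (!rejected) {
      if ((config@restart && fNew > fX) || !config@accelerate) {
        tmom <- 1
        y <- xNew
        resY <- fwdNew - b
        yIsX <- TRUE
      } else {
        tNew <- (1 + sqrt(1 + 4 * tmom^2)) / 2
        beta <- (tmom - 1) / tNew
        y <- xNew + beta * (xNew - x)
        resY <- (1 + beta) * fwdNew - beta * fwdX - b   # linearity of R
        tmom <- tNew
        yIsX <- beta == 0
      }
      x <- xNew
      fwdX <- fwdNew
      dataX <- dataNew
      fX <- fNew
    }
    trace[k] <- fX
    dtrace[k] <- dataX
    iters <- k
    if (config@stopTolerance > 0 && k > 1L &&
        abs(trace[k - 1L] - trace[k]) <=
          config@stopTolerance * max(abs(trace[k - 1L]), .Machine$double.eps))
      break
  }

  echo <- list(solver = c(toConfig(config), list(resolvedStep = alpha)),
               prior = toConfig(params))
  new("ReconResult", volume = tomoVolume(x, g@pixelSize),
      objectiveTrace = trace[seq_len(iters)],
      dataTermTrace = dtrace[seq_len(iters)],
      iterationsRun = iters, configEcho = echo)
}

#' Reconstruct over a spectrum of regularization strengths
#'
#' One reconstruction per sigma value with all other settings identical
#' (the hyper-parameter survey protocol, typically run on a small slice
#' subset of the data).
#'
#' @param sino projection data (usually restricted to one or a few slices).
#' @param plan an \linkS4class{OperatorPlan}.
#' @param sigmas numeric vector of positive sigma values.
#' @param baseParams a \linkS4class{QGGMRFParams}; only sigma is varied.
#' @param config a \linkS4class{SolverConfig}.
#' @return list of \code{list(sigma=, result=)} in input order.
#' @export
sweepSigma <- function(sino, plan, sigmas, baseParams,
                       config = solverConfig()) {
  stopifnot(all(sigmas > 0))
  lapply(sigmas, function(s) {
    pp <- qggmrfParams(sigma = s, p = baseParams@p, c = baseParams@c)
    list(sigma = s, result = solveMBIR(sino, plan, pp, config))
  })
}
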