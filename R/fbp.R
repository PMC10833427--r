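#' Filter specification for filtered back-projection
#'
#' @param name one of \code{"ram-lak"}, \code{"shepp-logan"},
#'   \code{"butterworth"}, \code{"none"}.
#' @param order Butterworth order (>= 1).
#' @param cutoff normalized cutoff frequency in (0, 0.5] on the
#'   Nyquist-normalized axis.
#' @return a \linkS4class{FilterSpec}.
#' @export
filterSpec <- function(name = "ram-lak", order = 2, cutoff = 0.25) {
  new("FilterSpec", name = as.character(name), order = as.numeric(order),
      cutoff = as.numeric(cutoff))
}

#' Frequency response of an FBP apodizing filter
#'
#' All |k|-weighted filters vanish at k = 0 (DC removal):
#' \describe{
#'   \item{ram-lak}{\eqn{|k|}}
#'   \item{shepp-logan}{\eqn{|k| \,\mathrm{sinc}(k / (2 \cdot 0.5))}}
#'   \item{butterworth}{\eqn{|k| / (1 + (k/\mathrm{cutoff})^{2\,\mathrm{order}})}}
#'   \item{none}{1}
#' }
#'
#' @param spec a \linkS4class{FilterSpec}.
#' @param frequencies normalized |k| values in [0, 0.5].
#' @return numeric weights, same length as \code{frequencies}.
#' @examples
#' filterResponse(filterSpec("butterworth", 2, 0.25), 0.25)  # 0.125
#' @export
filterResponse <- function(spec, frequencies) {
  if (any(frequencies < 0) || any(frequencies > 0.5))
    stop("frequencies must lie in [0, 0.5]")
  k <- frequencies
  switch(spec@name,
    "ram-lak" = k,
    "shepp-logan" = {
      x <- k / (2 * 0.5)
      s <- ifelse(x == 0, 1, sin(pi * x) / (pi * x))
      k * s
    },
    "butterworth" = k / (1 + (k / spec@cutoff)^(2 * spec@order)),
    "none" = rep(1, length(k)),
    stop(sprintf("unknown filter '%s'", spec@name)))
}

#' Filtered back-projection reconstruction
#'
#' Per slice: 1-D FFT of each projection along the detector, multiplication
#' by the filter response on the Nyquist-normalized radial axis, then the
#' NUFFT adjoint back-projection. The angular density factor
#' \eqn{\pi / n_\mathrm{angles}} is included so a densely sampled scan
#' recovers absolute density.
#'
#' Detector rows are zero-padded to twice the detector width for the
#' radial FFT (\code{padFactor = 2}) to suppress the circular-convolution
#' cupping artifact of unpadded FBP.
#'
#' @param sino a \linkS4class{Sinogram}.
#' @param plan an \linkS4class{OperatorPlan}; when omitted, one is built
#'   from \code{geometry(sino)} with \code{radialCount = padFactor *
#'   numColumns}.
#' @param filter a \linkS4class{FilterSpec}.
#' @param padFactor radial zero-padding factor for the default plan.
#' @param kernel spreading kernel for the default plan.
#' @return a \linkS4class{Volume}.
#' @export
fbpReconstruct <- function(sino, plan = NULL,
                           filter = filterSpec("ram-lak"),
                           padFactor = 2L, kernel = spreadingKernel()) {
  if (is.null(plan))
    plan <- operatorPlan(sino@geometry, kernel,
                         radialCount = padFactor * sino@geometry@numColumns)
  validObject(filter)
  mt <- plan@polar@radialCount
  fw <- filterResponse(filter, plan@radialFreq[seq_len(mt)])
  vol <- .adjointArray(sino@data, plan, filterWeights = fw) *
    (pi / length(plan@geometry@angles))
  tomoVolume(vol, voxelSize = plan@geometry@pixelSize)
}
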