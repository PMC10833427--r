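# shared fixture builders (all deterministic)

equispacedGeometry <- function(nAngles, n, nSlices = 1L, offset = 0) {
  scanGeometry(pi * (0:(nAngles - 1)) / nAngles, n, nSlices, offset)
}

# smooth Gaussian blob slice (effectively band-limited; discretization
# error negligible for operator cross-checks)
blobSlice <- function(n, width = n / 10) {
  cc <- (n - 1) / 2
  u <- (0:(n - 1)) - cc
  exp(-outer(u^2, u^2, "+") / (2 * width^2))
}

# coverage anti-aliased disk of radius r
diskSlice <- function(n, r, value = 1) {
  cc <- (n - 1) / 2
  u <- (0:(n - 1)) - cc
  rr <- sqrt(outer(u^2, u^2, "+"))
  value * pmin(pmax(r - rr + 0.5, 0), 1)
}

detOffsets <- function(n) (0:(n - 1)) - (n - 1) / 2

relL2 <- function(a, b) sqrt(sum((a - b)^2) / sum(b^2))

randomVolume <- function(seed, ns, n, scale = 1) {
  set.seed(seed)
  tomoVolume(array(rnorm(ns * n * n) * scale, c(ns, n, n)))
}

randomSinogram <- function(seed, geom) {
  set.seed(seed)
  sinogram(array(rnorm(length(geom@angles) * geom@numSlices * geom@numColumns),
                 c(length(geom@angles), geom@numSlices, geom@numColumns)),
           geom)
}
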