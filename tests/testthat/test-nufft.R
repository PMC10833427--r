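# Forward/adjoint NUFFT operators against brute-force oracles.

test_that("polar grid has the stated layout and symmetry", {
  g1 <- scanGeometry(0, 4L)
  pg <- buildPolarGrid(g1, 4L)
  expect_error(buildPolarGrid(g1, 1L), "radialCount")
  expect_equal(pg@points[, 2L], rep(0, 4))            # theta = 0: on k_x axis

  g4 <- equispacedGeometry(4L, 8L)
  pg8 <- buildPolarGrid(g4, 8L)
  expect_equal(pg8@totalCount, 32L)

  # with an odd radial count the radial frequencies are symmetric about
  # zero and the point set is exactly symmetric under k -> -k; an even
  # count leaves only the (self-paired modulo 2*pi) Nyquist bin apart
  pg9 <- buildPolarGrid(g4, 9L)
  pts <- round(pg9@points, 10)
  key <- function(m) paste(m[, 1], m[, 2])
  expect_setequal(key(pts), key(-pts))
  expect_setequal(round(sort(unique(pg9@radialIndex)), 10),
                  round(sort(unique(-pg9@radialIndex)), 10))
})

test_that("kernel width follows the accuracy contract", {
  expect_true(kernelWidth(1e-6) >= 6 && kernelWidth(1e-6) <= 8)
  eps <- 10^seq(-14, -1)
  w <- vapply(eps, kernelWidth, integer(1))
  expect_true(all(diff(w) <= 0))                      # non-increasing in eps
  expect_error(kernelWidth(1), "tolerance")
  expect_error(kernelWidth(1e-15), "tolerance")
})

test_that("NUFFT evaluation matches the direct DFT oracle at its tolerance", {
  n <- 16L
  g <- equispacedGeometry(8L, n)
  pos <- nufftTomo:::.gridPositions(n)
  prevErr <- Inf
  for (eps in c(1e-2, 1e-6, 1e-12)) {
    plan <- operatorPlan(g, spreadingKernel(eps))
    set.seed(7)
    img <- matrix(rnorm(n * n), n, n)
    vals <- nufftTomo:::.nufftGridToPolar(img, plan)
    direct <- as.vector(t(exp(-1i * (pos %*% t(plan@polar@points)))) %*%
                          as.vector(img))
    err2 <- sqrt(sum(Mod(vals - direct)^2) / sum(Mod(direct)^2))
    expect_lt(err2, 10 * eps)
    # polar -> grid side against dftOracle (Hermitian coefficients)
    img1 <- nufftTomo:::.nufftPolarToGrid(vals, plan)
    d1 <- Re(matrix(dftOracle(vals, plan@polar, pos), n, n))
    err1 <- sqrt(sum((img1 - d1)^2) / sum(d1^2))
    expect_lt(err1, 10 * eps)
    # tightening eps never increases the discrepancy
    expect_lte(err2, prevErr)
    prevErr <- err2
  }
})

test_that("tight-tolerance NUFFT reaches 1e-10 on a 32^2 grid", {
  n <- 32L
  g <- equispacedGeometry(8L, n)
  plan <- operatorPlan(g, spreadingKernel(1e-12))
  set.seed(11)
  img <- matrix(rnorm(n * n), n, n)
  pos <- nufftTomo:::.gridPositions(n)
  vals <- nufftTomo:::.nufftGridToPolar(img, plan)
  direct <- as.vector(t(exp(-1i * (pos %*% t(plan@polar@points)))) %*%
                        as.vector(img))
  expect_lt(sqrt(sum(Mod(vals - direct)^2) / sum(Mod(direct)^2)), 1e-10)
})

test_that("dftOracle trivial cases and guard", {
  g <- equispacedGeometry(4L, 8L)
  pg <- buildPolarGrid(g)
  coef <- rep(0 + 0i, pg@totalCount)
  pos <- nufftTomo:::.gridPositions(8L)
  expect_equal(dftOracle(coef, pg, pos), rep(0 + 0i, nrow(pos)))
  coef[1L] <- 3 + 0i                                 # DC term (m' = 0 bin)
  expect_equal(dftOracle(coef, pg, pos), rep(3 + 0i, nrow(pos)))
  big <- matrix(0, 1e6, 2)
  expect_error(dftOracle(coef, pg, big), "guard")
})

test_that("forward projection is linear and maps zero to zero", {
  n <- 24L
  g <- equispacedGeometry(6L, n)
  plan <- operatorPlan(g)
  expect_lt(max(abs(sinogramData(forwardProject(zeroVolume(g), plan)))),
            1e-12)
  f1 <- randomVolume(1, 1L, n)
  f2 <- randomVolume(2, 1L, n)
  lhs <- forwardProject(tomoVolume(2 * f1@data - 3 * f2@data), plan)
  rhs <- 2 * sinogramData(forwardProject(f1, plan)) -
    3 * sinogramData(forwardProject(f2, plan))
  expect_lt(relL2(sinogramData(lhs), rhs), 1e-12)
})

test_that("projections of a centered disk are rotation invariant and match
           the analytic chord profile", {
  n <- 32L
  g <- scanGeometry(c(0, 1.1), n)
  # rotation invariance needs a band-limited edge (sigmoid profile);
  # a 1-pixel anti-aliased edge still carries angle-dependent aliasing
  cc <- (n - 1) / 2
  u <- (0:(n - 1)) - cc
  rr <- sqrt(outer(u^2, u^2, "+"))
  smooth <- forwardProject(tomoVolume(1 / (1 + exp((rr - 10) / 0.6))),
                           operatorPlan(g))
  dev <- max(abs(smooth@data[1, 1, ] - smooth@data[2, 1, ])) /
    max(abs(smooth@data))
  expect_lt(dev, 1e-3)

  disk <- tomoVolume(diskSlice(n, 10))
  p <- forwardProject(disk, operatorPlan(g))
  tdet <- detOffsets(n)
  chord <- 2 * sqrt(pmax(100 - tdet^2, 0))
  interior <- abs(tdet) < 8
  expect_lt(max(abs(p@data[1, 1, interior] - chord[interior]) /
                  chord[interior]), 0.02)
})

test_that("forward projection matches the dense-ray Radon oracle", {
  n <- 32L
  g <- equispacedGeometry(8L, n)
  plan <- operatorPlan(g)
  vol <- tomoVolume(blobSlice(n))
  expect_lt(relL2(sinogramData(forwardProject(vol, plan)),
                  sinogramData(radonOracle(vol, g))), 1e-2)
})

test_that("back projection is the exact adjoint of the forward operator", {
  n <- 16L
  g <- equispacedGeometry(8L, n)
  plan <- operatorPlan(g, spreadingKernel(1e-7))
  for (i in 1:10) {
    f <- randomVolume(i, 1L, n)@data
    s <- randomSinogram(100 + i, g)@data
    lhs <- sum(nufftTomo:::.forwardArray(f, plan) * s)
    rhs <- sum(f * nufftTomo:::.adjointArray(s, plan))
    expect_lt(abs(lhs - rhs) / abs(rhs), 1e-5)
  }
})

test_that("back projection trivia: zero input; single axis-aligned view
           smears along y", {
  n <- 16L
  g <- equispacedGeometry(8L, n)
  plan <- operatorPlan(g)
  zs <- sinogram(array(0, c(8, 1, n)), g)
  expect_lt(max(abs(volumeData(backProject(zs, plan)))), 1e-12)

  g1 <- scanGeometry(0, n)                            # theta = 0: beam along y
  plan1 <- operatorPlan(g1)
  set.seed(5)
  row <- rnorm(n)
  bp <- backProject(sinogram(array(row, c(1, 1, n)), g1), plan1)@data[1, , ]
  spread <- apply(bp, 2, function(col) max(col) - min(col))
  expect_lt(max(spread), 1e-4 * max(abs(bp)))
})

test_that("radon oracle: delta mass is near one and stable across angles;
           zero maps to zero; guards enforced", {
  n <- 32L
  del <- array(0, c(1L, n, n))
  del[1, n / 2, n / 2] <- 1
  g <- scanGeometry(pi * (0:7) / 8 + 0.05, n)
  so <- radonOracle(tomoVolume(del), g)
  mass <- apply(so@data[, 1, ], 1, sum)
  # bilinear quadrature on a rotated lattice: per-angle mass is 1 up to
  # interpolation aliasing of a few percent
  expect_true(all(abs(mass - 1) < 0.03))
  expect_lt(max(mass) - min(mass), 0.05)
  expect_equal(max(abs(sinogramData(radonOracle(zeroVolume(g), g)))), 0)
  expect_error(radonOracle(tomoVolume(array(0, c(1, 128, 128))),
                           equispacedGeometry(2L, 128L)), "<= 64")
})
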