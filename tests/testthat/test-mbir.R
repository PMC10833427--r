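test_that("Beer-Lambert conversion: closed forms and positivity guards", {
  i0 <- array(100, c(2, 1, 4))
  expect_equal(beerLambert(i0, i0), array(0, c(2, 1, 4)))
  expect_equal(beerLambert(i0 * exp(-1), i0), array(1, c(2, 1, 4)))
  expect_equal(beerLambert(i0 / 2, i0)[1], log(2), tolerance = 1e-12)
  bad <- i0; bad[3] <- 0
  expect_error(beerLambert(bad, i0), "index 3")
  expect_error(beerLambert(i0, i0 * 0), "flat")
  g <- equispacedGeometry(2L, 4L)
  expect_s4_class(beerLambert(i0, i0, g), "Sinogram")
})

test_that("center correction: identity, integer-shift equivalence,
           inverse pair", {
  g <- equispacedGeometry(3L, 16L)
  b <- randomSinogram(31, g)
  expect_equal(centerCorrect(b, 0)@data, b@data, tolerance = 1e-12)

  sh <- centerCorrect(b, 3)
  ref <- b@data[, , c(4:16, 1:3), drop = FALSE]      # row[m] <- row[m + 3]
  expect_lt(max(abs(sh@data - ref)), 1e-10)

  # fractional shifts are exactly invertible away from the Nyquist bin
  # (whose component a real-valued fractional delay necessarily projects)
  alt <- rep(c(1, -1), length.out = 16)
  bn <- b
  for (s in 1) for (a in 1:3) {
    row <- bn@data[a, s, ]
    bn@data[a, s, ] <- row - mean(row * alt) * alt
  }
  back <- centerCorrect(centerCorrect(bn, 2.37), -2.37)
  expect_lt(max(abs(back@data - bn@data)), 1e-10)
  expect_equal(centerOffset(centerCorrect(b, 1.5)), -1.5)
  expect_error(centerCorrect(b, 9), "out of range")
})

test_that("a rotation-offset acquisition is recovered after center
           correction", {
  n <- 32L
  vol <- tomoVolume(blobSlice(n) + diskSlice(n, 5, 0.5))
  acq <- acquisitionSpec(24L, poissonNoise = FALSE, centerOffset = 2.5)
  sim <- simulateAcquisition(vol, acq)
  expect_equal(centerOffset(sim$clean), 2.5)
  fixed <- centerCorrect(sim$clean, 2.5)
  straight <- simulateAcquisition(vol, acquisitionSpec(24L,
                                                       poissonNoise = FALSE))
  expect_lt(relL2(fixed@data, straight$clean@data), 1e-6)
})

test_that("objective breakdown: zero case, consistency at the truth, and
           the sigma -> infinity limit", {
  n <- 16L
  g <- equispacedGeometry(8L, n)
  plan <- operatorPlan(g)
  pp <- qggmrfParams(sigma = 1)
  z <- zeroVolume(g)
  zb <- sinogram(array(0, c(8, 1, n)), g)
  expect_equal(mbirObjective(z, zb, plan, pp)@total, 0)

  f <- tomoVolume(blobSlice(n))
  b <- forwardProject(f, plan)
  ob <- mbirObjective(f, b, plan, pp)
  expect_lt(ob@dataTerm, 1e-10 * sum(b@data^2))

  f2 <- randomVolume(41, 1L, n)
  obInf <- mbirObjective(f2, b, plan, qggmrfParams(sigma = 1e9))
  expect_lt(obInf@priorTerm, 1e-6 * obInf@total)
  expect_equal(obInf@total, obInf@dataTerm + obInf@priorTerm)
})

test_that("analytic objective gradient matches finite differences", {
  n <- 16L
  g <- equispacedGeometry(8L, n, nSlices = 16L)
  plan <- operatorPlan(g)
  pp <- qggmrfParams(sigma = 0.2)
  f <- randomVolume(51, 16L, n, scale = 0.1)
  b <- randomSinogram(52, g)
  gr <- mbirGradient(f, b, plan, pp)@data
  h <- 1e-5
  set.seed(53)
  idx <- sample(length(f@data), 30L)
  for (i in idx) {
    fp <- f@data; fp[i] <- fp[i] + h
    fm <- f@data; fm[i] <- fm[i] - h
    num <- (mbirObjective(tomoVolume(fp), b, plan, pp)@total -
              mbirObjective(tomoVolume(fm), b, plan, pp)@total) / (2 * h)
    expect_lt(abs(gr[i] - num) / max(abs(gr)), 1e-4)
  }
})

test_that("gradient trivia: stationary at the noiseless truth; equals
           -R^T b at zero", {
  n <- 16L
  g <- equispacedGeometry(8L, n)
  plan <- operatorPlan(g)
  inf <- qggmrfParams(sigma = 1e9)
  f <- tomoVolume(blobSlice(n))
  b <- forwardProject(f, plan)
  gr <- mbirGradient(f, b, plan, inf)@data
  expect_lt(sqrt(sum(gr^2)), 1e-6 * sqrt(sum(f@data^2)))

  b2 <- randomSinogram(61, g)
  g0 <- mbirGradient(zeroVolume(g), b2, plan, inf)@data
  expect_lt(relL2(g0, -nufftTomo:::.adjointArray(b2@data, plan)), 1e-9)
})

test_that("step estimate is deterministic and matches the dense-operator
           norm", {
  g <- equispacedGeometry(6L, 12L)
  plan <- operatorPlan(g)
  expect_identical(estimateStep(plan, 7L), estimateStep(plan, 7L))
  # explicit matrix of R on a 12^2 grid, 6 angles
  n <- 12L
  mat <- vapply(seq_len(n * n), function(j) {
    e <- array(0, c(1L, n, n)); e[j] <- 1
    as.vector(nufftTomo:::.forwardArray(e, plan))
  }, numeric(6 * n))
  lTrue <- max(svd(mat, nu = 0, nv = 0)$d)^2
  expect_lt(abs(0.9 / estimateStep(plan, 7L) - lTrue) / lTrue, 0.05)
  expect_gt(estimateStep(operatorPlan(equispacedGeometry(6L, 6L)), 1L), 0)
})

test_that("the accelerated solver drives a noiseless well-posed problem to
           a tiny data term with a monotone, deterministic trace", {
  n <- 32L
  g <- equispacedGeometry(64L, n)
  plan <- operatorPlan(g)
  b <- forwardProject(tomoVolume(diskSlice(n, 10)), plan)
  cfg <- solverConfig(maxIterations = 200L, seed = 2L)
  res <- solveMBIR(b, plan, qggmrfParams(sigma = 1e9), cfg)
  expect_lt(dataTermTrace(res)[200], 1e-4 * (0.5 * sum(b@data^2)))
  tr <- objectiveTrace(res)
  expect_true(all(diff(tr) <= 1e-9 * pmax(abs(tr[-length(tr)]), 1)))
  res2 <- solveMBIR(b, plan, qggmrfParams(sigma = 1e9), cfg)
  expect_identical(objectiveTrace(res2), tr)
})

test_that("plain gradient descent reaches the accelerated objective given
           more iterations (consistent minimizer)", {
  n <- 16L
  g <- equispacedGeometry(16L, n)
  plan <- operatorPlan(g)
  b <- forwardProject(tomoVolume(blobSlice(n)), plan)
  pp <- qggmrfParams(sigma = 0.05)
  acc <- solveMBIR(b, plan, pp, solverConfig(60L, seed = 1L))
  plain <- solveMBIR(b, plan, pp,
                     solverConfig(300L, seed = 1L, accelerate = FALSE))
  lo <- min(objectiveTrace(acc))
  expect_lt(abs(min(objectiveTrace(plain)) - lo) / lo, 0.01)
})

test_that("stop tolerance truncates the trace; init is honored;
           non-finite objectives abort with the iteration index", {
  n <- 16L
  g <- equispacedGeometry(8L, n)
  plan <- operatorPlan(g)
  b <- forwardProject(tomoVolume(blobSlice(n)), plan)
  pp <- qggmrfParams(sigma = 1)
  res <- solveMBIR(b, plan, pp, solverConfig(200L, stopTolerance = 1e-6))
  expect_lt(iterationsRun(res), 200L)
  warm <- solveMBIR(b, plan, qggmrfParams(sigma = 1e9), solverConfig(2L),
                    init = tomoVolume(blobSlice(n)))
  expect_lt(dataTermTrace(warm)[1], 1e-10 * sum(b@data^2))
  expect_error(solveMBIR(b, plan, pp,
                         solverConfig(5L, stepSize = 1e150, monotone = FALSE,
                                      restart = FALSE)),
               "iteration")
})

test_that("sigma sweep: single and empty grids; stronger regularization
           lowers the solution's total variation", {
  n <- 32L
  g <- equispacedGeometry(16L, n)
  plan <- operatorPlan(g)
  vol <- tomoVolume(diskSlice(n, 10, 0.02))
  sim <- simulateAcquisition(vol, acquisitionSpec(16L, flux = 1e4, seed = 5L))
  b <- beerLambert(sim$intensity, sim$flat, geom = sim$clean@geometry)
  pp <- qggmrfParams(sigma = 1)
  cfg <- solverConfig(30L, seed = 3L)
  expect_identical(sweepSigma(b, plan, numeric(0), pp, cfg), list())
  one <- sweepSigma(b, plan, 0.01, pp, cfg)
  expect_equal(one[[1L]]$result@volume@data,
               solveMBIR(b, plan, qggmrfParams(0.01), cfg)@volume@data)

  sig <- 0.02 * c(0.25, 0.5, 2, 8)
  sw <- sweepSigma(b, plan, sig, pp, cfg)
  tv <- vapply(sw, function(r) {
    m <- r$result@volume@data[1, , ]
    sum(abs(diff(m))) + sum(abs(t(diff(t(m)))))
  }, numeric(1))
  # total variation non-increasing in 1/sigma == non-decreasing in sigma...
  # stronger constraint (smaller sigma) must not increase roughness
  expect_true(all(diff(tv) >= -1e-8 * tv[-length(tv)]))
})
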