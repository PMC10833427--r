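test_that("sinogram downsampling block-averages detector columns", {
  g <- equispacedGeometry(2L, 4L, nSlices = 1L, offset = 1)
  row <- c(0, 2, 4, 6)
  b <- sinogram(array(rep(row, each = 2), c(2, 1, 4)), g)
  down <- downsampleSinogram(b, 2L)
  expect_equal(down@data[1, 1, ], c(1, 5))
  expect_equal(centerOffset(down), 0.5)
  expect_equal(down@geometry@pixelSize, 2)
  expect_identical(downsampleSinogram(b, 1L), b)

  g8 <- equispacedGeometry(3L, 8L)
  const <- sinogram(array(2.5, c(3, 1, 8)), g8)
  d4 <- downsampleSinogram(const, 4L)
  expect_equal(d4@data, array(2.5, c(3, 1, 2)))
  expect_error(downsampleSinogram(sinogram(array(0, c(3, 1, 6)),
                                           equispacedGeometry(3L, 6L)), 4L),
               "divisible")
})

test_that("volume upsampling preserves constants and reproduces affine
           ramps exactly", {
  v <- tomoVolume(array(3.7, c(2, 8, 8)))
  up <- upsampleVolume(v, 2L)
  expect_equal(up@data, array(3.7, c(2, 16, 16)), tolerance = 1e-12)
  expect_identical(upsampleVolume(v, 1L), v)

  n <- 8L
  ramp <- outer(seq_len(n), seq_len(n), function(y, x) 2 * x - 3 * y + 1)
  upr <- upsampleVolume(tomoVolume(ramp), 4L)@data[1, , ]
  # fine-grid coordinates of the same affine function
  uf <- ((seq_len(32) - 0.5) / 4 - 0.5) + 1
  want <- outer(uf, uf, function(y, x) 2 * x - 3 * y + 1)
  expect_lt(max(abs(upr - want)), 1e-10)
})

test_that("down-then-up on a constant sinogram is the identity", {
  g <- equispacedGeometry(3L, 16L)
  const <- sinogram(array(1.2, c(3, 1, 16)), g)
  down <- downsampleSinogram(const, 4L)
  expect_equal(down@data[1, 1, ], rep(1.2, 4))
})

test_that("a single-level schedule reproduces solveMBIR exactly", {
  n <- 16L
  g <- equispacedGeometry(8L, n)
  plan <- operatorPlan(g)
  b <- forwardProject(tomoVolume(blobSlice(n)), plan)
  pp <- qggmrfParams(sigma = 0.1)
  cfg <- solverConfig(seed = 4L)
  h <- hierarchicalReconstruct(b, pp, cfg, levelSchedule(1L, 12L))
  s <- solveMBIR(b, plan, pp, solverConfig(12L, seed = 4L))
  expect_equal(h@volume@data, s@volume@data, tolerance = 1e-12)
  expect_equal(h@objectiveTrace, s@objectiveTrace, tolerance = 1e-12)
})

test_that("per-level sigma rescaling is applied and echoed", {
  n <- 16L
  g <- equispacedGeometry(8L, n)
  b <- forwardProject(tomoVolume(blobSlice(n)), operatorPlan(g))
  pp <- qggmrfParams(sigma = 0.2)
  h <- hierarchicalReconstruct(b, pp, solverConfig(seed = 1L),
                               levelSchedule(c(2L, 1L), c(3L, 2L)),
                               sigmaScale = c(0.5, 1))
  expect_equal(h@configEcho$sigmaPerLevel, c(0.1, 0.2))
  expect_equal(h@configEcho$schedule$factors, c(2L, 1L))
  expect_equal(h@iterationsRun, 5L)
})

test_that("the coarse-to-fine warm start never hurts: hierarchical final
           objective is at most that of an equal fine-iteration cold run", {
  set.seed(71)
  spec <- foamSpec(32L, 1L, voidCount = 8L, materialDensity = 6 / 32,
                   seed = 3L)
  vol <- makeFoam(spec)
  sim <- simulateAcquisition(vol, acquisitionSpec(16L, flux = 1e4, seed = 9L))
  b <- beerLambert(sim$intensity, sim$flat, geom = sim$clean@geometry)
  pp <- qggmrfParams(sigma = 6 / 32)
  cfg <- solverConfig(seed = 5L)
  sched <- levelSchedule(c(2L, 1L), c(20L, 8L))
  h <- hierarchicalReconstruct(b, pp, cfg, sched)
  cold <- solveMBIR(b, operatorPlan(b@geometry), pp,
                    solverConfig(8L, seed = 5L))
  expect_lte(utils::tail(h@objectiveTrace, 1),
             utils::tail(cold@objectiveTrace, 1))
})
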