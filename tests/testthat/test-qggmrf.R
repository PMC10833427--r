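# brute-force triple-loop prior energy, independent of the C++ path
priorValueLoop <- function(f, params) {
  nw <- neighborWeights()
  d <- dim(f)
  total <- 0
  for (a in 1:d[1]) for (b in 1:d[2]) for (cc in 1:d[3]) {
    for (k in 1:26) {
      o <- nw$offsets[k, ]
      aa <- a + o[1]; bb <- b + o[2]; cx <- cc + o[3]
      if (aa < 1 || aa > d[1] || bb < 1 || bb > d[2] ||
          cx < 1 || cx > d[3]) next
      total <- total + nw$weights[k] *
        qggmrfPotential(f[a, b, cc] - f[aa, bb, cx], params)
    }
  }
  total
}

test_that("the 26 neighbor weights partition unity with 1/distance ratios", {
  nw <- neighborWeights()
  expect_equal(nrow(nw$offsets), 26L)
  expect_lt(abs(sum(nw$weights) - 1), 1e-15)
  d <- sqrt(rowSums(nw$offsets^2))
  face <- nw$weights[d == 1][1L]
  corner <- nw$weights[abs(d - sqrt(3)) < 1e-12][1L]
  expect_equal(face / corner, sqrt(3), tolerance = 1e-12)
  expect_equal(face, 1 / (6 + 12 / sqrt(2) + 8 / sqrt(3)), tolerance = 1e-12)
  expect_equal(face, 0.05234, tolerance = 1e-4)
})

test_that("potential: even, zero at zero, strictly increasing, closed form", {
  pp <- qggmrfParams(sigma = 1, p = 1.2, c = 1e-4)
  expect_equal(qggmrfPotential(0, pp), 0)
  x <- c(0.1, 1, 10)
  expect_equal(qggmrfPotential(-x, pp), qggmrfPotential(x, pp))
  expect_equal(qggmrfPotential(1, pp), 1 / (1e-4 + 1), tolerance = 1e-12)
  xs <- seq(0, 5, by = 0.01)
  expect_true(all(diff(qggmrfPotential(xs, pp)) > 0))
})

test_that("potential has quadratic small-|delta| and p-power large-|delta|
           growth", {
  pp <- qggmrfParams(sigma = 1, p = 1.2, c = 1e-4)
  slope <- function(x1, x2)
    (log(qggmrfPotential(x2, pp)) - log(qggmrfPotential(x1, pp))) /
      (log(x2) - log(x1))
  # well below the transition |delta| ~ sigma * c^{1/(2-p)}
  expect_equal(slope(1e-8, 1e-9), 2, tolerance = 1e-3)
  expect_equal(slope(1e4, 1e5), 1.2, tolerance = 1e-3)
})

test_that("prior value matches the triple-loop oracle and is symmetric", {
  set.seed(21)
  f <- array(rnorm(27), c(3, 3, 3))
  pp <- qggmrfParams(sigma = 0.7, p = 1.2, c = 1e-4)
  expect_equal(priorValue(f, pp), priorValueLoop(f, pp), tolerance = 1e-12)
  mirror <- f[, , 3:1]
  expect_equal(priorValue(mirror, pp), priorValue(f, pp), tolerance = 1e-12)
  expect_equal(priorValue(array(2.5, c(3, 3, 3)), pp), 0)
})

test_that("prior gradient matches central finite differences and vanishes
           exactly on constants", {
  set.seed(22)
  f <- array(rnorm(64), c(4, 4, 4))
  pp <- qggmrfParams(sigma = 0.5, p = 1.2, c = 1e-4)
  g <- priorGradient(f, pp)
  h <- 1e-5
  num <- array(0, dim(f))
  for (i in seq_along(f)) {
    fp <- f; fp[i] <- fp[i] + h
    fm <- f; fm[i] <- fm[i] - h
    num[i] <- (priorValue(fp, pp) - priorValue(fm, pp)) / (2 * h)
  }
  expect_lt(max(abs(g - num)) / max(abs(num)), 1e-5)
  expect_equal(max(abs(priorGradient(array(1.3, c(4, 4, 4)), pp))), 0)
  # dependence on differences only
  expect_equal(priorGradient(f + 5, pp), g, tolerance = 1e-9)
})

test_that("gradient accumulates into a supplied array and checks shape", {
  set.seed(23)
  f <- array(rnorm(27), c(3, 3, 3))
  acc <- array(rnorm(27), c(3, 3, 3))
  pp <- qggmrfParams(sigma = 1)
  expect_equal(priorGradient(f, pp, accumulate = acc),
               acc + priorGradient(f, pp))
  expect_error(priorGradient(f, pp, accumulate = array(0, c(2, 3, 3))),
               "shape mismatch")
})

test_that("decreasing sigma strictly increases the prior value", {
  set.seed(24)
  f <- array(rnorm(27), c(3, 3, 3))
  vals <- vapply(c(2, 1, 0.5, 0.25), function(s)
    priorValue(f, qggmrfParams(sigma = s)), numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("single-slice volumes degrade to the 8-neighbor 2-D prior", {
  set.seed(25)
  m <- matrix(rnorm(16), 4, 4)
  f3 <- array(m, c(1, 4, 4))
  pp <- qggmrfParams(sigma = 0.9)
  # brute force over in-plane neighbors only
  expect_equal(priorValue(f3, pp), priorValueLoop(f3, pp), tolerance = 1e-12)
})
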