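pointsOnSphere <- function(n = 500, R = 8.5, seed = 2) {
  set.seed(seed)
  x <- matrix(rnorm(3 * n), n, 3)
  R * x / sqrt(rowSums(x^2))
}

test_that("scenario pressure fields match their stated shapes", {
  x <- pointsOnSphere()
  R <- 8.5
  hom <- scenarioHomogeneous(1000)
  expect_equal(hom@pressureFun(x, R), rep(1000, nrow(x)))
  null <- scenarioHomogeneous(0)
  expect_equal(null@pressureFun(x, R), rep(0, nrow(x)))

  per <- scenarioPeriodic(600, 1000, pi / 4)
  p <- per@pressureFun(x, R)
  expect_true(all(p >= 600 - 1e-9 & p <= 1000 + 1e-9))
  phi <- seq(0, 2 * pi, length.out = 5001)[-5001]
  grid <- cbind(R * cos(phi), R * sin(phi), 0)
  pg <- per@pressureFun(grid, R)
  expect_equal(range(pg), c(600, 1000), tolerance = 1e-4)
  # 8 full periods around the equator (16 level crossings, circularly)
  ind <- pg >= 800
  expect_equal(sum(abs(diff(c(ind, ind[1])))), 16)
  expect_equal(scenarioPeriodic(700, 700)@pressureFun(x, R),
               rep(700, nrow(x)))
  expect_error(scenarioPeriodic(600, 1000, 1.1), "divide")

  quad <- scenarioQuadratic(1000, 600)
  expect_equal(quad@pressureFun(rbind(c(R, 0, 0), c(0, R, 0)), R),
               c(1000, 1000))
  expect_equal(quad@pressureFun(rbind(c(0, 0, R), c(0, 0, -R)), R),
               c(600, 600))
  # axisymmetric about z
  z <- x[, 3]
  expect_equal(quad@pressureFun(x, R), 1000 - 400 * (z / R)^2,
               tolerance = 1e-9)
  expect_equal(scenarioQuadratic(800, 800)@pressureFun(x, R),
               rep(800, nrow(x)))
})

test_that("shear tractions are tangential with the stated magnitude", {
  x <- pointsOnSphere(800)
  R <- 8.5
  ps <- scenarioPressureShear(800, 120)
  expect_equal(ps@pressureFun(x, R), rep(800, nrow(x)))
  tr <- ps@tractionFun(x, R)
  n <- x / R
  expect_lt(max(abs(rowSums(tr * n))), 1e-12 * 120)
  mag <- sqrt(rowSums(tr^2))
  # away from the poles the magnitude is exactly tau
  away <- abs(x[, 3]) < 0.99 * R & abs(x[, 1]) > 0.01 * R
  expect_equal(mag[away], rep(120, sum(away)), tolerance = 1e-9)
  # tau = 0 reduces to the homogeneous scenario
  expect_equal(max(abs(scenarioPressureShear(800, 0)@tractionFun(x, R))), 0)
})

test_that("homogeneous forward displacements are radial", {
  tm <- beadMesh2()
  fwd <- forwardScenario(scenarioHomogeneous(1000), tm, valMaterial())
  u <- displacements(fwd$solution)
  ids <- surfaceNodeIds(tm)
  xs <- meshNodes(tm)[ids, ]
  n <- xs / sqrt(rowSums(xs^2))
  ur <- rowSums(u[ids, ] * n)
  utan <- u[ids, ] - ur * n
  expect_lt(max(sqrt(rowSums(utan^2))) / max(abs(ur)), 1e-6)
})

test_that("the boundary-traction identity fixes the mean stress at small loads", {
  tm <- beadMesh2()
  mat <- valMaterial()
  scen <- list(scenarioHomogeneous(50), scenarioPeriodic(30, 50),
               scenarioQuadratic(50, 30))
  for (sc in scen) {
    fwd <- forwardScenario(sc, tm, mat)
    oracle <- appliedMeanStress(sc, tm)
    expect_equal(meanPressure(fwd$summary), stressPressure(oracle),
                 tolerance = 0.02 * stressPressure(oracle))
  }
  # tangential dead loads on a sphere are trace-free in the identity:
  # the pressure+shear scenario at (50, 7.5) Pa keeps mean pressure at 50
  fwd <- forwardScenario(scenarioPressureShear(50, 7.5), tm, mat)
  expect_equal(meanPressure(fwd$summary), 50, tolerance = 0.02 * 50)
})

test_that("uncertainty analysis is deterministic and degenerates cleanly", {
  sc <- scenarioHomogeneous(400)
  a <- uncertaintyAnalysis(sc, diameterSD = 0, ESD = 0, nSamples = 3,
                           seed = 9, refinement = 1, layers = 3)
  expect_equal(a$sd, 0)
  b1 <- uncertaintyAnalysis(sc, nSamples = 4, seed = 4, refinement = 1,
                            layers = 3)
  b2 <- uncertaintyAnalysis(sc, nSamples = 4, seed = 4, refinement = 1,
                            layers = 3)
  expect_identical(b1$samples, b2$samples)
})

test_that("recovered pressure scales linearly with the assumed modulus", {
  # with the shape and diameter fixed, the reconstruction displacement
  # field is modulus-independent, so pressure/E must be constant
  a <- uncertaintyAnalysis(scenarioHomogeneous(400), diameterSD = 0,
                           ESD = 400, nSamples = 5, seed = 7,
                           refinement = 1, layers = 3)
  ratio <- a$samples$pressure / a$samples$E
  expect_lt(diff(range(ratio)) / abs(mean(ratio)), 1e-6)
})
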