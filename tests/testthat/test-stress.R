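test_that("pressure is the negative third of the trace", {
  expect_equal(stressPressure(-1000 * diag(3)), 1000)
  shear <- matrix(0, 3, 3); shear[1, 2] <- shear[2, 1] <- 120
  expect_equal(stressPressure(shear), 0)
  expect_equal(stressPressure(diag(c(-600, -800, -1000))), 800)
  ns <- matrix(c(0, 5, 0, 0, 0, 0, 0, 0, 0), 3, 3)
  expect_error(stressPressure(ns), "symmetric")
})

test_that("volumetric mean is the volume-weighted tensor average", {
  f1 <- new("StressField",
            tensors = matrix(rep(c(-3, -2, -1, 0.5, 0, 0), 4), 4, 6,
                             byrow = TRUE),
            volumes = c(1, 2, 3, 4), J = rep(1, 4),
            centroids = matrix(0, 4, 3))
  expect_equal(volumetricMean(f1),
               matrix(c(-3, 0.5, 0, 0.5, -2, 0, 0, 0, -1), 3, 3))
  # two equal-volume points
  f2 <- new("StressField",
            tensors = rbind(c(-1000, 0, 0, 0, 0, 0),
                            c(0, -1000, 0, 0, 0, 0)),
            volumes = c(1, 1), J = c(1, 1), centroids = matrix(0, 2, 3))
  expect_equal(volumetricMean(f2), diag(c(-500, -500, 0)))
  # volumes 1 and 3, pressures 400 and 800 -> mean pressure 700
  f3 <- new("StressField",
            tensors = rbind(c(-400, -400, -400, 0, 0, 0),
                            c(-800, -800, -800, 0, 0, 0)),
            volumes = c(1, 3), J = c(1, 1), centroids = matrix(0, 2, 3))
  expect_equal(stressPressure(volumetricMean(f3)), 700)
  # linearity: pressure of the mean equals the weighted mean of pressures
  set.seed(1)
  tens <- matrix(rnorm(60), 10, 6)
  vols <- runif(10, 0.5, 2)
  f4 <- new("StressField", tensors = tens, volumes = vols, J = rep(1, 10),
            centroids = matrix(0, 10, 3))
  pw <- -rowSums(tens[, 1:3]) / 3
  expect_equal(stressPressure(volumetricMean(f4)),
               sum(pw * vols) / sum(vols), tolerance = 1e-9)
})

test_that("principal decomposition sorts, orients and rotates correctly", {
  iso <- principalStresses(-7 * diag(3))
  expect_equal(iso$values, rep(-7, 3))
  expect_equal(crossprod(iso$directions), diag(3), tolerance = 1e-12)
  perm <- principalStresses(diag(c(3, 1, 2)))
  expect_equal(perm$values, c(3, 2, 1))
  expect_equal(abs(perm$directions),
               matrix(c(1, 0, 0, 0, 0, 1, 0, 1, 0), 3, 3), tolerance = 1e-12)
  # similarity invariance under a known rotation
  R <- rotZ(0.7)
  base <- diag(c(3, 2, 1))
  rot <- principalStresses(R %*% base %*% t(R))
  expect_equal(rot$values, c(3, 2, 1), tolerance = 1e-12)
  for (k in 1:3)
    expect_equal(abs(sum(rot$directions[, k] * (R %*% diag(3)[, k]))), 1,
                 tolerance = 1e-9)
})

test_that("stress summaries satisfy their internal identities", {
  tm <- beadMesh1()
  mat <- valMaterial()
  fwd <- forwardScenario(scenarioHomogeneous(200), tm, mat)
  s <- fwd$summary
  expect_equal(meanPressure(s), -sum(principalValues(s)) / 3,
               tolerance = 1e-9)
  expect_equal(crossprod(principalDirections(s)), diag(3),
               tolerance = 1e-9)
  expect_equal(unname(summaryVolumes(s)["reference"]), meshVolume(tm))
})

test_that("normal-stress profiles follow the tensor algebra", {
  iso <- normalStressProfile(-5 * diag(3), 36)
  expect_equal(as.vector(iso@values), rep(-5, 36))
  uni <- normalStressProfile(diag(c(2, 0, 0)), 360)
  expect_equal(as.vector(uni@values), 2 * cos(uni@angles)^2,
               tolerance = 1e-12)
  # period pi
  g <- normalStressProfile(matrix(c(1, 0.3, 0, 0.3, -2, 0, 0, 0, 5), 3, 3),
                           360)
  v <- as.vector(g@values)
  expect_equal(v, v[c(181:360, 1:180)], tolerance = 1e-12)
})

test_that("profile extrema align with in-plane principal directions", {
  R <- rotZ(0.4)
  sig <- R %*% diag(c(4, 1, -2)) %*% t(R)
  prof <- normalStressProfile(sig, 3600)
  amax <- prof@angles[which.max(prof@values)]
  expect_lt(min(abs(((amax - 0.4) %% pi)), abs(((amax - 0.4) %% pi) - pi)),
            2 * pi / 3600 + 1e-9)
})

test_that("amplification preserves means and normalization hits 1", {
  p1 <- normalStressProfile(diag(c(-100, -140, -120)), 90)
  p2 <- normalStressProfile(diag(c(-150, -90, -130)), 90)
  series <- profileSeries(p1, p2)
  amp <- amplifyNormalize(series, 5)
  expect_equal(max(abs(amp@values)), 1)
  # per-time-point means preserved up to the single global constant
  scale <- rowMeans(series@values) / rowMeans(amp@values)
  expect_equal(scale[1], scale[2], tolerance = 1e-9)
  # the formula: m = 100, value 120, factor 5 -> 200 before normalization
  m <- 100; v <- 120
  expect_equal(m + 5 * (v - m), 200)
  # constant nonzero profile maps to its sign
  pc <- new("NormalStressProfile", angles = p1@angles,
            values = matrix(-3, 1, 90), amplification = 1,
            normalized = FALSE)
  expect_equal(as.vector(amplifyNormalize(pc, 5)@values), rep(-1, 90))
  pz <- new("NormalStressProfile", angles = p1@angles,
            values = matrix(0, 1, 90), amplification = 1,
            normalized = FALSE)
  expect_error(amplifyNormalize(pz), "zero")
})

test_that("summary comparison reports differences and angles", {
  tm <- beadMesh1()
  fwd <- forwardScenario(scenarioQuadratic(200, 120), tm, valMaterial())
  s <- fwd$summary
  same <- compareToReference(s, s)
  expect_equal(same$principalDiffs, rep(0, 3))
  expect_equal(same$pressureRelDiff, 0)
  expect_equal(max(same$directionAngles), 0, tolerance = 1e-6)
  # pressures 950 vs 1000 -> relative difference -0.05
  mk <- function(p) new("StressSummary", meanTensor = -p * diag(3),
                        principalValues = rep(-p, 3),
                        principalDirections = diag(3), meanPressure = p,
                        currentVolume = 1, referenceVolume = 1)
  expect_equal(compareToReference(mk(950), mk(1000))$pressureRelDiff, -0.05)
  # a 5-degree rotation about z is reported as 5 degrees
  R <- rotZ(5 * pi / 180)
  a <- new("StressSummary", meanTensor = diag(c(3, 2, 1)),
           principalValues = c(3, 2, 1), principalDirections = diag(3),
           meanPressure = -2, currentVolume = 1, referenceVolume = 1)
  b <- new("StressSummary", meanTensor = R %*% diag(c(3, 2, 1)) %*% t(R),
           principalValues = c(3, 2, 1), principalDirections = R,
           meanPressure = -2, currentVolume = 1, referenceVolume = 1)
  cmp <- compareToReference(b, a, degeneracyTol = 1e-9)
  expect_equal(cmp$directionAngles[1], 5, tolerance = 1e-6)
  expect_equal(cmp$directionAngles[2], 5, tolerance = 1e-6)
  expect_equal(cmp$directionAngles[3], 0, tolerance = 1e-6)
})
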