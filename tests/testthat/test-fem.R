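test_that("unloaded problems stay at the origin with zero stress", {
  tm <- beadMesh1()
  mat <- valMaterial()
  ids <- surfaceNodeIds(tm)
  sol <- solveStatic(tm, mat,
                     dirichlet = dirichletBC(ids,
                                             matrix(0, length(ids), 3)))
  expect_equal(max(abs(displacements(sol))), 0)
  f <- cauchyStress(tm, sol, mat)
  expect_equal(max(abs(stressTensors(f))), 0)
  expect_equal(f@J, rep(1, nrow(stressTensors(f))))
})

test_that("follower pressure reproduces the uniform-dilatation oracle", {
  tm <- beadMesh1()
  mat <- valMaterial()
  for (p in c(10, 100, 1000)) {
    st <- uniformDilatationState(p, mat)
    sol <- solveStatic(tm, mat,
                       tractions = tractionPressure(allBoundaryFaces(tm), p))
    f <- cauchyStress(tm, sol, mat)
    Jbar <- sum(f@J * pointVolumes(f)) / sum(pointVolumes(f))
    expect_lt(abs(Jbar - st["J"]) / st["J"], 0.01)
    # stress is hydrostatic -p I at every integration point within 1%
    s <- stressTensors(f)
    expect_lt(max(abs(s[, 1:3] + p)), 0.01 * p)
    expect_lt(max(abs(s[, 4:6])), 0.01 * p)
  }
})

test_that("small loads reproduce the linear volumetric response", {
  tm <- beadMesh1()
  mat <- valMaterial()
  p <- 10
  sol <- solveStatic(tm, mat,
                     tractions = tractionPressure(allBoundaryFaces(tm), p))
  dm <- deformedMesh(tm, sol)
  dV <- (meshVolume(dm) - meshVolume(tm)) / meshVolume(tm)
  expect_equal(dV, -p / bulkModulus(mat), tolerance = 0.02)
})

test_that("prescribed radial contraction yields a linear interior field", {
  tm <- beadMesh2()
  mat <- valMaterial()
  ids <- surfaceNodeIds(tm)
  bnd <- meshNodes(tm)[ids, ]
  sol <- solveStatic(tm, mat, dirichlet = dirichletBC(ids, -0.1 * bnd))
  # uniform dilatation is exactly representable: u = -0.1 x everywhere
  expect_equal(displacements(sol), -0.1 * meshNodes(tm), tolerance = 1e-8)
  # constitutive check: F = 0.9 I gives a uniform hydrostatic stress
  f <- cauchyStress(tm, sol, mat)
  J <- 0.9^3
  mu <- shearModulus(mat); lam <- lameFirst(mat)
  sExp <- (mu * (J^(2 / 3) - 1) + lam * log(J)) / J
  s <- stressTensors(f)
  expect_equal(s[, 1], rep(sExp, nrow(s)), tolerance = 1e-6)
  expect_equal(s[, 2], rep(sExp, nrow(s)), tolerance = 1e-6)
  expect_lt(max(abs(s[, 4:6])) / abs(sExp), 1e-6)
})

test_that("applied follower pressure is globally self-equilibrated", {
  tm <- beadMesh1()
  g <- beadstress:::faceGeometry(meshNodes(tm), boundaryFaces(tm))
  net <- colSums(g$normals * g$areas)
  expect_lt(max(abs(net)), 1e-10 * sum(g$areas))
})

test_that("recovered mean pressure is mesh-converged in the 1000 Pa state", {
  mat <- valMaterial()
  p1 <- meanPressure(summarizeStress(
    forwardScenario(scenarioHomogeneous(1000), beadMesh1(), mat)$field))
  p2 <- meanPressure(summarizeStress(
    forwardScenario(scenarioHomogeneous(1000), beadMesh2(), mat)$field))
  expect_lt(abs(p2 - p1) / p2, 0.01)
})

test_that("solver reports divergence with the last converged fraction", {
  tm <- beadMesh1()
  mat <- valMaterial()
  ids <- surfaceNodeIds(tm)
  # an extreme prescribed collapse (95% contraction) must invert elements
  bnd <- meshNodes(tm)[ids, ]
  expect_error(solveStatic(tm, mat,
                           dirichlet = dirichletBC(ids, -0.999 * bnd),
                           nLoadSteps = 1),
               "diverged|inverted")
})
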