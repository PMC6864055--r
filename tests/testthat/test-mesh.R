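test_that("icosphere construction has exact radii and face counts", {
  s0 <- makeSphereSurface(1, 0)
  expect_equal(nrow(meshFaces(s0)), 20)
  expect_equal(nrow(meshVertices(s0)), 12)
  s <- makeSphereSurface(8.5, 3)
  expect_equal(nrow(meshFaces(s)), 20 * 4^3)
  expect_equal(sqrt(rowSums(meshVertices(s)^2)),
               rep(8.5, nrow(meshVertices(s))), tolerance = 1e-14)
  # refinement 4 volume within 0.5% of the closed form
  s4 <- makeSphereSurface(8.5, 4)
  expect_lt(abs(meshVolume(s4) - sphereVol(8.5)) / sphereVol(8.5), 0.005)
})

test_that("tetrahedralization fills star-shaped surfaces consistently", {
  tm <- beadMesh2()
  expect_lt(abs(meshVolume(tm) - sphereVol(8.5)) / sphereVol(8.5), 0.05)
  # total tet volume equals the enclosed surface volume within 1%
  expect_equal(meshVolume(tm), meshVolume(makeSphereSurface(8.5, 2)),
               tolerance = 0.01)
  # every element positively oriented
  expect_true(all(beadstress:::tetVolumes(meshNodes(tm), meshTets(tm)) > 0))
  # boundary vertices preserved exactly
  surf <- makeSphereSurface(8.5, 2)
  ids <- surfaceNodeIds(tm)
  bnd <- meshNodes(tm)[ids, ]
  expect_equal(sort(sqrt(rowSums(bnd^2))),
               sort(sqrt(rowSums(meshVertices(surf)^2))), tolerance = 1e-12)
  # halving the target tet volume increases the element count
  t1 <- tetrahedralize(surf, maxTetVolume = 2)
  t2 <- tetrahedralize(surf, maxTetVolume = 0.25)
  expect_gt(nrow(meshTets(t2)), nrow(meshTets(t1)))
})

test_that("mesh volume matches closed forms and scaling laws", {
  # regular tetrahedron, edge 1: V = 1/(6 sqrt(2))
  n <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
             c(0.5, sqrt(3) / 6, sqrt(2 / 3)))
  tm <- tetMesh(n, matrix(1:4, 1))
  expect_equal(meshVolume(tm), 1 / (6 * sqrt(2)), tolerance = 1e-12)
  # uniform scaling scales volume by lambda^3 exactly
  big <- beadMesh2()
  scaled <- tetMesh(meshNodes(big) * 1.7, meshTets(big))
  expect_equal(meshVolume(scaled), meshVolume(big) * 1.7^3,
               tolerance = 1e-12)
  # inverted element reported with its id
  bad <- meshTets(big)
  bad[5, c(1, 2)] <- bad[5, c(2, 1)]
  expect_error(meshVolume(new("TetMesh", nodes = meshNodes(big), tets = bad,
                              boundaryFaces = boundaryFaces(big),
                              surfaceNodeIds = surfaceNodeIds(big))),
               "5")
})

test_that("tet volume equals the divergence-theorem boundary integral", {
  tm <- beadMesh2()
  expect_equal(meshVolume(boundarySurface(tm)), meshVolume(tm),
               tolerance = 1e-9)
  # also on a non-spherical mesh
  ell <- tetMesh(sweep(meshNodes(tm), 2, c(1.2, 0.9, 0.8), "*"),
                 meshTets(tm))
  expect_equal(meshVolume(boundarySurface(ell)), meshVolume(ell),
               tolerance = 1e-9)
})

test_that("surfaces extracted from labels recover analytic volumes", {
  lab <- sphereLabels(8.5, 0.2, 1)
  surf <- surfaceFromLabels(lab, smoothingIterations = 10)
  expect_lt(abs(meshVolume(surf) - sphereVol(8.5)) / sphereVol(8.5), 0.03)
  # raw isosurface (no smoothing) stays within a voxel layer of the labels
  raw <- surfaceFromLabels(lab, smoothingIterations = 0)
  expect_lt(abs(meshVolume(raw) - labelVolume(lab)) / labelVolume(lab), 0.06)
  # ellipsoid with semi-axes (10, 8, 7): V = 4/3 pi a b c
  sxy <- 0.2; sz <- 1
  nx <- ceiling(24 / sxy); nz <- ceiling(18 / sz)
  x <- (seq_len(nx) - 0.5) * sxy - 12
  z <- (seq_len(nz) - 0.5) * sz - 9
  r2 <- outer(outer((x / 10)^2, (x / 8)^2, "+"), (z / 7)^2, "+")
  ell <- labelStack(array(r2 <= 1, dim = c(nx, nx, nz)), sxy, sz)
  vol <- 4 / 3 * pi * 10 * 8 * 7
  se <- surfaceFromLabels(ell, smoothingIterations = 10)
  expect_lt(abs(meshVolume(se) - vol) / vol, 0.03)
})

test_that("labels touching the stack border are rejected", {
  lab <- sphereLabels(8.5, 0.5, 1, pad = 2)
  arr <- labelData(lab)
  arr[1, , 5] <- TRUE
  expect_error(surfaceFromLabels(labelStack(arr, 0.5, 1)), "border")
})
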