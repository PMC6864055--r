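test_that("rendering is deterministic and respects the slice geometry", {
  surf <- makeSphereSurface(8.5, 2)
  a <- renderBeadStack(surf, 0.2, 1, blurSigma = 0.2, noiseLevel = 0.05,
                       seed = 11)
  b <- renderBeadStack(surf, 0.2, 1, blurSigma = 0.2, noiseLevel = 0.05,
                       seed = 11)
  expect_identical(voxelData(a), voxelData(b))
  cc <- renderBeadStack(surf, 0.2, 1, blurSigma = 0.2, noiseLevel = 0.05,
                        seed = 12)
  expect_false(identical(voxelData(a), voxelData(cc)))
  # a 17 um sphere at 1 um z-step spans ~17 slices
  clean <- renderBeadStack(surf, 0.2, 1, blurSigma = 0, noiseLevel = 0)
  zspan <- range(which(apply(voxelData(clean) >= 0.5, 3, any)))
  expect_true((diff(zspan) + 1) %in% 16:18)
})

test_that("noiseless rendering is the voxelized interior", {
  surf <- makeSphereSurface(8.5, 2)
  st <- renderBeadStack(surf, 0.2, 1, blurSigma = 0, noiseLevel = 0)
  v <- voxelData(st)
  # binary away from the surface: partial-volume values only in a thin shell
  frac <- mean(v > 0.01 & v < 0.99)
  expect_lt(frac, 0.1)
  lab <- segmentBead(st)
  # segmentation agrees with the 0.5-level interior except at the boundary
  ref <- v >= 0.5
  expect_lt(mean(xor(labelData(lab), ref)), 0.005)
  vol <- labelVolume(lab)
  expect_lt(abs(vol - meshVolume(surf)) / meshVolume(surf), 0.03)
})

test_that("segmentation is invariant to uniform intensity scaling", {
  surf <- makeSphereSurface(8.5, 2)
  st <- renderBeadStack(surf, 0.2, 1, blurSigma = 0.2, noiseLevel = 0.05,
                        seed = 3)
  lab1 <- segmentBead(st)
  st2 <- imageStack(voxelData(st) * 7.3, spacingXY(st), spacingZ(st))
  lab2 <- segmentBead(st2)
  expect_identical(labelData(lab1), labelData(lab2))
})

test_that("segmentation rejects empty stacks", {
  expect_error(segmentBead(imageStack(array(0, c(8, 8, 4)), 0.2, 1)),
               "no signal")
})

test_that("label volume counts voxels with anisotropic spacing", {
  arr <- array(FALSE, c(5, 5, 4))
  arr[3, 3, 2] <- TRUE
  expect_equal(labelVolume(labelStack(arr, 0.1, 1)), 0.01)
  expect_error(labelVolume(labelStack(array(FALSE, c(5, 5, 4)), 0.1, 1)),
               "empty")
  # voxelized 8.5 um sphere at 0.1 um xy / 1 um z within 3% of closed form
  lab <- sphereLabels(8.5, 0.1, 1)
  expect_lt(abs(labelVolume(lab) - sphereVol(8.5)) / sphereVol(8.5), 0.03)
  # cube scaling law: radii scaled by 0.9 give a volume ratio near 0.729
  lab9 <- sphereLabels(8.5 * 0.9, 0.1, 1)
  expect_equal(labelVolume(lab9) / labelVolume(lab), 0.729,
               tolerance = 0.02)
})

test_that("equivalent diameter inverts the sphere volume", {
  expect_equal(equivalentDiameter(sphereVol(8.5)), 17)
  expect_equal(equivalentDiameter(pi / 6), 1)
  expect_equal(equivalentDiameter(8 * 123), 2 * equivalentDiameter(123))
  expect_error(equivalentDiameter(0))
})

test_that("volume estimates converge with grid refinement", {
  errs <- vapply(list(c(0.8, 2), c(0.4, 1), c(0.2, 0.5)), function(sp) {
    lab <- sphereLabels(8.5, sp[1], sp[2])
    abs(labelVolume(lab) - sphereVol(8.5)) / sphereVol(8.5)
  }, numeric(1))
  # the discretization error bound halves with the spacing (the sampled
  # error itself fluctuates below it)
  bounds <- c(0.02, 0.01, 0.005)
  expect_true(all(errs < bounds))
})
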