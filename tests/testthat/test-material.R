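test_that("derived moduli are consistent with (E, nu) to machine precision", {
  m <- material(1800, 0.443)
  E <- youngModulus(m); nu <- poissonRatio(m)
  expect_equal(shearModulus(m), E / (2 * (1 + nu)))
  expect_equal(lameFirst(m), E * nu / ((1 + nu) * (1 - 2 * nu)))
  expect_equal(bulkModulus(m), E / (3 * (1 - 2 * nu)))
  # kappa = lambda + 2/3 mu identity
  expect_equal(bulkModulus(m), lameFirst(m) + 2 / 3 * shearModulus(m))
  expect_error(material(-1, 0.3))
  expect_error(material(1000, 0.5))
})

test_that("bulk-modulus fit recovers exact and noisy slopes", {
  s <- seq(0, 0.1, by = 0.01)
  fit <- fitBulkModulus(6200 * s, s)
  expect_equal(unname(fit["kappa"]), 6200)
  expect_equal(unname(fit["se"]), 0)
  # two points define the slope
  fit2 <- fitBulkModulus(c(0, 620), c(0, 0.1))
  expect_equal(unname(fit2["kappa"]), 6200)
  # noisy synthetic recovery within 2 SE
  set.seed(42)
  s <- runif(20, 0.01, 0.14)
  p <- 6200 * s + rnorm(20, sd = 30)
  fit3 <- fitBulkModulus(p, s)
  expect_lt(abs(fit3["kappa"] - 6200), 2 * fit3["se"])
  # scale equivariance: scaling pressures scales kappa exactly
  fit4 <- fitBulkModulus(3 * p, s)
  expect_equal(unname(fit4["kappa"]), 3 * unname(fit3["kappa"]))
})

test_that("fit respects the strain cutoff and input contracts", {
  expect_error(fitBulkModulus(c(100, 200), c(0.3, 0.4), strainCutoff = 0.15),
               "at least 2")
  expect_error(fitBulkModulus(c(-5, 10), c(0.01, 0.02)))
  # points above the cutoff are excluded from the fit
  s <- c(0.01, 0.05, 0.1, 0.5)
  p <- c(6200 * s[1:3], 99999)
  expect_equal(unname(fitBulkModulus(p, s)["kappa"]), 6200)
})

test_that("modulus relations are mutually inverse and guard nu", {
  expect_equal(youngFromBulk(6200, 0), 3 * 6200)
  expect_equal(bulkFromYoung(2100, 0), 700)
  for (nu in c(0, 0.2, 0.443, 0.49))
    expect_equal(bulkFromYoung(youngFromBulk(1234, nu), nu), 1234,
                 tolerance = 1e-12)
  m <- material(1800, 0.443)
  expect_equal(youngFromBulk(bulkModulus(m), poissonRatio(m)), 1800,
               tolerance = 1e-12)
  expect_error(youngFromBulk(6200, 0.5), "incompressible")
  expect_error(bulkFromYoung(2100, 0.6))
})
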