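test_that("profile ratio normalizes at the central axis and resamples", {
  r <- seq(0, 20, by = 0.5)
  m <- ProfileCurve(r, 1 + 0.002 * r^2)
  p <- ProfileCurve(r, rep(1, length(r)))
  # identical profiles: unit ratio
  expect_equal(ratioValues(computeRatio(p, p)), rep(1, length(r)))
  # a global scale difference is absorbed by CAX normalization
  m2 <- ProfileCurve(r, 1.05 * (1 + 0.002 * r^2))
  expect_equal(ratioValues(computeRatio(m2, ProfileCurve(r, 1 + 0.002 * r^2))),
               rep(1, length(r)), tolerance = 1e-12)
  # measured = predicted * (1 + 0.002 r^2): the ratio is that factor
  expect_equal(ratioValues(computeRatio(m, p)), 1 + 0.002 * r^2)
  # resampling: predicted on a coarser grid, ratio on measured's grid
  pc <- ProfileCurve(seq(0, 20, by = 2), rep(2, 11))
  rat <- computeRatio(m, pc)
  expect_equal(rCm(rat), r)
  # no overlap is an error
  expect_error(computeRatio(m, ProfileCurve(c(0, 0.1), c(1, 1))), "overlap")
})

test_that("polynomial fit recovers exact ratios and honours conventions", {
  r <- seq(0, 22, by = 0.25)
  # unit ratio: zero polynomial, R^2 = 1 by the zero-variance convention
  rc <- new("RatioCurve", rCm = r, ratio = rep(1, length(r)),
            orientation = "measured_over_predicted")
  corr0 <- fitCorrection(rc, 4, 0, 22)
  expect_equal(corr0@coefficients, rep(0, 5), tolerance = 1e-12)
  expect_identical(corr0@rSquared, 1)
  expect_equal(correctionFactor(corr0, c(0, 5, 15)), rep(0, 3),
               tolerance = 1e-12)
  # exact quartic: coefficients recovered to 1e-9, R^2 = 1
  co <- c(0, 2e-4, -3e-5, 1.5e-6, 2e-8)
  y <- drop(outer(r, 0:4, "^") %*% co)
  rcq <- new("RatioCurve", rCm = r, ratio = 1 + y,
             orientation = "measured_over_predicted")
  corr <- fitCorrection(rcq, 4, 0, 22)
  expect_equal(corr@coefficients, co, tolerance = 1e-9)
  expect_equal(corr@rSquared, 1)
  expect_equal(correctionFactor(corr, 13.7), sum(co * 13.7^(0:4)),
               tolerance = 1e-10)
  # failure modes
  expect_error(fitCorrection(rcq, 4, 0, 0.6), "at least 5 samples")
})

test_that("quartic fit of the noisy benchmark ratio keeps R^2 above 0.999", {
  r <- seq(0, 22, by = 0.078125)
  set.seed(11)
  noisy <- syntheticRatio(r, "envelope") * (1 + rnorm(length(r), 0, 0.001))
  noisy[1] <- 1
  rc <- new("RatioCurve", rCm = r, ratio = noisy,
            orientation = "measured_over_predicted")
  corr <- fitCorrection(rc, 4, 0, 22)
  expect_gte(corr@rSquared, 0.999)
})

test_that("correction factor is exactly zero beyond the application radius", {
  co <- c(0.001, 2e-4, -3e-5, 1.5e-6, 2e-8)
  corr <- new("PolyCorrection", coefficients = co, order = 4L,
              rFitMinCm = 0, rFitMaxCm = 11, rApplyMaxCm = 14,
              rSquared = 1, mode = "inhouse_20x20",
              ratioOrientation = "measured_over_predicted",
              applyStyle = "divide")
  expect_equal(correctionFactor(corr, 14.01), 0)
  set.seed(99)
  rOut <- runif(1000, 14 + 1e-9, 60)
  expect_identical(correctionFactor(corr, rOut), rep(0, 1000))
  rIn <- runif(1000, 0, 14)
  expect_equal(correctionFactor(corr, rIn),
               drop(outer(rIn, 0:4, "^") %*% co), tolerance = 1e-12)
  expect_error(correctionFactor(corr, -0.1), "non-negative")
})

test_that("profile correction divides, renormalizes, and can taper", {
  prof <- ProfileCurve(c(0, 10, 20), c(1, 1.05, 0.95))
  zero <- new("PolyCorrection", coefficients = rep(0, 5), order = 4L,
              rFitMinCm = 0, rFitMaxCm = 22, rApplyMaxCm = 22, rSquared = 1,
              mode = "custom", ratioOrientation = "measured_over_predicted",
              applyStyle = "divide")
  expect_equal(profileValues(applyProfileCorrection(prof, zero)),
               profileValues(prof))
  # constant c = 0.099 inside a window: divide inside, unchanged outside,
  # CAX renormalized (c(0) = 0.099 too, so the anchor divides out)
  const <- new("PolyCorrection", coefficients = c(0.099, 0, 0, 0, 0),
               order = 4L, rFitMinCm = 0, rFitMaxCm = 15, rApplyMaxCm = 15,
               rSquared = 1, mode = "custom",
               ratioOrientation = "measured_over_predicted",
               applyStyle = "divide")
  out <- applyProfileCorrection(prof, const)
  expect_equal(profileValues(out)[1], 1)
  expect_equal(profileValues(out)[2], 1.05)            # same factor as CAX
  expect_equal(profileValues(out)[3], 0.95 * 1.099)    # outside: only renorm
  # multiply style inverts the operation
  constM <- const; constM@applyStyle <- "multiply"
  outM <- applyProfileCorrection(prof, constM)
  expect_equal(profileValues(outM)[3], 0.95 / 1.099)
  # catastrophic corrections refuse to apply
  bad <- const; bad@coefficients[1] <- -1.5
  expect_error(applyProfileCorrection(prof, bad), "non-positive")
  # taper: at the application edge the correction ramps to zero
  profF <- ProfileCurve(seq(0, 20, 0.5), rep(1, 41))
  outT <- applyProfileCorrection(profF, const, taperCm = 1)
  cf <- correctionFactor(const, seq(0, 20, 0.5))
  w <- pmin(pmax((15 - seq(0, 20, 0.5)) / 1, 0), 1)
  expect_equal(profileValues(outT), (1 / (1 + cf * w)) / (1 / (1 + 0.099)))
})

test_that("derivation modes carry the documented constants", {
  r <- seq(0, 25, by = 0.25)
  m <- ProfileCurve(r, (1 + 0.0001 * r^2) * (1 - 0.002 * r / 25))
  p <- ProfileCurve(r, 1 + 0.0001 * r^2)
  c20 <- deriveCorrection("inhouse_20x20", m, p)
  expect_equal(c20@order, 4L)
  expect_equal(c(c20@rFitMinCm, c20@rFitMaxCm, c20@rApplyMaxCm),
               c(0, 11, 14))
  cb <- deriveCorrection("bailey", m, p)
  expect_equal(cb@order, 1L)
  expect_equal(c(cb@rFitMinCm, cb@rFitMaxCm), c(10, 25))
  cl <- deriveCorrection("inhouse_large", m, p)
  expect_equal(c(cl@order, cl@rFitMaxCm, cl@rApplyMaxCm), c(4, 22, 22))
  # identical profiles: the correction is numerically zero and applying it
  # is the identity map
  cz <- deriveCorrection("inhouse_large", p, p)
  expect_lt(max(abs(correctionFactor(cz, seq(0, 22, 0.1)))), 1e-9)
  out <- applyProfileCorrection(p, cz)
  expect_equal(profileValues(out), profileValues(p) / profileValues(p)[1],
               tolerance = 1e-9)
})

test_that("ratio orientation flips the correction and both apply styles agree", {
  r <- seq(0, 22, by = 0.25)
  rho <- 1 + 2e-4 * r^2
  m <- ProfileCurve(r, rho)
  p <- ProfileCurve(r, rep(1, length(r)))
  cMP <- deriveCorrection("inhouse_large", m, p)
  cPM <- deriveCorrection("inhouse_large", m, p,
                          orientation = "predicted_over_measured")
  # measured/predicted fits rho - 1; predicted/measured fits 1/rho - 1
  expect_equal(correctionFactor(cMP, 15), rho[r == 15] - 1, tolerance = 1e-6)
  # quartic truncation of 1/rho leaves a small but nonzero fit residual
  expect_equal(correctionFactor(cPM, 15), 1 / rho[r == 15] - 1,
               tolerance = 1e-4)
  # dividing by (1 + cMP) equals multiplying by (1 + cPM) up to O(fit error)
  cPMmult <- cPM; cPMmult@applyStyle <- "multiply"
  prof <- ProfileCurve(r, 1 + 0.0005 * r^2)
  expect_equal(profileValues(applyProfileCorrection(prof, cMP)),
               profileValues(applyProfileCorrection(prof, cPMmult)),
               tolerance = 1e-5)
})

test_that("synthetic ratio curves span their documented ranges", {
  r <- seq(0, 22, by = 0.01)
  over <- syntheticRatio(r, "overresponse") - 1
  expect_equal(min(over), -0.004, tolerance = 1e-4)
  expect_equal(max(over), 0.099, tolerance = 2e-3)
  env <- syntheticRatio(r, "envelope") - 1
  expect_equal(min(env), -0.1, tolerance = 1e-4)
  expect_lt(max(abs(env)), 0.1 + 1e-6)
})
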