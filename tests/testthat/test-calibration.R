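flatProfile <- function(rMax = 30) ProfileCurve(c(0, rMax), c(1, 1))

makeCal <- function(dark, flood, profile = flatProfile(), pitch = 10) {
  CalibrationSet(ImageGrid(dark, pitch), ImageGrid(flood, pitch), profile)
}

test_that("dark/flood correction matches hand arithmetic", {
  # worked 2x2 case: (raw - 1) / 3, rescaled by mean(flood - dark) = 3
  cal <- makeCal(matrix(1, 2, 2), matrix(4, 2, 2))
  raw <- ImageGrid(matrix(c(10, 14, 12, 16), 2, 2), 10)
  out <- applyDarkFlood(raw, cal)
  expect_equal(imageValues(out), matrix(c(9, 13, 11, 15), 2, 2))
  # raw == flood divides itself out to a uniform mean(flood - dark)
  expect_equal(imageValues(applyDarkFlood(ImageGrid(matrix(4, 2, 2), 10), cal)),
               matrix(3, 2, 2))
  # raw == dark maps to zero
  expect_equal(imageValues(applyDarkFlood(ImageGrid(matrix(1, 2, 2), 10), cal)),
               matrix(0, 2, 2))
})

test_that("dark/flood correction rejects bad geometry and bad calibration", {
  cal <- makeCal(matrix(1, 2, 2), matrix(4, 2, 2))
  expect_error(applyDarkFlood(ImageGrid(matrix(1, 3, 2), 10), cal),
               "geometry")
  flood <- matrix(4, 2, 2); flood[2, 1] <- 1  # flood - dark = 0 there
  expect_error(makeCal(matrix(1, 2, 2), flood), "row 2, col 1")
})

test_that("beam-profile restoration scales pixels by their radial distance", {
  g <- ImageGrid(matrix(1, 96, 128), pitchMm = 3.125)
  # constant profile: identity
  expect_equal(imageValues(restoreBeamProfile(g, flatProfile())),
               imageValues(g))
  # linear profile 1 + 0.01 r: exact under linear interpolation
  prof <- ProfileCurve(seq(0, 26, by = 0.5), 1 + 0.01 * seq(0, 26, by = 0.5))
  out <- restoreBeamProfile(g, prof)
  rmap <- radialDistanceMap(g)
  expect_equal(imageValues(out), 1 + 0.01 * rmap, tolerance = 1e-12)
  # CAX readout moves only by the sub-pixel interpolation of the profile
  # (the beam axis falls between pixels on an even grid)
  expect_equal(caxValue(out), 1, tolerance = 5e-3)
  # corner pixel near 25 cm scaled by ~1.25
  expect_equal(max(imageValues(out)), 1 + 0.01 * max(rmap))
  # short profile: clamped with warning, or an error on request
  short <- ProfileCurve(c(0, 10), c(1, 1.1))
  expect_warning(restoreBeamProfile(g, short), "clamping")
  expect_error(restoreBeamProfile(g, short, extrapolate = "error"), "covers")
})

test_that("CU calibration is the reciprocal CAX and scales linearly", {
  cal <- makeCal(matrix(0, 2, 2), matrix(1, 2, 2))
  ref <- ImageGrid(matrix(2, 2, 2), 10)
  cal2 <- calibrateCU(ref, cal)
  expect_equal(cal2@cuScale, 0.5)
  expect_equal(calibrateCU(ImageGrid(matrix(1, 2, 2), 10), cal)@cuScale, 1)
  out <- doseCalibrate(ref, cal2)
  expect_equal(imageValues(out), matrix(1, 2, 2))
  # linearity and zero preservation
  expect_equal(imageValues(doseCalibrate(ImageGrid(matrix(4, 2, 2), 10), cal2)),
               matrix(2, 2, 2))
  expect_equal(imageValues(doseCalibrate(ImageGrid(matrix(0, 2, 2), 10), cal2)),
               matrix(0, 2, 2))
  expect_error(doseCalibrate(ref, cal), "calibrateCU")
  expect_error(calibrateCU(ImageGrid(matrix(0, 2, 2), 10), cal), "positive")
})

test_that("simulated reference delivery reads exactly 1 CU on the beam axis", {
  cfg <- smallPanelConfig()
  inputs <- makeCalibrationInputs(cfg, "f40x30")
  cal <- CalibrationSet(inputs$dark, inputs$flood, beamProfileCurve(cfg))
  cal <- calibrateCU(processImage(inputs$reference, cal, toCU = FALSE), cal)
  cu <- processImage(inputs$reference, cal)
  expect_equal(caxValue(cu), 1, tolerance = 1e-9)
})

test_that("2D correction map multiplies element-wise and matches the profile path", {
  g <- ImageGrid(matrix(1:4, 2, 2), 10)
  expect_equal(imageValues(apply2DCorrection(g, matrix(1, 2, 2))),
               imageValues(g))
  chk <- matrix(c(2, 1, 1, 2), 2, 2)
  expect_equal(imageValues(apply2DCorrection(g, chk)), imageValues(g) * chk)
  expect_error(apply2DCorrection(g, matrix(1, 3, 2)), "geometry")
  # a radially evaluated profile map reproduces restoreBeamProfile exactly
  img <- ImageGrid(matrix(runif(96 * 128, 0.5, 1), 96, 128), 3.125)
  prof <- ProfileCurve(seq(0, 26, by = 0.25),
                       1 + 0.004 * seq(0, 26, by = 0.25)^1.5 / 10)
  rmap <- radialDistanceMap(img)
  mp <- matrix(profileValueAt(prof, as.vector(rmap)), 96, 128)
  expect_equal(imageValues(apply2DCorrection(img, mp)),
               imageValues(restoreBeamProfile(img, prof)),
               tolerance = 1e-12)
})

test_that("the chain cancels the flood field and preserves CU through a round trip", {
  cfg <- smallPanelConfig(noiseSigma = 0)
  inputs <- makeCalibrationInputs(cfg, "f40x30")
  cal <- CalibrationSet(inputs$dark, inputs$flood, flatProfile())
  # processing the flood itself with a flat profile gives a uniform image
  out <- applyDarkFlood(inputs$flood, cal)
  v <- imageValues(out)
  expect_lt(diff(range(v)) / mean(v), 1e-9)
  # CU round trip holds for arbitrary simulator settings
  cfg2 <- smallPanelConfig(backscatterAmplitude = 0.08, noiseSigma = 0.004,
                           darkLevel = 0.05)
  inputs2 <- makeCalibrationInputs(cfg2, "f20x20")
  cal2 <- CalibrationSet(inputs2$dark, inputs2$flood, beamProfileCurve(cfg2))
  cal2 <- calibrateCU(processImage(inputs2$reference, cal2, toCU = FALSE), cal2)
  expect_equal(caxValue(processImage(inputs2$reference, cal2)), 1,
               tolerance = 1e-9)
})
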