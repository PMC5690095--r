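test_that("the simulator is deterministic for a fixed configuration", {
  cfg <- smallPanelConfig()
  fl <- makeFieldFluence(cfg, 5, 5, 5, 5)
  a <- simulateRaw(fl, cfg, noiseStream = 3L)
  b <- simulateRaw(fl, cfg, noiseStream = 3L)
  expect_identical(imageValues(a), imageValues(b))
  # distinct noise streams differ, but structure maps are shared
  c <- simulateRaw(fl, cfg, noiseStream = 4L)
  expect_false(identical(imageValues(a), imageValues(c)))
  in1 <- makeCalibrationInputs(cfg, "f40x30")
  in2 <- makeCalibrationInputs(cfg, "f40x30")
  expect_identical(imageValues(in1$flood), imageValues(in2$flood))
  # the simulator leaves the caller's RNG state untouched
  set.seed(123); before <- .Random.seed
  invisible(simulateRaw(fl, cfg, noiseStream = 9L))
  expect_identical(before, .Random.seed)
})

test_that("with every distortion disabled the measurement equals the prediction", {
  cfg <- smallPanelConfig(backscatterAmplitude = 0, noiseSigma = 0,
                          sensitivitySigma = 0, darkLevel = 0,
                          overresponseParams = c(0, 0))
  fl <- makeFieldFluence(cfg, 7, 7, 7, 7)
  raw <- simulateRaw(fl, cfg)
  pred <- simulatePredicted(fl, cfg)
  expect_equal(imageValues(raw), imageValues(pred), tolerance = 1e-15)
  # and the gamma comparison passes everywhere
  res <- gammaIndex(pred, raw, GammaParams(lowDoseThresholdPct = 10))
  expect_equal(passRatePct(res), 100)
})

test_that("field fluences have the right extent, CAX value and floor", {
  cfg <- smallPanelConfig()
  f10 <- makeFieldFluence(cfg, 5, 5, 5, 5)
  expect_equal(caxValue(f10), 1)
  co <- pixelCoordinatesCm(f10)
  v <- imageValues(f10)
  inside <- outer(abs(co$y) < 4.5, abs(co$x) < 4.5, "&")
  outside <- outer(abs(co$y) > 5.5, abs(co$x) > 5.5, "&")
  expect_true(all(v[inside] == 1))
  expect_true(all(v[outside] == cfg@transmission))
  # the large calibration-check field reaches +/-19 x +/-14 cm
  f38 <- makeFieldFluence(cfg, 19, 19, 14, 14)
  v38 <- imageValues(f38)
  expect_true(all(v38[outer(abs(co$y) < 13.5, abs(co$x) < 18.5, "&")] == 1))
  expect_lt(v38[which.min(abs(co$y - 0)), which.min(abs(co$x + 19.5))], 1)
  expect_error(makeFieldFluence(cfg, 25, 25, 14, 14), "outside the panel")
  # split pattern: reduced intensity on the X2 half and a junction dip
  fs <- makeFieldFluence(cfg, 12, 12, 11, 11, pattern = "split_imrt")
  vs <- imageValues(fs)
  jy <- which.min(abs(co$y - 5))
  expect_lt(vs[jy, which.min(abs(co$x - 8))],
            vs[jy, which.min(abs(co$x + 8))])
  # pyramid pattern: monotone steps from the centre outward
  fp <- makeFieldFluence(cfg, 12, 12, 12, 12, pattern = "pyramid")
  vp <- imageValues(fp)
  expect_equal(caxValue(fp), 1)
  expect_equal(vp[jy <- which.min(abs(co$y)), which.min(abs(co$x - 11))],
               0.4, tolerance = 0.2)
})

test_that("predicted images are radially symmetric for symmetric fluences", {
  cfg <- smallPanelConfig()
  fl <- makeFieldFluence(cfg, 8, 8, 8, 8)
  pred <- simulatePredicted(fl, cfg)
  expect_equal(imageValues(pred), rot180(imageValues(pred)), tolerance = 1e-12)
  expect_equal(caxValue(simulatePredicted(makeFieldFluence(cfg, 5, 5, 5, 5),
                                          cfg)), 1, tolerance = 1e-4)
})

test_that("flood-corrected small fields under-respond on the gantry side by 1-3%", {
  cfg <- simConfig()  # full panel, default conditions
  built <- buildCalibration("uncorrected", cfg)
  fl <- makeFieldFluence(cfg, 5, 5, 5, 5)
  m <- processImage(simulateRaw(fl, cfg, noiseStream = 7L), built$cal)
  co <- pixelCoordinatesCm(m)
  v <- imageValues(m)
  selx <- abs(co$x) < 2
  yprof <- rowMeans(v[, selx])          # x-averaged radial (Y) profile
  for (ytest in c(3, 4, 4.5)) {
    gantry <- yprof[which.min(abs(co$y - ytest))]
    mirror <- yprof[which.min(abs(co$y + ytest))]
    deficit <- 1 - gantry / mirror
    expect_gt(deficit, 0.01)
    expect_lt(deficit, 0.03)
  }
})

test_that("the large-field diagonal ratio rises to about +10% near 22 cm", {
  cfg <- simConfig()
  built <- buildCalibration("uncorrected", cfg)
  fl <- makeFieldFluence(cfg, 19, 19, 14, 14)
  m <- processImage(simulateRaw(fl, cfg, noiseStream = 8L), built$cal)
  p <- simulatePredicted(fl, cfg)
  n <- 221L
  rat <- computeRatio(extractDiagonalProfile(m, n, 22),
                      extractDiagonalProfile(p, n, 22))
  rv <- ratioValues(rat); r <- rCm(rat)
  expect_gt(rv[which.min(abs(r - 22))], 1.08)
  expect_lt(rv[which.min(abs(r - 22))], 1.12)
  # monotone rise over the outer window (smoothed against pixel noise)
  sm <- stats::filter(rv, rep(1 / 5, 5), sides = 2)
  idx <- which(r > 15 & r < 21.5)
  expect_true(all(diff(sm[idx]) > -0.002))
})

test_that("a 20x20 flood embeds less arm backscatter than a 40x30 flood", {
  cfg <- smallPanelConfig(noiseSigma = 0)
  cfg0 <- smallPanelConfig(noiseSigma = 0, backscatterAmplitude = 0)
  fl40 <- makeFieldFluence(cfg, 20 - 1e-6, 20 - 1e-6, 15 - 1e-6, 15 - 1e-6)
  fl20 <- makeFieldFluence(cfg, 10, 10, 10, 10)
  bs40 <- imageValues(simulateRaw(fl40, cfg)) -
          imageValues(simulateRaw(fl40, cfg0))
  bs20 <- imageValues(simulateRaw(fl20, cfg)) -
          imageValues(simulateRaw(fl20, cfg0))
  expect_lt(mean(bs20), mean(bs40))
  expect_lt(mean(bs20) / mean(bs40), 0.5)
  # backscatter lives on the gantry half only
  co <- pixelCoordinatesCm(fl40)
  expect_equal(max(abs(bs40[co$y < 0, ])), 0)
  expect_gt(mean(bs40[co$y > 5, ]), 0)
})
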