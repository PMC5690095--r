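# Parametric synthetic EPID image generator. The physics terms (horn shape,
# residual over-response, backscatter kernel, sensitivity map) are labelled
# stand-ins calibrated to published effect magnitudes (a few percent of horn
# structure, 2-3% gantry-side asymmetry for small square fields, up to ~10%
# off-axis over-response); they make no claim to reproduce any vendor's
# hardware.

evalEvenPoly <- function(coef2, r) 1 + coef2[1] * r^2 + coef2[2] * r^4

emptyGrid <- function(config) {
  ImageGrid(matrix(0, config@nY, config@nX), config@pitchMm)
}

# run fn() under a temporary, seeded RNG state, restoring the caller's state
withSimSeed <- function(seed, fn) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed %% .Machine$integer.max)
  fn()
}

# Smooth unit-mean sensitivity map: coarse seeded Gaussian grid, bilinearly
# upsampled to the panel.
sensitivityMap <- function(config, sigma = config@sensitivitySigma,
                           coarse = c(6L, 8L)) {
  if (sigma == 0) return(matrix(1, config@nY, config@nX))
  withSimSeed(config@sensitivitySeed, function() {
    z <- matrix(stats::rnorm(prod(coarse), 0, sigma), coarse[1], coarse[2])
    rj <- seq(1, coarse[1], length.out = config@nY)
    ci <- seq(1, coarse[2], length.out = config@nX)
    j0 <- pmin(floor(rj), coarse[1] - 1L); fj <- rj - j0
    i0 <- pmin(floor(ci), coarse[2] - 1L); fi <- ci - i0
    up <- z[j0, i0] * outer(1 - fj, 1 - fi) +
          z[j0, i0 + 1L] * outer(1 - fj, fi) +
          z[j0 + 1L, i0] * outer(fj, 1 - fi) +
          z[j0 + 1L, i0 + 1L] * outer(fj, fi)
    1 + up
  })
}

# Fixed dark-signal pattern: mean darkLevel with a 10% smooth seeded ripple.
darkPattern <- function(config) {
  if (config@darkLevel == 0) return(matrix(0, config@nY, config@nX))
  s <- sensitivityMap(simConfig(nX = config@nX, nY = config@nY,
                                pitchMm = config@pitchMm,
                                sensitivitySeed = config@sensitivitySeed + 1L),
                      sigma = 0.1)
  config@darkLevel * s
}

# Arm-backscatter shape: zero on the non-gantry half, concave rise
# sqrt(y / extent) on the gantry (+Y) side, clipped at 1. The concave rise is
# calibrated so that with the default 3% amplitude a 10x10 field shows a
# ~1.5% gantry-side deficit after flood correction and an 18x18 field ~2%,
# matching the published 2-3% scale for sub-20x20 square fields.
backscatterShape <- function(config) {
  p <- config@pitchMm / 10
  exY <- config@nY * p
  y <- exY / 2 - (seq_len(config@nY) - 0.5) * p
  ramp <- pmin(sqrt(pmax(y, 0) / config@backscatterExtentCm), 1)
  matrix(ramp, config@nY, config@nX)
}

#' Build a field fluence
#'
#' Jaw positions follow the X1/X2/Y1/Y2 convention: the field spans
#' `[-x1Cm, x2Cm]` along X and `[-y1Cm, y2Cm]` along Y. The penumbra is a
#' 3 mm linear ramp; outside the jaws a jaw-transmission floor
#' (`config@transmission`) remains. Patterns:
#' \describe{
#'   \item{`open`}{uniform fluence 1 inside the jaws.}
#'   \item{`split_imrt`}{two abutting half fields split at x = 0, the X2 half
#'     at 97% intensity, with a 5% under-dosed 1 cm junction band — the
#'     signature of a split-field delivery.}
#'   \item{`pyramid`}{three concentric intensity steps (1.0 / 0.7 / 0.4 from
#'     the centre outward).}
#' }
#'
#' @param config a [SimConfig-class].
#' @param x1Cm,x2Cm,y1Cm,y2Cm jaw half-extents, cm (all positive).
#' @param pattern `"open"`, `"split_imrt"` or `"pyramid"`.
#' @return An [ImageGrid-class] fluence with 1 at the central axis for open
#'   fields.
#' @examples
#' cfg <- simConfig()
#' f <- makeFieldFluence(cfg, 5, 5, 5, 5)    # a 10x10 open field
#' caxValue(f)
#' @export
makeFieldFluence <- function(config, x1Cm, x2Cm, y1Cm, y2Cm,
                             pattern = c("open", "split_imrt", "pyramid")) {
  stopifnot(is(config, "SimConfig"))
  pattern <- match.arg(pattern)
  if (any(c(x1Cm, x2Cm, y1Cm, y2Cm) <= 0))
    stop("jaw half-extents must be positive")
  p <- config@pitchMm / 10
  exX <- config@nX * p; exY <- config@nY * p
  if (x1Cm > exX / 2 + 1e-9 || x2Cm > exX / 2 + 1e-9 ||
      y1Cm > exY / 2 + 1e-9 || y2Cm > exY / 2 + 1e-9)
    stop("field extends outside the panel")
  x <- (seq_len(config@nX) - 0.5) * p - exX / 2
  y <- exY / 2 - (seq_len(config@nY) - 0.5) * p
  ramp <- 0.3  # 3 mm penumbra
  inside1d <- function(t, lo, hi) {
    pmin(pmax((t - lo) / ramp + 0.5, 0), 1) *
      pmin(pmax((hi - t) / ramp + 0.5, 0), 1)
  }
  fx <- inside1d(x, -x1Cm, x2Cm)
  fy <- inside1d(y, -y1Cm, y2Cm)
  fl <- outer(fy, fx)
  if (pattern == "split_imrt") {
    xm <- matrix(x, config@nY, config@nX, byrow = TRUE)
    mod <- ifelse(xm > 0, 0.97, 1)
    mod <- mod * (1 - 0.05 * pmax(0, 1 - abs(xm) / 0.5))
    fl <- fl * mod
  } else if (pattern == "pyramid") {
    xm <- matrix(abs(x), config@nY, config@nX, byrow = TRUE)
    ym <- matrix(abs(y), config@nY, config@nX)
    fracx <- pmax(xm / max(x1Cm, x2Cm), ym / max(y1Cm, y2Cm))
    lev <- ifelse(fracx < 1 / 3, 1, ifelse(fracx < 2 / 3, 0.7, 0.4))
    fl <- fl * lev
  }
  ImageGrid(pmax(fl, config@transmission), config@pitchMm)
}

#' Simulate the predicted portal image
#'
#' The prediction surrogate: fluence times the radially symmetric beam
#' profile P(r), noise-free, so that an open 10x10 reference field has value
#' 1.0 at the central axis. It assumes a perfectly radially symmetric
#' detector response — exactly the assumption whose violation the
#' measurement-side corrections address.
#'
#' @param fluence an [ImageGrid-class] from [makeFieldFluence()].
#' @param config a [SimConfig-class].
#' @return An [ImageGrid-class].
#' @export
simulatePredicted <- function(fluence, config) {
  stopifnot(is(fluence, "ImageGrid"), is(config, "SimConfig"))
  r <- radialDistanceMap(fluence)
  ImageGrid(fluence@values * evalEvenPoly(config@hornParams, r),
            config@pitchMm)
}

#' Simulate a raw (uncalibrated) portal image
#'
#' The measurement surrogate:
#' \deqn{raw = [F \cdot P(r) \cdot \rho(r) \cdot S(x,y) \cdot mu/100
#'   + B(x,y) \cdot cov(F) + D(x,y)] \times (1 + \epsilon)}
#' where P is the beam-horn profile, \eqn{\rho} the residual radial
#' over-response (the component flood correction cannot remove), S the
#' smooth seeded sensitivity map, B the gantry-side arm-backscatter map
#' scaled by the fraction of the panel the field covers (a full flood field
#' embeds more backscatter than a small field, which is what makes
#' flood-corrected small fields under-respond on the gantry side), D the
#' fixed dark pattern and \eqn{\epsilon} per-pixel Gaussian noise.
#'
#' @param fluence an [ImageGrid-class].
#' @param config a [SimConfig-class].
#' @param mu delivered monitor units (default 100; the signal scales
#'   linearly).
#' @param includeOverresponse include the residual over-response
#'   \eqn{\rho(r)} (default `TRUE`; `FALSE` for flood acquisitions, whose
#'   spectrum defines the baseline response).
#' @param includeBackscatter include the arm-backscatter term.
#' @param noiseStream integer offset added to the noise seed so distinct
#'   acquisitions carry independent (but reproducible) noise.
#' @return An [ImageGrid-class] in raw signal units.
#' @export
simulateRaw <- function(fluence, config, mu = 100,
                        includeOverresponse = TRUE,
                        includeBackscatter = TRUE, noiseStream = 0L) {
  stopifnot(is(fluence, "ImageGrid"), is(config, "SimConfig"))
  r <- radialDistanceMap(fluence)
  sig <- fluence@values * evalEvenPoly(config@hornParams, r) * (mu / 100)
  if (includeOverresponse)
    sig <- sig * evalEvenPoly(config@overresponseParams, r)
  sig <- sig * sensitivityMap(config)
  if (includeBackscatter && config@backscatterAmplitude > 0) {
    coverage <- mean(fluence@values)
    sig <- sig + config@backscatterAmplitude * coverage *
      backscatterShape(config) * (mu / 100)
  }
  sig <- sig + darkPattern(config)
  if (config@noiseSigma > 0) {
    noise <- withSimSeed(config@noiseSeed + as.integer(noiseStream), function()
      matrix(stats::rnorm(length(sig), 0, config@noiseSigma),
             nrow(sig), ncol(sig)))
    sig <- sig * (1 + noise)
  }
  ImageGrid(sig, config@pitchMm)
}

floodJaws <- function(config, floodField) {
  p <- config@pitchMm / 10
  half <- c(config@nX, config@nY) * p / 2
  jaws <- switch(floodField,
                 f40x30 = c(20, 20, 15, 15),
                 f40x32 = c(20, 20, 16, 16),
                 f20x20 = c(10, 10, 10, 10),
                 stop(sprintf("unknown flood field '%s'", floodField)))
  # clip to the panel (the 40x32 flood overshoots the 30 cm panel height)
  pmin(jaws, c(half[1], half[1], half[2], half[2]) - 1e-9)
}

#' Generate dark, flood and reference calibration acquisitions
#'
#' @param config a [SimConfig-class].
#' @param floodField flood-field size: `"f40x30"` (standard), `"f40x32"`
#'   (clipped to the 40 x 30 panel) or `"f20x20"`.
#' @return A list with [ImageGrid-class] entries `dark`, `flood` (raw
#'   open-beam acquisition, without the residual over-response term — the
#'   flood beam defines the baseline response) and `reference` (raw 10x10,
#'   100 MU delivery), plus `floodField`.
#' @export
makeCalibrationInputs <- function(config,
                                  floodField = c("f40x30", "f40x32",
                                                 "f20x20")) {
  stopifnot(is(config, "SimConfig"))
  floodField <- match.arg(floodField)
  jaws <- floodJaws(config, floodField)
  floodFl <- makeFieldFluence(config, jaws[1], jaws[2], jaws[3], jaws[4],
                              pattern = "open")
  dark <- darkPattern(config)
  if (config@noiseSigma > 0) {
    noise <- withSimSeed(config@noiseSeed + 101L, function()
      matrix(stats::rnorm(length(dark), 0, config@noiseSigma),
             nrow(dark), ncol(dark)))
    dark <- dark * (1 + noise)
  }
  flood <- simulateRaw(floodFl, config, includeOverresponse = FALSE,
                       noiseStream = 102L)
  refFl <- makeFieldFluence(config, 5, 5, 5, 5, pattern = "open")
  reference <- simulateRaw(refFl, config, mu = 100, noiseStream = 103L)
  list(dark = ImageGrid(dark, config@pitchMm), flood = flood,
       reference = reference, floodField = floodField)
}

#' Sample the configured beam profile as a ProfileCurve
#'
#' The diagonal beam profile a clinic would take from commissioning data
#' (e.g. a water-tank diagonal scan), here generated from the simulator's
#' horn polynomial. Used as `beamProfile` in a [CalibrationSet-class].
#'
#' @param config a [SimConfig-class].
#' @param rMaxCm last tabulated radius (default 25, the panel half-diagonal).
#' @param by sample spacing in cm (default one pixel pitch).
#' @return A [ProfileCurve-class] anchored at r = 0 with value 1.
#' @export
beamProfileCurve <- function(config, rMaxCm = 25, by = config@pitchMm / 10) {
  r <- seq(0, rMaxCm, by = by)
  ProfileCurve(r, evalEvenPoly(config@hornParams, r))
}
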