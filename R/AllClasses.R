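#' @import methods
NULL

#' ImageGrid: a portal image with physical panel geometry
#'
#' A 2D array of pixel values together with the pixel pitch of the panel.
#' The physical axis convention is +X toward patient left and +Y toward the
#' gantry side of the EPID; the beam axis maps to the panel centre, i.e. the
#' continuous pixel coordinate \eqn{((n_x-1)/2, (n_y-1)/2)}. Pixel centres sit
#' at \eqn{x_i = (i + 0.5)\,p - L_x/2} (0-based index \eqn{i}, pitch \eqn{p},
#' extent \eqn{L_x}), so the centre of an even-dimensioned panel falls between
#' pixels, as on real 512x384 hardware.
#'
#' Values are stored as a matrix with `nY(x)` rows and `nX(x)` columns; row 1
#' is the gantry-side (+Y) edge and column 1 the patient-right (-X) edge,
#' matching the CSV layout written by [writeImageCSV()].
#'
#' @slot values numeric matrix of pixel values (signal units or CU). All
#'   values must be finite; small negative values can legitimately arise from
#'   dark-field subtraction of noisy frames.
#' @slot pitchMm single positive numeric, pixel pitch in mm (square pixels).
#'
#' @seealso [ImageGrid()], [radialDistanceMap()], [extractDiagonalProfile()]
#' @export
setClass("ImageGrid",
  representation(values = "matrix", pitchMm = "numeric"))

setValidity("ImageGrid", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("'values' must be a numeric matrix")
  if (nrow(v) < 1L || ncol(v) < 1L) return("'values' must have positive dimensions")
  if (any(!is.finite(v))) return("'values' must be finite")
  if (length(object@pitchMm) != 1L || !is.finite(object@pitchMm) ||
      object@pitchMm <= 0) return("'pitchMm' must be a single positive number")
  TRUE
})

#' Construct an ImageGrid
#'
#' @param values numeric matrix (rows = Y from the gantry side downward,
#'   columns = X from patient right to patient left).
#' @param pitchMm pixel pitch in mm (identical along both axes).
#' @return An [ImageGrid-class] object.
#' @examples
#' g <- ImageGrid(matrix(1, 384, 512), pitchMm = 0.78125)
#' nX(g); nY(g)
#' @export
ImageGrid <- function(values, pitchMm) {
  if (is.data.frame(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  new("ImageGrid", values = values, pitchMm = as.numeric(pitchMm))
}

#' ProfileCurve: a sampled 1D radial profile
#'
#' A 1D function of diagonal off-axis distance r (cm) giving relative signal
#' P(r). Distances are strictly increasing and non-negative; values are
#' strictly positive. Profiles anchored at the central axis have
#' `rCm(x)[1] == 0`.
#'
#' @slot rCm strictly increasing numeric vector of off-axis distances (cm).
#' @slot value positive numeric vector of relative signal, same length.
#' @seealso [ProfileCurve()], [extractDiagonalProfile()], [profileValueAt()]
#' @export
setClass("ProfileCurve",
  representation(rCm = "numeric", value = "numeric"))

setValidity("ProfileCurve", function(object) {
  r <- object@rCm; v <- object@value
  if (length(r) < 2L) return("a profile needs at least two samples")
  if (length(r) != length(v)) return("'rCm' and 'value' lengths differ")
  if (any(!is.finite(r)) || any(!is.finite(v))) return("samples must be finite")
  if (any(r < 0)) return("'rCm' must be non-negative")
  if (any(diff(r) <= 0)) return("'rCm' must be strictly increasing")
  if (any(v <= 0)) return("'value' must be strictly positive")
  TRUE
})

#' Construct a ProfileCurve
#'
#' @param rCm strictly increasing distances from the beam axis (cm, >= 0).
#' @param value positive relative signal at each distance.
#' @return A [ProfileCurve-class] object.
#' @examples
#' ProfileCurve(c(0, 5, 10, 20), c(1, 1.01, 1.03, 0.99))
#' @export
ProfileCurve <- function(rCm, value) {
  new("ProfileCurve", rCm = as.numeric(rCm), value = as.numeric(value))
}

#' RatioCurve: measured/predicted diagonal-profile ratio
#'
#' The ratio of two central-axis-normalized diagonal profiles, sampled on a
#' common r grid. When the grid is anchored at r = 0 the ratio there is 1 by
#' construction (both inputs are renormalized at the central axis).
#'
#' @slot rCm increasing distances (cm).
#' @slot ratio positive ratio values.
#' @slot orientation `"measured_over_predicted"` or
#'   `"predicted_over_measured"`.
#' @seealso [computeRatio()], [fitCorrection()]
#' @export
setClass("RatioCurve",
  representation(rCm = "numeric", ratio = "numeric", orientation = "character"))

setValidity("RatioCurve", function(object) {
  r <- object@rCm; v <- object@ratio
  if (length(r) != length(v)) return("'rCm' and 'ratio' lengths differ")
  if (length(r) < 2L) return("a ratio curve needs at least two samples")
  if (any(diff(r) <= 0)) return("'rCm' must be strictly increasing")
  if (any(v <= 0)) return("'ratio' must be strictly positive")
  if (r[1] == 0 && abs(v[1] - 1) > 1e-9)
    return("ratio at r = 0 must equal 1 (central-axis normalization)")
  if (!object@orientation %in% c("measured_over_predicted",
                                 "predicted_over_measured"))
    return("unknown 'orientation'")
  TRUE
})

#' PolyCorrection: a polynomial off-axis correction c(r)
#'
#' The correction factor is a polynomial in diagonal off-axis distance r,
#' fitted over `[rFitMinCm, rFitMaxCm]` and applied only up to `rApplyMaxCm`:
#' beyond that radius the correction is exactly zero (hard cutoff).
#'
#' @slot coefficients numeric, polynomial coefficients of c(r), constant term
#'   first, length `order + 1`.
#' @slot order polynomial order (4 for the in-house modes, 1 for Bailey mode).
#' @slot rFitMinCm,rFitMaxCm fit window (cm).
#' @slot rApplyMaxCm application limit (cm); `correctionFactor()` is 0 beyond.
#' @slot rSquared coefficient of determination of the fit, in [0, 1].
#' @slot mode character label (`"inhouse_large"`, `"inhouse_20x20"`,
#'   `"bailey"` or `"custom"`).
#' @slot ratioOrientation orientation of the ratio the fit was derived from.
#' @slot applyStyle `"divide"` (profile / (1 + c)) or `"multiply"`
#'   (profile * (1 + c)).
#' @seealso [fitCorrection()], [correctionFactor()], [applyProfileCorrection()]
#' @export
setClass("PolyCorrection",
  representation(coefficients = "numeric", order = "integer",
    rFitMinCm = "numeric", rFitMaxCm = "numeric", rApplyMaxCm = "numeric",
    rSquared = "numeric", mode = "character", ratioOrientation = "character",
    applyStyle = "character"))

setValidity("PolyCorrection", function(object) {
  if (length(object@coefficients) != object@order + 1L)
    return("'coefficients' must have length order + 1")
  if (object@order < 0L) return("'order' must be non-negative")
  if (object@rApplyMaxCm <= 0) return("'rApplyMaxCm' must be positive")
  if (object@rFitMinCm < 0 || object@rFitMaxCm <= object@rFitMinCm)
    return("fit window must satisfy 0 <= rFitMinCm < rFitMaxCm")
  if (!is.na(object@rSquared) &&
      (object@rSquared < 0 || object@rSquared > 1))
    return("'rSquared' must lie in [0, 1]")
  if (!object@applyStyle %in% c("divide", "multiply"))
    return("'applyStyle' must be 'divide' or 'multiply'")
  TRUE
})

#' CalibrationSet: dark field, flood field, beam profile and CU scale
#'
#' Holds everything the portal-dose calibration chain needs: the dark-field
#' image (background signal), the flood-field image (open-beam sensitivity),
#' the diagonal beam profile used to restore the horns (normalized to 1 at
#' r = 0), the signal-to-CU scale factor, and optionally a generic 2D
#' multiplicative correction map that replaces the profile restoration.
#'
#' One calibrated unit (CU) is defined so that the central-axis value of a
#' fully processed 100 MU, 10x10 cm2 reference delivery reads 1.0 CU.
#'
#' @slot dark,flood [ImageGrid-class] objects sharing geometry; `flood - dark`
#'   must be strictly positive at every pixel.
#' @slot beamProfile [ProfileCurve-class], anchored at r = 0 with value 1.
#' @slot cuScale positive numeric signal-to-CU factor, or `NA_real_` until
#'   [calibrateCU()] has been run.
#' @slot correction2d numeric matrix of positive multiplicative factors, or a
#'   0x0 matrix when unset.
#' @slot muReference monitor units of the reference delivery (100).
#' @slot fieldReference reference field label ("10x10").
#' @seealso [CalibrationSet()], [processImage()], [calibrateCU()]
#' @export
setClass("CalibrationSet",
  representation(dark = "ImageGrid", flood = "ImageGrid",
    beamProfile = "ProfileCurve", cuScale = "numeric",
    correction2d = "matrix", muReference = "numeric",
    fieldReference = "character"))

setValidity("CalibrationSet", function(object) {
  d <- object@dark@values; f <- object@flood@values
  if (!identical(dim(d), dim(f)) ||
      object@dark@pitchMm != object@flood@pitchMm)
    return("dark and flood must share geometry")
  bad <- which(f - d <= 0)
  if (length(bad) > 0) {
    ij <- arrayInd(bad[1], dim(f))
    return(sprintf(
      "flood - dark must be strictly positive at every pixel (first violation at row %d, col %d)",
      ij[1], ij[2]))
  }
  bp <- object@beamProfile
  if (bp@rCm[1] != 0) return("beamProfile must be anchored at r = 0")
  if (abs(bp@value[1] - 1) > 1e-9)
    return("beamProfile value at r = 0 must equal 1 (within 1e-9)")
  if (!is.na(object@cuScale) && object@cuScale <= 0)
    return("'cuScale' must be positive")
  if (length(object@correction2d) > 0) {
    if (!identical(dim(object@correction2d), dim(f)))
      return("'correction2d' must match the panel geometry")
    if (any(object@correction2d <= 0))
      return("'correction2d' must be strictly positive")
  }
  TRUE
})

#' Construct a CalibrationSet
#'
#' @param dark,flood [ImageGrid-class] calibration images (same geometry;
#'   `flood - dark` strictly positive everywhere).
#' @param beamProfile [ProfileCurve-class] diagonal beam profile, anchored at
#'   r = 0 and normalized to 1 there.
#' @param cuScale signal-to-CU factor; leave `NA` and call [calibrateCU()].
#' @param correction2d optional positive multiplicative 2D map matching the
#'   panel; when present it replaces profile restoration in [processImage()].
#' @param muReference,fieldReference reference-delivery metadata.
#' @return A [CalibrationSet-class] object.
#' @export
CalibrationSet <- function(dark, flood, beamProfile, cuScale = NA_real_,
                           correction2d = NULL, muReference = 100,
                           fieldReference = "10x10") {
  if (is.null(correction2d)) correction2d <- matrix(numeric(0), 0, 0)
  new("CalibrationSet", dark = dark, flood = flood,
      beamProfile = beamProfile, cuScale = as.numeric(cuScale),
      correction2d = correction2d, muReference = muReference,
      fieldReference = fieldReference)
}

#' GammaParams: gamma-index evaluation settings
#'
#' @slot doseCriterionPct dose-difference criterion in percent (default 3).
#' @slot distanceCriterionMm distance-to-agreement criterion in mm (default 3).
#' @slot normalization `"global_max"` (default) or `"global_cax"`; the dose
#'   denominator is the reference maximum or the reference central-axis value.
#' @slot lowDoseThresholdPct reference pixels below this percentage of the
#'   normalization value are excluded (default 0: evaluate all pixels).
#' @slot searchRadiusFactor search radius as a multiple of the distance
#'   criterion (default 3).
#' @slot searchSubsample interpolation subdivisions per distance criterion
#'   (default 10).
#' @slot local logical; `TRUE` switches to local dose-difference gamma.
#' @seealso [GammaParams()], [gammaIndex()], [gammaOracle()]
#' @export
setClass("GammaParams",
  representation(doseCriterionPct = "numeric", distanceCriterionMm = "numeric",
    normalization = "character", lowDoseThresholdPct = "numeric",
    searchRadiusFactor = "numeric", searchSubsample = "integer",
    local = "logical"))

setValidity("GammaParams", function(object) {
  if (object@doseCriterionPct <= 0) return("'doseCriterionPct' must be > 0")
  if (object@distanceCriterionMm <= 0) return("'distanceCriterionMm' must be > 0")
  if (!object@normalization %in% c("global_max", "global_cax"))
    return("'normalization' must be 'global_max' or 'global_cax'")
  if (object@lowDoseThresholdPct < 0 || object@lowDoseThresholdPct >= 100)
    return("'lowDoseThresholdPct' must lie in [0, 100)")
  if (object@searchRadiusFactor <= 0) return("'searchRadiusFactor' must be > 0")
  if (object@searchSubsample < 1L) return("'searchSubsample' must be >= 1")
  TRUE
})

#' Construct gamma evaluation parameters
#'
#' @param doseCriterionPct dose criterion, percent of the normalization value.
#' @param distanceCriterionMm distance-to-agreement criterion, mm.
#' @param normalization `"global_max"` or `"global_cax"`.
#' @param lowDoseThresholdPct low-dose exclusion threshold, percent.
#' @param searchRadiusFactor search radius in units of the distance criterion.
#' @param searchSubsample interpolation steps per distance criterion.
#' @param local use local dose differences instead of global normalization.
#' @return A [GammaParams-class] object.
#' @examples
#' GammaParams()                      # the 3%, 3 mm global criterion
#' GammaParams(2, 2, lowDoseThresholdPct = 10)
#' @export
GammaParams <- function(doseCriterionPct = 3, distanceCriterionMm = 3,
                        normalization = c("global_max", "global_cax"),
                        lowDoseThresholdPct = 0, searchRadiusFactor = 3,
                        searchSubsample = 10L, local = FALSE) {
  new("GammaParams", doseCriterionPct = doseCriterionPct,
      distanceCriterionMm = distanceCriterionMm,
      normalization = match.arg(normalization),
      lowDoseThresholdPct = lowDoseThresholdPct,
      searchRadiusFactor = searchRadiusFactor,
      searchSubsample = as.integer(searchSubsample), local = local)
}

#' GammaResult: per-pixel gamma map and pass-rate summary
#'
#' @slot gammaMap numeric matrix of gamma values; `NA` marks pixels excluded
#'   by the low-dose threshold.
#' @slot passRatePct percentage of evaluated pixels with gamma <= 1.
#' @slot nEvaluated number of evaluated (non-excluded) pixels.
#' @slot params the [GammaParams-class] used.
#' @seealso [gammaIndex()], [passRateSummary()]
#' @export
setClass("GammaResult",
  representation(gammaMap = "matrix", passRatePct = "numeric",
    nEvaluated = "integer", params = "GammaParams"))

setValidity("GammaResult", function(object) {
  if (object@passRatePct < 0 || object@passRatePct > 100)
    return("'passRatePct' must lie in [0, 100]")
  if (object@nEvaluated < 0) return("'nEvaluated' must be non-negative")
  TRUE
})

#' SimConfig: synthetic EPID simulator configuration
#'
#' Parametric stand-ins for the physical effects portal images exhibit:
#' beam horns, residual off-axis over-response, asymmetric support-arm
#' backscatter, a smooth pixel-sensitivity map, dark signal and per-pixel
#' noise. All randomness is seeded so identical configurations produce
#' bit-identical outputs.
#'
#' @slot nX,nY panel matrix size (default 512 x 384).
#' @slot pitchMm pixel pitch in mm (default 0.78125, a 40 x 30 cm2 panel).
#' @slot hornParams even-polynomial coefficients `(h2, h4)` of the radially
#'   symmetric beam profile `P(r) = 1 + h2 r^2 + h4 r^4` (r in cm).
#' @slot overresponseParams even-polynomial coefficients `(a2, a4)` of the
#'   residual radial over-response `rho(r) = 1 + a2 r^2 + a4 r^4`; the default
#'   curve dips to -0.4% near 9 cm and rises to +9.9% at 22 cm.
#' @slot backscatterAmplitude peak arm-backscatter signal as a fraction of the
#'   central-axis signal for a full-panel field (default 0.03).
#' @slot backscatterExtentCm distance over which the backscatter ramp reaches
#'   its full amplitude on the gantry (+Y) side (default 15, the panel
#'   half-height).
#' @slot sensitivitySeed,noiseSeed integer seeds for the fixed structure maps
#'   (sensitivity, dark pattern) and for per-frame noise.
#' @slot sensitivitySigma relative amplitude of the smooth pixel-sensitivity
#'   map (default 0.03; 0 gives a perfectly uniform detector).
#' @slot noiseSigma relative Gaussian noise per pixel (default 0.002).
#' @slot darkLevel mean dark signal (default 0.02 in open-field CAX units).
#' @slot transmission jaw-transmission floor of every fluence (default 0.005).
#' @seealso [simConfig()], [simulateRaw()], [makeCalibrationInputs()]
#' @export
setClass("SimConfig",
  representation(nX = "integer", nY = "integer", pitchMm = "numeric",
    hornParams = "numeric", overresponseParams = "numeric",
    backscatterAmplitude = "numeric", backscatterExtentCm = "numeric",
    sensitivitySeed = "integer", noiseSeed = "integer",
    sensitivitySigma = "numeric", noiseSigma = "numeric",
    darkLevel = "numeric", transmission = "numeric"))

setValidity("SimConfig", function(object) {
  if (object@nX < 2L || object@nY < 2L) return("panel must be at least 2x2")
  if (object@pitchMm <= 0) return("'pitchMm' must be positive")
  if (length(object@hornParams) != 2L || length(object@overresponseParams) != 2L)
    return("'hornParams' and 'overresponseParams' must each have length 2 (r^2, r^4)")
  if (object@backscatterAmplitude < 0) return("'backscatterAmplitude' must be >= 0")
  if (object@backscatterExtentCm <= 0) return("'backscatterExtentCm' must be positive")
  if (object@sensitivitySigma < 0) return("'sensitivitySigma' must be >= 0")
  if (object@noiseSigma < 0) return("'noiseSigma' must be >= 0")
  if (object@darkLevel < 0) return("'darkLevel' must be >= 0")
  if (object@transmission < 0 || object@transmission >= 1)
    return("'transmission' must lie in [0, 1)")
  TRUE
})

#' Construct a simulator configuration
#'
#' Defaults emulate a 40 x 30 cm2 amorphous-silicon panel (512 x 384 pixels,
#' 0.78125 mm pitch) with a few-percent horn structure, a residual off-axis
#' over-response spanning -0.4% to +9.9% over 0-22 cm, a 3% peak arm
#' backscatter on the gantry side, 0.2% per-pixel noise and a 0.5%
#' jaw-transmission floor.
#'
#' @param nX,nY,pitchMm panel geometry.
#' @param hornParams,overresponseParams even-polynomial coefficients, see
#'   [SimConfig-class].
#' @param backscatterAmplitude,backscatterExtentCm arm-backscatter scale and
#'   reach (see [SimConfig-class]).
#' @param sensitivitySeed,noiseSeed RNG seeds for structure maps and frame
#'   noise.
#' @param sensitivitySigma amplitude of the smooth sensitivity map.
#' @param noiseSigma relative per-pixel Gaussian noise.
#' @param darkLevel mean dark signal in open-field CAX units.
#' @param transmission jaw-transmission floor.
#' @return A [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(noiseSigma = 0)   # a noiseless panel
#' @export
simConfig <- function(nX = 512L, nY = 384L, pitchMm = 0.78125,
                      hornParams = c(3e-4, -8e-7),
                      overresponseParams = c(-1.004e-4, 6.3e-7),
                      backscatterAmplitude = 0.03, backscatterExtentCm = 15,
                      sensitivitySeed = 1201L, noiseSeed = 3404L,
                      sensitivitySigma = 0.03, noiseSigma = 0.002,
                      darkLevel = 0.02, transmission = 0.005) {
  new("SimConfig", nX = as.integer(nX), nY = as.integer(nY),
      pitchMm = pitchMm, hornParams = hornParams,
      overresponseParams = overresponseParams,
      backscatterAmplitude = backscatterAmplitude,
      backscatterExtentCm = backscatterExtentCm,
      sensitivitySeed = as.integer(sensitivitySeed),
      noiseSeed = as.integer(noiseSeed),
      sensitivitySigma = sensitivitySigma, noiseSigma = noiseSigma,
      darkLevel = darkLevel, transmission = transmission)
}

#' ExperimentSpec: a QA summary-table experiment definition
#'
#' @slot scenario calibration scenario: `"uncorrected"`, `"inhouse_40x30"`,
#'   `"inhouse_20x20"` or `"generic_2d"`.
#' @slot fieldCases list of field-case definitions (see [fieldCase()]).
#' @slot gammaParams [GammaParams-class] used for every comparison.
#' @slot config [SimConfig-class] driving the simulator.
#' @slot outputDir output directory, or `""` to skip file output.
#' @seealso [experimentSpec()], [runExperiment()]
#' @export
setClass("ExperimentSpec",
  representation(scenario = "character", fieldCases = "list",
    gammaParams = "GammaParams", config = "SimConfig",
    outputDir = "character"))

setValidity("ExperimentSpec", function(object) {
  if (!object@scenario %in% c("uncorrected", "inhouse_40x30",
                              "inhouse_20x20", "generic_2d"))
    return("unknown scenario")
  if (length(object@fieldCases) == 0) return("no field cases")
  TRUE
})
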