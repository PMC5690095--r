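# Wires simulator, calibration, correction and gamma into reproducible
# Table-style QA experiments.

#' Define a field case for an experiment
#'
#' @param name case label.
#' @param planType plan-type group for the summary table (e.g. `"square"`,
#'   `"imrt"`, `"split_imrt"`).
#' @param x1Cm,x2Cm,y1Cm,y2Cm jaw half-extents, cm.
#' @param pattern fluence pattern, see [makeFieldFluence()].
#' @param mu delivered monitor units.
#' @return A named list describing the case.
#' @export
fieldCase <- function(name, planType, x1Cm, x2Cm, y1Cm, y2Cm,
                      pattern = "open", mu = 100) {
  list(name = name, planType = planType, x1Cm = x1Cm, x2Cm = x2Cm,
       y1Cm = y1Cm, y2Cm = y2Cm, pattern = pattern, mu = mu)
}

#' Default field-case suites
#'
#' `defaultSquareFieldCases()` is the square-field suite (5x5 up to 28x28
#' cm2, open fields). `defaultSplitFieldCases()` is a set of split-field
#' IMRT-like cases whose half-extents exceed 10 cm, i.e. fields that
#' overrun the usable area of a 20x20 flood-field calibration.
#'
#' @return A list of [fieldCase()] definitions.
#' @export
defaultSquareFieldCases <- function() {
  sizes <- c(5, 10, 15, 20, 28)
  lapply(sizes, function(s)
    fieldCase(sprintf("open_%gx%g", s, s), "square", s / 2, s / 2,
              s / 2, s / 2))
}

#' @rdname defaultSquareFieldCases
#' @export
defaultSplitFieldCases <- function() {
  list(
    fieldCase("split_24x22", "split_imrt", 12, 12, 11, 11,
              pattern = "split_imrt"),
    fieldCase("split_26x20", "split_imrt", 13, 13, 10, 10,
              pattern = "split_imrt"),
    fieldCase("split_22x24", "split_imrt", 11, 11, 12, 12,
              pattern = "split_imrt"))
}

#' Construct an experiment specification
#'
#' @param scenario calibration scenario: `"uncorrected"`,
#'   `"inhouse_40x30"` (4th-order profile correction derived from a 38x28
#'   field, 40x30 flood), `"inhouse_20x20"` (correction derived from a
#'   20x20 field with a 20x20 flood) or `"generic_2d"` (externally supplied
#'   multiplicative 2D map, 40x32 flood).
#' @param fieldCases list of [fieldCase()] definitions.
#' @param gammaParams [GammaParams-class]; the default applies the 3%, 3 mm
#'   global criterion with a 10% low-dose threshold, the usual portal-QA
#'   convention for field comparisons.
#' @param config a [SimConfig-class].
#' @param outputDir optional output directory for report files.
#' @return An [ExperimentSpec-class].
#' @export
experimentSpec <- function(scenario, fieldCases = defaultSquareFieldCases(),
                           gammaParams = GammaParams(lowDoseThresholdPct = 10),
                           config = simConfig(), outputDir = "") {
  new("ExperimentSpec", scenario = scenario, fieldCases = fieldCases,
      gammaParams = gammaParams, config = config, outputDir = outputDir)
}

# number of profile samples at one per pixel pitch over [0, rMax]
profileSampleCount <- function(config, rMaxCm) {
  as.integer(floor(rMaxCm / (config@pitchMm / 10))) + 1L
}

#' Build the calibration for a scenario
#'
#' Runs the full calibration workflow a clinic would: acquire dark, flood
#' and the 100 MU 10x10 reference; for the in-house scenarios additionally
#' acquire a large open field (38x28 or 20x20), process it with the
#' uncorrected calibration, extract measured and predicted diagonal
#' profiles, derive the polynomial correction, apply it to the calibration
#' beam profile and recalibrate the CU scale.
#'
#' @param scenario see [experimentSpec()].
#' @param config a [SimConfig-class].
#' @param correction2d optional positive 2D map for the `generic_2d`
#'   scenario; when missing, the radially evaluated beam profile is used
#'   (profile restoration expressed as a 2D map).
#' @return A list with the finished `cal` ([CalibrationSet-class]), the
#'   derived `correction` ([PolyCorrection-class] or `NULL`) and the
#'   scenario label.
#' @export
buildCalibration <- function(scenario, config = simConfig(),
                             correction2d = NULL) {
  floodField <- switch(scenario,
                       uncorrected = "f40x30", inhouse_40x30 = "f40x30",
                       inhouse_20x20 = "f20x20", generic_2d = "f40x32",
                       stop(sprintf("unknown scenario '%s'", scenario)))
  inputs <- makeCalibrationInputs(config, floodField)
  profile <- beamProfileCurve(config)
  cal <- CalibrationSet(inputs$dark, inputs$flood, profile)
  cal <- calibrateCU(processImage(inputs$reference, cal, toCU = FALSE), cal)
  corr <- NULL
  if (scenario %in% c("inhouse_40x30", "inhouse_20x20")) {
    if (scenario == "inhouse_40x30") {
      jaws <- c(19, 19, 14, 14); mode <- "inhouse_large"; rMax <- 22
    } else {
      jaws <- c(10, 10, 10, 10); mode <- "inhouse_20x20"; rMax <- 14
    }
    fl <- makeFieldFluence(config, jaws[1], jaws[2], jaws[3], jaws[4])
    raw <- simulateRaw(fl, config, noiseStream = 150L)
    measuredImg <- processImage(raw, cal)
    predictedImg <- simulatePredicted(fl, config)
    n <- profileSampleCount(config, rMax)
    mProf <- extractDiagonalProfile(measuredImg, n, rMax)
    pProf <- extractDiagonalProfile(predictedImg, n, rMax)
    corr <- deriveCorrection(mode, mProf, pProf)
    corrected <- applyProfileCorrection(profile, corr)
    cal <- CalibrationSet(inputs$dark, inputs$flood, corrected)
    cal <- calibrateCU(processImage(inputs$reference, cal, toCU = FALSE), cal)
  } else if (scenario == "generic_2d") {
    if (is.null(correction2d)) {
      rmap <- radialDistanceMap(inputs$flood)
      correction2d <- matrix(
        profileValueAt(profile, as.vector(rmap)), nrow(rmap), ncol(rmap))
    }
    cal <- CalibrationSet(inputs$dark, inputs$flood, profile,
                          correction2d = correction2d)
    cal <- calibrateCU(processImage(inputs$reference, cal, toCU = FALSE), cal)
  }
  list(cal = cal, correction = corr, scenario = scenario,
       floodField = floodField)
}

caseMaxHalfExtent <- function(case)
  max(case$x1Cm, case$x2Cm, case$y1Cm, case$y2Cm)

#' Run a QA experiment
#'
#' For every field case: simulate the raw acquisition and the predicted
#' image, process the raw image through the scenario's calibration, compute
#' the gamma index (predicted image as reference), and collect per-field
#' rows plus per-plan-type summary rows (average / minimum / maximum /
#' population sd / field count). Deterministic for a fixed
#' [SimConfig-class]: each field case uses its own derived noise stream.
#'
#' When `outputDir` is set, writes `report.json` (per-field rows, summary
#' and a manifest with the resolved configuration and seeds) and
#' `report.csv` (the summary table).
#'
#' @param spec an [ExperimentSpec-class].
#' @param correction2d optional 2D map for the `generic_2d` scenario.
#' @return A list with `perField` and `summary` data frames, the
#'   `calibration` list from [buildCalibration()], and the `spec`.
#' @export
runExperiment <- function(spec, correction2d = NULL) {
  stopifnot(is(spec, "ExperimentSpec"))
  config <- spec@config
  built <- buildCalibration(spec@scenario, config, correction2d)
  if (spec@scenario == "inhouse_20x20") {
    big <- vapply(spec@fieldCases, caseMaxHalfExtent, numeric(1)) > 10
    if (any(big))
      warning(sprintf(
        "20x20-mode calibration applied to %d field case(s) with half-extents > 10 cm; the corrected area is smaller than the field",
        sum(big)))
  }
  rows <- vector("list", length(spec@fieldCases))
  results <- vector("list", length(spec@fieldCases))
  for (i in seq_along(spec@fieldCases)) {
    case <- spec@fieldCases[[i]]
    fl <- makeFieldFluence(config, case$x1Cm, case$x2Cm, case$y1Cm,
                           case$y2Cm, pattern = case$pattern)
    raw <- simulateRaw(fl, config, mu = case$mu, noiseStream = 200L + i)
    measured <- processImage(raw, built$cal)
    predicted <- simulatePredicted(fl, config)
    res <- gammaIndex(predicted, measured, spec@gammaParams)
    results[[i]] <- res
    g <- gammaValues(res)
    rows[[i]] <- data.frame(
      scenario = spec@scenario, case = case$name, planType = case$planType,
      passRatePct = passRatePct(res), nEvaluated = nEvaluated(res),
      gammaMean = mean(g, na.rm = TRUE), gammaMax = max(g, na.rm = TRUE))
  }
  perField <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(perField, perField$planType),
    function(d) cbind(scenario = spec@scenario,
                      planType = d$planType[1],
                      passRateSummary(d$passRatePct))))
  rownames(summary) <- NULL
  out <- list(perField = perField, summary = summary, calibration = built,
              results = results, spec = spec)
  if (nzchar(spec@outputDir)) writeExperimentReport(out, spec@outputDir)
  out
}

#' Write an experiment report
#'
#' @param experiment result of [runExperiment()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeExperimentReport <- function(experiment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- experiment$spec@config
  manifest <- list(
    scenario = experiment$spec@scenario,
    flood_field = experiment$calibration$floodField,
    gamma = list(
      dose_pct = experiment$spec@gammaParams@doseCriterionPct,
      dist_mm = experiment$spec@gammaParams@distanceCriterionMm,
      normalization = experiment$spec@gammaParams@normalization,
      low_dose_threshold_pct = experiment$spec@gammaParams@lowDoseThresholdPct),
    simulator = list(
      n_x = cfg@nX, n_y = cfg@nY, pitch_mm = cfg@pitchMm,
      horn_params = cfg@hornParams,
      overresponse_params = cfg@overresponseParams,
      backscatter_amplitude = cfg@backscatterAmplitude,
      backscatter_extent_cm = cfg@backscatterExtentCm,
      noise_sigma = cfg@noiseSigma, dark_level = cfg@darkLevel,
      transmission = cfg@transmission,
      sensitivity_seed = cfg@sensitivitySeed, noise_seed = cfg@noiseSeed))
  jsonlite::write_json(
    list(manifest = manifest, per_field = experiment$perField,
         summary = experiment$summary),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  utils::write.csv(experiment$summary, file.path(dir, "report.csv"),
                   row.names = FALSE)
  invisible(dir)
}
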