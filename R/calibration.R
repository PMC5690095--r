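# The Varian-style portal-dose calibration chain:
#   raw -> dark/flood correction -> beam-profile restoration (or generic 2D
#   map) -> CU normalization.

checkSameGeometry <- function(a, b, what = "images") {
  if (!identical(dim(a@values), dim(b@values)) || a@pitchMm != b@pitchMm)
    stop(sprintf("%s must share geometry (%dx%d @ %g mm vs %dx%d @ %g mm)",
                 what, nY(a), nX(a), pitchMm(a), nY(b), nX(b), pitchMm(b)))
  invisible(TRUE)
}

#' Dark-field and flood-field correction
#'
#' Subtracts the dark field (background signal) and divides by the net flood
#' field (open-beam sensitivity), then rescales by the mean of
#' `flood - dark` so the overall signal magnitude is preserved:
#' \deqn{out = \frac{raw - dark}{flood - dark} \times \overline{flood - dark}.}
#' The flood correction divides out both detector sensitivity and the beam
#' nonuniformity; the horns are restored afterwards by
#' [restoreBeamProfile()].
#'
#' @param raw an [ImageGrid-class] raw portal image.
#' @param cal a [CalibrationSet-class] providing dark and flood.
#' @return An [ImageGrid-class] with the input geometry.
#' @examples
#' d <- ImageGrid(matrix(1, 2, 2), 1); f <- ImageGrid(matrix(4, 2, 2), 1)
#' cal <- CalibrationSet(d, f, ProfileCurve(c(0, 5), c(1, 1)))
#' raw <- ImageGrid(matrix(c(10, 14, 12, 16), 2, 2), 1)
#' imageValues(applyDarkFlood(raw, cal))  # (raw - 1)/3 * 3
#' @export
applyDarkFlood <- function(raw, cal) {
  stopifnot(is(raw, "ImageGrid"), is(cal, "CalibrationSet"))
  checkSameGeometry(raw, cal@dark, "raw and dark")
  checkSameGeometry(raw, cal@flood, "raw and flood")
  net <- cal@flood@values - cal@dark@values
  bad <- which(net <= 0)
  if (length(bad) > 0) {
    ij <- arrayInd(bad[1], dim(net))
    stop(sprintf("flood - dark is not positive at pixel (row %d, col %d)",
                 ij[1], ij[2]))
  }
  ImageGrid((raw@values - cal@dark@values) / net * mean(net), pitchMm(raw))
}

#' Restore the beam horns with a diagonal profile
#'
#' Multiplies each pixel by the beam profile evaluated (linear interpolation
#' in r) at that pixel's radial distance, bringing back the treatment-beam
#' nonuniformity that the flood correction divided out. The central-axis
#' value is unchanged since the profile is 1 at r = 0.
#'
#' @param image an [ImageGrid-class] (dark/flood-corrected).
#' @param profile a [ProfileCurve-class] normalized to 1 at r = 0.
#' @param extrapolate policy beyond the last profile sample: `"clamp"` the
#'   last value (default, with a warning) or `"error"`.
#' @return An [ImageGrid-class].
#' @export
restoreBeamProfile <- function(image, profile,
                               extrapolate = c("clamp", "error")) {
  stopifnot(is(image, "ImageGrid"), is(profile, "ProfileCurve"))
  extrapolate <- match.arg(extrapolate)
  if (abs(profileValueAt(profile, 0) - 1) > 1e-9)
    stop("beam profile must be normalized to 1 at r = 0")
  rmap <- radialDistanceMap(image)
  warn <- max(rmap) > max(profile@rCm) + 1e-12
  pv <- profileValueAt(profile, as.vector(rmap), extrapolate = extrapolate,
                       warn = warn)
  ImageGrid(image@values * matrix(pv, nrow(rmap), ncol(rmap)),
            pitchMm(image))
}

#' Apply a generic multiplicative 2D correction map
#'
#' Element-wise multiplication by an externally supplied correction map (the
#' hook by which a vendor-style 2D arm-backscatter/beam-profile correction
#' enters the chain, replacing [restoreBeamProfile()]).
#'
#' @param image an [ImageGrid-class].
#' @param correctionMap numeric matrix matching the image, strictly positive.
#' @return An [ImageGrid-class].
#' @export
apply2DCorrection <- function(image, correctionMap) {
  stopifnot(is(image, "ImageGrid"))
  if (!identical(dim(correctionMap), dim(image@values)))
    stop("correction map geometry does not match the image")
  ImageGrid(image@values * correctionMap, pitchMm(image))
}

#' Set the CU scale from a processed reference image
#'
#' One calibrated unit (CU) is defined so that the central axis of the fully
#' processed 100 MU, 10x10 cm2 reference delivery reads 1.0 CU; accordingly
#' `cuScale` is set to the reciprocal of the reference image's central-axis
#' value (bilinear interpolation at the beam-axis point).
#'
#' @param referenceImage the dark/flood-corrected, profile-restored reference
#'   delivery as an [ImageGrid-class].
#' @param cal a [CalibrationSet-class].
#' @return `cal` with `cuScale` set.
#' @export
calibrateCU <- function(referenceImage, cal) {
  stopifnot(is(referenceImage, "ImageGrid"), is(cal, "CalibrationSet"))
  cax <- caxValue(referenceImage)
  if (!is.finite(cax) || cax <= 0)
    stop(sprintf("reference central-axis value must be positive (got %g)", cax))
  cal@cuScale <- 1 / cax
  validObject(cal)
  cal
}

#' Convert a processed image to calibrated units
#'
#' Multiplies by the CU scale factor set by [calibrateCU()]; linear in the
#' input signal.
#'
#' @param image an [ImageGrid-class] (dark/flood-corrected and
#'   profile-restored).
#' @param cal a [CalibrationSet-class] with `cuScale` set.
#' @return An [ImageGrid-class] in CU.
#' @export
doseCalibrate <- function(image, cal) {
  stopifnot(is(image, "ImageGrid"), is(cal, "CalibrationSet"))
  if (is.na(cal@cuScale))
    stop("calibration set has no CU scale; run calibrateCU() first")
  ImageGrid(image@values * cal@cuScale, pitchMm(image))
}

#' Run the full calibration chain on a raw image
#'
#' Dark/flood correction, then beam-profile restoration (or, when the
#' calibration set carries a 2D correction map, that map instead), then CU
#' normalization unless `toCU = FALSE`.
#'
#' @param raw an [ImageGrid-class] raw portal image.
#' @param cal a [CalibrationSet-class].
#' @param toCU apply the CU scale (default `TRUE`; requires [calibrateCU()]).
#' @param extrapolate profile extrapolation policy, see
#'   [restoreBeamProfile()].
#' @return An [ImageGrid-class], in CU when `toCU = TRUE`.
#' @export
processImage <- function(raw, cal, toCU = TRUE,
                         extrapolate = c("clamp", "error")) {
  img <- applyDarkFlood(raw, cal)
  img <- if (length(cal@correction2d) > 0)
    apply2DCorrection(img, cal@correction2d)
  else
    restoreBeamProfile(img, cal@beamProfile, extrapolate = match.arg(extrapolate))
  if (toCU) img <- doseCalibrate(img, cal)
  img
}
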