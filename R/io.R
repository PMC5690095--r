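# Plain-text I/O. Images travel as CSV matrices with a two-line geometry
# header; profiles as two-column CSV; corrections as JSON; calibration sets
# as a directory of the above plus meta.json.

#' Write an image as a CSV matrix
#'
#' Layout: a header line `n_x,n_y,pitch_mm`, one line of the corresponding
#' values, then the pixel matrix (rows = Y from the gantry side downward,
#' columns = X from patient right to patient left).
#'
#' @param image an [ImageGrid-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeImageCSV <- function(image, path) {
  stopifnot(is(image, "ImageGrid"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("n_x,n_y,pitch_mm",
               paste(nX(image), nY(image), format(pitchMm(image), digits = 17),
                     sep = ",")), con)
  utils::write.table(image@values, con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read an image from a CSV matrix
#'
#' @param path file written by [writeImageCSV()] (or following its layout).
#' @return An [ImageGrid-class].
#' @export
readImageCSV <- function(path) {
  hdr <- readLines(path, n = 2L)
  if (!identical(trimws(hdr[1]), "n_x,n_y,pitch_mm"))
    stop(sprintf("'%s' lacks the expected 'n_x,n_y,pitch_mm' header", path))
  meta <- as.numeric(strsplit(hdr[2], ",")[[1]])
  vals <- as.matrix(utils::read.csv(path, skip = 2L, header = FALSE))
  dimnames(vals) <- NULL
  if (ncol(vals) != meta[1] || nrow(vals) != meta[2])
    stop(sprintf("matrix in '%s' is %dx%d but header declares %dx%d",
                 path, nrow(vals), ncol(vals), meta[2], meta[1]))
  ImageGrid(vals, meta[3])
}

#' Write a profile as two-column CSV
#'
#' @param profile a [ProfileCurve-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeProfileCSV <- function(profile, path) {
  stopifnot(is(profile, "ProfileCurve"))
  utils::write.csv(data.frame(r_cm = profile@rCm, value = profile@value),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a profile from two-column CSV
#'
#' @param path CSV file with header columns `r_cm,value`.
#' @return A [ProfileCurve-class].
#' @export
readProfileCSV <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("r_cm", "value") %in% names(df)))
    stop(sprintf("'%s' must have header columns r_cm,value", path))
  ProfileCurve(df$r_cm, df$value)
}

#' Persist a polynomial correction as JSON
#'
#' @param corr a [PolyCorrection-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeCorrectionJSON <- function(corr, path) {
  stopifnot(is(corr, "PolyCorrection"))
  jsonlite::write_json(list(
    mode = corr@mode, order = corr@order,
    coefficients = corr@coefficients,
    r_fit_min_cm = corr@rFitMinCm, r_fit_max_cm = corr@rFitMaxCm,
    r_apply_max_cm = corr@rApplyMaxCm, r_squared = corr@rSquared,
    ratio_orientation = corr@ratioOrientation,
    apply_style = corr@applyStyle), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a polynomial correction from JSON
#'
#' @param path file written by [writeCorrectionJSON()].
#' @return A [PolyCorrection-class].
#' @export
readCorrectionJSON <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("PolyCorrection", coefficients = as.numeric(x$coefficients),
      order = as.integer(x$order), rFitMinCm = x$r_fit_min_cm,
      rFitMaxCm = x$r_fit_max_cm, rApplyMaxCm = x$r_apply_max_cm,
      rSquared = x$r_squared, mode = x$mode,
      ratioOrientation = x$ratio_orientation, applyStyle = x$apply_style)
}

#' Persist a calibration set as a directory
#'
#' Writes `dark.csv`, `flood.csv`, `beam_profile.csv`, `meta.json` and, when
#' present, `correction_2d.csv` under `dir`.
#'
#' @param cal a [CalibrationSet-class].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeCalibrationSet <- function(cal, dir) {
  stopifnot(is(cal, "CalibrationSet"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeImageCSV(cal@dark, file.path(dir, "dark.csv"))
  writeImageCSV(cal@flood, file.path(dir, "flood.csv"))
  writeProfileCSV(cal@beamProfile, file.path(dir, "beam_profile.csv"))
  has2d <- length(cal@correction2d) > 0
  if (has2d)
    writeImageCSV(ImageGrid(cal@correction2d, pitchMm(cal@flood)),
                  file.path(dir, "correction_2d.csv"))
  jsonlite::write_json(list(
    cu_scale = cal@cuScale, mu_reference = cal@muReference,
    field_reference = cal@fieldReference, has_correction_2d = has2d),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  invisible(dir)
}

#' Read a calibration set from a directory
#'
#' @param dir directory written by [writeCalibrationSet()].
#' @return A [CalibrationSet-class].
#' @export
readCalibrationSet <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  corr2d <- if (isTRUE(meta$has_correction_2d))
    readImageCSV(file.path(dir, "correction_2d.csv"))@values else NULL
  CalibrationSet(
    dark = readImageCSV(file.path(dir, "dark.csv")),
    flood = readImageCSV(file.path(dir, "flood.csv")),
    beamProfile = readProfileCSV(file.path(dir, "beam_profile.csv")),
    cuScale = if (is.null(meta$cu_scale) || is.na(meta$cu_scale))
      NA_real_ else meta$cu_scale,
    correction2d = corr2d, muReference = meta$mu_reference,
    fieldReference = meta$field_reference)
}
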