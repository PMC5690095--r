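# Physical coordinate model of the EPID panel.
#
# Pixel-centre convention: the centre of pixel (i, j) (0-based) lies at
#   x = (i + 0.5) * pitch - Lx/2,   y = Ly/2 - (j + 0.5) * pitch
# in cm, with +X toward patient left and +Y toward the gantry side; row 1 of
# the value matrix is the gantry-side edge. The beam axis is (0, 0).

#' Pixel pitch from sensitive length and pixel count
#'
#' @param sensitiveLengthMm sensitive panel length along one axis, mm.
#' @param nPixels number of pixels along that axis.
#' @return Pixel pitch in mm.
#' @examples
#' pixelPitch(400, 512)  # 0.78125 mm, the aS1000 half-resolution pitch
#' @export
pixelPitch <- function(sensitiveLengthMm, nPixels) {
  if (!is.numeric(sensitiveLengthMm) || length(sensitiveLengthMm) != 1L ||
      !is.finite(sensitiveLengthMm) || sensitiveLengthMm <= 0)
    stop("'sensitiveLengthMm' must be a single positive number")
  if (!is.numeric(nPixels) || length(nPixels) != 1L || !is.finite(nPixels) ||
      nPixels <= 0 || nPixels != as.integer(nPixels))
    stop("'nPixels' must be a single positive integer")
  sensitiveLengthMm / nPixels
}

#' Physical panel extent
#'
#' @param grid an [ImageGrid-class].
#' @return Numeric length-2 vector `c(x, y)` of the panel extent in cm.
#' @export
panelExtentCm <- function(grid) {
  stopifnot(is(grid, "ImageGrid"))
  c(nX(grid), nY(grid)) * pitchMm(grid) / 10
}

#' Pixel-centre physical coordinates
#'
#' @param grid an [ImageGrid-class].
#' @return List with numeric vectors `x` (length `nX`, cm, column order) and
#'   `y` (length `nY`, cm, row order: gantry side first).
#' @export
pixelCoordinatesCm <- function(grid) {
  stopifnot(is(grid, "ImageGrid"))
  p <- pitchMm(grid) / 10
  ex <- panelExtentCm(grid)
  list(x = (seq_len(nX(grid)) - 0.5) * p - ex[1] / 2,
       y = ex[2] / 2 - (seq_len(nY(grid)) - 0.5) * p)
}

# Bilinear interpolation of an image at physical points (xCm, yCm).
# Points outside the pixel-centre rectangle are clamped to the border
# (clamp = TRUE) or returned as NA.
bilinearAt <- function(grid, xCm, yCm, clamp = TRUE) {
  p <- pitchMm(grid) / 10
  ex <- panelExtentCm(grid)
  # fractional column/row indices (1-based pixel centres)
  ci <- (xCm + ex[1] / 2) / p + 0.5
  rj <- (ex[2] / 2 - yCm) / p + 0.5
  nx <- nX(grid); ny <- nY(grid)
  out <- if (clamp) NULL else (ci < 1 | ci > nx | rj < 1 | rj > ny)
  ci <- pmin(pmax(ci, 1), nx)
  rj <- pmin(pmax(rj, 1), ny)
  i0 <- pmin(floor(ci), nx - 1); j0 <- pmin(floor(rj), ny - 1)
  fx <- ci - i0; fy <- rj - j0
  v <- grid@values
  val <- v[cbind(j0, i0)]       * (1 - fx) * (1 - fy) +
         v[cbind(j0, i0 + 1)]   * fx       * (1 - fy) +
         v[cbind(j0 + 1, i0)]   * (1 - fx) * fy +
         v[cbind(j0 + 1, i0 + 1)] * fx     * fy
  if (!clamp) val[out] <- NA_real_
  val
}

#' Central-axis value of an image
#'
#' Bilinear interpolation at the exact beam-axis point, which falls between
#' pixels on an even-dimensioned panel.
#'
#' @param grid an [ImageGrid-class].
#' @return The interpolated value at (0, 0).
#' @export
caxValue <- function(grid) {
  stopifnot(is(grid, "ImageGrid"))
  bilinearAt(grid, 0, 0)
}

#' Per-pixel radial distance from the beam axis
#'
#' @param grid an [ImageGrid-class].
#' @return Numeric matrix (same shape as the image) of Euclidean distances
#'   from the beam-axis point, in cm. Symmetric under 180-degree rotation
#'   about the panel centre.
#' @examples
#' g <- ImageGrid(matrix(0, 30, 40), pitchMm = 10)
#' max(radialDistanceMap(g)) < sqrt(20^2 + 15^2)  # bounded by half-diagonal
#' @export
radialDistanceMap <- function(grid) {
  stopifnot(is(grid, "ImageGrid"))
  co <- pixelCoordinatesCm(grid)
  sqrt(outer(co$y^2, co$x^2, "+"))
}

#' Panel half-diagonal
#'
#' @param grid an [ImageGrid-class].
#' @return Half the panel diagonal, cm (25 cm for the 40 x 30 cm2 panel).
#' @export
halfDiagonalCm <- function(grid) {
  ex <- panelExtentCm(grid)
  sqrt(sum((ex / 2)^2))
}

#' Extract the diagonal profile of an image
#'
#' Samples the image by bilinear interpolation along the panel-diagonal ray
#' from the centre toward the gantry/patient-left corner, at uniform radial
#' spacing `rMaxCm / (nSamples - 1)`. On a square panel this is the
#' 45-degree ray; on the 40 x 30 cm2 panel the diagonal runs at
#' atan(30/40) = 36.9 degrees, which is what lets the profile reach the
#' panel half-diagonal (25 cm) rather than leaving the panel at 21.2 cm as
#' a literal 45-degree ray would. With `symmetrize = TRUE` the value at
#' each r is the mean over the two opposite rays; the default keeps the
#' single ray, so any gantry-side asymmetry present in the image is
#' retained in the profile.
#'
#' @param image an [ImageGrid-class].
#' @param nSamples number of samples (including r = 0).
#' @param rMaxCm maximum off-axis distance, cm; must not exceed the panel
#'   half-diagonal.
#' @param symmetrize average the two opposing rays (default `FALSE`).
#' @return A [ProfileCurve-class] anchored at r = 0.
#' @examples
#' g <- ImageGrid(matrix(5, 96, 128), pitchMm = 2)
#' p <- extractDiagonalProfile(g, nSamples = 50, rMaxCm = 8)
#' all(profileValues(p) == 5)
#' @export
extractDiagonalProfile <- function(image, nSamples, rMaxCm,
                                   symmetrize = FALSE) {
  stopifnot(is(image, "ImageGrid"))
  if (nSamples < 2L) stop("'nSamples' must be at least 2")
  if (rMaxCm <= 0) stop("'rMaxCm' must be positive")
  if (rMaxCm > halfDiagonalCm(image) + 1e-9)
    stop(sprintf("'rMaxCm' (%.3g) exceeds the panel half-diagonal (%.3g cm)",
                 rMaxCm, halfDiagonalCm(image)))
  r <- seq(0, rMaxCm, length.out = nSamples)
  ex <- panelExtentCm(image)
  u <- ex / sqrt(sum(ex^2))  # unit vector toward the gantry/left corner
  # clamp=TRUE tolerates the ray tip grazing the outermost pixel centres near
  # the corner; beyond-centre positions are border-clamped by < half a pixel
  val <- bilinearAt(image, r * u[1], r * u[2])
  if (symmetrize) val <- (val + bilinearAt(image, -r * u[1], -r * u[2])) / 2
  ProfileCurve(r, val)
}

#' Evaluate a profile at arbitrary radii
#'
#' Linear interpolation in r; beyond the last tabulated sample the behaviour
#' is governed by `extrapolate`: `"clamp"` (default) holds the last value,
#' `"error"` raises a coverage error. Radii below the first sample clamp to
#' the first value.
#'
#' @param profile a [ProfileCurve-class].
#' @param r numeric vector of radii (cm, >= 0).
#' @param extrapolate `"clamp"` or `"error"`.
#' @param warn warn when clamping beyond the tabulated range.
#' @return Numeric vector of profile values at `r`.
#' @export
profileValueAt <- function(profile, r, extrapolate = c("clamp", "error"),
                           warn = FALSE) {
  stopifnot(is(profile, "ProfileCurve"))
  extrapolate <- match.arg(extrapolate)
  rmax <- max(profile@rCm)
  beyond <- r > rmax + 1e-12
  if (any(beyond)) {
    if (extrapolate == "error")
      stop(sprintf("profile covers r <= %.4g cm but %.4g cm was requested",
                   rmax, max(r)))
    if (warn)
      warning(sprintf("clamping profile beyond its last sample (%.4g cm)", rmax))
  }
  stats::approx(profile@rCm, profile@value, xout = pmin(pmax(r, profile@rCm[1]), rmax),
                method = "linear", rule = 2)$y
}
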