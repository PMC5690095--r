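# Global gamma-index comparison of measured vs predicted portal images,
# with an exhaustive brute-force oracle for verification.

gammaNormValue <- function(reference, params) {
  nv <- switch(params@normalization,
               global_max = max(reference@values),
               global_cax = caxValue(reference))
  if (!is.finite(nv) || nv <= 0)
    stop("reference normalization value must be positive")
  nv
}

# Per-pixel absolute dose tolerance and evaluation mask shared by the fast
# path and the oracle.
gammaSetup <- function(reference, evaluated, params) {
  stopifnot(is(reference, "ImageGrid"), is(evaluated, "ImageGrid"),
            is(params, "GammaParams"))
  checkSameGeometry(reference, evaluated, "reference and evaluated")
  nv <- gammaNormValue(reference, params)
  evalMask <- reference@values >= (params@lowDoseThresholdPct / 100) * nv
  doseTol <- if (params@local) {
    pmax(abs(reference@values), 1e-12 * nv) * params@doseCriterionPct / 100
  } else {
    matrix(nv * params@doseCriterionPct / 100,
           nrow(reference@values), ncol(reference@values))
  }
  list(doseTol = doseTol, evalMask = evalMask)
}

summarizeGamma <- function(g, params) {
  evaluated <- !is.na(g)
  n <- sum(evaluated)
  pass <- if (n > 0) 100 * sum(g[evaluated] <= 1) / n else NA_real_
  new("GammaResult", gammaMap = g, passRatePct = pass,
      nEvaluated = as.integer(n), params = params)
}

#' Gamma-index map and pass rate
#'
#' Computes the Low-style gamma index of the evaluated image against the
#' reference image: for each reference pixel,
#' \deqn{\gamma = \min_s \sqrt{d(s)^2/\Delta d^2 + \delta D(s)^2/\Delta D^2}}
#' over evaluated-image positions \eqn{s} within
#' `searchRadiusFactor * distanceCriterionMm` of the pixel, sampled on a
#' grid of `distanceCriterionMm / searchSubsample` steps with bilinear
#' interpolation. Dose differences are normalized globally by the reference
#' maximum (or central-axis value), or locally when `params@local`.
#' Reference pixels below the low-dose threshold are excluded (`NA` in the
#' map). A pixel passes when gamma <= 1 (ties pass).
#'
#' By QA convention the *predicted* image is the reference and the
#' measurement is evaluated against it.
#'
#' @param reference,evaluated [ImageGrid-class] objects with identical
#'   geometry.
#' @param params a [GammaParams-class] (default: 3%, 3 mm, global maximum,
#'   no threshold).
#' @return A [GammaResult-class].
#' @examples
#' g <- ImageGrid(matrix(runif(64, 0.5, 1), 8, 8), pitchMm = 1)
#' passRatePct(gammaIndex(g, g))  # identical images: 100
#' @export
gammaIndex <- function(reference, evaluated, params = GammaParams()) {
  s <- gammaSetup(reference, evaluated, params)
  step <- params@distanceCriterionMm / params@searchSubsample
  radius <- params@searchRadiusFactor * params@distanceCriterionMm
  g <- cpp_gamma_map(reference@values, evaluated@values, s$doseTol,
                     s$evalMask, pitchMm(reference),
                     params@distanceCriterionMm, radius, step)
  summarizeGamma(g, params)
}

#' Brute-force gamma oracle
#'
#' Same contract as [gammaIndex()], computed by exhaustive search over a
#' fixed fine offset grid (50 subdivisions per distance criterion) with no
#' shortcuts, in plain R. Intended as ground truth on small images
#' (<= 64 x 64 advisory); cost grows as pixels x offsets.
#'
#' @inheritParams gammaIndex
#' @param subsample fine-grid subdivisions per distance criterion (50).
#' @return A [GammaResult-class].
#' @export
gammaOracle <- function(reference, evaluated, params = GammaParams(),
                        subsample = 50L) {
  s <- gammaSetup(reference, evaluated, params)
  if (nrow(reference@values) > 64 || ncol(reference@values) > 64)
    warning("gammaOracle is exhaustive; images above 64x64 will be slow")
  pitch <- pitchMm(reference)
  dtol <- params@distanceCriterionMm
  radius <- params@searchRadiusFactor * dtol
  step <- dtol / subsample
  k <- floor(radius / step + 1e-9)
  g1 <- seq(-k, k) * step
  dr <- rep(g1, times = length(g1))
  dc <- rep(g1, each = length(g1))
  keep <- dr^2 + dc^2 <= radius^2 + 1e-9
  dr <- dr[keep] / pitch              # row offset, pixels
  dc <- dc[keep] / pitch              # col offset, pixels
  dist2 <- (dr^2 + dc^2) * (pitch / dtol)^2
  ev <- evaluated@values
  nr <- nrow(ev); nc <- ncol(ev)
  g <- matrix(NA_real_, nr, nc)
  for (j in seq_len(nr)) {
    for (i in seq_len(nc)) {
      if (!s$evalMask[j, i]) next
      rr <- (j - 1) + dr
      cc <- (i - 1) + dc
      ok <- rr >= 0 & rr <= nr - 1 & cc >= 0 & cc <= nc - 1
      j0 <- pmin(floor(rr[ok]), nr - 2); i0 <- pmin(floor(cc[ok]), nc - 2)
      fy <- rr[ok] - j0; fx <- cc[ok] - i0
      v <- ev[cbind(j0 + 1, i0 + 1)] * (1 - fx) * (1 - fy) +
           ev[cbind(j0 + 1, i0 + 2)] * fx * (1 - fy) +
           ev[cbind(j0 + 2, i0 + 1)] * (1 - fx) * fy +
           ev[cbind(j0 + 2, i0 + 2)] * fx * fy
      dd <- (v - reference@values[j, i]) / s$doseTol[j, i]
      g[j, i] <- sqrt(min(dist2[ok] + dd^2))
    }
  }
  summarizeGamma(g, params)
}

#' Summarize pass rates over a set of gamma results
#'
#' Arithmetic mean, minimum, maximum, population standard deviation of the
#' pass rates, and the field count — the columns of a QA summary table.
#'
#' @param results a non-empty list of [GammaResult-class] objects, or a
#'   numeric vector of pass rates in percent.
#' @return A one-row `data.frame` with columns `avg`, `min`, `max`, `sd`,
#'   `nFields`.
#' @examples
#' passRateSummary(c(99.5, 100, 99.9, 99.8))
#' @export
passRateSummary <- function(results) {
  rates <- if (is.numeric(results)) results
  else vapply(results, function(x) {
    stopifnot(is(x, "GammaResult")); x@passRatePct
  }, numeric(1))
  if (length(rates) == 0) stop("no gamma results supplied")
  data.frame(avg = mean(rates), min = min(rates), max = max(rates),
             sd = sqrt(mean((rates - mean(rates))^2)),
             nFields = length(rates))
}
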