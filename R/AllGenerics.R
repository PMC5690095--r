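# Accessor generics and show methods.

#' @rdname ImageGrid-class
#' @param x,object an object.
#' @export
setGeneric("nX", function(x) standardGeneric("nX"))
#' @rdname ImageGrid-class
#' @export
setGeneric("nY", function(x) standardGeneric("nY"))
#' @rdname ImageGrid-class
#' @export
setGeneric("pitchMm", function(x) standardGeneric("pitchMm"))
#' @rdname ImageGrid-class
#' @export
setGeneric("imageValues", function(x) standardGeneric("imageValues"))

#' @rdname ImageGrid-class
#' @export
setMethod("nX", "ImageGrid", function(x) ncol(x@values))
#' @rdname ImageGrid-class
#' @export
setMethod("nY", "ImageGrid", function(x) nrow(x@values))
#' @rdname ImageGrid-class
#' @export
setMethod("pitchMm", "ImageGrid", function(x) x@pitchMm)
#' @rdname ImageGrid-class
#' @export
setMethod("imageValues", "ImageGrid", function(x) x@values)

#' @rdname ImageGrid-class
#' @export
setMethod("dim", "ImageGrid", function(x) dim(x@values))

#' @rdname ImageGrid-class
#' @export
setMethod("show", "ImageGrid", function(object) {
  ex <- panelExtentCm(object)
  cat(sprintf("ImageGrid: %d x %d pixels, pitch %.5g mm (%.3g x %.3g cm)\n",
              nX(object), nY(object), pitchMm(object), ex[1], ex[2]))
  v <- object@values
  cat(sprintf("  values: [%.4g, %.4g], CAX %.4g\n",
              min(v), max(v), caxValue(object)))
})

#' @rdname ProfileCurve-class
#' @param x,object an object.
#' @export
setGeneric("rCm", function(x) standardGeneric("rCm"))
#' @rdname ProfileCurve-class
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))

#' @rdname ProfileCurve-class
#' @export
setMethod("rCm", "ProfileCurve", function(x) x@rCm)
#' @rdname ProfileCurve-class
#' @export
setMethod("profileValues", "ProfileCurve", function(x) x@value)
#' @rdname RatioCurve-class
#' @param x,object an object.
#' @export
setMethod("rCm", "RatioCurve", function(x) x@rCm)

#' @rdname RatioCurve-class
#' @export
setGeneric("ratioValues", function(x) standardGeneric("ratioValues"))
#' @rdname RatioCurve-class
#' @export
setMethod("ratioValues", "RatioCurve", function(x) x@ratio)

#' @rdname ProfileCurve-class
#' @export
setMethod("length", "ProfileCurve", function(x) length(x@rCm))

#' @rdname ProfileCurve-class
#' @export
setMethod("show", "ProfileCurve", function(object) {
  cat(sprintf("ProfileCurve: %d samples, r in [%.3g, %.3g] cm, values in [%.4g, %.4g]\n",
              length(object@rCm), min(object@rCm), max(object@rCm),
              min(object@value), max(object@value)))
})

#' @rdname RatioCurve-class
#' @export
setMethod("show", "RatioCurve", function(object) {
  cat(sprintf("RatioCurve (%s): %d samples, r in [%.3g, %.3g] cm, ratio in [%.5g, %.5g]\n",
              object@orientation, length(object@rCm), min(object@rCm),
              max(object@rCm), min(object@ratio), max(object@ratio)))
})

#' @rdname PolyCorrection-class
#' @param object an object.
#' @export
setMethod("show", "PolyCorrection", function(object) {
  cat(sprintf("PolyCorrection (%s): order %d, fit [%.3g, %.3g] cm, applied to %.3g cm\n",
              object@mode, object@order, object@rFitMinCm, object@rFitMaxCm,
              object@rApplyMaxCm))
  cat(sprintf("  R^2 = %.6g; c(r) range on fit window: [%.4g%%, %.4g%%]\n",
              object@rSquared,
              100 * min(correctionFactor(object,
                seq(object@rFitMinCm, object@rFitMaxCm, length.out = 201))),
              100 * max(correctionFactor(object,
                seq(object@rFitMinCm, object@rFitMaxCm, length.out = 201)))))
})

#' @rdname CalibrationSet-class
#' @param object an object.
#' @export
setMethod("show", "CalibrationSet", function(object) {
  cat(sprintf("CalibrationSet: %d x %d panel, pitch %.5g mm\n",
              nX(object@flood), nY(object@flood), pitchMm(object@flood)))
  cat(sprintf("  cuScale: %s; 2D correction: %s; reference: %g MU, %s field\n",
              if (is.na(object@cuScale)) "unset" else
                format(object@cuScale, digits = 6),
              if (length(object@correction2d) > 0) "present" else "none",
              object@muReference, object@fieldReference))
})

#' @rdname GammaResult-class
#' @param x,object an object.
#' @export
setGeneric("gammaValues", function(x) standardGeneric("gammaValues"))
#' @rdname GammaResult-class
#' @export
setMethod("gammaValues", "GammaResult", function(x) x@gammaMap)
#' @rdname GammaResult-class
#' @export
setGeneric("passRatePct", function(x) standardGeneric("passRatePct"))
#' @rdname GammaResult-class
#' @export
setMethod("passRatePct", "GammaResult", function(x) x@passRatePct)
#' @rdname GammaResult-class
#' @export
setGeneric("nEvaluated", function(x) standardGeneric("nEvaluated"))
#' @rdname GammaResult-class
#' @export
setMethod("nEvaluated", "GammaResult", function(x) x@nEvaluated)

#' @rdname GammaResult-class
#' @export
setMethod("show", "GammaResult", function(object) {
  p <- object@params
  cat(sprintf("GammaResult: %.1f%%/%.1f mm (%s%s), %d pixels evaluated\n",
              p@doseCriterionPct, p@distanceCriterionMm,
              if (p@local) "local" else "global",
              if (p@lowDoseThresholdPct > 0)
                sprintf(", threshold %g%%", p@lowDoseThresholdPct) else "",
              object@nEvaluated))
  g <- object@gammaMap[!is.na(object@gammaMap)]
  cat(sprintf("  pass rate %.2f%%; gamma mean %.3f, max %.3f\n",
              object@passRatePct, mean(g), max(g)))
})

#' @rdname SimConfig-class
#' @param object an object.
#' @export
setMethod("show", "SimConfig", function(object) {
  cat(sprintf("SimConfig: %d x %d panel, pitch %.5g mm\n",
              object@nX, object@nY, object@pitchMm))
  cat(sprintf("  horns (h2, h4): %s; over-response (a2, a4): %s\n",
              paste(signif(object@hornParams, 4), collapse = ", "),
              paste(signif(object@overresponseParams, 4), collapse = ", ")))
  cat(sprintf("  backscatter: amplitude %.3g, extent %.3g cm; noise sigma %.3g; dark %.3g\n",
              object@backscatterAmplitude, object@backscatterExtentCm,
              object@noiseSigma, object@darkLevel))
  cat(sprintf("  seeds: sensitivity %d, noise %d\n",
              object@sensitivitySeed, object@noiseSeed))
})
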