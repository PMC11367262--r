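#' @rdname Arc-class
#' @param object,x an object.
#' @export
setGeneric("nControlPoints", function(x) standardGeneric("nControlPoints"))

#' @rdname Arc-class
#' @export
setGeneric("nLeafPairs", function(x) standardGeneric("nLeafPairs"))

#' @rdname Arc-class
#' @export
setGeneric("beamId", function(x) standardGeneric("beamId"))

#' @rdname Arc-class
#' @export
setGeneric("totalMU", function(x) standardGeneric("totalMU"))

#' @rdname Arc-class
#' @export
setGeneric("treatmentSite", function(x) standardGeneric("treatmentSite"))

#' @rdname Plan-class
#' @export
setGeneric("arcs", function(x) standardGeneric("arcs"))

#' @rdname Plan-class
#' @export
setGeneric("planId", function(x) standardGeneric("planId"))

#' @rdname GammaResult-class
#' @export
setGeneric("gpr", function(x) standardGeneric("gpr"))

#' @rdname Arc-class
#' @export
setMethod("nControlPoints", "Arc", function(x) length(x@gantryAngle))

#' @rdname Arc-class
#' @export
setMethod("nLeafPairs", "Arc", function(x) ncol(x@bankA))

#' @rdname Arc-class
#' @export
setMethod("beamId", "Arc", function(x) x@beamId)

#' @rdname Arc-class
#' @export
setMethod("totalMU", "Arc", function(x) x@totalMU)

#' @rdname Arc-class
#' @export
setMethod("treatmentSite", "Arc", function(x) x@treatmentSite)

#' @rdname Plan-class
#' @export
setMethod("treatmentSite", "Plan", function(x) x@treatmentSite)

#' @rdname Plan-class
#' @export
setMethod("arcs", "Plan", function(x) x@arcs)

#' @rdname Plan-class
#' @export
setMethod("planId", "Plan", function(x) x@planId)

#' @rdname GammaResult-class
#' @export
setMethod("gpr", "GammaResult", function(x) x@gpr)

#' Extract one control point from an arc
#'
#' @param arc an \linkS4class{Arc}.
#' @param i control-point index (1-based).
#' @return A \linkS4class{ControlPoint}.
#' @export
controlPoint <- function(arc, i) {
  stopifnot(is(arc, "Arc"), i >= 1, i <= nControlPoints(arc))
  new("ControlPoint",
      index = as.integer(i),
      gantryAngle = arc@gantryAngle[i],
      cumulativeMetersetWeight = arc@cumulativeMetersetWeight[i],
      doseRate = arc@doseRate[i],
      bankA = arc@bankA[i, ],
      bankB = arc@bankB[i, ],
      jawX = arc@jawX[i, ],
      jawY = arc@jawY[i, ])
}

setMethod("show", "Arc", function(object) {
  cat(sprintf("Arc '%s' (%s, %s): %d control points, %d leaf pairs, %.1f MU, site '%s'\n",
              object@beamId, object@machine, object@energy,
              nControlPoints(object), nLeafPairs(object), object@totalMU,
              object@treatmentSite))
  g <- object@gantryAngle
  cat(sprintf("  gantry %.1f deg -> %.1f deg\n", g[1], g[length(g)]))
})

setMethod("show", "Plan", function(object) {
  cat(sprintf("Plan '%s' (site '%s'): %d arc(s)\n", object@planId,
              object@treatmentSite, length(object@arcs)))
  for (a in object@arcs)
    cat(sprintf("  - %s: %d control points, %.1f MU\n", a@beamId,
                nControlPoints(a), a@totalMU))
})

setMethod("show", "DoseGrid", function(object) {
  cat(sprintf("DoseGrid %d x %d, spacing (%.2f, %.2f) mm, origin (%.1f, %.1f) mm, max %.3g\n",
              nrow(object@values), ncol(object@values), object@spacing[1],
              object@spacing[2], object@origin[1], object@origin[2],
              max(object@values)))
})

setMethod("show", "GammaResult", function(object) {
  cat(sprintf("GammaResult: GPR %.2f%% (%d points evaluated) -> %s at %g%% action limit\n",
              object@gpr, object@nEvaluated,
              if (object@pass) "PASS" else "FAIL",
              object@criteria@actionLimit))
})

setMethod("show", "SpecificationLimits", function(object) {
  t <- object@table
  cat(sprintf("SpecificationLimits (%g/%g percentiles, baseline '%s'): %d site(s), %d row(s)\n",
              100 * object@percentiles[1], 100 * object@percentiles[2],
              object@baselineLabel, length(unique(t$site)), nrow(t)))
})

setMethod("show", "GPRModel", function(object) {
  cat(sprintf("GPRModel v%s: %d features, trained on n = %d (seed %d)\n",
              object@meta$version, length(object@featureNames),
              object@meta$n, object@meta$seed))
})

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport: MAE %.2f pp, sensitivity %s, specificity %s (n = %d, action limit %g%%)\n",
              object@mae,
              ifelse(is.na(object@sensitivity), "undefined",
                     sprintf("%.2f", object@sensitivity)),
              sprintf("%.2f", object@specificity),
              object@nTest, object@actionLimit))
})

setMethod("show", "RiskReport", function(object) {
  cat(sprintf("RiskReport for plan '%s' (site '%s'): %s (reason: %s), mean predicted GPR %.1f%%\n",
              object@planId, object@site,
              if (object@planAtRisk) "AT RISK" else "not at risk",
              object@reason, object@meanPredictedGPR))
  for (ar in object@arcReports)
    cat(sprintf("  arc %s: predicted GPR %.1f%%, %d/10 metrics out of spec, defect = %s, at risk = %s\n",
                ar$beamId, ar$predictedGPR,
                sum(ar$flags$status != "IN_SPEC"),
                ar$defect, ar$atRisk))
})
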