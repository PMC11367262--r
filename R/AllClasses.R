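#' @import methods
#' @importFrom stats quantile sd approx pnorm rnorm runif wilcox.test median
#' @importFrom stats setNames predict plogis rbeta
#' @importFrom utils read.csv write.csv write.table head tail
#' @useDynLib vmatqa, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Canonical names of the ten per-arc complexity metrics
#'
#' Order is fixed and used everywhere a complexity vector is stored or
#' exchanged (CSV columns, specification limits, model features).
#'
#' @return Character vector of length ten.
#' @export
complexityMetricNames <- function() {
  c("q1_mlc_gap", "median_mlc_gap", "sas10", "mean_tgi", "mcs",
    "mi_total", "bi", "bm", "edge_metric", "lt_al")
}

#' A single VMAT control point
#'
#' Machine state sampled along an arc: gantry angle, cumulative meterset
#' weight, optional dose rate, both MLC bank positions (IEC-X, mm at
#' isocenter; bank A is the left bank, smaller x) and the X/Y jaw windows.
#'
#' @slot index integer control-point index (1-based).
#' @slot gantryAngle numeric, degrees in [0, 360).
#' @slot cumulativeMetersetWeight numeric fraction in [0, 1].
#' @slot doseRate numeric, MU/min (NA when not recorded).
#' @slot bankA,bankB numeric vectors of leaf-tip x positions, one per pair.
#' @slot jawX,jawY numeric length-2 jaw windows (x1, x2) / (y1, y2), mm.
#' @export
setClass("ControlPoint", representation(
  index = "integer",
  gantryAngle = "numeric",
  cumulativeMetersetWeight = "numeric",
  doseRate = "numeric",
  bankA = "numeric",
  bankB = "numeric",
  jawX = "numeric",
  jawY = "numeric"
))

setValidity("ControlPoint", function(object) {
  msg <- character()
  if (length(object@bankA) != length(object@bankB))
    msg <- c(msg, "bankA and bankB must have the same length")
  if (any(object@bankB + 1e-9 < object@bankA))
    msg <- c(msg, "bank B (right) positions must be >= bank A (left) positions")
  if (length(object@jawX) != 2 || diff(object@jawX) <= 0)
    msg <- c(msg, "jawX must be a non-degenerate (x1, x2) interval")
  if (length(object@jawY) != 2 || diff(object@jawY) <= 0)
    msg <- c(msg, "jawY must be a non-degenerate (y1, y2) interval")
  w <- object@cumulativeMetersetWeight
  if (!is.finite(w) || w < -1e-9 || w > 1 + 1e-9)
    msg <- c(msg, "cumulativeMetersetWeight must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' A VMAT arc (one dynamic beam)
#'
#' Control points are stored column-wise in matrices for speed: row k of
#' \code{bankA}/\code{bankB} holds the leaf positions at control point k.
#'
#' @slot beamId character beam identifier.
#' @slot machine,energy character machine name and nominal energy label.
#' @slot totalMU numeric total monitor units of the beam (> 0).
#' @slot gantryAngle numeric vector (degrees, one per control point).
#' @slot cumulativeMetersetWeight numeric non-decreasing, first 0, last 1.
#' @slot doseRate numeric vector (MU/min; NA allowed).
#' @slot bankA,bankB numeric matrices (control points x leaf pairs), mm.
#' @slot jawX,jawY numeric matrices (control points x 2), mm.
#' @slot leafBoundaries numeric vector of pairs + 1 strictly increasing
#'   y-coordinates (mm) bounding the leaf pairs.
#' @slot treatmentSite character site label.
#' @export
setClass("Arc", representation(
  beamId = "character",
  machine = "character",
  energy = "character",
  totalMU = "numeric",
  gantryAngle = "numeric",
  cumulativeMetersetWeight = "numeric",
  doseRate = "numeric",
  bankA = "matrix",
  bankB = "matrix",
  jawX = "matrix",
  jawY = "matrix",
  leafBoundaries = "numeric",
  treatmentSite = "character"
))

setValidity("Arc", function(object) {
  msg <- character()
  n <- length(object@gantryAngle)
  p <- ncol(object@bankA)
  if (n < 2) msg <- c(msg, "an arc needs at least 2 control points")
  if (!isTRUE(object@totalMU > 0)) msg <- c(msg, "totalMU must be > 0")
  if (length(object@cumulativeMetersetWeight) != n ||
      nrow(object@bankA) != n || nrow(object@bankB) != n ||
      nrow(object@jawX) != n || nrow(object@jawY) != n ||
      length(object@doseRate) != n)
    msg <- c(msg, "all per-control-point fields must have one row per control point")
  if (ncol(object@bankB) != p)
    msg <- c(msg, "bank matrices must have the same number of leaf pairs")
  if (length(object@leafBoundaries) != p + 1)
    msg <- c(msg, "leafBoundaries must have length nLeafPairs + 1")
  if (any(diff(object@leafBoundaries) <= 0))
    msg <- c(msg, "leafBoundaries must be strictly increasing")
  w <- object@cumulativeMetersetWeight
  if (length(w) >= 2) {
    if (any(diff(w) < -1e-9))
      msg <- c(msg, "cumulative meterset weight must be non-decreasing")
    if (abs(w[1]) > 1e-6 || abs(w[length(w)] - 1) > 1e-6)
      msg <- c(msg, "cumulative meterset weight must start at 0 and end at 1")
  }
  if (any(object@bankB + 1e-9 < object@bankA))
    msg <- c(msg, "bank B positions must be >= bank A positions everywhere")
  if (length(msg)) msg else TRUE
})

#' A VMAT plan: one or more arcs sharing a treatment site
#'
#' @slot planId character plan identifier.
#' @slot arcs list of \linkS4class{Arc}.
#' @slot treatmentSite character site label shared by all arcs.
#' @slot approvalTime POSIXct approval timestamp.
#' @export
setClass("Plan", representation(
  planId = "character",
  arcs = "list",
  treatmentSite = "character",
  approvalTime = "POSIXct"
))

setValidity("Plan", function(object) {
  msg <- character()
  if (length(object@arcs) < 1) msg <- c(msg, "a plan needs at least one arc")
  if (!all(vapply(object@arcs, is, logical(1), "Arc")))
    msg <- c(msg, "arcs must all be Arc objects")
  sites <- vapply(object@arcs, function(a) a@treatmentSite, character(1))
  if (length(sites) && !all(sites == object@treatmentSite))
    msg <- c(msg, "all arcs must share the plan's treatment site")
  if (length(msg)) msg else TRUE
})

#' Aperture geometry of one control point
#'
#' Jaw-clipped open region of the MLC aperture: per-pair exposed intervals,
#' open gaps, area, closed-boundary perimeter and exposed adjacent-leaf
#' side-edge length. This is the shared geometry kernel behind all
#' aperture-shape complexity metrics.
#'
#' @slot openPairs integer indices of leaf pairs counted as open.
#' @slot gaps numeric exposed gap (mm) per open pair.
#' @slot widths numeric jaw-clipped strip width (mm) per open pair.
#' @slot exposedA,exposedB numeric clipped interval endpoints per open pair.
#' @slot area numeric open area, mm^2.
#' @slot perimeter numeric boundary length of the open region, mm.
#' @slot sideEdgeLength numeric exposed adjacent-leaf step length, mm.
#' @export
setClass("ApertureGeometry", representation(
  openPairs = "integer",
  gaps = "numeric",
  widths = "numeric",
  exposedA = "numeric",
  exposedB = "numeric",
  area = "numeric",
  perimeter = "numeric",
  sideEdgeLength = "numeric"
))

setValidity("ApertureGeometry", function(object) {
  msg <- character()
  if (object@area < 0) msg <- c(msg, "area must be >= 0")
  if (object@perimeter < 0) msg <- c(msg, "perimeter must be >= 0")
  if (any(object@gaps <= 0)) msg <- c(msg, "listed gaps must be > 0")
  if (length(msg)) msg else TRUE
})

#' Delivery-system limits used by the timing model
#'
#' Defaults correspond to a TrueBeam-class C-arm linac: 25 mm/s leaf speed,
#' 6 deg/s gantry speed, 600 MU/min dose rate.
#'
#' @slot maxLeafSpeed numeric mm/s.
#' @slot maxGantrySpeed numeric deg/s.
#' @slot maxDoseRate numeric MU/min.
#' @export
setClass("MachineLimits", representation(
  maxLeafSpeed = "numeric",
  maxGantrySpeed = "numeric",
  maxDoseRate = "numeric"
))

setValidity("MachineLimits", function(object) {
  if (object@maxLeafSpeed > 0 && object@maxGantrySpeed > 0 &&
      object@maxDoseRate > 0) TRUE
  else "all machine limits must be > 0"
})

#' @describeIn MachineLimits-class Constructor with TrueBeam-class defaults.
#' @param maxLeafSpeed,maxGantrySpeed,maxDoseRate positive numerics.
#' @export
machineLimits <- function(maxLeafSpeed = 25, maxGantrySpeed = 6,
                          maxDoseRate = 600) {
  new("MachineLimits", maxLeafSpeed = maxLeafSpeed,
      maxGantrySpeed = maxGantrySpeed, maxDoseRate = maxDoseRate)
}

#' A planar dose grid
#'
#' @slot values numeric matrix of dose (consistent arbitrary units, >= 0).
#' @slot spacing numeric length-2 (row, col) pixel spacing, mm.
#' @slot origin numeric length-2 (y, x) position of pixel [1, 1], mm.
#' @export
setClass("DoseGrid", representation(
  values = "matrix",
  spacing = "numeric",
  origin = "numeric"
))

setValidity("DoseGrid", function(object) {
  msg <- character()
  if (length(object@spacing) != 2 || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be two positive numbers (row, col)")
  if (length(object@origin) != 2)
    msg <- c(msg, "origin must be (y, x)")
  if (!all(is.finite(object@values)) || any(object@values < 0))
    msg <- c(msg, "dose values must be finite and >= 0")
  if (length(msg)) msg else TRUE
})

#' Gamma-comparison criteria
#'
#' Global gamma criteria in the PSQA sense: dose tolerance as a percentage of
#' the reference-grid maximum, distance-to-agreement in mm, a low-dose cutoff
#' (points of the reference grid below this percentage of the maximum are not
#' evaluated) and the passing-rate action limit.
#'
#' @slot doseTolerance numeric percent of the reference maximum.
#' @slot distanceTolerance numeric mm.
#' @slot lowDoseCutoff numeric percent of the reference maximum.
#' @slot actionLimit numeric percent.
#' @export
setClass("GammaCriteria", representation(
  doseTolerance = "numeric",
  distanceTolerance = "numeric",
  lowDoseCutoff = "numeric",
  actionLimit = "numeric"
))

setValidity("GammaCriteria", function(object) {
  ok <- c(object@doseTolerance, object@distanceTolerance,
          object@lowDoseCutoff, object@actionLimit)
  if (all(ok > 0)) TRUE else "all gamma criteria must be > 0"
})

#' @describeIn GammaCriteria-class Constructor; defaults are the clinical
#'   EPID-PSQA setting: 3\% (global) / 1 mm, 10\% cutoff, 90\% action limit.
#' @param doseTolerance,distanceTolerance,lowDoseCutoff,actionLimit positive
#'   numerics (percent, mm, percent, percent).
#' @export
gammaCriteria <- function(doseTolerance = 3, distanceTolerance = 1,
                          lowDoseCutoff = 10, actionLimit = 90) {
  new("GammaCriteria", doseTolerance = doseTolerance,
      distanceTolerance = distanceTolerance, lowDoseCutoff = lowDoseCutoff,
      actionLimit = actionLimit)
}

#' Result of a gamma comparison
#'
#' @slot gammaMap numeric matrix of gamma values (NaN below the cutoff).
#' @slot gpr numeric gamma passing rate, percent.
#' @slot nEvaluated integer number of evaluated points.
#' @slot pass logical, gpr >= action limit.
#' @slot criteria the \linkS4class{GammaCriteria} used.
#' @export
setClass("GammaResult", representation(
  gammaMap = "matrix",
  gpr = "numeric",
  nEvaluated = "integer",
  pass = "logical",
  criteria = "GammaCriteria"
))

setValidity("GammaResult", function(object) {
  msg <- character()
  g <- object@gammaMap
  if (any(g[is.finite(g)] < 0)) msg <- c(msg, "gamma values must be >= 0")
  if (object@gpr < 0 || object@gpr > 100)
    msg <- c(msg, "gpr must lie in [0, 100]")
  if (length(msg)) msg else TRUE
})

#' Per-site percentile specification limits
#'
#' For every (treatment site, metric) pair the 5th/95th percentiles of a
#' baseline cohort, with the stratum size; strata smaller than
#' \code{minStratum} are kept but marked unusable.
#'
#' @slot table data.frame with columns site, metric, low, high, n, usable.
#' @slot percentiles numeric length-2, the probabilities used (default .05/.95).
#' @slot baselineLabel character free-text label of the baseline period.
#' @export
setClass("SpecificationLimits", representation(
  table = "data.frame",
  percentiles = "numeric",
  baselineLabel = "character"
))

setValidity("SpecificationLimits", function(object) {
  need <- c("site", "metric", "low", "high", "n", "usable")
  if (!all(need %in% names(object@table)))
    return("limits table must have columns site, metric, low, high, n, usable")
  bad <- with(object@table, is.finite(low) & is.finite(high) & low > high)
  if (any(bad)) return("low limit must be <= high limit")
  TRUE
})

#' A trained gamma-passing-rate regression model
#'
#' Wraps a serialized gradient-boosted tree ensemble together with the fixed
#' 19-name feature list and training metadata, so that predictions refuse to
#' run on a mismatched feature set and serialization round-trips exactly.
#'
#' @slot booster raw vector, serialized xgboost booster.
#' @slot featureNames character vector of length 19, fixed order.
#' @slot meta list: n, seed, params, trainedAt, version.
#' @export
setClass("GPRModel", representation(
  booster = "raw",
  featureNames = "character",
  meta = "list"
))

setValidity("GPRModel", function(object) {
  if (length(object@featureNames) != 19)
    return("a GPR model uses exactly 19 named features")
  TRUE
})

#' Held-out evaluation of a GPR model
#'
#' @slot mae numeric mean absolute error, percentage points.
#' @slot sensitivity numeric P(pred < limit | label < limit), NA when there
#'   are no failing cases in the test set.
#' @slot specificity numeric P(pred >= limit | label >= limit).
#' @slot nTest integer test-set size.
#' @slot actionLimit numeric percent.
#' @export
setClass("EvaluationReport", representation(
  mae = "numeric",
  sensitivity = "numeric",
  specificity = "numeric",
  nTest = "integer",
  actionLimit = "numeric"
))

#' Per-plan risk report
#'
#' One entry per arc (metrics, flags, predicted GPR, defect / at-risk
#' booleans, feature attribution) plus the plan-level decision and the reason
#' clause that fired.
#'
#' @slot planId,site character identifiers.
#' @slot timestamp POSIXct report time.
#' @slot arcReports list, one per arc.
#' @slot planAtRisk logical.
#' @slot reason character: "complexity-majority", "predicted-GPR", "both" or
#'   "none".
#' @slot meanPredictedGPR numeric percent.
#' @export
setClass("RiskReport", representation(
  planId = "character",
  site = "character",
  timestamp = "POSIXct",
  arcReports = "list",
  planAtRisk = "logical",
  reason = "character",
  meanPredictedGPR = "numeric"
))
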