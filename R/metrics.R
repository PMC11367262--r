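# Per-arc complexity metrics.
#
# MU weighting convention: segment k runs from control point k to k + 1 and
# carries meterset fraction dw_k = w_{k+1} - w_k. Every MU-weighted aperture
# metric evaluates its per-control-point quantity at the segment *start* and
# weights it by dw_k (left-endpoint rule). This makes all weighted metrics
# exactly invariant both to re-normalization of the meterset weights and to
# splitting a control point into identical halves with divided segment MU.

.segWeights <- function(arc) {
  dw <- diff(arc@cumulativeMetersetWeight)
  dw / sum(dw)
}

# weighted mean of per-control-point values over segment-start points,
# restricted to control points where the aperture is open
.cpWeightedMean <- function(values, dw, openCP) {
  k <- seq_along(dw)
  use <- openCP[k]
  if (!any(use)) stop("no open aperture in any weighted control point")
  sum(values[k][use] * dw[use]) / sum(dw[use])
}

.openGaps <- function(geom) {
  g <- geom$gap[geom$open]
  if (!length(g)) stop("arc has no open aperture: gap metrics are undefined")
  g
}

.arcAngularDeltas <- function(gantry) {
  d <- abs(diff(gantry))
  pmin(d, 360 - d)            # shortest-path wrap at the 0/360 seam
}

#' First quartile and median of the pooled MLC gap distribution
#'
#' Open gaps (jaw-clipped, above the open threshold) are pooled over all
#' control points of the arc; quantiles use linear interpolation between
#' order statistics.
#'
#' @param arc an \linkS4class{Arc}.
#' @param minGap open-pair threshold (mm), see [apertureGeometry()].
#' @param geom optional precomputed geometry (internal reuse).
#' @return Named numeric: \code{q1} and \code{median}, mm.
#' @export
gapQuantiles <- function(arc, minGap = 0.5, geom = NULL) {
  if (is.null(geom)) geom <- .arcGeometry(arc, minGap)
  g <- .openGaps(geom)
  q <- quantile(g, c(0.25, 0.5), names = FALSE, type = 7)
  c(q1 = q[1], median = q[2])
}

#' Small aperture score
#'
#' Fraction of pooled open MLC gaps strictly below \code{threshold}
#' (default 10 mm), unweighted over control points.
#'
#' @inheritParams gapQuantiles
#' @param threshold gap size (mm) below which an aperture counts as small.
#' @return Fraction in [0, 1].
#' @export
smallApertureScore <- function(arc, threshold = 10, minGap = 0.5, geom = NULL) {
  if (is.null(geom)) geom <- .arcGeometry(arc, minGap)
  g <- .openGaps(geom)
  mean(g < threshold)
}

#' Mean tongue-and-groove index
#'
#' Per control point, TGI = S / (S + G) where S is the exposed adjacent-leaf
#' step length and G the total open gap length; the arc value is the
#' MU-weighted mean. 0 for rectangular apertures, always < 1.
#'
#' @inheritParams gapQuantiles
#' @return Fraction in [0, 1).
#' @export
meanTGI <- function(arc, minGap = 0.5, geom = NULL) {
  if (is.null(geom)) geom <- .arcGeometry(arc, minGap)
  openCP <- rowSums(geom$open) > 0
  G <- rowSums(ifelse(geom$open, geom$gap, 0))
  S <- geom$steps
  tgi <- ifelse(openCP, S / (S + G), 0)
  .cpWeightedMean(tgi, .segWeights(arc), openCP)
}

.aavlsv <- function(arc, geom) {
  n <- nControlPoints(arc)
  gapO <- ifelse(geom$open, geom$gap, 0)
  pairMax <- apply(gapO, 2, max)             # per-pair max open gap over arc
  denom <- sum(pairMax)
  aav <- if (denom > 0) rowSums(gapO) / denom else rep(0, n)
  lsvBank <- function(pos, openRow) {
    idx <- which(openRow)
    if (length(idx) < 2) return(1)
    p <- pos[idx]
    pmaxv <- max(p) - min(p)
    if (pmaxv == 0) return(1)
    sum(pmaxv - abs(diff(p))) / ((length(idx) - 1) * pmaxv)
  }
  lsv <- vapply(seq_len(n), function(k) {
    lsvBank(arc@bankA[k, ], geom$open[k, ]) *
      lsvBank(arc@bankB[k, ], geom$open[k, ])
  }, numeric(1))
  list(aav = aav, lsv = lsv)
}

#' Modulation complexity score (VMAT)
#'
#' Product of the aperture-area variability (AAV, per-control-point open area
#' normalized by the per-pair maximum gaps over the arc) and the leaf-sequence
#' variability (LSV, positional smoothness of each bank over open pairs),
#' accumulated over segments with MU weighting. 1 for a static conformal arc;
#' smaller values mean more modulation.
#'
#' @inheritParams gapQuantiles
#' @return Score in (0, 1].
#' @export
mcs <- function(arc, minGap = 0.5, geom = NULL) {
  if (is.null(geom)) geom <- .arcGeometry(arc, minGap)
  openCP <- rowSums(geom$open) > 0
  if (!any(openCP)) stop("arc has no open aperture: MCS is undefined")
  al <- .aavlsv(arc, geom)
  .cpWeightedMean(al$aav * al$lsv, .segWeights(arc), openCP)
}

#' Modulation index for total modulation
#'
#' Measures joint MLC-speed, MLC-acceleration, gantry-speed and dose-rate
#' variability. Segment durations come from the limiting axis
#' (gantry rotation at \code{maxGantrySpeed} or MU delivery at
#' \code{maxDoseRate}); leaf speeds and accelerations are standardized by
#' their own spread, and the exceedance fraction
#' Z(f) = weighted fraction of (leaf, segment) samples with speed > f sd or
#' |acceleration| > f sd is integrated over f in [0, 2] (trapezoid, step
#' 0.01). Segments are weighted by
#' (1 + |d gantry speed| / max)(1 + |d dose rate| / max).
#'
#' @inheritParams gapQuantiles
#' @param limits a \linkS4class{MachineLimits}.
#' @param step integration step for f (default 0.01).
#' @return Dimensionless value >= 0 (0 for a static MLC).
#' @export
miTotal <- function(arc, limits = machineLimits(), minGap = 0.5,
                    step = 0.01, geom = NULL) {
  n <- nControlPoints(arc)
  if (n < 3) stop("miTotal needs at least 3 control points")
  dg <- .arcAngularDeltas(arc@gantryAngle)
  dmu <- diff(arc@cumulativeMetersetWeight) * arc@totalMU
  dt <- pmax(dg / limits@maxGantrySpeed, dmu / (limits@maxDoseRate / 60))
  if (any(dt <= 0))
    stop("zero-duration segment(s): ", paste(which(dt <= 0), collapse = ", "))
  dxa <- abs(diff(arc@bankA)); dxb <- abs(diff(arc@bankB))
  v <- cbind(dxa, dxb) / dt                  # (n-1) x 2p leaf speeds, mm/s
  dtMid <- (dt[-1] + dt[-length(dt)]) / 2
  acc <- diff(v) / dtMid                     # (n-2) x 2p accelerations
  sdv <- sd(as.vector(v)); sda <- sd(as.vector(acc))
  critOf <- function(x, s) {
    if (isTRUE(s > 0)) x / s else ifelse(x > 0, Inf, 0)
  }
  critV <- critOf(v, sdv)
  critA <- rbind(matrix(0, 1, ncol(v)), critOf(abs(acc), sda))
  crit <- pmax(critV, critA)                 # sample flagged iff f < crit
  gs <- dg / dt
  dr <- dmu / dt * 60
  W <- (1 + c(0, abs(diff(gs))) / limits@maxGantrySpeed) *
       (1 + c(0, abs(diff(dr))) / limits@maxDoseRate)
  wSample <- matrix(W / (ncol(v) * sum(W)), nrow(v), ncol(v))
  ord <- order(as.vector(crit))
  cs <- cumsum(as.vector(wSample)[ord])      # weight with crit <= f
  sortedCrit <- as.vector(crit)[ord]
  f <- seq(0, 2, by = step)
  Z <- 1 - c(0, cs)[findInterval(f, sortedCrit) + 1]
  sum((Z[-1] + Z[-length(Z)]) / 2) * step
}

#' Beam irregularity
#'
#' Per control point, aperture irregularity AI = perimeter^2 / (4 pi area)
#' (1 for a disc, 4/pi for a square); the arc value is the MU-weighted mean.
#'
#' @inheritParams gapQuantiles
#' @return Value >= 1.
#' @export
beamIrregularity <- function(arc, minGap = 0.5, geom = NULL) {
  if (is.null(geom)) geom <- .arcGeometry(arc, minGap)
  openCP <- rowSums(geom$open) > 0
  ai <- ifelse(openCP, geom$perimeter^2 / (4 * pi * pmax(geom$area, 1e-12)), 0)
  .cpWeightedMean(ai, .segWeights(arc), openCP)
}

# per-pair union of exposed intervals over open control points, as an area
.unionArea <- function(geom) {
  p <- ncol(geom$open)
  total <- 0
  for (i in seq_len(p)) {
    k <- which(geom$open[, i])
    if (!length(k)) next
    a <- geom$a[k, i]; b <- geom$b[k, i]
    o <- order(a)
    a <- a[o]; b <- b[o]
    len <- 0; curA <- a[1]; curB <- b[1]
    for (j in seq_along(a)[-1]) {
      if (a[j] > curB) { len <- len + (curB - curA); curA <- a[j]; curB <- b[j] }
      else curB <- max(curB, b[j])
    }
    len <- len + (curB - curA)
    total <- total + len * max(geom$w[k, i])
  }
  total
}

#' Beam modulation
#'
#' BM = 1 - (MU-weighted mean aperture area) / (area of the union of all
#' control-point apertures). 0 when every control point shows the same
#' aperture; approaches 1 when each segment is delivered through a small
#' sub-aperture of a large composite field.
#'
#' @inheritParams gapQuantiles
#' @return Fraction in [0, 1).
#' @export
beamModulation <- function(arc, minGap = 0.5, geom = NULL) {
  if (is.null(geom)) geom <- .arcGeometry(arc, minGap)
  openCP <- rowSums(geom$open) > 0
  if (!any(openCP)) stop("arc has no open aperture: BM is undefined")
  aUnion <- .unionArea(geom)
  meanArea <- .cpWeightedMean(geom$area, .segWeights(arc), openCP)
  1 - meanArea / aUnion
}

#' Edge metric
#'
#' Per control point, the exposed MLC side-edge length (adjacent-leaf steps
#' plus the end caps bounding the open region in the leaf-travel direction)
#' divided by the aperture area; the arc value is the MU-weighted mean.
#' Doubling all linear dimensions halves it.
#'
#' @inheritParams gapQuantiles
#' @return Value >= 0, 1/mm.
#' @export
edgeMetric <- function(arc, minGap = 0.5, geom = NULL) {
  if (is.null(geom)) geom <- .arcGeometry(arc, minGap)
  openCP <- rowSums(geom$open) > 0
  em <- ifelse(openCP, (geom$steps + geom$caps) / pmax(geom$area, 1e-12), 0)
  .cpWeightedMean(em, .segWeights(arc), openCP)
}

#' Leaf travel per arc length
#'
#' Mean total travel distance (mm) of the leaves that are ever part of an
#' open pair, divided by the gantry arc length (degrees, absolute segment
#' deltas with shortest-path wrap at the 0/360 seam).
#'
#' @inheritParams gapQuantiles
#' @return mm/deg, >= 0.
#' @export
leafTravelPerArcLength <- function(arc, minGap = 0.5, geom = NULL) {
  if (is.null(geom)) geom <- .arcGeometry(arc, minGap)
  al <- sum(.arcAngularDeltas(arc@gantryAngle))
  if (al <= 0) stop("arc has zero gantry arc length")
  everOpen <- colSums(geom$open) > 0
  if (!any(everOpen)) stop("arc has no open aperture: leaf travel is undefined")
  travelA <- colSums(abs(diff(arc@bankA)))[everOpen]
  travelB <- colSums(abs(diff(arc@bankB)))[everOpen]
  mean(c(travelA, travelB)) / al
}

#' Compute all ten complexity metrics of an arc
#'
#' Runs a single aperture-geometry pass and evaluates the ten per-arc
#' metrics. Errors from individual metrics propagate with the metric name.
#'
#' @inheritParams miTotal
#' @return Named numeric vector of length ten, names as
#'   [complexityMetricNames()].
#' @examples
#' arc <- generateArc(generatorConfig(modulation = 0, seed = 1))
#' computeComplexity(arc)
#' @export
computeComplexity <- function(arc, limits = machineLimits(), minGap = 0.5,
                              geom = NULL) {
  stopifnot(is(arc, "Arc"))
  if (is.null(geom)) geom <- .arcGeometry(arc, minGap)
  wrap <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("%s: %s", name, conditionMessage(e)), call. = FALSE))
  }
  q <- wrap("gap_quantiles", gapQuantiles(arc, minGap, geom = geom))
  out <- c(
    q1_mlc_gap = unname(q["q1"]),
    median_mlc_gap = unname(q["median"]),
    sas10 = wrap("sas10", smallApertureScore(arc, minGap = minGap, geom = geom)),
    mean_tgi = wrap("mean_tgi", meanTGI(arc, minGap, geom = geom)),
    mcs = wrap("mcs", mcs(arc, minGap, geom = geom)),
    mi_total = wrap("mi_total", miTotal(arc, limits, minGap, geom = geom)),
    bi = wrap("bi", beamIrregularity(arc, minGap, geom = geom)),
    bm = wrap("bm", beamModulation(arc, minGap, geom = geom)),
    edge_metric = wrap("edge_metric", edgeMetric(arc, minGap, geom = geom)),
    lt_al = wrap("lt_al", leafTravelPerArcLength(arc, minGap, geom = geom))
  )
  stopifnot(identical(names(out), complexityMetricNames()))
  out
}

#' Per-arc complexity table for a set of plans
#'
#' The interchange format used for baseline building and model training: one
#' row per arc with plan id, beam id, site and the ten metrics.
#'
#' @param plans a list of \linkS4class{Plan} objects (or a single Plan).
#' @param limits a \linkS4class{MachineLimits}.
#' @param minGap open-pair threshold (mm).
#' @return data.frame with columns plan_id, beam_id, site and the ten
#'   metric columns.
#' @export
metricsTable <- function(plans, limits = machineLimits(), minGap = 0.5) {
  if (is(plans, "Plan")) plans <- list(plans)
  rows <- lapply(plans, function(p) {
    do.call(rbind, lapply(p@arcs, function(a) {
      m <- computeComplexity(a, limits, minGap)
      cbind(data.frame(plan_id = p@planId, beam_id = a@beamId,
                       site = p@treatmentSite, stringsAsFactors = FALSE),
            as.data.frame(as.list(m)))
    }))
  })
  do.call(rbind, rows)
}

#' Export an arc's control-point table as CSV (debugging aid)
#'
#' @param arc an \linkS4class{Arc}.
#' @param path output CSV path.
#' @return Invisibly, the written data.frame.
#' @export
exportControlPointsCSV <- function(arc, path) {
  p <- nLeafPairs(arc)
  df <- data.frame(index = seq_len(nControlPoints(arc)),
                   gantry_angle = arc@gantryAngle,
                   cumulative_meterset_weight = arc@cumulativeMetersetWeight,
                   dose_rate = arc@doseRate,
                   jaw_x1 = arc@jawX[, 1], jaw_x2 = arc@jawX[, 2],
                   jaw_y1 = arc@jawY[, 1], jaw_y2 = arc@jawY[, 2])
  bankA <- as.data.frame(arc@bankA)
  names(bankA) <- paste0("A", seq_len(p))
  bankB <- as.data.frame(arc@bankB)
  names(bankB) <- paste0("B", seq_len(p))
  df <- cbind(df, bankA, bankB)
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}
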