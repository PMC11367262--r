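# Synthetic VMAT fixtures: arcs with a tunable modulation dial, cohorts with
# site mixes, logistic GPR labels, and dose-grid pairs. Everything is
# deterministic for a fixed seed.

#' Configuration for the synthetic arc generator
#'
#' The modulation dial \code{modulation} (m in [0, 1]) controls how far the
#' arc departs from a static rectangular field conformal to the target
#' cross-section: m = 0 gives a static aperture (identical at every control
#' point); as m grows, leaf tips blend toward the elliptical target outline,
#' the gap scale shrinks, and a growing subset of leaves picks up smooth
#' random excursions of growing amplitude.
#'
#' @param modulation m in [0, 1].
#' @param nControlPoints number of control points (default 178, a typical
#'   full arc sampled every ~2 degrees).
#' @param nLeafPairs number of MLC leaf pairs (default 40).
#' @param leafWidth leaf width at isocenter, mm (default 5).
#' @param semiAxes target-ellipse semi-axes (x, y), mm.
#' @param muPerControlPoint monitor units per control point (default 2).
#' @param site treatment-site label.
#' @param seed integer seed.
#' @return A list of class \code{generatorConfig}.
#' @export
generatorConfig <- function(modulation = 0.3, nControlPoints = 178,
                            nLeafPairs = 40, leafWidth = 5,
                            semiAxes = c(50, 80), muPerControlPoint = 2,
                            site = "unknown", seed = 1) {
  stopifnot(modulation >= 0, modulation <= 1, nControlPoints >= 2,
            nLeafPairs >= 2, leafWidth > 0, all(semiAxes > 0),
            muPerControlPoint > 0)
  structure(list(modulation = modulation, nControlPoints = nControlPoints,
                 nLeafPairs = nLeafPairs, leafWidth = leafWidth,
                 semiAxes = semiAxes, muPerControlPoint = muPerControlPoint,
                 site = site, seed = as.integer(seed)),
            class = "generatorConfig")
}

# smooth random leaf trajectories: 2 harmonics with random phase/frequency
.smoothField <- function(n, p, active, amp) {
  out <- matrix(0, n, p)
  k <- seq_len(n) / n
  for (i in which(active)) {
    f <- sample(1:5, 2, replace = TRUE)
    ph <- runif(2, 0, 2 * pi)
    c2 <- runif(2, 0.3, 1)
    out[, i] <- amp * (c2[1] * sin(2 * pi * f[1] * k + ph[1]) +
                       c2[2] * sin(2 * pi * f[2] * k + ph[2])) / 2
  }
  out
}

#' Generate a synthetic VMAT arc
#'
#' @param config a [generatorConfig()].
#' @param beamId beam identifier.
#' @return An \linkS4class{Arc} satisfying all domain invariants; identical
#'   output for identical config (including seed).
#' @examples
#' arc <- generateArc(generatorConfig(modulation = 0.8, seed = 7))
#' computeComplexity(arc)
#' @export
generateArc <- function(config, beamId = "arc1") {
  stopifnot(inherits(config, "generatorConfig"))
  set.seed(config$seed)
  m <- config$modulation
  n <- config$nControlPoints
  p <- config$nLeafPairs
  a <- config$semiAxes[1]; b <- config$semiAxes[2]
  boundaries <- config$leafWidth * (seq_len(p + 1) - 1 - p / 2)
  yc <- (boundaries[-1] + boundaries[-(p + 1)]) / 2
  inField <- abs(yc) < b
  ell <- sqrt(pmax(0, 1 - (yc / b)^2))
  # blend from the static rectangle (m = 0) to the conformal ellipse outline
  # (complete by m = 0.3), then shrink the gap scale with the dial
  beta <- min(1, m / 0.3)
  half <- a * ((1 - beta) + beta * ell) * (1 - 0.6 * m)
  half[!inField] <- 0

  activeFrac <- 0.15 + 0.75 * m
  activeA <- inField & (runif(p) < activeFrac)
  activeB <- inField & (runif(p) < activeFrac)
  amp <- 12 * m
  pertA <- .smoothField(n, p, activeA, amp)
  pertB <- .smoothField(n, p, activeB, amp)

  baseA <- matrix(-half, n, p, byrow = TRUE)
  baseB <- matrix(half, n, p, byrow = TRUE)
  bankA <- baseA + pertA
  bankB <- baseB + pertB
  closed <- matrix(!inField, n, p, byrow = TRUE)
  bankA[closed] <- 0; bankB[closed] <- 0
  # keep opposing leaves apart where the pair is in-field
  tooClose <- !closed & (bankB - bankA < 1)
  if (any(tooClose)) {
    mid <- (bankA + bankB) / 2
    bankA[tooClose] <- mid[tooClose] - 0.5
    bankB[tooClose] <- mid[tooClose] + 0.5
  }

  # full arc 181 deg -> 179 deg through 0 deg: 358 deg of gantry travel
  gantry <- (181 + 358 * (seq_len(n) - 1) / (n - 1)) %% 360
  cmw <- (seq_len(n) - 1) / (n - 1)
  jawX <- matrix(rep(c(-(a + 25), a + 25), each = n), n, 2)
  jy <- range(boundaries[c(which(inField), max(which(inField)) + 1)])
  jawY <- matrix(rep(jy, each = n), n, 2)

  new("Arc",
      beamId = beamId,
      machine = "synthetic-truebeam",
      energy = "6X",
      totalMU = config$muPerControlPoint * n,
      gantryAngle = gantry,
      cumulativeMetersetWeight = cmw,
      doseRate = rep(600, n),
      bankA = bankA, bankB = bankB,
      jawX = jawX, jawY = jawY,
      leafBoundaries = boundaries,
      treatmentSite = config$site)
}

#' Generate a synthetic cohort of VMAT plans with its metrics table
#'
#' Draws a modulation level per plan, 1-3 arcs per plan, and a treatment site
#' from \code{siteMix}; returns both the plans and the per-arc interchange
#' table (metrics plus plan/beam/site columns and the generating modulation).
#'
#' @param n number of plans.
#' @param siteMix named numeric of site proportions (normalized internally).
#' @param mSampler function(n) drawing n modulation levels in [0, 1];
#'   default Beta(2, 3.5).
#' @param seed integer seed.
#' @param limits a \linkS4class{MachineLimits} for the metric computation.
#' @param arcConfig named list of [generatorConfig()] overrides applied to
#'   every arc (e.g. \code{list(nControlPoints = 72)} for lighter cohorts).
#' @return list(plans = list of \linkS4class{Plan}, table = data.frame).
#' @export
generateCohort <- function(n,
                           siteMix = c(head_neck = 0.3, thorax_sbrt = 0.2,
                                       abdomen_sbrt = 0.2, genitourinary = 0.3),
                           mSampler = function(k) stats::rbeta(k, 2, 3.5),
                           seed = 1, limits = machineLimits(),
                           arcConfig = list()) {
  set.seed(seed)
  siteMix <- siteMix / sum(siteMix)
  sites <- sample(names(siteMix), n, replace = TRUE, prob = siteMix)
  mPlan <- pmin(1, pmax(0, mSampler(n)))
  nArcs <- sample(1:3, n, replace = TRUE, prob = c(0.4, 0.45, 0.15))
  arcSeeds <- sample.int(.Machine$integer.max, n)
  plans <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    arcsI <- vector("list", nArcs[i])
    mArc <- pmin(1, pmax(0, mPlan[i] + runif(nArcs[i], -0.05, 0.05)))
    for (j in seq_len(nArcs[i])) {
      cfg <- do.call(generatorConfig, c(
        list(modulation = mArc[j], site = sites[i],
             seed = (arcSeeds[i] + j) %% .Machine$integer.max),
        arcConfig))
      arcsI[[j]] <- generateArc(cfg, beamId = sprintf("arc%d", j))
    }
    plans[[i]] <- new("Plan", planId = sprintf("plan%04d", i), arcs = arcsI,
                      treatmentSite = sites[i],
                      approvalTime = as.POSIXct("2024-01-01", tz = "UTC") +
                        i * 3600)
    tab <- metricsTable(plans[[i]], limits)
    tab$modulation <- mArc
    rows[[i]] <- tab
  }
  list(plans = plans, table = do.call(rbind, rows))
}

#' Simulate gamma-passing-rate labels from a metrics table
#'
#' The generative label model is logistic in directed complexity:
#' label = 70 + 30 * logistic((a0 - sum(w_j * z_j)) / tau) + N(0, noiseSD),
#' clipped to [0, 100], where z_j is the standardized metric oriented so that
#' larger means more complex. The scale tau spreads the bulk of the labels
#' over roughly 92-99\% instead of piling them onto the logistic plateau;
#' the defaults put roughly 6\% of labels of a default cohort below the 90\%
#' action limit, emulating a strongly imbalanced PSQA history.
#'
#' @param table a metrics table as from [generateCohort()] or
#'   [metricsTable()].
#' @param weights named weights on the directed standardized metrics
#'   (default 0.15 on each of the ten).
#' @param a0 logistic offset (default 3.4).
#' @param tau logistic scale (default 1.2).
#' @param noiseSD Gaussian noise, percentage points (default 2).
#' @param seed integer seed.
#' @return Numeric labels in [0, 100], one per table row.
#' @export
simulateGPRLabels <- function(table, weights = NULL, a0 = 3.4, tau = 1.2,
                              noiseSD = 2, seed = 1) {
  set.seed(seed)
  mets <- complexityMetricNames()
  stopifnot(all(mets %in% names(table)))
  if (is.null(weights)) weights <- setNames(rep(0.15, 10), mets)
  dirs <- complexityDirections()
  z <- vapply(mets, function(mname) {
    v <- table[[mname]]
    s <- sd(v)
    zz <- if (s > 0) (v - mean(v)) / s else rep(0, length(v))
    if (dirs[[mname]] == "LOW_IS_COMPLEX") -zz else zz
  }, numeric(nrow(table)))
  score <- as.numeric(z %*% weights[mets])
  label <- 70 + 30 * stats::plogis((a0 - score) / tau) +
    rnorm(nrow(table), 0, noiseSD)
  pmin(100, pmax(0, label))
}

#' Generate a reference/evaluated planar dose pair
#'
#' The reference is a sum of 2D Gaussian blobs on a 0.5 mm grid; the
#' evaluated grid derives from it per \code{kind}: \code{identical},
#' \code{scaled} (uniform factor), \code{shifted} (rigid in-plane shift via
#' the grid origin) or \code{noisy} (additive Gaussian noise, sd as a
#' fraction of the maximum).
#'
#' @param kind one of "identical", "scaled", "shifted", "noisy".
#' @param factor scale factor for kind = "scaled".
#' @param shift length-2 (dy, dx) mm for kind = "shifted".
#' @param noiseSD noise sd as fraction of the reference maximum, for "noisy".
#' @param size grid edge length in pixels (default 60).
#' @param spacing pixel spacing mm (default 0.5).
#' @param nBlobs number of Gaussian blobs (default 3).
#' @param seed integer seed.
#' @return list(reference = \linkS4class{DoseGrid},
#'   evaluated = \linkS4class{DoseGrid}).
#' @export
generateDosePair <- function(kind = c("identical", "scaled", "shifted",
                                      "noisy"),
                             factor = 1.03, shift = c(0, 2), noiseSD = 0.01,
                             size = 60, spacing = 0.5, nBlobs = 3, seed = 1) {
  kind <- match.arg(kind)
  set.seed(seed)
  ext <- (size - 1) * spacing
  pos <- seq(0, ext, by = spacing)
  vals <- matrix(0, size, size)
  for (i in seq_len(nBlobs)) {
    cy <- runif(1, 0.25, 0.75) * ext
    cx <- runif(1, 0.25, 0.75) * ext
    sg <- runif(1, 0.12, 0.3) * ext
    ampl <- runif(1, 0.5, 1)
    vals <- vals + ampl * outer(pos, pos, function(y, x)
      exp(-((y - cy)^2 + (x - cx)^2) / (2 * sg^2)))
  }
  vals <- vals / max(vals) * 100
  ref <- new("DoseGrid", values = vals, spacing = c(spacing, spacing),
             origin = c(0, 0))
  ev <- switch(kind,
    identical = ref,
    scaled = new("DoseGrid", values = vals * factor,
                 spacing = c(spacing, spacing), origin = c(0, 0)),
    shifted = new("DoseGrid", values = vals, spacing = c(spacing, spacing),
                  origin = shift),
    noisy = {
      nv <- vals + matrix(rnorm(length(vals), 0, noiseSD * max(vals)),
                          nrow(vals), ncol(vals))
      nv[nv < 0] <- 0
      new("DoseGrid", values = nv, spacing = c(spacing, spacing),
          origin = c(0, 0))
    })
  list(reference = ref, evaluated = ev)
}
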