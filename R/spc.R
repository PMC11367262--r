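# Lean Six Sigma monitoring: percentile specification limits, directed
# outlier flags, defect / at-risk rules, DPMO arithmetic and the pre/post
# distribution comparison.

#' Complexity direction of each metric
#'
#' Which side of a metric's distribution is the high-complexity side: small
#' gaps and small MCS mean a harder-to-deliver plan (LOW_IS_COMPLEX), while
#' large values of the remaining metrics do (HIGH_IS_COMPLEX).
#'
#' @return Named character vector over the ten metrics with values
#'   \code{"LOW_IS_COMPLEX"} or \code{"HIGH_IS_COMPLEX"}.
#' @export
complexityDirections <- function() {
  c(q1_mlc_gap = "LOW_IS_COMPLEX",
    median_mlc_gap = "LOW_IS_COMPLEX",
    sas10 = "HIGH_IS_COMPLEX",
    mean_tgi = "HIGH_IS_COMPLEX",
    mcs = "LOW_IS_COMPLEX",
    mi_total = "HIGH_IS_COMPLEX",
    bi = "HIGH_IS_COMPLEX",
    bm = "HIGH_IS_COMPLEX",
    edge_metric = "HIGH_IS_COMPLEX",
    lt_al = "HIGH_IS_COMPLEX")
}

#' Build per-site specification limits from a baseline metrics table
#'
#' Per treatment site and metric, the limits are the 5th and 95th percentiles
#' (linear interpolation) of the baseline distribution; values outside them
#' are outliers in the Lean Six Sigma sense. Strata with fewer than
#' \code{minStratum} arcs are kept but marked unusable (with a warning).
#'
#' @param table data.frame with a \code{site} column and the ten metric
#'   columns ([complexityMetricNames()]).
#' @param percentiles length-2 probabilities (default c(0.05, 0.95)).
#' @param minStratum minimum arcs per stratum (default 20).
#' @param baselineLabel free-text label for the baseline period.
#' @return A \linkS4class{SpecificationLimits}.
#' @export
buildLimits <- function(table, percentiles = c(0.05, 0.95), minStratum = 20,
                        baselineLabel = "baseline") {
  mets <- complexityMetricNames()
  stopifnot("site" %in% names(table), all(mets %in% names(table)))
  rows <- list()
  for (s in unique(table$site)) {
    sub <- table[table$site == s, , drop = FALSE]
    usable <- nrow(sub) >= minStratum
    if (!usable)
      warning(sprintf("stratum '%s' has only %d arc(s) (< %d): marked unusable",
                      s, nrow(sub), minStratum))
    for (mname in mets) {
      q <- quantile(sub[[mname]], percentiles, names = FALSE, type = 7)
      rows[[length(rows) + 1]] <- data.frame(
        site = s, metric = mname, low = q[1], high = q[2], n = nrow(sub),
        usable = usable, stringsAsFactors = FALSE)
    }
  }
  new("SpecificationLimits", table = do.call(rbind, rows),
      percentiles = percentiles, baselineLabel = baselineLabel)
}

#' Flag a complexity vector against specification limits
#'
#' Each metric is IN_SPEC when it lies inside the closed interval
#' [low, high]; strictly below is LOW_OUTLIER, strictly above HIGH_OUTLIER
#' (values exactly on a limit are in spec). A flag is additionally a
#' high-complexity flag when the outlier lies on the complex side of the
#' metric's direction.
#'
#' @param v named numeric complexity vector (ten metrics).
#' @param limits a \linkS4class{SpecificationLimits}.
#' @param site treatment-site label; must exist in \code{limits} unless
#'   \code{unknownSitePolicy = "pool"}, in which case the pooled limits over
#'   all baseline sites are used.
#' @param directions as [complexityDirections()].
#' @param unknownSitePolicy "error" (default) or "pool".
#' @return data.frame with columns metric, value, low, high, status,
#'   is_high_complexity.
#' @export
flagMetrics <- function(v, limits, site,
                        directions = complexityDirections(),
                        unknownSitePolicy = c("error", "pool")) {
  unknownSitePolicy <- match.arg(unknownSitePolicy)
  stopifnot(is(limits, "SpecificationLimits"))
  mets <- complexityMetricNames()
  stopifnot(all(mets %in% names(v)))
  t <- limits@table
  if (!site %in% t$site) {
    if (unknownSitePolicy == "error")
      stop(sprintf("unknown treatment site '%s'; known sites: %s", site,
                   paste(sort(unique(t$site)), collapse = ", ")))
    t <- do.call(rbind, lapply(mets, function(mname) {
      sub <- t[t$metric == mname, ]
      data.frame(site = site, metric = mname,
                 low = min(sub$low), high = max(sub$high),
                 n = sum(sub$n), usable = any(sub$usable))
    }))
  }
  t <- t[t$site == site, ]
  rows <- lapply(mets, function(mname) {
    lim <- t[t$metric == mname, ]
    val <- unname(v[[mname]])
    status <- if (val < lim$low) "LOW_OUTLIER"
              else if (val > lim$high) "HIGH_OUTLIER"
              else "IN_SPEC"
    hic <- (status == "HIGH_OUTLIER" &&
              directions[[mname]] == "HIGH_IS_COMPLEX") ||
           (status == "LOW_OUTLIER" &&
              directions[[mname]] == "LOW_IS_COMPLEX")
    data.frame(metric = mname, value = val, low = lim$low, high = lim$high,
               status = status, is_high_complexity = hic,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Defect and at-risk rules for an arc
#'
#' An arc is a defect of the optimization process when more than five of its
#' ten metrics are outside the specification limits; it is at risk of PSQA
#' failure when more than five metrics are outliers on the high-complexity
#' side. Both boundaries are strict ("more than five" means at least six).
#'
#' @param flags a flag table from [flagMetrics()].
#' @return Logical.
#' @export
arcIsDefect <- function(flags) {
  stopifnot(nrow(flags) == 10)
  sum(flags$status != "IN_SPEC") > 5
}

#' @rdname arcIsDefect
#' @export
arcAtRisk <- function(flags) {
  stopifnot(nrow(flags) == 10)
  sum(flags$is_high_complexity) > 5
}

#' Plan-level at-risk decision
#'
#' A plan is at risk of PSQA failure when a strict majority of its arcs are
#' at risk by complexity, or when the mean predicted GPR over its arcs falls
#' below the action limit. Exact ties (e.g. 1 of 2 arcs) do not trigger the
#' complexity clause.
#'
#' @param arcAtRiskFlags logical vector, one per arc.
#' @param predictedGPRs numeric vector, percent, one per arc.
#' @param actionLimit percent (default 90).
#' @return list(atRisk = logical, reason = "complexity-majority",
#'   "predicted-GPR", "both" or "none", meanPredictedGPR = numeric).
#' @export
planAtRisk <- function(arcAtRiskFlags, predictedGPRs, actionLimit = 90) {
  stopifnot(length(arcAtRiskFlags) >= 1,
            length(predictedGPRs) == length(arcAtRiskFlags))
  majority <- sum(arcAtRiskFlags) > length(arcAtRiskFlags) / 2
  meanGPR <- mean(predictedGPRs)
  lowGPR <- meanGPR < actionLimit
  reason <- if (majority && lowGPR) "both"
            else if (majority) "complexity-majority"
            else if (lowGPR) "predicted-GPR"
            else "none"
  list(atRisk = majority || lowGPR, reason = reason,
       meanPredictedGPR = meanGPR)
}

#' Defects per million opportunities at a sigma level
#'
#' One-sided DPMO under the conventional 1.5-sigma long-term shift:
#' 1e6 times the standard-normal upper tail beyond (sigmaLevel - shift).
#' At six sigma this gives the canonical 3.4 defects per million.
#'
#' @param sigmaLevel process sigma level (>= shift).
#' @param shift long-term mean shift in sigma units (default 1.5).
#' @return Defects per million opportunities.
#' @examples
#' dpmo(6)      # ~3.4
#' dpmo(1.5)    # 500000
#' @export
dpmo <- function(sigmaLevel, shift = 1.5) {
  stopifnot(sigmaLevel >= shift, shift >= 0)
  1e6 * pnorm(sigmaLevel - shift, lower.tail = FALSE)
}

#' Compare two GPR distributions (pre vs post)
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test, plus the
#' "median [first, third] quartile" summaries of both samples.
#'
#' @param pre,post numeric GPR samples, percent.
#' @return list(U, pValue, preSummary, postSummary, formatted strings).
#' @export
compareGPRDistributions <- function(pre, post) {
  stopifnot(length(pre) >= 1, length(post) >= 1)
  ht <- wilcox.test(pre, post, alternative = "two.sided", exact = FALSE)
  summ <- function(x) quantile(x, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
  fmt <- function(q) sprintf("%.1f%% [%.1f, %.1f]%%", q[1], q[2], q[3])
  preQ <- summ(pre); postQ <- summ(post)
  list(U = unname(ht$statistic), pValue = ht$p.value,
       preSummary = preQ, postSummary = postQ,
       preFormatted = fmt(preQ), postFormatted = fmt(postQ))
}

#' Low/high occupancy of the complexity regions
#'
#' Fraction of arcs strictly below the low limit and strictly above the high
#' limit, per site and metric — the monitoring table of the Control phase.
#' Sites absent from the limits are reported as missing.
#'
#' @param table per-arc metrics table with a \code{site} column.
#' @param limits a \linkS4class{SpecificationLimits}.
#' @param directions as [complexityDirections()] (carried into the output).
#' @return data.frame with columns site, metric, n, low_rate, high_rate,
#'   direction.
#' @export
occupancySummary <- function(table, limits,
                             directions = complexityDirections()) {
  mets <- complexityMetricNames()
  lt <- limits@table
  rows <- list()
  for (s in unique(table$site)) {
    sub <- table[table$site == s, , drop = FALSE]
    for (mname in mets) {
      lim <- lt[lt$site == s & lt$metric == mname, ]
      if (nrow(lim) == 0) {
        rows[[length(rows) + 1]] <- data.frame(
          site = s, metric = mname, n = nrow(sub), low_rate = NA_real_,
          high_rate = NA_real_, direction = directions[[mname]])
        next
      }
      rows[[length(rows) + 1]] <- data.frame(
        site = s, metric = mname, n = nrow(sub),
        low_rate = mean(sub[[mname]] < lim$low),
        high_rate = mean(sub[[mname]] > lim$high),
        direction = directions[[mname]])
    }
  }
  do.call(rbind, rows)
}

#' Save / load specification limits as JSON
#'
#' JSON layout: site -> metric -> {low, high, n, usable}, plus the
#' percentiles and baseline label.
#'
#' @param limits a \linkS4class{SpecificationLimits}.
#' @param path JSON file path.
#' @export
writeLimitsJSON <- function(limits, path) {
  stopifnot(is(limits, "SpecificationLimits"))
  t <- limits@table
  sites <- list()
  for (s in unique(t$site)) {
    sub <- t[t$site == s, ]
    sites[[s]] <- setNames(lapply(seq_len(nrow(sub)), function(i)
      list(low = sub$low[i], high = sub$high[i], n = sub$n[i],
           usable = sub$usable[i])), sub$metric)
  }
  jsonlite::write_json(list(percentiles = limits@percentiles,
                            baseline = limits@baselineLabel,
                            sites = sites),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeLimitsJSON
#' @export
readLimitsJSON <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  rows <- list()
  for (s in names(j$sites)) {
    for (mname in names(j$sites[[s]])) {
      e <- j$sites[[s]][[mname]]
      rows[[length(rows) + 1]] <- data.frame(
        site = s, metric = mname, low = as.numeric(e$low),
        high = as.numeric(e$high), n = as.integer(e$n),
        usable = isTRUE(e$usable), stringsAsFactors = FALSE)
    }
  }
  new("SpecificationLimits", table = do.call(rbind, rows),
      percentiles = as.numeric(unlist(j$percentiles)),
      baselineLabel = as.character(j$baseline))
}
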