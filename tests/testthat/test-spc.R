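# Specification limits, directed flags, defect/at-risk rules, DPMO,
# distribution comparison, occupancy.

# a metrics table of iid uniforms: every metric column U(0, 100)
uniformTable <- function(n, site = "siteA", seed = 1) {
  set.seed(seed)
  tab <- as.data.frame(matrix(runif(n * 10, 0, 100), n, 10))
  names(tab) <- complexityMetricNames()
  tab$site <- site
  tab
}

# a complexity vector sitting at given quantiles of a limits stratum
vectorAt <- function(limits, site, at = "mid") {
  t <- limits@table[limits@table$site == site, ]
  v <- setNames((t$low + t$high) / 2, t$metric)
  v[complexityMetricNames()]
}

test_that("directions cover all ten metrics with the documented defaults", {
  d <- complexityDirections()
  expect_named(d, complexityMetricNames())
  expect_equal(unname(d[c("q1_mlc_gap", "median_mlc_gap", "mcs")]),
               rep("LOW_IS_COMPLEX", 3))
  expect_true(all(d[c("sas10", "mean_tgi", "mi_total", "bi", "bm",
                      "edge_metric", "lt_al")] == "HIGH_IS_COMPLEX"))
})

test_that("limits of a uniform baseline sit at the 5th/95th percentiles", {
  tab <- uniformTable(10000, seed = 2)
  lim <- buildLimits(tab)
  t <- lim@table
  expect_equal(nrow(t), 10)
  expect_true(all(abs(t$low - 5) < 1))      # order-statistics oracle
  expect_true(all(abs(t$high - 95) < 1))
  expect_true(all(t$usable))
})

test_that("small strata are marked unusable and constants degenerate safely", {
  tab <- uniformTable(10, seed = 3)
  expect_warning(lim <- buildLimits(tab), "unusable")
  expect_false(any(lim@table$usable))

  cst <- uniformTable(100, seed = 4)
  cst$mcs <- 0.4
  lim2 <- buildLimits(cst)
  row <- lim2@table[lim2@table$metric == "mcs", ]
  expect_equal(row$low, row$high)
  v <- vectorAt(lim2, "siteA")
  flags <- flagMetrics(v, lim2, "siteA")
  expect_equal(flags$status[flags$metric == "mcs"], "IN_SPEC")
})

test_that("flags use strict inequalities and directed complexity", {
  tab <- uniformTable(5000, seed = 5)
  lim <- buildLimits(tab)
  v <- vectorAt(lim, "siteA")
  flags <- flagMetrics(v, lim, "siteA")
  expect_true(all(flags$status == "IN_SPEC"))
  expect_false(any(flags$is_high_complexity))

  t <- lim@table
  # exactly on a limit: still in spec
  vEdge <- v
  vEdge["mcs"] <- t$low[t$metric == "mcs"]
  fEdge <- flagMetrics(vEdge, lim, "siteA")
  expect_equal(fEdge$status[fEdge$metric == "mcs"], "IN_SPEC")
  # below the low limit: LOW_OUTLIER, and complex because MCS is low-complex
  vLow <- v
  vLow["mcs"] <- t$low[t$metric == "mcs"] - 1e-6
  fLow <- flagMetrics(vLow, lim, "siteA")
  expect_equal(fLow$status[fLow$metric == "mcs"], "LOW_OUTLIER")
  expect_true(fLow$is_high_complexity[fLow$metric == "mcs"])
  # high outlier on a low-complex metric is an outlier but not complex
  vHigh <- v
  vHigh["mcs"] <- t$high[t$metric == "mcs"] + 1e-6
  fHigh <- flagMetrics(vHigh, lim, "siteA")
  expect_equal(fHigh$status[fHigh$metric == "mcs"], "HIGH_OUTLIER")
  expect_false(fHigh$is_high_complexity[fHigh$metric == "mcs"])

  expect_error(flagMetrics(v, lim, "nowhere"), "known sites.*siteA")
  fPool <- flagMetrics(v, lim, "nowhere", unknownSitePolicy = "pool")
  expect_true(all(fPool$status == "IN_SPEC"))
})

test_that("defect and at-risk rules use the strict more-than-five boundary", {
  tab <- uniformTable(5000, seed = 6)
  lim <- buildLimits(tab)
  t <- lim@table
  base <- vectorAt(lim, "siteA")
  pushComplex <- function(v, k) {
    # push the first k metrics into their high-complexity region
    dirs <- complexityDirections()
    for (mname in complexityMetricNames()[seq_len(k)]) {
      r <- t[t$metric == mname, ]
      v[mname] <- if (dirs[[mname]] == "LOW_IS_COMPLEX") r$low - 1 else r$high + 1
    }
    v
  }
  f5 <- flagMetrics(pushComplex(base, 5), lim, "siteA")
  f6 <- flagMetrics(pushComplex(base, 6), lim, "siteA")
  expect_false(arcIsDefect(f5))   # five outliers: not yet a defect
  expect_true(arcIsDefect(f6))    # six outliers: defect
  expect_false(arcAtRisk(f5))
  expect_true(arcAtRisk(f6))
  f0 <- flagMetrics(base, lim, "siteA")
  expect_false(arcIsDefect(f0))
  expect_false(arcAtRisk(f0))

  # six outliers of which only three on the complex side: defect, not at risk
  dirs <- complexityDirections()
  vMixed <- pushComplex(base, 3)
  for (mname in complexityMetricNames()[4:6]) {
    r <- t[t$metric == mname, ]
    vMixed[mname] <- if (dirs[[mname]] == "LOW_IS_COMPLEX") r$high + 1
                     else r$low - 1
  }
  fMixed <- flagMetrics(vMixed, lim, "siteA")
  expect_equal(sum(fMixed$status != "IN_SPEC"), 6)
  expect_equal(sum(fMixed$is_high_complexity), 3)
  expect_true(arcIsDefect(fMixed))
  expect_false(arcAtRisk(fMixed))
})

test_that("plan rule: strict arc majority or mean predicted GPR below limit", {
  r <- planAtRisk(c(TRUE, TRUE, FALSE), c(95, 96, 97))
  expect_true(r$atRisk); expect_equal(r$reason, "complexity-majority")
  r2 <- planAtRisk(c(FALSE, FALSE), c(94, 84.9))   # mean 89.45 < 90
  expect_true(r2$atRisk); expect_equal(r2$reason, "predicted-GPR")
  r3 <- planAtRisk(c(TRUE, FALSE), c(95, 95))      # exact tie: no trigger
  expect_false(r3$atRisk); expect_equal(r3$reason, "none")
  r4 <- planAtRisk(c(TRUE, TRUE), c(80, 85))
  expect_true(r4$atRisk); expect_equal(r4$reason, "both")
  # boundary: mean exactly at the action limit is not below it
  r5 <- planAtRisk(c(FALSE), c(90))
  expect_false(r5$atRisk)
})

test_that("plan rule is monotone in arc risk and predicted GPR", {
  set.seed(8)
  for (i in 1:50) {
    nArcs <- sample(1:4, 1)
    flags <- runif(nArcs) < 0.4
    gprs <- runif(nArcs, 80, 100)
    base <- planAtRisk(flags, gprs)
    if (!base$atRisk) next
    worseFlags <- flags; worseFlags[sample(nArcs, 1)] <- TRUE
    expect_true(planAtRisk(worseFlags, gprs)$atRisk)
    worseG <- gprs - runif(nArcs, 0, 10)
    expect_true(planAtRisk(flags, worseG)$atRisk)
  }
})

test_that("baseline self-flagging reproduces the tail rates", {
  # per-metric outlier rate 10% +/- 1% when a continuous baseline is flagged
  # against its own percentile limits (n = 10,000)
  tab <- uniformTable(10000, seed = 9)
  lim <- buildLimits(tab)
  occ <- occupancySummary(tab, lim)
  expect_equal(nrow(occ), 10)
  outlierRate <- occ$low_rate + occ$high_rate
  expect_true(all(abs(outlierRate - 0.10) < 0.01))
  expect_true(all(abs(occ$low_rate - 0.05) < 0.006))
  expect_true(all(abs(occ$high_rate - 0.05) < 0.006))
})

test_that("defect rate under independent metrics matches the binomial tail", {
  # 10 independent metrics, each with outlier probability 0.1: the defect
  # rule (> 5 outliers) fires with P = upper tail of Binomial(10, 0.1)
  pTail <- sum(dbinom(6:10, 10, 0.1))
  n <- 200000
  set.seed(10)
  outliers <- matrix(runif(n * 10) < 0.1, n, 10)
  rate <- mean(rowSums(outliers) > 5)
  expect_lt(rate, 3 * pTail)
  expect_gt(rate, pTail / 3)
  # and the analytic tail is the documented ~1.5e-4
  expect_equal(pTail, 1.47e-4, tolerance = 0.02)
})

test_that("dpmo reproduces the canonical six-sigma arithmetic", {
  expect_equal(dpmo(6, 1.5), 3.4, tolerance = 0.01)     # printed value
  expect_equal(dpmo(1.5, 1.5), 500000)
  expect_equal(dpmo(4.5, 0), dpmo(6, 1.5))
  # strictly decreasing in the sigma level
  lv <- seq(2, 6, by = 0.5)
  expect_true(all(diff(vapply(lv, dpmo, numeric(1))) < 0))
  expect_error(dpmo(1, 1.5))
})

test_that("pre/post comparison reports the rank-sum test and quartiles", {
  set.seed(11)
  pre <- rnorm(50, 92, 3)
  same <- compareGPRDistributions(pre, pre)
  expect_gt(same$pValue, 0.9)
  post <- pre + 5
  shifted <- compareGPRDistributions(pre, post)
  expect_lt(shifted$pValue, 0.05)
  expect_match(shifted$preFormatted, "^\\d+\\.\\d% \\[\\d+\\.\\d, \\d+\\.\\d\\]%$")
  expect_equal(shifted$postSummary[1], median(post))
})

test_that("specification limits survive the JSON round trip", {
  tab <- rbind(uniformTable(300, "siteA", seed = 12),
               uniformTable(300, "siteB", seed = 13))
  lim <- buildLimits(tab, baselineLabel = "2013-2021")
  f <- withr::local_tempfile(fileext = ".json")
  writeLimitsJSON(lim, f)
  back <- readLimitsJSON(f)
  reord <- function(t) t[order(t$site, t$metric), ]
  expect_equal(reord(back@table), reord(lim@table), ignore_attr = TRUE)
  expect_equal(back@percentiles, c(0.05, 0.95))
  expect_equal(back@baselineLabel, "2013-2021")
})

test_that("occupancy summary reports missing strata as missing", {
  tab <- uniformTable(500, "siteA", seed = 14)
  lim <- buildLimits(tab)
  other <- uniformTable(50, "ghost", seed = 15)
  occ <- occupancySummary(other, lim)
  expect_true(all(is.na(occ$low_rate)))
  expect_true(all(is.na(occ$high_rate)))
})
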