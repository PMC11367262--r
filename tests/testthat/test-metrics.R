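# Hand oracles and property checks for the ten per-arc complexity metrics.

# independent sort-and-interpolate quantile oracle (linear interpolation
# between order statistics)
bruteQuantile <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

test_that("gap quantiles match the brute-force sort-and-interpolate oracle", {
  # constant gaps: both quantiles equal the constant
  cst <- makeStaticArc(bankA = rep(-5, 4), bankB = rep(5, 4),
                       boundaries = seq(-10, 10, 5))
  expect_equal(unname(gapQuantiles(cst)), c(10, 10))

  # pooled gaps {2,4,6,8} at cp1 and {10,12,14,16} at cp2
  arc <- makeArc(bankA = rbind(c(-1, -2, -3, -4), c(-5, -6, -7, -8)),
                 bankB = rbind(c(1, 2, 3, 4), c(5, 6, 7, 8)),
                 boundaries = seq(-10, 10, 5))
  pooled <- c(2, 4, 6, 8, 10, 12, 14, 16)
  q <- gapQuantiles(arc)
  expect_equal(unname(q["q1"]), bruteQuantile(pooled, 0.25))
  expect_equal(unname(q["median"]), bruteQuantile(pooled, 0.5))
  expect_error(gapQuantiles(makeStaticArc(rep(0, 4), rep(0, 4),
                                          seq(-10, 10, 5))),
               "no open aperture")
})

test_that("small aperture score is the fraction of gaps under 10 mm", {
  wide <- makeStaticArc(rep(-10, 4), rep(10, 4), seq(-10, 10, 5))
  expect_equal(smallApertureScore(wide), 0)
  tight <- makeStaticArc(rep(-2.5, 4), rep(2.5, 4), seq(-10, 10, 5))
  expect_equal(smallApertureScore(tight), 1)
  half <- makeStaticArc(c(-2.5, -2.5, -7.5, -7.5), c(2.5, 2.5, 7.5, 7.5),
                        seq(-10, 10, 5))
  expect_equal(smallApertureScore(half), 0.5)
})

test_that("mean tongue-and-groove index matches hand evaluation", {
  # rectangular aperture: no steps, TGI = 0
  rect <- makeStaticArc(rep(-10, 4), rep(10, 4), seq(-10, 10, 5))
  expect_equal(meanTGI(rect), 0)
  # two open pairs, gaps 10 + 10, steps 5 on each bank:
  # S = 5 + 5, G = 20 -> 10/30
  stepped <- makeStaticArc(c(-5, 0), c(5, 10), c(-5, 0, 5))
  expect_equal(meanTGI(stepped), 10 / 30)
  expect_lt(meanTGI(generateArc(generatorConfig(modulation = 1, seed = 3))), 1)
})

test_that("MCS is 1 for a static rectangle and matches a hand-worked case", {
  rect <- makeStaticArc(rep(-10, 4), rep(10, 4), seq(-10, 10, 5))
  expect_equal(mcs(rect), 1)

  # two control points, three pairs; MU weighting puts all weight on the
  # first (segment-start) control point
  arc <- makeArc(bankA = rbind(c(-10, -8, -6), c(-6, -5, -9)),
                 bankB = rbind(c(5, 9, 7), c(2, 4, 8)),
                 boundaries = c(-7.5, -2.5, 2.5, 7.5))
  # AAV(cp1): gaps 15,17,13; per-pair max over arc 15,17,17 -> 45/49
  # LSV(cp1): bank A (-10,-8,-6): pmax 4, ((4-2)+(4-2))/(2*4) = 0.5
  #           bank B (5,9,7):    pmax 4, ((4-4)+(4-2))/(2*4) = 0.25
  expect_equal(mcs(arc), (45 / 49) * 0.5 * 0.25)
  expect_gt(mcs(arc), 0)
  expect_lte(mcs(arc), 1)
})

test_that("modulation index is 0 for a static MLC and grid-converged", {
  static <- makeStaticArc(rep(-10, 4), rep(10, 4), seq(-10, 10, 5), nCP = 6)
  expect_equal(miTotal(static), 0)

  arc <- generateArc(generatorConfig(modulation = 0.7, nControlPoints = 20,
                                     seed = 12))
  coarse <- miTotal(arc, step = 0.01)
  dense <- miTotal(arc, step = 1e-4)
  expect_lt(abs(coarse - dense), 1e-3)
  expect_gt(coarse, 0)
})

test_that("beam irregularity is 4/pi for square apertures and >= 1 always", {
  # 4 pairs x 5 mm = 20 mm tall, gap 20 mm -> square
  square <- makeStaticArc(rep(-10, 4), rep(10, 4), seq(-10, 10, 5))
  expect_equal(beamIrregularity(square), 4 / pi)
  for (s in c(4, 9, 21)) {
    arc <- generateArc(generatorConfig(modulation = runif(1), seed = s))
    expect_gte(beamIrregularity(arc), 1)
  }
})

test_that("staircase-disc irregularity converges to the taxicab limit", {
  # a leaf staircase inscribing a disc keeps the taxicab perimeter 8r as
  # leaves get thinner, so AI -> (8r)^2 / (4 pi * pi r^2) = 16/pi^2, not 1
  r <- 50
  ai <- vapply(c(10, 40, 160), function(p) {
    bnds <- seq(-r, r, length.out = p + 1)
    yc <- (bnds[-1] + bnds[-(p + 1)]) / 2
    half <- r * sqrt(pmax(0, 1 - (yc / r)^2))
    arc <- makeStaticArc(-half, half, bnds)
    beamIrregularity(arc, minGap = 0)
  }, numeric(1))
  expect_true(all(diff(abs(ai - 16 / pi^2)) < 0))
  expect_lt(abs(ai[3] - 16 / pi^2), 0.001)
  expect_true(all(ai >= 1))
})

test_that("beam modulation separates static from split-field delivery", {
  static <- makeStaticArc(rep(-10, 4), rep(10, 4), seq(-10, 10, 5))
  expect_equal(beamModulation(static), 0)
  # two disjoint half-apertures, equal MU -> BM = 0.5
  arc <- makeArc(bankA = rbind(c(-10, -10), c(0, 0), c(0, 0)),
                 bankB = rbind(c(0, 0), c(10, 10), c(10, 10)),
                 boundaries = c(-5, 0, 5),
                 cmw = c(0, 0.5, 1))
  expect_equal(beamModulation(arc), 0.5)
  coh <- smallCohort()
  expect_true(all(coh$table$bm >= 0 & coh$table$bm < 1))
})

test_that("edge metric matches hand geometry and halves on doubling", {
  # static rectangle: steps 0, caps = 2 x gap
  rect <- makeStaticArc(rep(-10, 4), rep(10, 4), seq(-10, 10, 5))
  expect_equal(edgeMetric(rect), (2 * 20) / (20 * 20))
  # 3 adjacent pairs stepped 3 mm on each bank, gaps 20 each, width 5:
  # steps = 2 x (3+3) = 12, caps = 20 + 20 (first/last pair), area = 300
  stepped <- makeStaticArc(c(-10, -7, -4), c(10, 13, 16), c(-7.5, -2.5, 2.5, 7.5))
  expect_equal(edgeMetric(stepped), (12 + 40) / 300)
  doubled <- makeStaticArc(2 * c(-10, -7, -4), 2 * c(10, 13, 16),
                           2 * c(-7.5, -2.5, 2.5, 7.5))
  expect_equal(edgeMetric(doubled), edgeMetric(stepped) / 2)
})

test_that("leaf travel per arc length handles motion and gantry wrap", {
  static <- makeStaticArc(rep(-10, 4), rep(10, 4), seq(-10, 10, 5))
  expect_equal(leafTravelPerArcLength(static), 0)
  # every leaf moves 1 mm per 2-degree segment -> 0.5 mm/deg
  n <- 5
  drift <- matrix(seq_len(n) - 1, n, 4)
  arc <- makeArc(bankA = -10 + drift, bankB = 10 + drift,
                 boundaries = seq(-10, 10, 5),
                 gantry = 181 - 2 * (seq_len(n) - 1))
  expect_equal(leafTravelPerArcLength(arc), 0.5)
  # gantry 181 -> 179 through 0: arc length 358, not 2
  wrap <- makeArc(bankA = -10 + drift, bankB = 10 + drift,
                  boundaries = seq(-10, 10, 5),
                  gantry = c(181, 270.5, 0, 89.5, 179))
  expect_equal(leafTravelPerArcLength(wrap), 4 / 358)
})

test_that("computeComplexity is consistent with the individual metrics", {
  arc <- generateArc(generatorConfig(modulation = 0.6, seed = 8))
  v <- computeComplexity(arc)
  expect_named(v, complexityMetricNames())
  expect_true(all(is.finite(v)))
  q <- gapQuantiles(arc)
  expect_equal(v[["q1_mlc_gap"]], unname(q["q1"]))
  expect_equal(v[["median_mlc_gap"]], unname(q["median"]))
  expect_equal(v[["mcs"]], mcs(arc))
  expect_equal(v[["mi_total"]], miTotal(arc))
  expect_equal(v[["bm"]], beamModulation(arc))
  expect_equal(v[["lt_al"]], leafTravelPerArcLength(arc))
})

test_that("metric range bounds hold across a generated cohort", {
  tab <- smallCohort()$table
  expect_true(all(tab$sas10 >= 0 & tab$sas10 <= 1))
  expect_true(all(tab$mean_tgi >= 0 & tab$mean_tgi < 1))
  expect_true(all(tab$mcs > 0 & tab$mcs <= 1))
  expect_true(all(tab$bi >= 1))
  expect_true(all(tab$bm >= 0 & tab$bm < 1))
  expect_true(all(tab$mi_total >= 0))
  expect_true(all(tab$edge_metric >= 0))
  expect_true(all(tab$lt_al >= 0))
  expect_true(all(tab$q1_mlc_gap <= tab$median_mlc_gap))
})

test_that("weighted metrics are invariant to MU rescaling and to splitting
           a control point into identical halves", {
  arc <- generateArc(generatorConfig(modulation = 0.65, nControlPoints = 40,
                                     seed = 15))
  # MU rescaling: aperture-shape metrics do not depend on absolute MU
  scaled <- arc
  scaled@totalMU <- arc@totalMU * 3.7
  for (f in list(meanTGI, mcs, beamIrregularity, beamModulation, edgeMetric))
    expect_equal(f(scaled), f(arc), tolerance = 1e-12)

  # split control point k: duplicate the machine state, dividing the
  # segment meterset between the halves
  k <- 17
  w <- arc@cumulativeMetersetWeight
  wMid <- w[k] + 0.37 * (w[k + 1] - w[k])
  dup <- function(mat) mat[c(seq_len(k), k, (k + 1):nrow(mat)), , drop = FALSE]
  split <- new("Arc", beamId = arc@beamId, machine = arc@machine,
               energy = arc@energy, totalMU = arc@totalMU,
               gantryAngle = c(arc@gantryAngle[seq_len(k)], arc@gantryAngle[k],
                               arc@gantryAngle[(k + 1):length(w)]),
               cumulativeMetersetWeight = c(w[seq_len(k)], wMid,
                                            w[(k + 1):length(w)]),
               doseRate = c(arc@doseRate[seq_len(k)], arc@doseRate[k],
                            arc@doseRate[(k + 1):length(w)]),
               bankA = dup(arc@bankA), bankB = dup(arc@bankB),
               jawX = dup(arc@jawX), jawY = dup(arc@jawY),
               leafBoundaries = arc@leafBoundaries,
               treatmentSite = arc@treatmentSite)
  for (f in list(mcs, beamIrregularity, beamModulation, edgeMetric, meanTGI))
    expect_equal(f(split), f(arc), tolerance = 1e-9)
})

test_that("each directed metric tracks the modulation dial (rank >= 0.7)", {
  set.seed(42)
  ms <- runif(200)
  tab <- t(vapply(seq_along(ms), function(i)
    computeComplexity(generateArc(generatorConfig(modulation = ms[i],
                                                  seed = 1000 + i))),
    numeric(10)))
  dirs <- complexityDirections()
  for (j in seq_len(ncol(tab))) {
    v <- tab[, j]
    if (dirs[[colnames(tab)[j]]] == "LOW_IS_COMPLEX") v <- -v
    rho <- cor(ms, v, method = "spearman")
    expect_gte(rho, 0.7)
  }
})
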