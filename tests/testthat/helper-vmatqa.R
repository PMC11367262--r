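# Shared fixture builders: tiny hand-constructed arcs and control points for
# the geometry and metric oracles.

# Arc from explicit bank matrices; defaults give uniform meterset weights and
# a 2-degree-per-segment gantry sweep with wide jaws.
makeArc <- function(bankA, bankB, boundaries,
                    cmw = NULL, gantry = NULL, jawX = NULL, jawY = NULL,
                    totalMU = 100, doseRate = 600, site = "testsite") {
  bankA <- as.matrix(bankA); bankB <- as.matrix(bankB)
  n <- nrow(bankA)
  if (is.null(cmw)) cmw <- (seq_len(n) - 1) / (n - 1)
  if (is.null(gantry)) gantry <- (181 - 2 * (seq_len(n) - 1)) %% 360
  if (is.null(jawX)) jawX <- matrix(rep(c(-200, 200), each = n), n, 2)
  if (is.null(jawY)) jawY <- matrix(rep(range(boundaries), each = n), n, 2)
  new("Arc", beamId = "test-arc", machine = "test", energy = "6X",
      totalMU = totalMU, gantryAngle = gantry,
      cumulativeMetersetWeight = cmw,
      doseRate = rep(doseRate, n),
      bankA = bankA, bankB = bankB, jawX = jawX, jawY = jawY,
      leafBoundaries = boundaries, treatmentSite = site)
}

# Arc whose every control point shows the same aperture
makeStaticArc <- function(bankA, bankB, boundaries, nCP = 5, ...) {
  makeArc(matrix(bankA, nCP, length(bankA), byrow = TRUE),
          matrix(bankB, nCP, length(bankB), byrow = TRUE),
          boundaries, ...)
}

makeCP <- function(bankA, bankB, jawX = c(-200, 200), jawY = c(-200, 200)) {
  new("ControlPoint", index = 1L, gantryAngle = 180,
      cumulativeMetersetWeight = 0, doseRate = 600,
      bankA = bankA, bankB = bankB, jawX = jawX, jawY = jawY)
}

# Pixel-raster area oracle for an aperture (0.1 mm grid)
rasterArea <- function(bankA, bankB, boundaries, jawX, jawY, minGap = 0.5,
                       px = 0.1) {
  p <- length(bankA)
  total <- 0
  for (i in seq_len(p)) {
    a <- max(bankA[i], jawX[1]); b <- min(bankB[i], jawX[2])
    ylo <- max(boundaries[i], jawY[1]); yhi <- min(boundaries[i + 1], jawY[2])
    if (b - a <= minGap || yhi - ylo <= 0) next
    nx <- length(seq(a + px / 2, b, by = px))
    ny <- length(seq(ylo + px / 2, yhi, by = px))
    total <- total + nx * ny * px^2
  }
  total
}

# quick 3-plan cache for expensive shared fixtures (built lazily per session)
.testEnv <- new.env(parent = emptyenv())

smallCohort <- function() {
  if (is.null(.testEnv$cohort))
    .testEnv$cohort <- generateCohort(40, seed = 404,
                                      arcConfig = list(nControlPoints = 48))
  .testEnv$cohort
}

# larger labelled feature table for the model-recovery checks (cached);
# uses the generator's default arc geometry — the label-score distribution
# (and hence the recoverable ranking signal) depends on it
labelledFeatures <- function(noiseSD = 2) {
  key <- paste0("features", noiseSD)
  if (is.null(.testEnv[[key]])) {
    coh <- generateCohort(1650, seed = 808)
    ft <- featureTable(coh$plans)
    ft$gpr <- simulateGPRLabels(coh$table, noiseSD = noiseSD, seed = 809)
    ft$gpr_true <- simulateGPRLabels(coh$table, noiseSD = 0, seed = 809)
    .testEnv[[key]] <- ft
  }
  .testEnv[[key]]
}

# shared monitoring fixture: baseline limits + small model + plan directory
# with nine ordinary plans and one forced high-complexity plan
monitorFixture <- function() {
  if (!is.null(.testEnv$monitor)) return(.testEnv$monitor)
  coh <- smallCohort()
  # small synthetic baseline: accept strata down to 10 arcs
  lim <- buildLimits(coh$table, minStratum = 10)
  ft <- featureTable(coh$plans)
  ft$gpr <- simulateGPRLabels(coh$table, seed = 51)
  model <- trainGPRModel(ft, nrounds = 80, seed = 52)

  planDir <- file.path(tempdir(), "monitor-plans")
  dir.create(planDir, showWarnings = FALSE)
  sites <- c("head_neck", "thorax_sbrt", "abdomen_sbrt", "genitourinary")
  set.seed(53)
  for (i in 1:9) {
    s <- sites[(i %% 4) + 1]
    arc <- generateArc(generatorConfig(modulation = runif(1, 0.15, 0.35),
                                       nControlPoints = 48, site = s,
                                       seed = 600 + i))
    plan <- new("Plan", planId = sprintf("ok%02d", i), arcs = list(arc),
                treatmentSite = s,
                approvalTime = as.POSIXct("2024-02-01", tz = "UTC"))
    writeRTPlan(plan, file.path(planDir, paste0(plan@planId, ".dcm")))
  }
  hot <- generateArc(generatorConfig(modulation = 1, nControlPoints = 48,
                                     site = "head_neck", seed = 700))
  hotPlan <- new("Plan", planId = "hotplan", arcs = list(hot),
                 treatmentSite = "head_neck",
                 approvalTime = as.POSIXct("2024-02-01", tz = "UTC"))
  writeRTPlan(hotPlan, file.path(planDir, "hotplan.dcm"))
  writeLines("this is not a DICOM file", file.path(planDir, "garbage.dcm"))

  .testEnv$monitor <- list(limits = lim, model = model, planDir = planDir)
  .testEnv$monitor
}
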