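test_that("aperture geometry handles rectangles and closed apertures", {
  # one pair open 10 mm x 5 mm strip, everything else parked closed
  cp <- makeCP(bankA = c(0, -5, 0), bankB = c(0, 5, 0))
  geo <- apertureGeometry(cp, boundaries = c(-7.5, -2.5, 2.5, 7.5))
  expect_equal(geo@openPairs, 2L)
  expect_equal(geo@gaps, 10)
  expect_equal(geo@area, 50)
  expect_equal(geo@perimeter, 2 * 5 + 2 * 10)
  expect_equal(geo@sideEdgeLength, 0)

  closed <- makeCP(bankA = c(3, 3, 3), bankB = c(3, 3, 3))
  geoC <- apertureGeometry(closed, boundaries = c(-7.5, -2.5, 2.5, 7.5))
  expect_length(geoC@openPairs, 0)
  expect_equal(geoC@area, 0)
  expect_equal(geoC@perimeter, 0)
})

test_that("adjacent-leaf steps accumulate per adjacency on both banks", {
  # three adjacent open pairs, each offset 3 mm from its neighbor on both
  # banks: two adjacencies x (3 + 3) mm
  cp <- makeCP(bankA = c(-10, -7, -4), bankB = c(10, 13, 16))
  geo <- apertureGeometry(cp, boundaries = c(-7.5, -2.5, 2.5, 7.5))
  expect_equal(geo@sideEdgeLength, 12)
  # two pairs: a single adjacency
  cp2 <- makeCP(bankA = c(-10, -7), bankB = c(10, 13))
  geo2 <- apertureGeometry(cp2, boundaries = c(-5, 0, 5))
  expect_equal(geo2@sideEdgeLength, 6)
})

test_that("aperture area matches the 0.1 mm pixel-raster oracle", {
  set.seed(31)
  for (rep in 1:10) {
    p <- 8
    bnds <- seq(-20, 20, by = 5)
    bankA <- runif(p, -40, 5)
    bankB <- bankA + runif(p, 2, 45)
    jawX <- sort(runif(2, -35, 35)); jawX[2] <- jawX[1] + max(diff(jawX), 5)
    jawY <- sort(sample(seq(-17.5, 17.5, by = 2.5), 2))
    if (diff(jawY) < 5) jawY[2] <- jawY[1] + 5
    cp <- makeCP(bankA, bankB, jawX, jawY)
    geo <- apertureGeometry(cp, bnds)
    oracle <- rasterArea(bankA, bankB, bnds, jawX, jawY, px = 0.02)
    expect_equal(geo@area, oracle, tolerance = 0.01)
  }
})

test_that("jaw clipping never increases area, perimeter, or gap count", {
  set.seed(77)
  for (rep in 1:10) {
    p <- 10
    bnds <- seq(-25, 25, by = 5)
    bankA <- runif(p, -30, 0)
    bankB <- bankA + runif(p, 0, 35)
    wide <- apertureGeometry(makeCP(bankA, bankB), bnds)
    narrow <- apertureGeometry(
      makeCP(bankA, bankB, jawX = c(-12, 9), jawY = c(-11, 7)), bnds)
    expect_lte(narrow@area, wide@area + 1e-12)
    expect_lte(narrow@perimeter, wide@perimeter + 1e-12)
    expect_lte(length(narrow@openPairs), length(wide@openPairs))
  }
})

test_that("RT Plan write/read round-trips every field to 1e-3 mm", {
  arcs <- list(
    generateArc(generatorConfig(modulation = 0.4, site = "head_neck",
                                seed = 5), "arcA"),
    generateArc(generatorConfig(modulation = 0.7, site = "head_neck",
                                seed = 6), "arcB"))
  plan <- new("Plan", planId = "rt-roundtrip", arcs = arcs,
              treatmentSite = "head_neck",
              approvalTime = as.POSIXct("2024-03-04 15:30:00", tz = "UTC"))
  f <- withr::local_tempfile(fileext = ".dcm")
  writeRTPlan(plan, f)
  back <- readRTPlan(f)
  expect_equal(planId(back), "rt-roundtrip")
  expect_equal(treatmentSite(back), "head_neck")
  expect_length(arcs(back), 2)
  expect_equal(format(back@approvalTime, "%Y%m%d%H%M%S"), "20240304153000")
  for (i in 1:2) {
    a0 <- arcs[[i]]; a1 <- arcs(back)[[i]]
    expect_equal(beamId(a1), beamId(a0))
    expect_equal(a1@machine, a0@machine)
    expect_equal(a1@energy, a0@energy)
    expect_equal(totalMU(a1), totalMU(a0), tolerance = 1e-9)
    expect_equal(nControlPoints(a1), 178)
    for (slot in c("bankA", "bankB", "jawX", "jawY"))
      expect_lt(max(abs(methods::slot(a1, slot) - methods::slot(a0, slot))),
                1e-3)
    expect_lt(max(abs(a1@gantryAngle - a0@gantryAngle)), 1e-3)
    expect_lt(max(abs(a1@cumulativeMetersetWeight -
                        a0@cumulativeMetersetWeight)), 1e-9)
    expect_lt(max(abs(a1@leafBoundaries - a0@leafBoundaries)), 1e-3)
  }
})

test_that("writer refuses invariant-violating plans", {
  arc <- generateArc(generatorConfig(seed = 2))
  plan <- new("Plan", planId = "ok", arcs = list(arc),
              treatmentSite = "unknown",
              approvalTime = as.POSIXct("2024-01-01", tz = "UTC"))
  f <- withr::local_tempfile(fileext = ".dcm")

  noArcs <- plan
  noArcs@arcs <- list()
  expect_error(writeRTPlan(noArcs, f), "at least one arc")

  badW <- plan
  badW@arcs[[1]]@cumulativeMetersetWeight <-
    rev(badW@arcs[[1]]@cumulativeMetersetWeight)
  expect_error(writeRTPlan(badW, f), "non-decreasing")
})

test_that("non-VMAT and MLC-less beams are rejected with the beam named", {
  # hand-build minimal DICOM datasets through the internal codec
  el <- vmatqa:::.dcmEl
  staticBeam <- list(
    el(0x300A, 0x00C0, "IS", 1L),
    el(0x300A, 0x00C2, "LO", "field7"),
    el(0x300A, 0x00C4, "CS", "STATIC"),
    el(0x300A, 0x00CE, "CS", "TREATMENT"))
  ds <- list(el(0x300A, 0x0002, "SH", "badplan"),
             el(0x300A, 0x00B0, "SQ", list(staticBeam)))
  f <- withr::local_tempfile(fileext = ".dcm")
  vmatqa:::.dcmWriteFile(ds, f)
  expect_error(readRTPlan(f), "field7")

  dynNoCP <- list(
    el(0x300A, 0x00C0, "IS", 1L),
    el(0x300A, 0x00C2, "LO", "field9"),
    el(0x300A, 0x00C4, "CS", "DYNAMIC"),
    el(0x300A, 0x00CE, "CS", "TREATMENT"))
  ds2 <- list(el(0x300A, 0x0002, "SH", "badplan2"),
              el(0x300A, 0x00B0, "SQ", list(dynNoCP)))
  f2 <- withr::local_tempfile(fileext = ".dcm")
  vmatqa:::.dcmWriteFile(ds2, f2)
  expect_error(readRTPlan(f2), "field9.*ControlPointSequence")
})

test_that("written files are readable by an independent DICOM parser", {
  plan <- new("Plan", planId = "xval",
              arcs = list(generateArc(generatorConfig(modulation = 0.5,
                                                      site = "thorax_sbrt",
                                                      seed = 9))),
              treatmentSite = "thorax_sbrt",
              approvalTime = as.POSIXct("2024-06-01 08:00:00", tz = "UTC"))
  f <- withr::local_tempfile(fileext = ".dcm")
  writeRTPlan(plan, f)
  py <- Sys.which("python")
  script <- paste(
    "import sys, pydicom",
    "ds = pydicom.dcmread(sys.argv[1])",
    "print(ds.RTPlanLabel)",
    "print(len(ds.BeamSequence))",
    "print(ds.BeamSequence[0].NumberOfControlPoints)",
    "cp = ds.BeamSequence[0].ControlPointSequence[0]",
    "mlc = [x for x in cp.BeamLimitingDevicePositionSequence",
    "       if x.RTBeamLimitingDeviceType == 'MLCX'][0]",
    "print(round(float(mlc.LeafJawPositions[12]), 4))",
    sep = "\n")
  out <- system2(py, c("-", f), input = script, stdout = TRUE)
  expect_equal(out[1], "xval")
  expect_equal(as.integer(out[2]), 1L)
  expect_equal(as.integer(out[3]), 178L)
  expect_equal(as.numeric(out[4]),
               round(arcs(plan)[[1]]@bankA[1, 13], 4))
})
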