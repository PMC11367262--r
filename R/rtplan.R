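# DICOM RT Plan mapping: Plan/Arc <-> the RT Plan module subset needed for
# complexity analysis (BeamSequence, ControlPointSequence, MLCX/ASYMX/ASYMY
# BeamLimitingDevice(Position)Sequence, FractionGroupSequence metersets).

.bldItem <- function(type, positions, nPairs = 1L, boundaries = NULL) {
  it <- list(
    .dcmEl(0x300A, 0x00B8, "CS", type),
    .dcmEl(0x300A, 0x00BC, "IS", nPairs)
  )
  if (!is.null(boundaries))
    it[[length(it) + 1]] <- .dcmEl(0x300A, 0x00BE, "DS", boundaries)
  if (!is.null(positions))
    it[[length(it) + 1]] <- .dcmEl(0x300A, 0x011C, "DS", positions)
  it
}

.arcToBeamItem <- function(arc, beamNumber) {
  p <- nLeafPairs(arc)
  n <- nControlPoints(arc)
  cps <- lapply(seq_len(n), function(k) {
    list(
      .dcmEl(0x300A, 0x0112, "IS", k - 1L),
      .dcmEl(0x300A, 0x0115, "DS",
             if (is.na(arc@doseRate[k])) numeric(0) else arc@doseRate[k]),
      .dcmEl(0x300A, 0x011E, "DS", arc@gantryAngle[k]),
      .dcmEl(0x300A, 0x0134, "DS", arc@cumulativeMetersetWeight[k]),
      .dcmEl(0x300A, 0x011A, "SQ", list(
        .bldItem("ASYMX", arc@jawX[k, ]),
        .bldItem("ASYMY", arc@jawY[k, ]),
        .bldItem("MLCX", c(arc@bankA[k, ], arc@bankB[k, ]), nPairs = p)
      ))
    )
  })
  list(
    .dcmEl(0x300A, 0x00B2, "SH", arc@machine),
    .dcmEl(0x300A, 0x00C0, "IS", beamNumber),
    .dcmEl(0x300A, 0x00C2, "LO", arc@beamId),
    .dcmEl(0x300A, 0x00C3, "LO", arc@energy),
    .dcmEl(0x300A, 0x00C4, "CS", "DYNAMIC"),
    .dcmEl(0x300A, 0x00C6, "CS", "PHOTON"),
    .dcmEl(0x300A, 0x00CE, "CS", "TREATMENT"),
    .dcmEl(0x300A, 0x00B6, "SQ", list(
      .bldItem("ASYMX", NULL),
      .bldItem("ASYMY", NULL),
      .bldItem("MLCX", NULL, nPairs = p, boundaries = arc@leafBoundaries)
    )),
    .dcmEl(0x300A, 0x010E, "DS", 1),
    .dcmEl(0x300A, 0x0110, "IS", n),
    .dcmEl(0x300A, 0x0111, "SQ", cps)
  )
}

#' Write a plan as a DICOM RT Plan file
#'
#' Emits an Explicit-VR-Little-Endian RT Plan with one DYNAMIC beam per arc,
#' full leaf/jaw positions at every control point, leaf boundaries, and beam
#' metersets in the fraction-group sequence. Refuses to write a plan that
#' violates the domain invariants.
#'
#' @param plan a valid \linkS4class{Plan}.
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @seealso [readRTPlan()]
#' @export
writeRTPlan <- function(plan, path) {
  stopifnot(is(plan, "Plan"))
  validObject(plan)
  for (a in plan@arcs) validObject(a)
  nb <- length(plan@arcs)
  refBeams <- lapply(seq_len(nb), function(i) list(
    .dcmEl(0x300A, 0x0086, "DS", plan@arcs[[i]]@totalMU),
    .dcmEl(0x300C, 0x0006, "IS", i)
  ))
  ds <- list(
    .dcmEl(0x0008, 0x0016, "UI", .DCM_SOP_RTPLAN),
    .dcmEl(0x0008, 0x0060, "CS", "RTPLAN"),
    .dcmEl(0x300A, 0x0002, "SH", plan@planId),
    .dcmEl(0x300A, 0x0004, "ST", plan@treatmentSite),
    .dcmEl(0x300A, 0x0006, "DA", format(plan@approvalTime, "%Y%m%d")),
    .dcmEl(0x300A, 0x0007, "TM", format(plan@approvalTime, "%H%M%S")),
    .dcmEl(0x300A, 0x0070, "SQ", list(list(
      .dcmEl(0x300A, 0x0071, "IS", 1L),
      .dcmEl(0x300A, 0x0078, "IS", 1L),
      .dcmEl(0x300A, 0x0080, "IS", nb),
      .dcmEl(0x300C, 0x0004, "SQ", refBeams)
    ))),
    .dcmEl(0x300A, 0x00B0, "SQ",
           lapply(seq_len(nb), function(i) .arcToBeamItem(plan@arcs[[i]], i)))
  )
  ds <- ds[order(vapply(ds, function(e) e$group * 2^16 + e$element, numeric(1)))]
  .dcmWriteFile(ds, path)
  invisible(path)
}

.itemGet <- function(item, group, element, default = NULL) {
  el <- item[[.dcmTagKey(group, element)]]
  if (is.null(el)) default else el$value
}

.beamToArc <- function(beam, beamMU, site) {
  beamName <- .itemGet(beam, 0x300A, 0x00C2, "unnamed beam")
  beamType <- .itemGet(beam, 0x300A, 0x00C4, "")
  if (!identical(beamType, "DYNAMIC"))
    stop(sprintf("beam '%s' is not a dynamic-arc (VMAT) beam (BeamType '%s')",
                 beamName, beamType))
  cpsEl <- beam[[.dcmTagKey(0x300A, 0x0111)]]
  if (is.null(cpsEl))
    stop(sprintf("beam '%s' has no ControlPointSequence: unsupported beam",
                 beamName))
  bld <- .itemGet(beam, 0x300A, 0x00B6)
  boundaries <- NULL; p <- NULL
  for (it in if (is.null(bld)) list() else bld) {
    if (identical(.itemGet(it, 0x300A, 0x00B8), "MLCX")) {
      boundaries <- .itemGet(it, 0x300A, 0x00BE)
      p <- .itemGet(it, 0x300A, 0x00BC)
    }
  }
  if (is.null(boundaries))
    stop(sprintf("beam '%s' has no MLCX leaf boundaries: unsupported beam",
                 beamName))
  p <- as.integer(p)
  cps <- cpsEl$value
  n <- length(cps)
  if (n < 2)
    stop(sprintf("beam '%s' has fewer than 2 control points", beamName))

  gantry <- numeric(n); cmw <- numeric(n); dr <- rep(NA_real_, n)
  bankA <- matrix(NA_real_, n, p); bankB <- matrix(NA_real_, n, p)
  jawX <- matrix(NA_real_, n, 2); jawY <- matrix(NA_real_, n, 2)
  lastG <- NA_real_; lastDR <- NA_real_
  lastA <- NULL; lastB <- NULL; lastJX <- NULL; lastJY <- NULL
  for (k in seq_len(n)) {
    cp <- cps[[k]]
    g <- .itemGet(cp, 0x300A, 0x011E)
    if (!is.null(g) && length(g)) lastG <- g
    d <- .itemGet(cp, 0x300A, 0x0115)
    if (!is.null(d) && length(d)) lastDR <- d
    w <- .itemGet(cp, 0x300A, 0x0134)
    if (is.null(w) || !length(w))
      stop(sprintf("beam '%s': control point %d lacks a cumulative meterset weight",
                   beamName, k))
    pos <- .itemGet(cp, 0x300A, 0x011A)
    for (it in if (is.null(pos)) list() else pos) {
      type <- .itemGet(it, 0x300A, 0x00B8)
      vals <- .itemGet(it, 0x300A, 0x011C)
      if (identical(type, "MLCX")) {
        if (length(vals) != 2 * p)
          stop(sprintf("beam '%s': MLCX positions have length %d, expected %d",
                       beamName, length(vals), 2 * p))
        lastA <- vals[seq_len(p)]; lastB <- vals[p + seq_len(p)]
      } else if (identical(type, "ASYMX")) lastJX <- vals
      else if (identical(type, "ASYMY")) lastJY <- vals
    }
    if (is.null(lastA))
      stop(sprintf("beam '%s' has no MLCX position sequence: unsupported beam",
                   beamName))
    if (is.null(lastJX)) lastJX <- c(min(lastA), max(lastB))
    if (is.null(lastJY)) lastJY <- range(boundaries)
    gantry[k] <- lastG; cmw[k] <- w; dr[k] <- lastDR
    bankA[k, ] <- lastA; bankB[k, ] <- lastB
    jawX[k, ] <- lastJX; jawY[k, ] <- lastJY
  }
  if (any(diff(cmw) < -1e-9))
    stop(sprintf("beam '%s': cumulative meterset weight is not non-decreasing",
                 beamName))
  span <- cmw[n] - cmw[1]
  if (span <= 0)
    stop(sprintf("beam '%s': degenerate meterset weights", beamName))
  cmw <- (cmw - cmw[1]) / span
  if (is.null(beamMU) || !isTRUE(beamMU > 0))
    stop(sprintf("beam '%s' has no positive beam meterset (total MU)", beamName))
  new("Arc",
      beamId = beamName,
      machine = .itemGet(beam, 0x300A, 0x00B2, "unknown"),
      energy = .itemGet(beam, 0x300A, 0x00C3, "unknown"),
      totalMU = beamMU,
      gantryAngle = gantry,
      cumulativeMetersetWeight = cmw,
      doseRate = dr,
      bankA = bankA, bankB = bankB,
      jawX = jawX, jawY = jawY,
      leafBoundaries = boundaries,
      treatmentSite = site)
}

#' Read a DICOM RT Plan file into a Plan
#'
#' Accepts VMAT (DYNAMIC) beams only; setup beams are skipped, static beams
#' rejected with an error naming the beam. Meterset weights are re-normalized
#' to [0, 1]; leaf/jaw positions omitted at a control point are carried
#' forward from the previous one, per the DICOM RT convention.
#'
#' @param path path to an RT Plan file (Explicit VR Little Endian).
#' @return A \linkS4class{Plan}.
#' @seealso [writeRTPlan()]
#' @export
readRTPlan <- function(path) {
  ds <- .dcmReadFile(path)
  beamsEl <- ds[[.dcmTagKey(0x300A, 0x00B0)]]
  if (is.null(beamsEl)) stop("file has no BeamSequence: not an RT Plan? ", path)
  site <- .dcmGet(ds, 0x300A, 0x0004, "unknown")
  planId <- .dcmGet(ds, 0x300A, 0x0002, tools::file_path_sans_ext(basename(path)))
  da <- .dcmGet(ds, 0x300A, 0x0006, "19000101")
  tm <- .dcmGet(ds, 0x300A, 0x0007, "000000")
  approval <- as.POSIXct(paste(da, substr(tm, 1, 6)), format = "%Y%m%d %H%M%S",
                         tz = "UTC")
  if (is.na(approval)) approval <- as.POSIXct("1900-01-01", tz = "UTC")

  mus <- list()
  fg <- .dcmGet(ds, 0x300A, 0x0070)
  for (fgItem in if (is.null(fg)) list() else fg) {
    rb <- .itemGet(fgItem, 0x300C, 0x0004)
    for (ref in if (is.null(rb)) list() else rb) {
      num <- .itemGet(ref, 0x300C, 0x0006)
      mu <- .itemGet(ref, 0x300A, 0x0086)
      if (!is.null(num) && !is.null(mu)) mus[[as.character(num)]] <- mu
    }
  }

  arcs <- list()
  for (beam in beamsEl$value) {
    delivery <- .itemGet(beam, 0x300A, 0x00CE, "TREATMENT")
    if (!identical(delivery, "TREATMENT")) next
    num <- .itemGet(beam, 0x300A, 0x00C0)
    beamMU <- if (!is.null(num)) mus[[as.character(num)]] else NULL
    arcs[[length(arcs) + 1]] <- .beamToArc(beam, beamMU, site)
  }
  if (!length(arcs)) stop("no treatment beams found in ", path)
  plan <- new("Plan", planId = planId, arcs = arcs, treatmentSite = site,
              approvalTime = approval)
  validObject(plan)
  for (a in plan@arcs) validObject(a)
  plan
}
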