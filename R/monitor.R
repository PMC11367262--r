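# The Poka Yoke layer: assess plans, write risk reports, scan a directory of
# approved plans at the end of the day.

#' Assess one plan: metrics, flags, predictions, plan-level decision
#'
#' @param plan a \linkS4class{Plan}.
#' @param limits a \linkS4class{SpecificationLimits}.
#' @param model a \linkS4class{GPRModel}.
#' @param machine a \linkS4class{MachineLimits}.
#' @param actionLimit percent (default 90).
#' @param directions as [complexityDirections()].
#' @param unknownSitePolicy passed to [flagMetrics()].
#' @return A \linkS4class{RiskReport}.
#' @export
assessPlan <- function(plan, limits, model, machine = machineLimits(),
                       actionLimit = 90,
                       directions = complexityDirections(),
                       unknownSitePolicy = "error") {
  stopifnot(is(plan, "Plan"))
  arcReports <- lapply(plan@arcs, function(a) {
    feats <- assembleFeatures(a, machine)
    flags <- flagMetrics(feats[complexityMetricNames()], limits,
                         plan@treatmentSite, directions, unknownSitePolicy)
    pred <- predictGPR(model, feats)
    attr <- featureAttribution(model, feats)
    list(beamId = a@beamId, metrics = feats[complexityMetricNames()],
         features = feats, flags = flags, predictedGPR = pred,
         defect = arcIsDefect(flags), atRisk = arcAtRisk(flags),
         attribution = attr)
  })
  decision <- planAtRisk(vapply(arcReports, `[[`, logical(1), "atRisk"),
                         vapply(arcReports, `[[`, numeric(1), "predictedGPR"),
                         actionLimit)
  new("RiskReport", planId = plan@planId, site = plan@treatmentSite,
      timestamp = Sys.time(), arcReports = arcReports,
      planAtRisk = decision$atRisk, reason = decision$reason,
      meanPredictedGPR = decision$meanPredictedGPR)
}

.riskReportToList <- function(report) {
  list(
    plan_id = report@planId,
    site = report@site,
    timestamp = format(report@timestamp, "%Y-%m-%d %H:%M:%S"),
    plan_at_risk = report@planAtRisk,
    reason = report@reason,
    mean_predicted_gpr = report@meanPredictedGPR,
    arcs = lapply(report@arcReports, function(ar) list(
      beam_id = ar$beamId,
      metrics = as.list(ar$metrics),
      flags = setNames(as.list(ar$flags$status), ar$flags$metric),
      high_complexity = setNames(as.list(ar$flags$is_high_complexity),
                                 ar$flags$metric),
      predicted_gpr = ar$predictedGPR,
      defect = ar$defect,
      at_risk = ar$atRisk,
      attribution = as.list(ar$attribution[1, ])
    ))
  )
}

#' Write a risk report as JSON (and a small human-readable HTML mirror)
#'
#' @param report a \linkS4class{RiskReport}.
#' @param dir output directory (created if needed).
#' @param html also write an HTML rendering (default TRUE).
#' @return Invisibly, the JSON path.
#' @export
writeRiskReport <- function(report, dir, html = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonPath <- file.path(dir, paste0(report@planId, ".json"))
  jsonlite::write_json(.riskReportToList(report), jsonPath,
                       auto_unbox = TRUE, digits = NA)
  if (html) {
    rows <- vapply(report@arcReports, function(ar) {
      outl <- sum(ar$flags$status != "IN_SPEC")
      sprintf("<tr><td>%s</td><td>%.1f%%</td><td>%d/10</td><td>%s</td><td>%s</td></tr>",
              ar$beamId, ar$predictedGPR, outl,
              ifelse(ar$defect, "yes", "no"), ifelse(ar$atRisk, "yes", "no"))
    }, character(1))
    html_txt <- c(
      "<html><head><meta charset='utf-8'><title>PSQA risk report</title></head><body>",
      sprintf("<h1>Plan %s (%s)</h1>", report@planId, report@site),
      sprintf("<p>Status: <b>%s</b> (reason: %s); mean predicted GPR %.1f%%</p>",
              ifelse(report@planAtRisk, "AT RISK", "not at risk"),
              report@reason, report@meanPredictedGPR),
      "<table border='1'><tr><th>Arc</th><th>Predicted GPR</th><th>Metrics out of spec</th><th>Defect</th><th>At risk</th></tr>",
      rows, "</table></body></html>")
    writeLines(html_txt, file.path(dir, paste0(report@planId, ".html")))
  }
  invisible(jsonPath)
}

#' End-of-day scan of a directory of approved plans
#'
#' Reads every RT Plan file in \code{planDir}, assesses it, writes a report
#' per plan under \code{outDir/reports}, and copies the reports of at-risk
#' plans into \code{outDir/outbox} (the notification hook point; a mail
#' system or scheduler can watch that directory). The scan is idempotent:
#' plan ids already listed in the scan state file are skipped unless
#' \code{force = TRUE}. Unreadable files are logged and skipped.
#'
#' @param planDir directory of DICOM RT Plan files.
#' @param limits a \linkS4class{SpecificationLimits}.
#' @param model a \linkS4class{GPRModel}.
#' @param outDir output directory (state, reports, outbox).
#' @param machine a \linkS4class{MachineLimits}.
#' @param actionLimit percent (default 90).
#' @param unknownSitePolicy passed to [flagMetrics()].
#' @param force rescan plans already reported (default FALSE).
#' @return Invisibly, list of new \linkS4class{RiskReport}s (possibly empty).
#' @export
dailyScan <- function(planDir, limits, model, outDir,
                      machine = machineLimits(), actionLimit = 90,
                      unknownSitePolicy = "error", force = FALSE) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  statePath <- file.path(outDir, "scan-state.json")
  seen <- if (file.exists(statePath) && !force)
    unlist(jsonlite::read_json(statePath, simplifyVector = TRUE))
  else character(0)
  files <- sort(list.files(planDir, pattern = "\\.dcm$", full.names = TRUE))
  reports <- list()
  for (f in files) {
    plan <- tryCatch(readRTPlan(f), error = function(e) {
      message(sprintf("skipping unreadable plan file '%s': %s", f,
                      conditionMessage(e)))
      NULL
    })
    if (is.null(plan) || plan@planId %in% seen) next
    report <- tryCatch(
      assessPlan(plan, limits, model, machine, actionLimit,
                 unknownSitePolicy = unknownSitePolicy),
      error = function(e) {
        message(sprintf("skipping plan '%s': %s", plan@planId,
                        conditionMessage(e)))
        NULL
      })
    if (is.null(report)) next
    writeRiskReport(report, file.path(outDir, "reports"))
    if (report@planAtRisk)
      writeRiskReport(report, file.path(outDir, "outbox"))
    seen <- c(seen, plan@planId)
    reports[[length(reports) + 1]] <- report
  }
  jsonlite::write_json(as.list(seen), statePath, auto_unbox = TRUE)
  invisible(reports)
}
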