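# GPR prediction: 19-feature assembly, gradient-boosted regression,
# evaluation and additive feature attribution.

#' Names of the 19 model features, in canonical order
#'
#' The ten complexity metrics plus nine plan/delivery features.
#'
#' @return Character vector of length 19.
#' @export
gprFeatureNames <- function() {
  c(complexityMetricNames(),
    "total_mu", "mu_per_deg", "mean_gantry_speed", "mean_dose_rate",
    "dose_rate_sd", "eq_square_field", "n_control_points",
    "arc_length_deg", "mean_aperture_area")
}

#' Assemble the 19-feature vector of an arc
#'
#' Complexity metrics come from [computeComplexity()]; the plan/delivery
#' features are total MU, MU per degree of gantry rotation, mean gantry
#' speed (deg/s) and mean dose rate (MU/min) under the limiting-axis timing
#' model, the standard deviation of the per-segment dose rate, the
#' equivalent-square side of the union aperture (mm), the number of control
#' points, the gantry arc length (deg) and the MU-weighted mean aperture
#' area (mm^2).
#'
#' @param arc an \linkS4class{Arc}.
#' @param limits a \linkS4class{MachineLimits}.
#' @param minGap open-pair threshold (mm).
#' @return Named numeric vector of length 19 in [gprFeatureNames()] order.
#' @export
assembleFeatures <- function(arc, limits = machineLimits(), minGap = 0.5) {
  geom <- .arcGeometry(arc, minGap)
  mets <- computeComplexity(arc, limits, minGap, geom = geom)
  dg <- .arcAngularDeltas(arc@gantryAngle)
  al <- sum(dg)
  dmu <- diff(arc@cumulativeMetersetWeight) * arc@totalMU
  dt <- pmax(dg / limits@maxGantrySpeed, dmu / (limits@maxDoseRate / 60))
  totalTime <- sum(dt)
  dr <- ifelse(dt > 0, dmu / dt * 60, 0)
  openCP <- rowSums(geom$open) > 0
  meanArea <- .cpWeightedMean(geom$area, .segWeights(arc), openCP)
  out <- c(mets,
           total_mu = arc@totalMU,
           mu_per_deg = if (al > 0) arc@totalMU / al else 0,
           mean_gantry_speed = if (totalTime > 0) al / totalTime else 0,
           mean_dose_rate = if (totalTime > 0)
             arc@totalMU / (totalTime / 60) else 0,
           dose_rate_sd = sd(dr),
           eq_square_field = sqrt(.unionArea(geom)),
           n_control_points = nControlPoints(arc),
           arc_length_deg = al,
           mean_aperture_area = meanArea)
  stopifnot(identical(names(out), gprFeatureNames()), all(is.finite(out)))
  out
}

#' Extend a metrics table with the nine plan/delivery features
#'
#' Convenience for building training tables: recomputes the full 19-feature
#' row for every arc of the given plans and carries over the table's label
#' column when present.
#'
#' @param plans list of \linkS4class{Plan}.
#' @param limits a \linkS4class{MachineLimits}.
#' @return data.frame with plan_id, beam_id, site and the 19 feature columns.
#' @export
featureTable <- function(plans, limits = machineLimits()) {
  if (is(plans, "Plan")) plans <- list(plans)
  do.call(rbind, lapply(plans, function(p)
    do.call(rbind, lapply(p@arcs, function(a)
      cbind(data.frame(plan_id = p@planId, beam_id = a@beamId,
                       site = p@treatmentSite, stringsAsFactors = FALSE),
            as.data.frame(as.list(assembleFeatures(a, limits))))))))
}

.defaultXGBParams <- function() {
  list(objective = "reg:squarederror", eta = 0.05, max_depth = 6,
       subsample = 0.9, colsample_bytree = 0.9, nthread = 1)
}

#' Train the GPR regression model
#'
#' Gradient-boosted trees (squared-error objective) on a feature table with
#' a \code{gpr} label column in [0, 100]. Deterministic for a fixed seed;
#' predictions are clipped to [0, 100].
#'
#' @param table data.frame holding the 19 feature columns
#'   ([gprFeatureNames()]) and a numeric \code{gpr} label column.
#' @param nrounds boosting rounds (default 400).
#' @param params xgboost parameter list; sensible modest defaults.
#' @param seed integer seed.
#' @return A \linkS4class{GPRModel}.
#' @export
trainGPRModel <- function(table, nrounds = 400, params = .defaultXGBParams(),
                          seed = 1) {
  feats <- gprFeatureNames()
  stopifnot(all(feats %in% names(table)), "gpr" %in% names(table))
  if (nrow(table) < 50)
    stop("need at least 50 training rows, got ", nrow(table))
  y <- table$gpr
  if (!all(is.finite(y))) stop("non-finite gpr labels")
  if (any(y < 0 | y > 100)) stop("gpr labels must lie in [0, 100]")
  x <- as.matrix(table[, feats])
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
  booster <- xgboost::xgb.train(params = c(params, list(seed = seed)),
                                data = dtrain, nrounds = nrounds,
                                verbose = 0)
  new("GPRModel",
      booster = xgboost::xgb.save.raw(booster),
      featureNames = feats,
      meta = list(n = nrow(table), seed = as.integer(seed),
                  params = c(params, list(nrounds = nrounds)),
                  trainedAt = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  version = "1"))
}

.boosterOf <- function(model) xgboost::xgb.load.raw(model@booster)

.featureMatrix <- function(model, features) {
  if (is.data.frame(features)) {
    if (!all(model@featureNames %in% names(features)))
      stop("feature-list mismatch: missing ",
           paste(setdiff(model@featureNames, names(features)), collapse = ", "))
    as.matrix(features[, model@featureNames])
  } else {
    if (is.null(dim(features))) features <- matrix(features, nrow = 1,
                                                   dimnames = list(NULL, names(features)))
    if (ncol(features) != length(model@featureNames))
      stop(sprintf("feature-list mismatch: %d features given, %d expected",
                   ncol(features), length(model@featureNames)))
    if (!is.null(colnames(features)) &&
        !identical(colnames(features), model@featureNames))
      stop("feature-list mismatch: names or order differ from the model's")
    features
  }
}

#' Predict the gamma passing rate of arcs
#'
#' @param model a \linkS4class{GPRModel}.
#' @param features a named 19-vector, a matrix, or a data.frame containing
#'   the feature columns. Refuses mismatched feature sets.
#' @return Numeric predictions in [0, 100], percent.
#' @export
predictGPR <- function(model, features) {
  stopifnot(is(model, "GPRModel"))
  x <- .featureMatrix(model, features)
  p <- predict(.boosterOf(model), xgboost::xgb.DMatrix(x, nthread = 1))
  pmin(100, pmax(0, p))
}

#' Evaluate a GPR model on held-out data
#'
#' MAE plus failure-detection sensitivity/specificity at the action limit:
#' sensitivity = P(pred < limit | label < limit), specificity =
#' P(pred >= limit | label >= limit). With no failing case in the test set
#' the sensitivity is undefined and reported as NA.
#'
#' @param model a \linkS4class{GPRModel}.
#' @param table held-out feature table with a \code{gpr} label column.
#' @param actionLimit percent (default 90).
#' @return An \linkS4class{EvaluationReport}.
#' @export
evaluateGPRModel <- function(model, table, actionLimit = 90) {
  pred <- predictGPR(model, table)
  y <- table$gpr
  fail <- y < actionLimit
  sens <- if (any(fail)) mean(pred[fail] < actionLimit) else NA_real_
  spec <- if (any(!fail)) mean(pred[!fail] >= actionLimit) else NA_real_
  new("EvaluationReport", mae = mean(abs(pred - y)), sensitivity = sens,
      specificity = spec, nTest = as.integer(nrow(table)),
      actionLimit = actionLimit)
}

#' Additive per-feature attribution of a prediction
#'
#' TreeSHAP contributions of the boosted ensemble: 19 signed scores plus a
#' baseline (bias), summing to the unclipped model prediction. The additive
#' contract is on the raw regression output; clipping to [0, 100] happens
#' after attribution.
#'
#' @param model a \linkS4class{GPRModel}.
#' @param features as in [predictGPR()].
#' @return data.frame rows = inputs, columns = 19 features plus
#'   \code{baseline} and \code{prediction} (raw, unclipped).
#' @export
featureAttribution <- function(model, features) {
  x <- .featureMatrix(model, features)
  contrib <- predict(.boosterOf(model), xgboost::xgb.DMatrix(x, nthread = 1),
                     predcontrib = TRUE)
  contrib <- matrix(contrib, nrow = nrow(x))
  colnames(contrib) <- c(model@featureNames, "baseline")
  out <- as.data.frame(contrib)
  out$prediction <- rowSums(contrib)
  out
}

#' Save / load a GPR model
#'
#' The booster bytes are stored base64-encoded in a JSON envelope together
#' with the feature list and training metadata; loading refuses files whose
#' feature list is not the canonical 19.
#'
#' @param model a \linkS4class{GPRModel}.
#' @param path file path.
#' @export
saveGPRModel <- function(model, path) {
  stopifnot(is(model, "GPRModel"))
  jsonlite::write_json(list(
    featureNames = model@featureNames,
    meta = model@meta,
    booster = jsonlite::base64_enc(model@booster)
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveGPRModel
#' @export
loadGPRModel <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- new("GPRModel",
               booster = jsonlite::base64_dec(j$booster),
               featureNames = as.character(j$featureNames),
               meta = as.list(j$meta))
  if (!identical(model@featureNames, gprFeatureNames()))
    stop("feature-list mismatch in model file ", path)
  model
}
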