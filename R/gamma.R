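# Gamma-index comparison of planar dose grids.

#' Construct a dose grid
#'
#' @param values numeric matrix of dose (finite, >= 0).
#' @param spacing (row, col) pixel spacing, mm.
#' @param origin (y, x) position of pixel [1, 1], mm.
#' @return A \linkS4class{DoseGrid}.
#' @export
doseGrid <- function(values, spacing = c(1, 1), origin = c(0, 0)) {
  new("DoseGrid", values = as.matrix(values), spacing = spacing,
      origin = origin)
}

.gridsOverlap <- function(a, b) {
  aExt <- list(y = a@origin[1] + c(0, (nrow(a@values) - 1) * a@spacing[1]),
               x = a@origin[2] + c(0, (ncol(a@values) - 1) * a@spacing[2]))
  bExt <- list(y = b@origin[1] + c(0, (nrow(b@values) - 1) * b@spacing[1]),
               x = b@origin[2] + c(0, (ncol(b@values) - 1) * b@spacing[2]))
  aExt$y[1] <= bExt$y[2] && bExt$y[1] <= aExt$y[2] &&
    aExt$x[1] <= bExt$x[2] && bExt$x[1] <= aExt$x[2]
}

.gammaResultFrom <- function(res, criteria) {
  if (res$nEvaluated == 0)
    stop("nothing to evaluate: all reference points are below the low-dose cutoff")
  gprVal <- 100 * res$nPass / res$nEvaluated
  new("GammaResult", gammaMap = res$gamma, gpr = gprVal,
      nEvaluated = as.integer(res$nEvaluated),
      pass = gprVal >= criteria@actionLimit, criteria = criteria)
}

#' Gamma-index map and passing rate
#'
#' For every reference point at or above the low-dose cutoff, the gamma index
#' is the minimum over nearby evaluated positions (bilinear sub-pixel
#' interpolation on a \code{step}-mm search lattice within
#' \code{searchFactor} times the distance tolerance) of
#' sqrt(distance^2/dta^2 + doseDiff^2/tol^2), with the dose tolerance taken
#' globally as a percentage of the reference maximum. Points with gamma <= 1
#' count as passing.
#'
#' @param reference the reference (TPS-calculated) \linkS4class{DoseGrid};
#'   normalization and cutoff are taken from this grid.
#' @param evaluated the evaluated (measured) \linkS4class{DoseGrid}.
#' @param criteria a \linkS4class{GammaCriteria}.
#' @param searchFactor search radius in units of the distance tolerance
#'   (default 3).
#' @param step search-lattice step, mm (default 0.05).
#' @return A \linkS4class{GammaResult}.
#' @examples
#' pair <- generateDosePair("identical", seed = 1)
#' gpr(gammaMap(pair$reference, pair$evaluated, gammaCriteria()))
#' @export
gammaMap <- function(reference, evaluated, criteria = gammaCriteria(),
                     searchFactor = 3, step = 0.05) {
  stopifnot(is(reference, "DoseGrid"), is(evaluated, "DoseGrid"),
            is(criteria, "GammaCriteria"))
  if (max(reference@values) <= 0) stop("reference grid has no positive dose")
  if (!.gridsOverlap(reference, evaluated))
    stop("reference and evaluated grids do not overlap spatially")
  res <- .gammaEngine(reference@values, reference@spacing, reference@origin,
                      evaluated@values, evaluated@spacing, evaluated@origin,
                      criteria@doseTolerance, criteria@distanceTolerance,
                      criteria@lowDoseCutoff, searchFactor, step)
  .gammaResultFrom(res, criteria)
}

#' Brute-force gamma oracle
#'
#' Exhaustive gamma search over the whole evaluated grid upsampled
#' \code{upFactor}-fold by bilinear interpolation, with no search-radius
#' restriction. Slower than [gammaMap()] but free of its locality
#' assumptions; used to validate the production engine.
#'
#' @inheritParams gammaMap
#' @param upFactor upsampling factor (default 10).
#' @return A \linkS4class{GammaResult}.
#' @export
gammaBruteForce <- function(reference, evaluated, criteria = gammaCriteria(),
                            upFactor = 10) {
  stopifnot(is(reference, "DoseGrid"), is(evaluated, "DoseGrid"),
            is(criteria, "GammaCriteria"))
  if (max(reference@values) <= 0) stop("reference grid has no positive dose")
  if (!.gridsOverlap(reference, evaluated))
    stop("reference and evaluated grids do not overlap spatially")
  res <- .gammaBruteEngine(reference@values, reference@spacing,
                           reference@origin, evaluated@values,
                           evaluated@spacing, evaluated@origin,
                           criteria@doseTolerance, criteria@distanceTolerance,
                           criteria@lowDoseCutoff, as.integer(upFactor))
  .gammaResultFrom(res, criteria)
}

#' Pass/fail decision against an action limit
#'
#' @param result a \linkS4class{GammaResult}.
#' @param actionLimit percent (default 90); passing means GPR >= limit.
#' @return Logical.
#' @export
passingDecision <- function(result, actionLimit = 90) {
  stopifnot(is(result, "GammaResult"))
  result@gpr >= actionLimit
}

#' Read / write a dose grid as a plain-text file
#'
#' Three header lines (\code{rows cols}, \code{spacing_row spacing_col},
#' \code{origin_y origin_x}) followed by the dose values row by row,
#' whitespace-separated.
#'
#' @param path file path.
#' @return [readDoseGrid()]: a \linkS4class{DoseGrid}.
#' @export
readDoseGrid <- function(path) {
  con <- file(path, "r")
  on.exit(close(con))
  dims <- scan(con, integer(), n = 2, quiet = TRUE)
  spacing <- scan(con, numeric(), n = 2, quiet = TRUE)
  origin <- scan(con, numeric(), n = 2, quiet = TRUE)
  vals <- scan(con, numeric(), n = dims[1] * dims[2], quiet = TRUE)
  new("DoseGrid", values = matrix(vals, dims[1], dims[2], byrow = TRUE),
      spacing = spacing, origin = origin)
}

#' @rdname readDoseGrid
#' @param grid a \linkS4class{DoseGrid} to write.
#' @export
writeDoseGrid <- function(grid, path) {
  stopifnot(is(grid, "DoseGrid"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste(nrow(grid@values), ncol(grid@values)),
               paste(grid@spacing, collapse = " "),
               paste(grid@origin, collapse = " ")), con)
  write.table(format(grid@values, digits = 10, trim = TRUE, scientific = TRUE),
              con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
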