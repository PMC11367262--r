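# Aperture geometry kernel shared by all complexity metrics.
#
# Orientation: leaves travel along IEC-X; leaf pair i covers the y-strip
# [boundaries[i], boundaries[i+1]]. The open region of a control point is the
# union of jaw-clipped per-pair rectangles, so its boundary decomposes into
# vertical leaf-end segments (length = strip width, two per open pair) and
# horizontal segments lying on strip boundaries (adjacent-leaf steps between
# two open pairs, plus end caps against closed pairs or the grid ends).

# Vectorized core: all inputs are n x p matrices (control points x pairs)
# except boundaries (p+1). Returns per-control-point geometry.
.apertureCore <- function(bankA, bankB, jawX, jawY, boundaries, minGap) {
  n <- nrow(bankA); p <- ncol(bankA)
  jx1 <- jawX[, 1]; jx2 <- jawX[, 2]
  jy1 <- jawY[, 1]; jy2 <- jawY[, 2]
  a <- pmax(bankA, jx1)                      # recycles by column: n x p
  b <- pmin(bankB, jx2)
  gap <- b - a
  lo <- matrix(boundaries[-(p + 1)], n, p, byrow = TRUE)
  hi <- matrix(boundaries[-1], n, p, byrow = TRUE)
  ylo <- pmax(lo, jy1)
  yhi <- pmin(hi, jy2)
  w <- yhi - ylo
  open <- (gap > minGap) & (w > 0)
  gapO <- ifelse(open, gap, 0)
  wO <- ifelse(open, w, 0)
  area <- rowSums(gapO * wO)
  vertical <- 2 * rowSums(wO)

  # horizontal boundary terms: p + 1 strip boundaries per control point
  emptyCol <- matrix(0, n, 1)
  falseCol <- matrix(FALSE, n, 1)
  gBelow <- cbind(emptyCol, gapO)            # pair below boundary j (j = 0..p)
  gAbove <- cbind(gapO, emptyCol)
  oBelow <- cbind(falseCol, open)
  oAbove <- cbind(open, falseCol)
  aBelow <- cbind(emptyCol, a); bBelow <- cbind(emptyCol, b)
  aAbove <- cbind(a, emptyCol); bAbove <- cbind(b, emptyCol)
  both <- oBelow & oAbove
  overlap <- pmax(0, pmin(bBelow, bAbove) - pmax(aBelow, aAbove))
  symdiff <- gBelow + gAbove - 2 * overlap   # valid where both open
  contrib <- ifelse(both, symdiff, gBelow + gAbove)  # one-sided -> its gap
  steps <- rowSums(ifelse(both, symdiff, 0))
  caps <- rowSums(contrib) - steps
  perimeter <- vertical + steps + caps

  list(a = a, b = b, gap = gap, w = w, open = open,
       area = area, vertical = vertical, steps = steps, caps = caps,
       perimeter = perimeter)
}

# Full-arc geometry pass (one call per arc, reused by every metric).
.arcGeometry <- function(arc, minGap = 0.5) {
  .apertureCore(arc@bankA, arc@bankB, arc@jawX, arc@jawY,
                arc@leafBoundaries, minGap)
}

#' Aperture geometry of a control point
#'
#' Clips the MLC aperture to the jaw window and summarizes the open region:
#' open leaf-pair gaps, area, closed-boundary perimeter and the exposed
#' adjacent-leaf step length. A pair counts as open when its jaw-clipped gap
#' exceeds \code{minGap} (default 0.5 mm, suppressing dosimetrically inert
#' closed-pair gaps) and its y-strip intersects the jaw-y window.
#'
#' @param cp a \linkS4class{ControlPoint}.
#' @param boundaries numeric vector of leaf-pair boundary y-coordinates
#'   (length = pairs + 1, strictly increasing, mm).
#' @param minGap minimum jaw-clipped gap (mm) for a pair to count as open.
#' @return An \linkS4class{ApertureGeometry}. A fully closed aperture gives
#'   zero area and an empty gap list (not an error).
#' @examples
#' cp <- new("ControlPoint", index = 1L, gantryAngle = 0,
#'           cumulativeMetersetWeight = 0, doseRate = 600,
#'           bankA = c(-5, 0), bankB = c(5, 0), jawX = c(-50, 50),
#'           jawY = c(-10, 10))
#' apertureGeometry(cp, boundaries = c(-10, 0, 10))
#' @export
apertureGeometry <- function(cp, boundaries, minGap = 0.5) {
  stopifnot(is(cp, "ControlPoint"), minGap >= 0)
  p <- length(cp@bankA)
  stopifnot(length(boundaries) == p + 1, all(diff(boundaries) > 0))
  g <- .apertureCore(matrix(cp@bankA, 1), matrix(cp@bankB, 1),
                     matrix(cp@jawX, 1), matrix(cp@jawY, 1),
                     boundaries, minGap)
  idx <- which(g$open[1, ])
  new("ApertureGeometry",
      openPairs = as.integer(idx),
      gaps = g$gap[1, idx],
      widths = g$w[1, idx],
      exposedA = g$a[1, idx],
      exposedB = g$b[1, idx],
      area = g$area[1],
      perimeter = if (length(idx)) g$perimeter[1] else 0,
      sideEdgeLength = g$steps[1])
}
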