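## Coordinate convention used throughout the package: x = column, y = row,
## both continuous with pixel centres at integer coordinates starting at 1
## (top-left pixel centre is (1, 1)); y increases downward, i.e. toward the
## ankle in a correctly oriented standing AP radiograph. "Above" therefore
## means smaller y. Angles are measured with atan2(cross, dot) in this frame,
## so a positive directed angle is a counter-clockwise rotation in image
## coordinates.

#' Construct a point
#'
#' @param x,y continuous pixel coordinates (x = column, y = row, y downward).
#' @return Named numeric vector `c(x =, y =)`.
#' @export
Point <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == 1L, length(y) == 1L,
            is.finite(x), is.finite(y))
  c(x = unname(x), y = unname(y))
}

#' Construct a directed line through two anchor points
#'
#' The direction of the line is p -> q.
#'
#' @param p,q points as returned by [Point()] (any length-2 numeric works).
#' @return An object of class `"Line"` with elements `p` and `q`.
#' @export
Line <- function(p, q) {
  p <- Point(p[1], p[2]); q <- Point(q[1], q[2])
  if (sqrt(sum((p - q)^2)) <= 0)
    .laStop("limbAlign_degenerate_line", "line anchors coincide")
  structure(list(p = p, q = q), class = "Line")
}

.lineDir <- function(line) {
  d <- line$q - line$p
  d / sqrt(sum(d^2))
}

#' @export
print.Line <- function(x, ...) {
  cat(sprintf("Line (%.2f, %.2f) -> (%.2f, %.2f)\n",
              x$p["x"], x$p["y"], x$q["x"], x$q["y"]))
  invisible(x)
}

#' Construct a closed outline
#'
#' An outline is an ordered, closed sequence of boundary points (the first
#' point is adjacent to the last; it is not repeated). Outlines produced by
#' [extractOutline()] are traced clockwise in image coordinates.
#'
#' @param points numeric matrix with columns x, y.
#' @return Matrix of class `"Outline"`.
#' @export
Outline <- function(points) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2L, all(is.finite(points)))
  colnames(points) <- c("x", "y")
  if (nrow(points) < 8L)
    .laStop("limbAlign_degenerate_outline",
            sprintf("outline needs >= 8 points, got %d", nrow(points)))
  nxt <- rbind(points[-1L, , drop = FALSE], points[1L, , drop = FALSE])
  if (any(rowSums(abs(points - nxt)) == 0))
    .laStop("limbAlign_degenerate_outline", "consecutive duplicate points")
  structure(points, class = c("Outline", "matrix", "array"))
}

## ---- connected components -------------------------------------------------

## 8-connected labelling built on EBImage::bwlabel (4-connected), merging
## labels that touch diagonally with a union-find pass.
.label8 <- function(mask) {
  m <- matrix(as.numeric(mask > 0), nrow(mask), ncol(mask))
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(m))))
  lab <- t(lab)
  nl <- max(lab)
  if (nl <= 1L) return(lab)
  H <- nrow(lab); W <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-H, -W]), as.vector(lab[-1L, -1L])),  # \ diagonal
    cbind(as.vector(lab[-1L, -W]), as.vector(lab[-H, -1L]))   # / diagonal
  )
  pairs <- pairs[pairs[, 1L] > 0 & pairs[, 2L] > 0 &
                 pairs[, 1L] != pairs[, 2L], , drop = FALSE]
  parent <- seq_len(nl)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(pairs)) for (r in seq_len(nrow(pairs))) {
    a <- find(pairs[r, 1L]); b <- find(pairs[r, 2L])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(nl), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

.largestComponent <- function(mask) {
  lab <- .label8(mask)
  if (max(lab) == 0) .laStop("limbAlign_empty_mask", "mask has no foreground pixels")
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes == max(sizes))[1L]
  lab == keep
}

## ---- outline extraction ---------------------------------------------------

#' Trace the outer boundary of the largest foreground component
#'
#' Moore neighbour tracing (8-connected foreground) on the largest connected
#' component of a binary mask; the boundary is returned clockwise in image
#' coordinates, starting at the topmost (then leftmost) foreground pixel.
#' Interior holes are ignored.
#'
#' @param mask binary matrix indexed `mask[y, x]`; values > 0 are foreground.
#' @return An [Outline()].
#' @export
extractOutline <- function(mask) {
  if (!any(mask > 0)) .laStop("limbAlign_empty_mask", "mask has no foreground pixels")
  comp <- .largestComponent(mask)
  H <- nrow(comp); W <- ncol(comp)
  fg <- function(x, y) x >= 1L && x <= W && y >= 1L && y <= H && comp[y, x]
  ## start: topmost then leftmost foreground pixel
  idx <- which(comp)
  ys <- (idx - 1L) %% H + 1L; xs <- (idx - 1L) %/% H + 1L
  o <- order(ys, xs)[1L]
  sx <- xs[o]; sy <- ys[o]
  ## neighbour offsets, clockwise in image coordinates starting East
  dx <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)
  dy <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
  ## the trace state is (pixel, backtrack direction); the deterministic
  ## successor map eventually cycles through the boundary loop, so we stop at
  ## the first repeated state and keep the cycle
  nAlloc <- 8L * sum(comp) + 16L
  ptsX <- integer(nAlloc); ptsY <- integer(nAlloc)
  seen <- new.env(hash = TRUE, size = 4096L)
  px <- sx; py <- sy
  bdir <- 5L  # index (1-based) of the backtrack neighbour: West of the start
  np <- 0L
  loopStart <- 1L
  repeat {
    key <- as.character(((px - 1L) * H + (py - 1L)) * 8L + bdir)
    prev <- seen[[key]]
    if (!is.null(prev)) { loopStart <- prev; break }
    np <- np + 1L
    if (np > nAlloc) .laStop("limbAlign_trace_failure", "boundary tracing did not close")
    seen[[key]] <- np
    ptsX[np] <- px; ptsY[np] <- py
    found <- FALSE
    lastBg <- bdir
    for (k in 1:8) {
      j <- ((bdir - 1L + k) %% 8L) + 1L
      nx <- px + dx[j]; ny <- py + dy[j]
      if (fg(nx, ny)) {
        ## direction from the new pixel back to the last background pixel seen
        bx <- px + dx[lastBg]; by <- py + dy[lastBg]
        bdir <- which(dx == (bx - nx) & dy == (by - ny))
        px <- nx; py <- ny
        found <- TRUE
        break
      }
      lastBg <- j
    }
    if (!found) break  # isolated pixel
  }
  pts <- cbind(x = ptsX[loopStart:np], y = ptsY[loopStart:np])
  ## drop consecutive duplicates (can arise on 1-px spurs) and the wrap duplicate
  keep <- c(TRUE, rowSums(abs(diff(pts))) > 0)
  pts <- pts[keep, , drop = FALSE]
  if (nrow(pts) > 1L && all(pts[1L, ] == pts[nrow(pts), ]))
    pts <- pts[-nrow(pts), , drop = FALSE]
  Outline(pts)
}

## ---- circle fitting -------------------------------------------------------

#' Least-squares circle fit (algebraic Kasa formulation)
#'
#' Solves the linear system `2*x*a + 2*y*b + c = x^2 + y^2` for the centre
#' (a, b) and `r = sqrt(c + a^2 + b^2)`. Closed-form, deterministic, and exact
#' for points lying on a true circle.
#'
#' @param points numeric matrix with columns x, y (>= 3 non-collinear points).
#' @return List with elements `center` (a [Point()]) and `radius`.
#' @export
fitCircle <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3L)
    .laStop("limbAlign_degenerate_circle", "need at least 3 points")
  x <- points[, 1L]; y <- points[, 2L]
  A <- cbind(2 * x, 2 * y, 1)
  qrA <- qr(A)
  if (qrA$rank < 3L)
    .laStop("limbAlign_degenerate_circle", "points are collinear")
  sol <- qr.coef(qrA, x^2 + y^2)
  r2 <- sol[3L] + sol[1L]^2 + sol[2L]^2
  if (!is.finite(r2) || r2 <= 0)
    .laStop("limbAlign_degenerate_circle", "degenerate circle fit")
  list(center = Point(sol[1L], sol[2L]), radius = sqrt(r2))
}

## ---- convex hull / bounding box -------------------------------------------

#' Convex hull vertices
#'
#' Thin wrapper over [grDevices::chull()] that enforces a consistent
#' orientation (clockwise in image coordinates) and rejects collinear input.
#'
#' @param points numeric matrix with columns x, y (>= 3 points).
#' @return List with `vertices` (matrix of hull vertices in clockwise image
#'   order) and `indices` (their row indices in `points`).
#' @export
convexHullPoints <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3L) .laStop("limbAlign_degenerate_hull", "need at least 3 points")
  idx <- grDevices::chull(points[, 1L], points[, 2L])
  if (length(idx) < 3L)
    .laStop("limbAlign_degenerate_hull", "all points are collinear")
  v <- points[idx, , drop = FALSE]
  area2 <- sum(v[, 1L] * v[c(2:nrow(v), 1L), 2L] - v[c(2:nrow(v), 1L), 1L] * v[, 2L])
  if (abs(area2) < 1e-9)
    .laStop("limbAlign_degenerate_hull", "all points are collinear")
  if (area2 < 0) { idx <- rev(idx); v <- v[rev(seq_len(nrow(v))), , drop = FALSE] }
  colnames(v) <- c("x", "y")
  list(vertices = v, indices = idx)
}

#' Tight axis-aligned bounding box of an outline or point set
#'
#' @param points an [Outline()] or any numeric matrix with columns x, y.
#' @return Named numeric vector `c(xmin, ymin, xmax, ymax)`. The "bottom line"
#'   of the box is the row `y = ymax`; the "upper corners" are
#'   `(xmin, ymin)` and `(xmax, ymin)`.
#' @export
boundingBox <- function(points) {
  points <- as.matrix(points)
  b <- c(xmin = min(points[, 1L]), ymin = min(points[, 2L]),
         xmax = max(points[, 1L]), ymax = max(points[, 2L]))
  if (b["xmin"] >= b["xmax"] || b["ymin"] >= b["ymax"])
    .laStop("limbAlign_degenerate_box", "degenerate bounding box")
  b
}

## ---- peak detection -------------------------------------------------------

## Local y-minima of the circular outline sequence with their prominences.
## Plateaus are collapsed to their first index. Prominence of a minimum is
## min(rise before a strictly lower value to the left, same to the right);
## the global minimum uses the overall maximum rise.
.outlinePeaks <- function(outline) {
  y <- outline[, 2L]
  n <- length(y)
  ## collapse circular runs of equal y
  runStart <- which(y != y[c(n, seq_len(n - 1L))])
  if (length(runStart) == 0L) return(NULL)           # constant-y outline
  ## rotate so runs are easy to index circularly
  vals <- y[runStart]
  m <- length(runStart)
  prevv <- vals[c(m, seq_len(m - 1L))]; nextv <- vals[c(2:m, 1L)]
  isMin <- vals < prevv & vals < nextv
  mins <- which(isMin)
  if (length(mins) == 0L) return(NULL)
  prom <- numeric(length(mins))
  for (k in seq_along(mins)) {
    i <- mins[k]; v <- vals[i]
    walk <- function(step) {
      j <- i; best <- v
      for (s in seq_len(m - 1L)) {
        j <- ((j - 1L + step) %% m) + 1L
        if (vals[j] < v) return(best - v)
        best <- max(best, vals[j])
      }
      best - v
    }
    prom[k] <- min(walk(1L), walk(-1L))
  }
  idx <- runStart[mins]
  data.frame(index = idx, x = outline[idx, 1L], y = outline[idx, 2L], prominence = prom)
}

#' Detect the two most prominent upward peaks of an outline
#'
#' A peak is a local minimum in y along the (circular) outline whose prominence
#' is at least 5 percent of the outline's bounding-box height; the two most
#' prominent peaks are returned, leftmost (smaller x) first. This is the
#' primitive behind tibial-spine detection.
#'
#' @param outline an [Outline()].
#' @param orientation only `"upward"` (toward smaller y) is supported.
#' @return List with `left`, `right` (points) and `indices` (outline row
#'   indices of the two peaks, in the same order).
#' @export
findTwoPeaks <- function(outline, orientation = "upward") {
  stopifnot(identical(orientation, "upward"))
  pk <- .outlinePeaks(outline)
  bb <- boundingBox(outline)
  minProm <- 0.05 * (bb["ymax"] - bb["ymin"])
  if (!is.null(pk)) pk <- pk[pk$prominence >= minProm, , drop = FALSE]
  if (is.null(pk) || nrow(pk) < 2L)
    .laStop("limbAlign_peaks_not_found",
            "fewer than two prominent upward peaks on the outline")
  pk <- pk[order(-pk$prominence, pk$index), , drop = FALSE][1:2, ]
  pk <- pk[order(pk$x, pk$index), , drop = FALSE]
  list(left = Point(pk$x[1L], pk$y[1L]),
       right = Point(pk$x[2L], pk$y[2L]),
       indices = pk$index)
}

## ---- lines and angles -----------------------------------------------------

#' Signed angle rotating one line's direction onto another's
#'
#' Positive is counter-clockwise in image coordinates (y down). The result is
#' in (-180, 180], antisymmetric, and additive modulo 360.
#'
#' @param a,b [Line()] objects.
#' @return Angle in degrees.
#' @export
directedAngle <- function(a, b) {
  u <- .lineDir(a); v <- .lineDir(b)
  .dirAngle(u, v)
}

.dirAngle <- function(u, v) {
  unname(atan2(u[1L] * v[2L] - u[2L] * v[1L], u[1L] * v[1L] + u[2L] * v[2L]) * 180 / pi)
}

.pointLineDistance <- function(points, line) {
  d <- line$q - line$p
  nrm <- sqrt(sum(d^2))
  abs((points[, 1L] - line$p["x"]) * d["y"] - (points[, 2L] - line$p["y"]) * d["x"]) / nrm
}

#' Outline point closest to an infinite line
#'
#' Minimises the perpendicular distance between the outline points (optionally
#' restricted to a contiguous arc given as row indices) and the infinite line
#' through `line`. Ties are broken by the smaller outline index.
#'
#' @param outline an [Outline()].
#' @param line a [Line()].
#' @param region optional integer vector of outline row indices (an arc).
#' @return The closest point, with attribute `"index"` (its outline row).
#' @export
closestPointOnOutline <- function(outline, line, region = NULL) {
  if (is.null(region)) region <- seq_len(nrow(outline))
  region <- as.integer(region)
  if (length(region) == 0L) .laStop("limbAlign_empty_region", "empty outline region")
  pts <- outline[region, , drop = FALSE]
  d <- .pointLineDistance(pts, line)
  hit <- region[d == min(d)]
  i <- min(hit)
  structure(Point(outline[i, 1L], outline[i, 2L]), index = i)
}

## Arc of the circular outline from index i to index j (exclusive of both),
## choosing the direction that does NOT contain index `avoiding`.
.arcBetween <- function(n, i, j, avoiding) {
  fwd <- if (i <= j) seq(i, j) else c(seq(i, n), seq(1L, j))
  if (!(avoiding %in% fwd)) {
    arc <- fwd
  } else {
    arc <- if (j <= i) seq(j, i) else c(seq(j, n), seq(1L, i))
    arc <- rev(arc)
  }
  arc[-c(1L, length(arc))]
}
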