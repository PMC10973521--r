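# Shared fixtures. The standard phantom is generated once per test session.

.stdPhantomEnv <- new.env()

standardPhantom <- function() {
  if (is.null(.stdPhantomEnv$case))
    .stdPhantomEnv$case <- generatePhantom(phantomSpec(seed = 20240101))
  .stdPhantomEnv$case
}

# random connected blob mask: thresholded smoothed noise, largest component
randomBlobMask <- function(seed, n = 40) {
  set.seed(seed)
  z <- matrix(rnorm(n * n), n, n)
  k <- 7
  sm <- matrix(0, n, n)
  for (di in -2:2) for (dj in -2:2) {
    sm <- sm + z[pmin(pmax(1:n + di, 1), n), pmin(pmax(1:n + dj, 1), n)]
  }
  m <- sm > quantile(sm, 0.7)
  m & matrix(TRUE, n, n)
}

# Outer-boundary pixel sets of a mask (interior holes filled first, since the
# traced outline is the outer boundary only). A clockwise Moore trace visits
# every foreground pixel 4-adjacent to the exterior, and nothing beyond the
# pixels 8-adjacent to the exterior.
boundaryPixels <- function(mask, connectivity = 4) {
  mask <- t(EBImage::imageData(EBImage::fillHull(EBImage::Image(t(mask * 1))))) > 0
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(FALSE, H + 2, W + 2); pad[2:(H + 1), 2:(W + 1)] <- mask
  offs <- if (connectivity == 4) list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
          else expand.grid(-1:1, -1:1) |> apply(1, identity, simplify = FALSE)
  nfull <- matrix(TRUE, H, W)
  for (o in offs) {
    if (o[1] == 0 && o[2] == 0) next
    nfull <- nfull & pad[2:(H + 1) + o[1], 2:(W + 1) + o[2]]
  }
  which(mask & !nfull, arr.ind = TRUE)
}

# brute-force convex hull vertex set: p is a vertex iff some line through p
# and another point has all remaining points strictly on one side
bruteHullVertices <- function(pts) {
  n <- nrow(pts)
  onHull <- logical(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      v <- pts[j, ] - pts[i, ]
      s <- sign(v[1] * (pts[, 2] - pts[i, 2]) - v[2] * (pts[, 1] - pts[i, 1]))
      s <- s[-c(i, j)]
      if (all(s >= 0) || all(s <= 0)) { onHull[i] <- TRUE; break }
    }
  }
  which(onHull)
}
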