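test_that("outline tracing: square boundary, largest-component rule, boundary-set oracle", {
  m <- matrix(0, 10, 10); m[4:7, 3:6] <- 1
  o <- extractOutline(m)
  expect_equal(nrow(o), 12L)                       # 4x4 square -> 12 boundary pixels
  expect_true(all(o[, "x"] %in% 3:6 & o[, "y"] %in% 4:7))
  ## clockwise in image coordinates: positive shoelace sum
  n <- nrow(o)
  area2 <- sum(o[, 1] * o[c(2:n, 1), 2] - o[c(2:n, 1), 1] * o[, 2])
  expect_gt(area2, 0)

  m2 <- m; m2[1:2, 9:10] <- 1                      # second, smaller component
  o2 <- extractOutline(m2)
  expect_equal(unclass(o2), unclass(o))

  expect_error(extractOutline(matrix(0, 5, 5)), class = "limbAlign_empty_mask")

  for (seed in 1:10) {
    blob <- randomBlobMask(seed)
    comp <- blob & LimbAlign:::.largestComponent(blob)
    out <- extractOutline(blob)
    got <- paste(out[, "y"], out[, "x"])
    inner <- boundaryPixels(comp, 4)               # must all be visited
    outer <- boundaryPixels(comp, 8)               # nothing beyond these
    expect_true(all(paste(inner[, "row"], inner[, "col"]) %in% got))
    expect_true(all(got %in% paste(outer[, "row"], outer[, "col"])))
  }
})

test_that("circle fit is exact on noiseless circles and matches a grid-search oracle under jitter", {
  set.seed(42)
  for (i in 1:20) {                                 # random centre/radius/arc >= 90 deg
    cx <- runif(1, -50, 50); cy <- runif(1, -50, 50); r <- runif(1, 5, 80)
    arc <- runif(1, pi / 2, 2 * pi)
    th <- seq(0, arc, length.out = 60)
    f <- fitCircle(cbind(cx + r * cos(th), cy + r * sin(th)))
    expect_lt(abs(f$center["x"] - cx), 1e-9 * r)
    expect_lt(abs(f$center["y"] - cy), 1e-9 * r)
    expect_lt(abs(f$radius - r), 1e-9 * r)
  }

  ## jittered circle: the algebraic fit agrees with a dense grid-search
  ## minimiser of the geometric residual (sd of radial distances) on every
  ## replicate, and the centre lands within 0.2 px of truth
  th <- seq(0, 2 * pi, length.out = 101)[-101]
  for (seed in 1:5) {
    set.seed(seed)
    pts <- cbind(50 + 20 * cos(th) + rnorm(100, 0, 0.5),
                 60 + 20 * sin(th) + rnorm(100, 0, 0.5))
    f <- fitCircle(pts)
    grid <- expand.grid(x = seq(49.5, 50.5, by = 0.02), y = seq(59.5, 60.5, by = 0.02))
    res <- apply(grid, 1, function(g) sd(sqrt((pts[, 1] - g[1])^2 + (pts[, 2] - g[2])^2)))
    oracle <- unlist(grid[which.min(res), ])
    expect_lt(sqrt(sum((f$center - oracle)^2)), 0.05)
    if (seed == 2) expect_lt(sqrt(sum((f$center - c(50, 60))^2)), 0.2)
  }

  f3 <- fitCircle(rbind(c(0, 0), c(2, 0), c(1, 1)))  # forced circumcircle
  expect_equal(unname(f3$center), c(1, 0), tolerance = 1e-12)
  expect_equal(f3$radius, 1, tolerance = 1e-12)

  expect_error(fitCircle(cbind(1:5, 2 * (1:5))), class = "limbAlign_degenerate_circle")
})

test_that("convex hull matches the brute-force half-plane oracle and rejects degenerate input", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0.5, 0.5), c(0.2, 0.8))
  h <- convexHullPoints(sq)
  expect_setequal(h$indices, 1:4)

  tri <- rbind(c(0, 0), c(4, 1), c(2, 5))
  expect_setequal(convexHullPoints(tri)$indices, 1:3)

  set.seed(11)
  for (i in 1:100) {
    pts <- cbind(runif(50, 0, 100), runif(50, 0, 100))
    expect_setequal(convexHullPoints(pts)$indices, bruteHullVertices(pts))
  }

  expect_error(convexHullPoints(cbind(1:6, 2 * (1:6) + 3)), class = "limbAlign_degenerate_hull")
})

test_that("bounding box is the exhaustive min/max per axis", {
  m <- matrix(0, 12, 12); m[3:9, 2:7] <- 1
  o <- extractOutline(m)
  expect_equal(boundingBox(o), c(xmin = 2, ymin = 3, xmax = 7, ymax = 9))
  set.seed(3)
  for (i in 1:100) {
    blob <- randomBlobMask(100 + i)
    o <- extractOutline(blob)
    bb <- boundingBox(o)
    expect_equal(unname(bb), c(min(o[, 1]), min(o[, 2]), max(o[, 1]), max(o[, 2])))
  }
})

test_that("two-peak detection finds comb-tooth tips and errors on single bumps", {
  ## two-tooth comb: base block with two teeth whose tips are at (10, 5) and (30, 7)
  m <- matrix(0, 30, 40)
  m[15:25, 2:38] <- 1
  for (d in 0:9) m[15 - d - 1, (10 - (9 - d)):(10 + (9 - d))] <- 1   # tooth 1, tip (10, 5)
  for (d in 0:7) m[15 - d - 1, (30 - (7 - d)):(30 + (7 - d))] <- 1   # tooth 2, tip (30, 7)
  pk <- findTwoPeaks(extractOutline(m))
  expect_equal(unname(pk$left), c(10, 5))
  expect_equal(unname(pk$right), c(30, 7))

  single <- matrix(0, 20, 20); single[10:18, 3:17] <- 1
  for (d in 0:6) single[10 - d - 1, (10 - (6 - d)):(10 + (6 - d))] <- 1
  expect_error(findTwoPeaks(extractOutline(single)), class = "limbAlign_peaks_not_found")
})

test_that("directed angles: convention, antisymmetry, additivity, atan2 oracle", {
  ex <- Line(c(0, 0), c(1, 0)); ey <- Line(c(0, 0), c(0, 1))
  expect_equal(directedAngle(ex, ey), 90)          # +x to +y (down) is +90 (CCW in image coords)
  expect_equal(directedAngle(ex, ex), 0)
  set.seed(5)
  for (i in 1:200) {
    p <- matrix(runif(12, -10, 10), 6, 2)
    a <- Line(p[1, ], p[2, ]); b <- Line(p[3, ], p[4, ]); cc <- Line(p[5, ], p[6, ])
    ## atan2 oracle
    ang <- function(l) atan2(l$q["y"] - l$p["y"], l$q["x"] - l$p["x"]) * 180 / pi
    wrap <- function(x) { x <- x %% 360; ifelse(x > 180, x - 360, x) }
    expect_equal(directedAngle(a, b), unname(wrap(ang(b) - ang(a))), tolerance = 1e-9)
    expect_equal(directedAngle(a, b), -directedAngle(b, a), tolerance = 1e-9)
    resid <- (directedAngle(a, cc) - directedAngle(a, b) - directedAngle(b, cc)) %% 360
    expect_lt(min(resid, 360 - resid), 1e-9)
  }
})

test_that("closest outline point to a line: notch vertex, tangency, exhaustive oracle", {
  ## block with a V notch carved from below, apex pixel at (11, 11); with the
  ## search restricted to the notch arc, the vertical line through the notch
  ## returns the vertex (the pixel just above the carved apex)
  m <- matrix(0, 20, 21); m[5:15, 2:20] <- 1
  for (d in 0:4) m[11 + d, (11 - d):(11 + d)] <- 0
  o <- extractOutline(m)
  arc <- which(o[, "y"] >= 9 & o[, "y"] <= 14)
  v <- closestPointOnOutline(o, Line(c(11, 0), c(11, 30)), region = arc)
  expect_equal(as.numeric(v), c(11, 10))

  ## circle vs tangent line -> tangency point
  mc <- matrix(0, 41, 41)
  mc <- LimbAlign:::.rasterDisk(mc, 21, 21, 12)
  oc <- extractOutline(mc)
  tp <- closestPointOnOutline(oc, Line(c(0, 33), c(41, 33)))   # tangent at (21, 33)
  expect_lt(sqrt(sum((tp - c(21, 33))^2)), 1.01)

  set.seed(9)
  for (i in 1:100) {
    blob <- randomBlobMask(200 + i)
    o <- extractOutline(blob)
    l <- Line(runif(2, 0, 40), runif(2, 0, 40))
    got <- closestPointOnOutline(o, l)
    d <- LimbAlign:::.pointLineDistance(o, l)
    expect_equal(attr(got, "index"), min(which(d == min(d))))
  }
  expect_error(closestPointOnOutline(o, l, region = integer(0)),
               class = "limbAlign_empty_region")
})

test_that("geometry operations are translation invariant (angles also scale invariant)", {
  off <- c(17, -9)
  set.seed(13)
  pts <- cbind(runif(30, 0, 50), runif(30, 0, 50))
  f1 <- fitCircle(pts); f2 <- fitCircle(sweep(pts, 2, -off))
  expect_equal(unname(f2$center - f1$center), off, tolerance = 1e-9)
  expect_equal(f1$radius, f2$radius, tolerance = 1e-9)
  expect_setequal(convexHullPoints(pts)$indices,
                  convexHullPoints(sweep(pts, 2, -off))$indices)
  a <- Line(pts[1, ], pts[2, ]); b <- Line(pts[3, ], pts[4, ])
  aT <- Line(pts[1, ] + off, pts[2, ] + off); bT <- Line(pts[3, ] + off, pts[4, ] + off)
  expect_equal(directedAngle(a, b), directedAngle(aT, bT), tolerance = 1e-9)
  aS <- Line(pts[1, ] * 3.7, pts[2, ] * 3.7); bS <- Line(pts[3, ] * 3.7, pts[4, ] * 3.7)
  expect_equal(directedAngle(a, b), directedAngle(aS, bS), tolerance = 1e-9)
})
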