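test_that("femoral head centre recovers a rasterised disk centre and fails on empty masks", {
  m <- matrix(0, 160, 240)
  m <- LimbAlign:::.rasterDisk(m, 120, 80, 40) * 1
  ctr <- femoralHeadCenter(m)
  expect_lt(sqrt(sum((ctr - c(120, 80))^2)), 0.5)
  expect_error(femoralHeadCenter(matrix(0, 10, 10)),
               class = "limbAlign_landmark_failure")
})

test_that("distal femur rules: W-shaped border, convex border failure", {
  ## symmetric W lower boundary: block with two teeth pointing down and a
  ## central apex between them
  m <- matrix(0, 40, 60)
  m[5:20, 6:55] <- 1
  for (d in 0:9) m[20 + d, (18 - (9 - d)):(18 + (9 - d))] <- 1  # left tooth, tip (18, 29)
  for (d in 0:9) m[20 + d, (42 - (9 - d)):(42 + (9 - d))] <- 1  # right tooth, tip (42, 29)
  lf <- distalFemurLandmarks(m, side = "right")
  expect_equal(as.numeric(lf$medial_condyle), c(42, 29))   # right leg: medial = larger x
  expect_equal(as.numeric(lf$lateral_condyle), c(18, 29))
  expect_equal(unname(lf$intercondylar_notch["y"]), 20)    # central apex of the W
  expect_lte(abs(lf$intercondylar_notch["x"] - 30), 3)

  ## mirrored side flips the labels
  lf2 <- distalFemurLandmarks(m, side = "left")
  expect_equal(as.numeric(lf2$medial_condyle), c(18, 29))

  ## single convex lower border has no notch
  conv <- matrix(0, 40, 60)
  conv <- LimbAlign:::.rasterDisk(conv, 30, 15, 12) * 1
  expect_error(distalFemurLandmarks(conv), class = "limbAlign_landmark_failure")
})

test_that("tibial spine centre: symmetric twin peaks give the midline valley, single peak fails", {
  m <- matrix(0, 50, 60)
  m[25:45, 8:52] <- 1
  ## two triangular spines with tips at (22, 10) and (38, 10), valley apex (30, 20)
  for (d in 0:9) {
    m[10 + d, (22 - ceiling(d / 2)):(22 + ceiling(d / 2))] <- 1
    m[10 + d, (38 - ceiling(d / 2)):(38 + ceiling(d / 2))] <- 1
  }
  for (d in 0:4) m[25 - d - 1, (30 - d):(30 + d)] <- 1   # valley floor rising to (30, 20)
  sp <- tibialSpineCenter(m)
  expect_lt(abs(sp["x"] - 30), 1)
  expect_error(tibialSpineCenter(LimbAlign:::.rasterDisk(matrix(0, 30, 30), 15, 15, 8) * 1),
               class = "limbAlign_landmark_failure")
})

test_that("plateau surface points: rectangle corners exactly; degenerate hull fails", {
  m <- matrix(0, 40, 50); m[12:30, 5:45] <- 1
  pp <- plateauSurfacePoints(m, side = "right")
  expect_equal(as.numeric(pp$medial_plateau), c(45, 12))
  expect_equal(as.numeric(pp$lateral_plateau), c(5, 12))
  pp2 <- plateauSurfacePoints(m, side = "left")
  expect_equal(as.numeric(pp2$medial_plateau), c(5, 12))

  ## triangle pointing up: a single hull vertex above the centroid
  tri <- matrix(0, 40, 40)
  tri <- LimbAlign:::.rasterConvexPoly(tri, rbind(c(20, 5), c(8, 35), c(32, 35))) * 1
  expect_error(plateauSurfacePoints(tri), class = "limbAlign_landmark_failure")
})

test_that("ankle centre: x-mirror symmetric talus gives the midline, empty talus fails", {
  tib <- matrix(0, 80, 60)
  tib[10:50, 22:38] <- 1; tib[45:55, 12:48] <- 1       # shaft + flat plafond
  tal <- matrix(0, 80, 60)
  tal <- LimbAlign:::.rasterConvexPoly(tal, rbind(c(14, 62), c(46, 62), c(40, 75), c(20, 75))) * 1
  ac <- ankleCenter(tib, tal)
  expect_lt(abs(ac["x"] - 30), 1)
  expect_error(ankleCenter(tib, matrix(0, 80, 60)), class = "limbAlign_landmark_failure")
})

test_that("phantom ground truth: per-landmark accuracy and 2 px RMS over the full set", {
  case <- standardPhantom()
  lm <- extractLandmarks(phantomMasks(case))
  truth <- landmarkPoints(truthLandmarks(case))
  d <- landmarkPoints(lm) - truth
  dist <- sqrt(rowSums(d^2))
  expect_lt(sqrt(mean(dist^2)), 2)                        # RMS over the 8 landmarks
  expect_lt(dist["femoral_head_center"], 2)
  for (nm in c("intercondylar_notch", "medial_condyle", "lateral_condyle",
               "tibial_spine_center", "medial_plateau", "lateral_plateau",
               "ankle_center"))
    expect_lt(dist[nm], 2.0)
  ## proximal-to-distal ordering invariant holds by construction of LandmarkSet
  p <- landmarkPoints(lm)
  expect_true(p["femoral_head_center", "y"] < p["intercondylar_notch", "y"])
  expect_true(p["intercondylar_notch", "y"] < p["ankle_center", "y"])
})

test_that("landmark extraction is translation-equivariant and mirror-equivariant", {
  case <- standardPhantom()
  masks <- phantomMasks(case)
  lm <- landmarkPoints(extractLandmarks(masks))
  dx <- 7L; dy <- 13L
  shift <- function(m) {
    out <- matrix(0L, nrow(m), ncol(m))
    out[(1 + dy):nrow(m), (1 + dx):ncol(m)] <- m[1:(nrow(m) - dy), 1:(ncol(m) - dx)]
    out
  }
  shifted <- do.call(LimbMasks, c(lapply(LimbAlign:::.boneNames,
                                         function(b) shift(boneMask(masks, b))),
                                  list(side = "right")))
  lmS <- landmarkPoints(extractLandmarks(shifted))
  expect_equal(lmS[, "x"], lm[, "x"] + dx)
  expect_equal(lmS[, "y"], lm[, "y"] + dy)

  W <- ncol(boneMask(masks, "talus"))
  mirrored <- do.call(LimbMasks, c(lapply(LimbAlign:::.boneNames,
                                          function(b) boneMask(masks, b)[, W:1]),
                                   list(side = "left")))
  lmM <- landmarkPoints(extractLandmarks(mirrored))
  ## mirrored coordinates up to the 1 px asymmetry of discrete tie-breaks
  ## (outline index order reverses under mirroring); the medial/lateral swap
  ## is absorbed by the side flag
  expect_lte(max(abs(lmM[, "x"] - (W + 1 - lm[, "x"]))), 1)
  expect_lte(max(abs(lmM[, "y"] - lm[, "y"])), 1)
})

test_that("aggregated extraction error names the failed regions", {
  case <- standardPhantom()
  masks <- phantomMasks(case)
  masks@masks$talus[] <- 0L
  err <- tryCatch(extractLandmarks(masks), error = function(e) e)
  expect_s3_class(err, "limbAlign_landmark_failure")
  expect_true("ankle" %in% err$region)
})

test_that("1 px boundary jitter moves no landmark by more than 3 px on the standard phantom", {
  case <- standardPhantom()
  lm <- landmarkPoints(extractLandmarks(phantomMasks(case)))
  corrupted <- corruptMasks(phantomMasks(case), p = 0.1, seed = 99)
  lmC <- landmarkPoints(extractLandmarks(corrupted))
  expect_lt(max(sqrt(rowSums((lmC - lm)^2))), 3)
})

test_that("a both-legs image splits into per-leg halves with the right side labels", {
  img <- matrix(seq_len(20 * 30), 20, 30)
  halves <- splitLegImage(img)
  expect_equal(ncol(halves$right$image), 15)
  expect_equal(halves$right$side, "right")   # patient right leg = image left half
  expect_equal(halves$left$side, "left")
  expect_equal(cbind(halves$right$image, halves$left$image), img)
})
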