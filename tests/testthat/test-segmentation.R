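test_that("stage-1 preprocessing resizes to 311 x 932 and rescales to [0, 1]", {
  img <- matrix(runif(3000 * 1000, 10, 240), 3000, 1000)     # 1000 x 3000 (w x h)
  r <- preprocessStage1(img, stageConfig("full"))
  expect_equal(dim(r), c(932, 311))
  expect_equal(min(r), 0)
  expect_equal(max(r), 1)

  ## already at size, already in [0, 1]: unchanged within interpolation tolerance
  base <- matrix(runif(932 * 311), 932, 311)
  base[1] <- 0; base[2] <- 1
  r2 <- preprocessStage1(base, stageConfig("full"))
  expect_lt(max(abs(r2 - base)), 1e-6)

  const <- preprocessStage1(matrix(7, 100, 50), stageConfig("full"))
  expect_true(all(const == 0))
  expect_equal(attr(const, "qualityFlags"), "constant_image")
})

test_that("crops use the per-bone working sizes and record an invertible transform", {
  cfg <- stageConfig("full")
  img <- matrix(runif(1600 * 900), 1600, 900)
  roi <- c(xmin = 101, ymin = 201, xmax = 500, ymax = 700)
  df <- cropAndResize(img, roi, "distal_femur", cfg)
  expect_equal(dim(df), c(540, 740))                          # 740 x 540 (w x h)
  expect_equal(dim(cropAndResize(img, roi, "talus", cfg)), c(220, 370))
  expect_equal(range(df), c(0, 1))

  ## round trip: a mask cropped and mapped back re-covers the roi footprint
  mask <- matrix(0L, 1600, 900)
  mask[250:650, 150:450] <- 1L
  cm <- cropAndResize(mask, roi, "proximal_tibia", cfg, isMask = TRUE)
  expect_true(all(cm %in% c(0L, 1L)))
  back <- mapMaskToRaw(cm, attr(cm, "transform"), dim(mask))
  inROI <- mask; inROI[, ] <- 0L
  inROI[201:700, 101:500] <- mask[201:700, 101:500]
  expect_gt(diceCoefficient(back, inROI), 0.995)              # nearest-neighbour quantisation only
  idx1 <- which(back > 0, arr.ind = TRUE); idx2 <- which(inROI > 0, arr.ind = TRUE)
  expect_lt(max(abs(range(idx1[, 1]) - range(idx2[, 1]))), 2)

  ## clipped roi is flagged; zero-area roi errors
  cl <- cropAndResize(img, c(xmin = -50, ymin = 1, xmax = 200, ymax = 300),
                      "femoral_head", cfg)
  expect_true("roi_clipped" %in% attr(cl, "qualityFlags"))
  expect_error(cropAndResize(img, c(xmin = 10, ymin = 10, xmax = 10, ymax = 300),
                             "talus", cfg), class = "limbAlign_empty_roi")
})

test_that("ROI geometry from ground-truth stage-1 labels contains each bone", {
  case <- standardPhantom()
  cfg <- stageConfig("desk")
  lab <- matrix(as.integer(LimbAlign:::.resizeRaster(
    LimbAlign:::.labelRaster(phantomMasks(case)),
    cfg$stage1Size[1], cfg$stage1Size[2], "none")),
    cfg$stage1Size[2], cfg$stage1Size[1])
  rois <- LimbAlign:::.roisFromLabels(lab, dim(phantomImage(case)), cfg, margin = 0.1)
  for (bone in LimbAlign:::.boneNames) {
    idx <- which(boneMask(phantomMasks(case), bone) > 0, arr.ind = TRUE)
    r <- rois[[bone]]
    expect_gte(min(idx[, 2]), r["xmin"] - 2)
    expect_lte(max(idx[, 2]), r["xmax"] + 2)
    expect_gte(min(idx[, 1]), r["ymin"] - 2)
    expect_lte(max(idx[, 1]), r["ymax"] + 2)
  }
  ## with zero margin the box matches the ground-truth extent up to the
  ## stage-1 resize quantisation (one stage-1 pixel)
  rois0 <- LimbAlign:::.roisFromLabels(lab, dim(phantomImage(case)), cfg, margin = 0)
  q <- nrow(phantomImage(case)) / cfg$stage1Size[2] + 1
  idx <- which(boneMask(phantomMasks(case), "distal_femur") > 0, arr.ind = TRUE)
  r0 <- rois0[["distal_femur"]]
  expect_lt(abs(r0["ymin"] - min(idx[, 1])), q + 1)
  expect_lt(abs(r0["ymax"] - max(idx[, 1])), q + 1)

  lab0 <- lab; lab0[lab0 == 5L] <- 0L
  expect_error(LimbAlign:::.roisFromLabels(lab0, dim(phantomImage(case)), cfg),
               class = "limbAlign_roi_not_found")
})

test_that("model construction: softmax normalisation, desk/full parameter ratio, seeding", {
  full <- buildSegModel("full", classes = 2L, seed = 3)
  p <- predictProbs(full, matrix(runif(64 * 64), 64, 64))
  expect_equal(dim(p), c(64, 64, 2))
  expect_equal(as.vector(p[, , 1] + p[, , 2]), rep(1, 64 * 64), tolerance = 1e-6)

  nPar <- function(m) sum(vapply(rapply(m@params, length, how = "unlist"), sum, numeric(1)))
  desk <- buildSegModel("desk", classes = 2L, seed = 3)
  expect_lt(nPar(desk) / nPar(full), 0.01)

  desk2 <- buildSegModel("desk", classes = 2L, seed = 3)
  expect_identical(desk@params, desk2@params)
  desk3 <- buildSegModel("desk", classes = 2L, seed = 4)
  expect_false(identical(desk@params, desk3@params))
})

segTrainingFixture <- function(n = 12, size = 32, seed = 5) {
  set.seed(seed)
  imgs <- list(); labs <- list()
  for (i in seq_len(n)) {
    m <- matrix(0, size, size)
    m <- LimbAlign:::.rasterDisk(m, runif(1, 12, 20), runif(1, 12, 20), runif(1, 6, 9))
    img <- 0.2 + 0.6 * m + matrix(rnorm(size^2, 0, 0.05), size, size)
    imgs[[i]] <- pmin(pmax(img, 0), 1)
    labs[[i]] <- matrix(as.integer(m), size, size)
  }
  list(images = imgs, labels = labs)
}

test_that("training: zero learning rate is an identity; loss decreases when learning", {
  fx <- segTrainingFixture()
  m0 <- buildSegModel("desk", classes = 2L, seed = 1)
  frozen <- trainSegModel(m0, fx$images, fx$labels,
                          trainConfig(learningRate = 0, maxEpochs = 2, seed = 1))
  expect_identical(frozen@params, m0@params)
  h <- trainingHistory(frozen)
  expect_equal(h$train_loss[1], h$train_loss[2], tolerance = 1e-12)

  trained <- trainSegModel(m0, fx$images[1:9], fx$labels[1:9],
                           trainConfig(maxEpochs = 6, seed = 2),
                           fx$images[10:12], fx$labels[10:12])
  h2 <- trainingHistory(trained)
  expect_lt(h2$val_loss[6], h2$val_loss[1])
  expect_true(trained@trained)
})

test_that("training is deterministic under fixed seeds", {
  fx <- segTrainingFixture(n = 8)
  run <- function() {
    m <- buildSegModel("desk", classes = 2L, seed = 7)
    trainingHistory(trainSegModel(m, fx$images, fx$labels,
                                  trainConfig(maxEpochs = 3, seed = 11)))
  }
  expect_identical(run(), run())
})

test_that("predictMask applies the largest-component and hole-filling rule", {
  fx <- segTrainingFixture(n = 12, seed = 9)
  m <- buildSegModel("desk", classes = 2L, seed = 2)
  m <- trainSegModel(m, fx$images, fx$labels, trainConfig(maxEpochs = 8, seed = 3))
  img <- fx$images[[1]]
  pred <- predictMask(m, img)
  raw <- predictLabels(m, img) > 0
  if (any(raw)) {
    comp <- LimbAlign:::.largestComponent(raw)
    oracle <- t(EBImage::imageData(EBImage::fillHull(EBImage::Image(t(comp * 1))))) > 0
    expect_identical(pred, matrix(as.integer(oracle), nrow(raw), ncol(raw)))
    expect_equal(max(LimbAlign:::.label8(pred)), 1L)        # single component
  } else {
    expect_true(all(pred == 0L))
  }
})

test_that("desk training reaches excellent agreement (DSC >= 0.7) on held-out disks", {
  fx <- segTrainingFixture(n = 24, seed = 13)
  m <- buildSegModel("desk", classes = 2L, seed = 4)
  m <- trainSegModel(m, fx$images[1:18], fx$labels[1:18],
                     trainConfig(maxEpochs = 40, seed = 5),
                     fx$images[19:21], fx$labels[19:21])
  d <- vapply(22:24, function(i) diceCoefficient(predictMask(m, fx$images[[i]]), fx$labels[[i]]),
              numeric(1))
  expect_gte(mean(d), 0.7)
})
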