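## End-to-end desk-scale experiment: generate a phantom population, train the
## two-step pipeline at desk scale, and evaluate held-out segmentation
## quality. This is the package's reproducible stand-in for the clinical
## training runs (which require hospital radiographs): same two-step design,
## same solver recipe, scaled-down sizes, synthetic data.

.labelRaster <- function(masks) {
  lab <- matrix(0L, nrow(masks@masks[[1L]]), ncol(masks@masks[[1L]]))
  for (k in seq_along(.boneNames)) lab[masks@masks[[.boneNames[k]]] > 0] <- k
  lab
}

.truthRoi <- function(mask, margin = 0.1) {
  idx <- which(mask > 0)
  H <- nrow(mask)
  ys <- (idx - 1L) %% H + 1L; xs <- (idx - 1L) %/% H + 1L
  x0 <- min(xs); x1 <- max(xs); y0 <- min(ys); y1 <- max(ys)
  mx <- margin * (x1 - x0); my <- margin * (y1 - y0)
  c(xmin = max(1, x0 - mx), ymin = max(1, y0 - my),
    xmax = min(ncol(mask), x1 + mx), ymax = min(nrow(mask), y1 + my))
}

## one case -> training tensors (stage-1 image + label, per-bone crops)
.caseTensors <- function(case, cfg) {
  img <- phantomImage(case)
  masks <- phantomMasks(case)
  s1img <- preprocessStage1(img, cfg)
  s1lab <- matrix(as.integer(.resizeRaster(.labelRaster(masks),
                                           cfg$stage1Size[1L], cfg$stage1Size[2L],
                                           "none")), cfg$stage1Size[2L], cfg$stage1Size[1L])
  crops <- list()
  for (bone in .boneNames) {
    roi <- .truthRoi(boneMask(masks, bone))
    ci <- cropAndResize(img, roi, bone, cfg, isMask = FALSE)
    cm <- cropAndResize(boneMask(masks, bone), roi, bone, cfg, isMask = TRUE)
    crops[[bone]] <- list(image = ci, label = cm)
  }
  list(s1img = s1img, s1lab = s1lab, crops = crops)
}

#' Desk-scale two-step segmentation study on synthetic phantoms
#'
#' Generates `nCases` phantoms from the population marginals of
#' [samplePopulation()], splits them 80/10/10 into training, validation and
#' test sets, trains the stage-1 multi-class model on whole-limb images and
#' one stage-2 binary model per bone on ground-truth-derived crops (SGD
#' momentum 0.9, learning rate 1e-2, mini-batch 4), then runs the full
#' two-step pipeline (stage-1 ROIs, stage-2 prediction, mapping back to raw
#' coordinates) on the held-out test cases and scores the predicted masks
#' against the ground truth with the Dice similarity coefficient.
#'
#' @param nCases population size (default 200).
#' @param populationSeed seed of the phantom population draw.
#' @param seed seed for the split and all training randomness.
#' @param stage1Epochs,stage2Epochs training epochs per stage.
#' @param verbose print progress.
#' @return List with `meanDSC` (named per-bone means over test cases),
#'   `dsc` (test-case x bone matrix), `models`, `histories`, and the split
#'   sizes.
#' @export
runDeskSegmentationStudy <- function(nCases = 200, populationSeed = 42, seed = 1,
                                     stage1Epochs = 24, stage2Epochs = 8,
                                     verbose = FALSE) {
  cfg <- stageConfig("desk")
  specs <- samplePopulation(nCases, seed = populationSeed, generate = FALSE)
  oldSeed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, envir = globalenv()))
  set.seed(seed)
  ord <- sample.int(nCases)
  nTest <- max(1L, round(0.1 * nCases))
  nVal <- max(1L, round(0.1 * nCases))
  nTrain <- nCases - nVal - nTest
  idxTrain <- ord[seq_len(nTrain)]
  idxVal <- ord[nTrain + seq_len(nVal)]
  idxTest <- ord[nTrain + nVal + seq_len(nTest)]

  collect <- function(indices) {
    s1i <- list(); s1l <- list()
    cr <- lapply(.boneNames, function(b) list(images = list(), labels = list()))
    names(cr) <- .boneNames
    for (i in indices) {
      tens <- .caseTensors(generatePhantom(specs[[i]]), cfg)
      s1i[[length(s1i) + 1L]] <- tens$s1img
      s1l[[length(s1l) + 1L]] <- tens$s1lab
      for (bone in .boneNames) {
        cr[[bone]]$images[[length(cr[[bone]]$images) + 1L]] <- tens$crops[[bone]]$image
        cr[[bone]]$labels[[length(cr[[bone]]$labels) + 1L]] <- tens$crops[[bone]]$label
      }
    }
    list(s1i = s1i, s1l = s1l, crops = cr)
  }
  if (verbose) message("generating training tensors (", nTrain, " cases)")
  tr <- collect(idxTrain)
  if (verbose) message("generating validation tensors (", nVal, " cases)")
  va <- collect(idxVal)

  if (verbose) message("training stage-1 model")
  s1model <- buildSegModel("desk", classes = length(.boneNames) + 1L, seed = seed)
  s1model <- trainSegModel(s1model, tr$s1i, tr$s1l,
                           trainConfig(maxEpochs = stage1Epochs, seed = seed + 1,
                                       classWeights = "balanced"),
                           va$s1i, va$s1l)
  s2models <- list(); s2hist <- list()
  for (bone in .boneNames) {
    if (verbose) message("training stage-2 model: ", bone)
    m <- buildSegModel("desk", classes = 2L, seed = seed + match(bone, .boneNames))
    m <- trainSegModel(m, tr$crops[[bone]]$images, tr$crops[[bone]]$labels,
                       trainConfig(maxEpochs = stage2Epochs, seed = seed + 10 + match(bone, .boneNames)),
                       va$crops[[bone]]$images, va$crops[[bone]]$labels)
    s2models[[bone]] <- m
    s2hist[[bone]] <- trainingHistory(m)
  }

  if (verbose) message("evaluating on ", nTest, " held-out cases")
  dsc <- matrix(NA_real_, nTest, length(.boneNames),
                dimnames = list(NULL, .boneNames))
  flags <- character(0)
  for (t in seq_len(nTest)) {
    case <- generatePhantom(specs[[idxTest[t]]])
    res <- segmentLimb(phantomImage(case), s1model, s2models, cfg, strict = FALSE)
    if (length(res$missing))
      flags <- c(flags, sprintf("case %d: no stage-1 roi for %s", idxTest[t],
                                paste(res$missing, collapse = ", ")))
    for (bone in .boneNames)
      dsc[t, bone] <- diceCoefficient(res$masks[[bone]], boneMask(phantomMasks(case), bone))
  }
  list(meanDSC = colMeans(dsc), dsc = dsc,
       models = c(list(stage1 = s1model), s2models),
       histories = c(list(stage1 = trainingHistory(s1model)), s2hist),
       nTrain = nTrain, nVal = nVal, nTest = nTest, flags = flags)
}

#' Landmark/angle round-trip over a deformity grid
#'
#' Generates one phantom per combination of the requested mLDFA, MPTA and
#' signed JLCA targets, extracts landmarks from the ground-truth masks,
#' computes the four angles, and reports recovered vs. truth.
#'
#' @param mLDFA,MPTA,JLCA numeric vectors of target angles (degrees), crossed
#'   with [expand.grid()].
#' @param grid optional data.frame with columns `mLDFA`, `MPTA`,
#'   `JLCA_signed`, overriding the crossed vectors (e.g. to sweep mLDFA and
#'   MPTA in lockstep).
#' @param side patient side for the generated phantoms.
#' @param baseSeed per-case seeds are derived from it.
#' @return data.frame with targets, truth and recovered angles and the
#'   absolute errors.
#' @export
angleRoundTrip <- function(mLDFA = 84:92, MPTA = 84:92, JLCA = 0:6,
                           grid = NULL, side = "right", baseSeed = 1) {
  if (is.null(grid)) grid <- expand.grid(mLDFA = mLDFA, MPTA = MPTA, JLCA_signed = JLCA)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    spec <- phantomSpec(mLDFA = grid$mLDFA[i], MPTA = grid$MPTA[i],
                        JLCA_signed = grid$JLCA_signed[i], side = side,
                        seed = baseSeed + i)
    case <- generatePhantom(spec)
    truth <- angleValues(truthAngles(case))
    rec <- angleValues(computeAngles(buildAxes(extractLandmarks(phantomMasks(case)))))
    data.frame(grid[i, , drop = FALSE],
               truth_mTFA = truth["mTFA"], truth_mLDFA = truth["mLDFA"],
               truth_MPTA = truth["MPTA"], truth_JLCA = truth["JLCA"],
               rec_mTFA = rec["mTFA"], rec_mLDFA = rec["mLDFA"],
               rec_MPTA = rec["MPTA"], rec_JLCA = rec["JLCA"],
               err_mTFA = abs(rec["mTFA"] - truth["mTFA"]),
               err_mLDFA = abs(rec["mLDFA"] - truth["mLDFA"]),
               err_MPTA = abs(rec["MPTA"] - truth["MPTA"]),
               err_JLCA = abs(rec["JLCA"] - truth["JLCA"]),
               row.names = NULL)
  })
  do.call(rbind, rows)
}
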