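#' @import methods
NULL

setOldClass("Line")

.boneNames <- c("femoral_head", "distal_femur", "proximal_tibia",
                "distal_tibia", "talus")

.landmarkNames <- c("femoral_head_center", "intercondylar_notch",
                    "tibial_spine_center", "medial_condyle", "lateral_condyle",
                    "medial_plateau", "lateral_plateau", "ankle_center")

.maskCentroid <- function(mask) {
  idx <- which(mask > 0)
  H <- nrow(mask)
  c(x = mean((idx - 1L) %/% H + 1L), y = mean((idx - 1L) %% H + 1L))
}

#' LimbMasks: the five per-bone binary masks of one leg
#'
#' Binary rasters for the femoral head, distal femur, proximal tibia, distal
#' tibia and talus of a single leg, on a shared image grid, together with the
#' patient side and an optional isotropic pixel spacing. Validity enforces
#' identical dimensions and the proximal-to-distal ordering of the component
#' centroids (femoral head above distal femur above proximal tibia above
#' distal tibia above talus).
#'
#' @slot masks named list of five binary matrices (`mask[y, x]`, values 0/1).
#' @slot side `"left"` or `"right"` (patient side).
#' @slot pixelSpacing mm per pixel (isotropic), `NA` if unknown.
#' @export
setClass("LimbMasks", representation(
  masks = "list", side = "character", pixelSpacing = "numeric"
))

setValidity("LimbMasks", function(object) {
  msg <- character(0)
  if (!identical(names(object@masks), .boneNames))
    msg <- c(msg, sprintf("masks must be named: %s", paste(.boneNames, collapse = ", ")))
  else {
    dims <- lapply(object@masks, dim)
    if (length(unique(dims)) != 1L)
      msg <- c(msg, "all five masks must share identical dimensions")
    ## empty masks are tolerated at construction (landmark extraction reports
    ## them as per-region failures); the ordering invariant applies to the
    ## non-empty ones
    nonEmpty <- vapply(object@masks, function(m) any(m > 0), logical(1))
    if (sum(nonEmpty) >= 2L) {
      cy <- vapply(object@masks[nonEmpty], function(m) .maskCentroid(m)["y"], numeric(1))
      if (any(diff(cy) <= 0))
        msg <- c(msg, "bone centroids must be ordered proximal to distal (femoral head to talus)")
    }
  }
  if (!(length(object@side) == 1L && object@side %in% c("left", "right")))
    msg <- c(msg, "side must be 'left' or 'right'")
  if (length(msg)) msg else TRUE
})

#' Construct a LimbMasks object
#'
#' @param femoral_head,distal_femur,proximal_tibia,distal_tibia,talus binary
#'   matrices on a shared grid (`m[y, x]`, foreground > 0).
#' @param side patient side, `"left"` or `"right"`.
#' @param pixelSpacing optional isotropic spacing in mm/px.
#' @return A [LimbMasks-class] object.
#' @export
LimbMasks <- function(femoral_head, distal_femur, proximal_tibia, distal_tibia,
                      talus, side = "right", pixelSpacing = NA_real_) {
  masks <- list(femoral_head = femoral_head, distal_femur = distal_femur,
                proximal_tibia = proximal_tibia, distal_tibia = distal_tibia,
                talus = talus)
  masks <- lapply(masks, function(m) {
    m <- matrix(as.integer(as.matrix(m) != 0), nrow(m), ncol(m))
    m
  })
  new("LimbMasks", masks = masks, side = side, pixelSpacing = as.numeric(pixelSpacing))
}

#' LandmarkSet: the eight anatomic feature points of one leg
#'
#' @slot points 8 x 2 numeric matrix (columns x, y), rows named
#'   `femoral_head_center`, `intercondylar_notch`, `tibial_spine_center`,
#'   `medial_condyle`, `lateral_condyle`, `medial_plateau`, `lateral_plateau`,
#'   `ankle_center`.
#' @slot side `"left"` or `"right"`.
#' @export
setClass("LandmarkSet", representation(points = "matrix", side = "character"))

setValidity("LandmarkSet", function(object) {
  p <- object@points
  msg <- character(0)
  if (!identical(rownames(p), .landmarkNames) || ncol(p) != 2L)
    msg <- c(msg, "points must be an 8 x 2 matrix with the canonical row names")
  else {
    if (!all(is.finite(p))) msg <- c(msg, "landmark coordinates must be finite")
    else {
      if (!(p["femoral_head_center", 2L] < p["intercondylar_notch", 2L] &&
            p["intercondylar_notch", 2L] < p["ankle_center", 2L]))
        msg <- c(msg, "proximal-to-distal ordering violated (head above notch above ankle)")
      for (pair in list(c("medial_condyle", "lateral_condyle"),
                        c("medial_plateau", "lateral_plateau"))) {
        if (p[pair[1L], 1L] == p[pair[2L], 1L])
          msg <- c(msg, sprintf("%s/%s must straddle the bone midline", pair[1L], pair[2L]))
      }
    }
  }
  if (!(length(object@side) == 1L && object@side %in% c("left", "right")))
    msg <- c(msg, "side must be 'left' or 'right'")
  if (length(msg)) msg else TRUE
})

#' Construct a LandmarkSet
#'
#' @param points 8 x 2 matrix (columns x, y) with the canonical row names, or a
#'   named list of length-2 points.
#' @param side patient side.
#' @return A [LandmarkSet-class] object.
#' @export
LandmarkSet <- function(points, side = "right") {
  if (is.list(points)) points <- do.call(rbind, points[.landmarkNames])
  points <- as.matrix(points)
  rownames(points) <- .landmarkNames
  colnames(points) <- c("x", "y")
  new("LandmarkSet", points = points, side = side)
}

#' AxisSet: the four lines of the alignment measurement
#'
#' Femoral and tibial mechanical axes plus the two articular surface lines.
#' Validity enforces rough anatomical orientation: mechanical axes within 45
#' degrees of image-vertical, articular lines within 45 degrees of horizontal.
#'
#' @slot femoral_mech femoral head centre -> intercondylar notch.
#' @slot tibial_mech tibial spine centre -> ankle centre.
#' @slot femoral_articular medial condyle -> lateral condyle.
#' @slot tibial_articular medial plateau -> lateral plateau.
#' @slot side `"left"` or `"right"`.
#' @export
setClass("AxisSet", representation(
  femoral_mech = "Line", tibial_mech = "Line",
  femoral_articular = "Line", tibial_articular = "Line", side = "character"
))

setValidity("AxisSet", function(object) {
  msg <- character(0)
  ang <- function(line) abs(.dirAngle(.lineDir(line), c(0, 1)))  # from vertical
  for (nm in c("femoral_mech", "tibial_mech")) {
    a <- ang(slot(object, nm))
    if (min(a, 180 - a) > 45) msg <- c(msg, sprintf("%s is > 45 deg from vertical", nm))
  }
  for (nm in c("femoral_articular", "tibial_articular")) {
    a <- ang(slot(object, nm))
    if (abs(90 - a) > 45) msg <- c(msg, sprintf("%s is > 45 deg from horizontal", nm))
  }
  if (!(length(object@side) == 1L && object@side %in% c("left", "right")))
    msg <- c(msg, "side must be 'left' or 'right'")
  if (length(msg)) msg else TRUE
})

#' AlignmentAngles: the four coronal alignment angles of one leg
#'
#' @slot mTFA mechanical tibiofemoral angle in degrees. Under the default
#'   `"varus_gt_180"` convention neutral is 180 and varus deformity is > 180.
#' @slot mLDFA mechanical lateral distal femoral angle (degrees).
#' @slot MPTA medial proximal tibial angle (degrees).
#' @slot JLCA_signed joint line convergence angle, positive = lateral joint
#'   line opening.
#' @slot JLCA reported magnitude of the joint line convergence angle.
#' @slot convention `"varus_gt_180"` or `"varus_lt_180"` (which side of 180
#'   the mTFA reports varus on).
#' @slot qualityFlags character vector of sanity-bound violations.
#' @export
setClass("AlignmentAngles", representation(
  mTFA = "numeric", mLDFA = "numeric", MPTA = "numeric",
  JLCA_signed = "numeric", JLCA = "numeric",
  convention = "character", qualityFlags = "character"
))

#' PhantomSpec: parameters of one synthetic limb phantom
#'
#' Geometric and noise parameters of the stylised long-leg radiograph
#' generator. All lengths are in pixels of the phantom canvas (the default
#' canvas emulates a ~0.5 mm/px long-leg field of view at desk resolution);
#' angle targets are in degrees.
#'
#' @slot imageWidth,imageHeight canvas size in pixels.
#' @slot side `"left"` or `"right"`.
#' @slot femurLength,tibiaLength mechanical-axis lengths (px).
#' @slot femoralHeadRadius radius of the femoral head disk (px).
#' @slot condyleRadius radius of each condylar lobe (px).
#' @slot condyleSeparation distance between the two condylar contact points (px).
#' @slot spineHeight height of the tibial spines above the inter-spine notch (px).
#' @slot spineSeparation distance between the two spine tips (px).
#' @slot mLDFA,MPTA,JLCA_signed target angles (degrees).
#' @slot boundaryJitterP Bernoulli probability of the boundary-noise model.
#' @slot intensitySigma Gaussian intensity noise SD (8-bit gray levels).
#' @slot seed RNG seed making the case reproducible.
#' @export
setClass("PhantomSpec", representation(
  imageWidth = "numeric", imageHeight = "numeric", side = "character",
  femurLength = "numeric", tibiaLength = "numeric",
  femoralHeadRadius = "numeric", condyleRadius = "numeric",
  condyleSeparation = "numeric", spineHeight = "numeric",
  spineSeparation = "numeric",
  mLDFA = "numeric", MPTA = "numeric", JLCA_signed = "numeric",
  boundaryJitterP = "numeric", intensitySigma = "numeric", seed = "numeric"
))

setValidity("PhantomSpec", function(object) {
  msg <- character(0)
  pos <- c("imageWidth", "imageHeight", "femurLength", "tibiaLength",
           "femoralHeadRadius", "condyleRadius", "condyleSeparation",
           "spineHeight", "spineSeparation")
  for (nm in pos) if (slot(object, nm) <= 0) msg <- c(msg, sprintf("%s must be > 0", nm))
  if (object@mLDFA < 60 || object@mLDFA > 120) msg <- c(msg, "mLDFA target outside [60, 120]")
  if (object@MPTA < 60 || object@MPTA > 120) msg <- c(msg, "MPTA target outside [60, 120]")
  if (abs(object@JLCA_signed) > 30) msg <- c(msg, "JLCA target outside [-30, 30]")
  if (object@boundaryJitterP < 0 || object@boundaryJitterP >= 0.5)
    msg <- c(msg, "boundaryJitterP must be in [0, 0.5)")
  if (object@intensitySigma < 0) msg <- c(msg, "intensitySigma must be >= 0")
  if (!(object@side %in% c("left", "right"))) msg <- c(msg, "side must be 'left' or 'right'")
  if (length(msg)) msg else TRUE
})

#' PhantomCase: one generated phantom with its ground truth
#'
#' @slot image grayscale raster (matrix, 0-255).
#' @slot masks ground-truth [LimbMasks-class].
#' @slot truthLandmarks ground-truth [LandmarkSet-class].
#' @slot truthAngles ground-truth [AlignmentAngles-class] (recomputable from
#'   the landmarks via [buildAxes()] + [computeAngles()] to within 1e-6 deg).
#' @slot spec the generating [PhantomSpec-class].
#' @export
setClass("PhantomCase", representation(
  image = "matrix", masks = "LimbMasks", truthLandmarks = "LandmarkSet",
  truthAngles = "AlignmentAngles", spec = "PhantomSpec"
))

#' SegModel: encoder-decoder segmentation network
#'
#' A SegNet-style encoder-decoder: each encoder block is convolution +
#' per-channel feature normalisation + ReLU followed by 2x2 max-pooling whose
#' argmax indices are reused by the matching decoder block for unpooling; the
#' final decoder convolution feeds a per-pixel softmax. `scale = "full"` mirrors the first 13 convolutional
#' layers of VGG16 in the encoder (and 13 in the decoder); `scale = "desk"` is
#' the same topology reduced to 4 single-convolution blocks of at most 32
#' channels so that it trains on a CPU.
#'
#' @slot scale `"full"` or `"desk"`.
#' @slot config architecture descriptor (blocks, channels, classes, input
#'   channels).
#' @slot params list of layer weights.
#' @slot classes integer number of output classes (background + bones).
#' @slot trained logical.
#' @slot seed initialisation seed.
#' @slot history data.frame of per-epoch training/validation loss (empty
#'   until trained).
#' @export
setClass("SegModel", representation(
  scale = "character", config = "list", params = "list", classes = "integer",
  trained = "logical", seed = "numeric", history = "data.frame"
))

## ---- show methods ---------------------------------------------------------

setMethod("show", "LimbMasks", function(object) {
  d <- dim(object@masks[[1L]])
  cat(sprintf("LimbMasks: %d x %d px, side = %s, spacing = %s mm/px\n",
              d[2L], d[1L], object@side,
              ifelse(is.na(object@pixelSpacing), "NA", format(object@pixelSpacing))))
  areas <- vapply(object@masks, function(m) sum(m > 0), numeric(1))
  cat(paste(sprintf("  %-15s %6d px", names(areas), areas), collapse = "\n"), "\n")
})

setMethod("show", "LandmarkSet", function(object) {
  cat(sprintf("LandmarkSet (side = %s):\n", object@side))
  p <- object@points
  cat(paste(sprintf("  %-20s (%7.2f, %7.2f)", rownames(p), p[, 1L], p[, 2L]),
            collapse = "\n"), "\n")
})

setMethod("show", "AxisSet", function(object) {
  cat(sprintf("AxisSet (side = %s): femoral/tibial mechanical axes + articular lines\n",
              object@side))
})

setMethod("show", "AlignmentAngles", function(object) {
  cat(sprintf("AlignmentAngles [%s]:\n  mTFA  %7.2f\n  mLDFA %7.2f\n  MPTA  %7.2f\n  JLCA  %7.2f (signed %+.2f)\n",
              object@convention, object@mTFA, object@mLDFA, object@MPTA,
              object@JLCA, object@JLCA_signed))
  if (length(object@qualityFlags))
    cat("  flags:", paste(object@qualityFlags, collapse = ", "), "\n")
})

setMethod("show", "PhantomCase", function(object) {
  d <- dim(object@image)
  cat(sprintf("PhantomCase: %d x %d px, side = %s\n", d[2L], d[1L], object@spec@side))
  show(object@truthAngles)
})

setMethod("show", "SegModel", function(object) {
  np <- sum(vapply(unlist(object@params, recursive = FALSE), length, numeric(1)))
  cat(sprintf("SegModel (%s): %d classes, %d parameters, %s\n", object@scale,
              object@classes, np, if (object@trained) "trained" else "untrained"))
})

## ---- accessors ------------------------------------------------------------

#' Access one bone mask of a LimbMasks object
#'
#' @param x a [LimbMasks-class].
#' @param bone one of `"femoral_head"`, `"distal_femur"`, `"proximal_tibia"`,
#'   `"distal_tibia"`, `"talus"`.
#' @return Binary integer matrix (`m[y, x]`).
#' @export
boneMask <- function(x, bone) {
  stopifnot(is(x, "LimbMasks"), bone %in% .boneNames)
  x@masks[[bone]]
}

#' Patient side of an object
#' @param x a `LimbMasks`, `LandmarkSet` or `AxisSet`.
#' @return `"left"` or `"right"`.
#' @export
limbSide <- function(x) x@side

#' Landmark coordinate matrix
#' @param x a [LandmarkSet-class].
#' @return 8 x 2 matrix with columns x, y.
#' @export
landmarkPoints <- function(x) {
  stopifnot(is(x, "LandmarkSet"))
  x@points
}

#' Extract one named landmark
#' @param x a [LandmarkSet-class].
#' @param name landmark name (see [LandmarkSet()]).
#' @return A [Point()].
#' @export
landmark <- function(x, name) {
  stopifnot(is(x, "LandmarkSet"), name %in% .landmarkNames)
  Point(x@points[name, 1L], x@points[name, 2L])
}

#' Alignment angles as a named vector
#' @param x an [AlignmentAngles-class] object.
#' @return Named numeric vector with mTFA, mLDFA, MPTA, JLCA, JLCA_signed.
#' @export
angleValues <- function(x) {
  stopifnot(is(x, "AlignmentAngles"))
  c(mTFA = x@mTFA, mLDFA = x@mLDFA, MPTA = x@MPTA,
    JLCA = x@JLCA, JLCA_signed = x@JLCA_signed)
}

#' Ground-truth components of a phantom case
#' @param x a [PhantomCase-class].
#' @return `phantomImage`: the grayscale raster; `phantomMasks`: the
#'   [LimbMasks-class]; `truthLandmarks`: the [LandmarkSet-class];
#'   `truthAngles`: the [AlignmentAngles-class].
#' @export
phantomImage <- function(x) { stopifnot(is(x, "PhantomCase")); x@image }

#' @rdname phantomImage
#' @export
phantomMasks <- function(x) { stopifnot(is(x, "PhantomCase")); x@masks }

#' @rdname phantomImage
#' @export
truthLandmarks <- function(x) { stopifnot(is(x, "PhantomCase")); x@truthLandmarks }

#' @rdname phantomImage
#' @export
truthAngles <- function(x) { stopifnot(is(x, "PhantomCase")); x@truthAngles }

#' Training history of a segmentation model
#' @param x a [SegModel-class].
#' @return data.frame with epoch, train and validation loss.
#' @export
trainingHistory <- function(x) { stopifnot(is(x, "SegModel")); x@history }
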