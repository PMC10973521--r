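## Two-step segmentation plumbing: stage 1 locates one region of interest per
## bone on the downscaled whole-limb image; stage 2 segments each bone inside
## its cropped, per-bone-sized window. Images are resized bilinearly, masks
## with nearest-neighbour (so they stay binary); every crop records its affine
## transform so predictions can be mapped back to raw-image coordinates.

.resizeRaster <- function(m, w, h, filter = c("bilinear", "none")) {
  filter <- match.arg(filter)
  out <- EBImage::resize(EBImage::Image(t(m)), w = w, h = h, filter = filter)
  t(EBImage::imageData(out))
}

#' Stage configuration: working sizes of the two-step pipeline
#'
#' At `"full"` scale the stage-1 image is 311 x 932 px and the per-bone crop
#' sizes are femoral head 470 x 470, distal femur 740 x 540, proximal tibia
#' 720 x 470, distal tibia 470 x 430 and talus 370 x 220 (width x height).
#' The `"desk"` scale keeps the same proportions at sizes a small CPU model
#' can train on (stage 1 48 x 128; crops 32-80 px, all divisible by the
#' pooling factor 16).
#'
#' @param scale `"full"` or `"desk"`.
#' @return List with `scale`, `stage1Size` `c(w, h)` and `cropSizes` (named
#'   list of `c(w, h)` per bone).
#' @export
stageConfig <- function(scale = c("full", "desk")) {
  scale <- match.arg(scale)
  if (scale == "full") {
    list(scale = scale, stage1Size = c(311, 932),
         cropSizes = list(femoral_head = c(470, 470), distal_femur = c(740, 540),
                          proximal_tibia = c(720, 470), distal_tibia = c(470, 430),
                          talus = c(370, 220)))
  } else {
    list(scale = scale, stage1Size = c(48, 128),
         cropSizes = list(femoral_head = c(48, 48), distal_femur = c(64, 80),
                          proximal_tibia = c(48, 64), distal_tibia = c(48, 48),
                          talus = c(64, 48)))
  }
}

#' Stage-1 preprocessing: resize and intensity normalisation
#'
#' Resizes the raw image bilinearly to the stage-1 working size and maps the
#' intensities affinely to `[0, 1]` (min to 0, max to 1). A constant image is
#' mapped to all zeros and flagged.
#'
#' @param image grayscale raster (matrix `m[y, x]`).
#' @param cfg a [stageConfig()].
#' @return Normalised matrix of the stage-1 size, with attribute
#'   `"qualityFlags"` (character, possibly empty).
#' @export
preprocessStage1 <- function(image, cfg = stageConfig("full")) {
  if (length(image) == 0L) .laStop("limbAlign_empty_image", "empty image")
  r <- .resizeRaster(image, cfg$stage1Size[1L], cfg$stage1Size[2L], "bilinear")
  flags <- character(0)
  rng <- range(r)
  if (diff(rng) == 0) { r[] <- 0; flags <- "constant_image" }
  else r <- (r - rng[1L]) / diff(rng)
  attr(r, "qualityFlags") <- flags
  r
}

## map a pixel-centre coordinate on a resized grid back to the raw grid
.resizedToRaw <- function(x, nNew, nRaw) (x - 0.5) * (nRaw / nNew) + 0.5

#' Locate per-bone regions of interest with the stage-1 model
#'
#' Predicts the multi-class label raster on the preprocessed stage-1 image,
#' takes the bounding box of the largest connected component of each bone
#' class, maps it back through the resize transform to raw-image coordinates
#' and pads it by a relative margin.
#'
#' @param image raw grayscale raster.
#' @param model trained multi-class stage-1 [SegModel-class] (classes =
#'   background + 5 bones, in the canonical bone order).
#' @param cfg a [stageConfig()].
#' @param margin relative padding per side (default 0.1).
#' @param strict if `TRUE` (default) a bone class absent from the prediction
#'   raises an error; if `FALSE` its entry is `NULL`.
#' @return Named list of boxes `c(xmin, ymin, xmax, ymax)` in raw coordinates.
#' @export
locateRois <- function(image, model, cfg = stageConfig("full"), margin = 0.1,
                       strict = TRUE) {
  s1 <- preprocessStage1(image, cfg)
  lab <- predictLabels(model, s1)
  .roisFromLabels(lab, dim(image), cfg, margin, strict)
}

## ROI boxes from a stage-1 label raster (separated from the model call so the
## resize-transform geometry is testable against ground-truth labels).
.roisFromLabels <- function(lab, rawDim, cfg, margin = 0.1, strict = TRUE) {
  H <- rawDim[1L]; W <- rawDim[2L]
  rois <- stats::setNames(vector("list", length(.boneNames)), .boneNames)
  for (k in seq_along(.boneNames)) {
    cls <- lab == k
    if (!any(cls)) {
      if (strict)
        .laStop("limbAlign_roi_not_found",
                sprintf("roi-not-found(%s): class absent from stage-1 prediction", .boneNames[k]),
                bone = .boneNames[k])
      next
    }
    comp <- .largestComponent(cls)
    idx <- which(comp)
    ys <- (idx - 1L) %% nrow(comp) + 1L; xs <- (idx - 1L) %/% nrow(comp) + 1L
    x0 <- .resizedToRaw(min(xs), cfg$stage1Size[1L], W)
    x1 <- .resizedToRaw(max(xs), cfg$stage1Size[1L], W)
    y0 <- .resizedToRaw(min(ys), cfg$stage1Size[2L], H)
    y1 <- .resizedToRaw(max(ys), cfg$stage1Size[2L], H)
    mx <- margin * (x1 - x0); my <- margin * (y1 - y0)
    box <- c(xmin = x0 - mx, ymin = y0 - my, xmax = x1 + mx, ymax = y1 + my)
    ## a degenerate stage-1 component (one or two pixels) must still yield a
    ## usable crop: enforce a minimum extent per side
    minExt <- 8
    if (box["xmax"] - box["xmin"] < minExt) {
      cx <- (box["xmin"] + box["xmax"]) / 2
      box["xmin"] <- cx - minExt / 2; box["xmax"] <- cx + minExt / 2
    }
    if (box["ymax"] - box["ymin"] < minExt) {
      cy <- (box["ymin"] + box["ymax"]) / 2
      box["ymin"] <- cy - minExt / 2; box["ymax"] <- cy + minExt / 2
    }
    rois[[.boneNames[k]]] <- c(xmin = max(1, box[["xmin"]]), ymin = max(1, box[["ymin"]]),
                               xmax = min(W, box[["xmax"]]), ymax = min(H, box[["ymax"]]))
  }
  rois
}

#' Crop a region of interest and resize it to a bone's working size
#'
#' @param image raster to crop (image or mask).
#' @param roi box `c(xmin, ymin, xmax, ymax)` in raw coordinates (clipped to
#'   the image if needed, with a quality flag).
#' @param bone bone name selecting the output size from `cfg$cropSizes`.
#' @param cfg a [stageConfig()].
#' @param isMask if `TRUE`, resize nearest-neighbour and skip intensity
#'   normalisation (masks stay binary).
#' @return Raster of the configured size with attributes `"transform"` (crop
#'   box and scales for inverse mapping) and `"qualityFlags"`.
#' @export
cropAndResize <- function(image, roi, bone, cfg = stageConfig("full"), isMask = FALSE) {
  stopifnot(bone %in% .boneNames)
  H <- nrow(image); W <- ncol(image)
  flags <- character(0)
  x0 <- round(roi["xmin"]); x1 <- round(roi["xmax"])
  y0 <- round(roi["ymin"]); y1 <- round(roi["ymax"])
  if (x0 < 1 || y0 < 1 || x1 > W || y1 > H) flags <- c(flags, "roi_clipped")
  x0 <- max(1, x0); y0 <- max(1, y0); x1 <- min(W, x1); y1 <- min(H, y1)
  if (x1 <= x0 || y1 <= y0) .laStop("limbAlign_empty_roi", "zero-area roi")
  sz <- cfg$cropSizes[[bone]]
  sub <- image[y0:y1, x0:x1, drop = FALSE]
  out <- .resizeRaster(sub, sz[1L], sz[2L], if (isMask) "none" else "bilinear")
  if (isMask) out <- matrix(as.integer(out > 0.5), sz[2L], sz[1L])
  else {
    rng <- range(out)
    if (diff(rng) == 0) { out[] <- 0; flags <- c(flags, "constant_crop") }
    else out <- (out - rng[1L]) / diff(rng)
  }
  attr(out, "transform") <- list(x0 = x0, y0 = y0, x1 = x1, y1 = y1,
                                 outW = sz[1L], outH = sz[2L])
  attr(out, "qualityFlags") <- flags
  out
}

#' Map a crop-space mask back to raw-image coordinates
#'
#' Inverse of [cropAndResize()]: nearest-neighbour resize of the mask back to
#' the crop extent, pasted into a zero raster of the raw size.
#'
#' @param mask binary matrix at the crop working size.
#' @param transform the `"transform"` attribute recorded by [cropAndResize()].
#' @param rawDim `c(nrow, ncol)` of the raw image.
#' @return Binary integer matrix at the raw size.
#' @export
mapMaskToRaw <- function(mask, transform, rawDim) {
  w <- transform$x1 - transform$x0 + 1L
  h <- transform$y1 - transform$y0 + 1L
  back <- .resizeRaster(mask, w, h, "none")
  out <- matrix(0L, rawDim[1L], rawDim[2L])
  out[transform$y0:transform$y1, transform$x0:transform$x1] <- as.integer(back > 0.5)
  out
}

#' Run the full two-step segmentation on one raw image
#'
#' Stage 1 locates the five bone ROIs; stage 2 segments each bone inside its
#' crop; predictions are mapped back to raw coordinates.
#'
#' @param image raw grayscale raster of one leg.
#' @param stage1Model trained multi-class [SegModel-class].
#' @param stage2Models named list of trained binary [SegModel-class], one per
#'   bone.
#' @param cfg a [stageConfig()].
#' @param margin ROI padding (see [locateRois()]).
#' @param strict passed to [locateRois()]; when `FALSE`, bones without a
#'   stage-1 ROI get an all-zero mask and are listed in `missing`.
#' @return List with `masks` (named list of binary rasters at raw size),
#'   `rois` and `missing` (character vector of bones without an ROI).
#' @export
segmentLimb <- function(image, stage1Model, stage2Models, cfg = stageConfig("full"),
                        margin = 0.1, strict = TRUE) {
  rois <- locateRois(image, stage1Model, cfg, margin, strict = strict)
  masks <- list()
  missing <- character(0)
  for (bone in .boneNames) {
    if (is.null(rois[[bone]])) {
      masks[[bone]] <- matrix(0L, nrow(image), ncol(image))
      missing <- c(missing, bone)
      next
    }
    crop <- cropAndResize(image, rois[[bone]], bone, cfg, isMask = FALSE)
    pred <- predictMask(stage2Models[[bone]], crop)
    masks[[bone]] <- mapMaskToRaw(pred, attr(crop, "transform"), dim(image))
  }
  list(masks = masks, rois = rois, missing = missing)
}
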