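## Rule-based landmark procedures. Each converts one (or two) per-bone masks
## into anatomic feature points; extractLandmarks() composes them into the
## eight-point LandmarkSet used for angle measurement.
##
## Medial/lateral assignment: in a standard AP radiograph the medial side of
## the right leg is at larger x, and of the left leg at smaller x.

.medialIsLargerX <- function(side) identical(side, "right")

#' Femoral head centre
#'
#' Fits a least-squares circle ([fitCircle()]) to the segmentation outline of
#' the femoral head and returns its centre.
#'
#' @param mask binary femoral-head mask (`m[y, x]`).
#' @return A [Point()].
#' @export
femoralHeadCenter <- function(mask) {
  tryCatch({
    out <- extractOutline(mask)
    fitCircle(out)$center
  }, limbAlignError = function(e) .landmarkFailure("femoral_head", conditionMessage(e), e))
}

#' Distal femur landmarks: condyle points and intercondylar notch
#'
#' The distal femur surface line is found by minimising the distance between
#' the bottom line of the outline's bounding box and the outline, one point
#' per lateral half of the lower arc (split at the centroid column), giving
#' the two condylar contact points. The intercondylar notch is the highest
#' point (minimum y) of the outline arc strictly between the two condyle
#' points and below the component centroid.
#'
#' @param mask binary distal-femur mask.
#' @param side patient side (resolves the medial/lateral labels).
#' @return List with points `intercondylar_notch`, `medial_condyle`,
#'   `lateral_condyle`.
#' @export
distalFemurLandmarks <- function(mask, side = "right") {
  tryCatch({
    out <- extractOutline(mask)
    ctr <- .maskCentroid(.largestComponent(mask))
    lower <- which(out[, 2L] > ctr["y"])
    iL <- lower[out[lower, 1L] < ctr["x"]]
    iR <- lower[out[lower, 1L] >= ctr["x"]]
    if (length(iL) == 0L || length(iR) == 0L)
      stop("lower arc does not span both sides of the centroid column")
    pick <- function(ii) ii[which.max(out[ii, 2L])]   # closest to box bottom
    cL <- pick(iL); cR <- pick(iR)
    ## notch: min-y point of the arc between the condyles that avoids the top
    top <- which.min(out[, 2L])
    arc <- .arcBetween(nrow(out), cL, cR, avoiding = top)
    arc <- arc[out[arc, 2L] > ctr["y"]]
    if (length(arc) == 0L) stop("no outline arc between the condyle points")
    notch <- arc[which.min(out[arc, 2L])]
    relief <- min(out[cL, 2L], out[cR, 2L]) - out[notch, 2L]
    if (relief < 2)
      stop("lower border is convex: no intercondylar notch between the condyle points")
    condyles <- list(Point(out[cL, 1L], out[cL, 2L]), Point(out[cR, 1L], out[cR, 2L]))
    medialFirst <- if (.medialIsLargerX(side)) order(c(out[cL, 1L], out[cR, 1L]),
                                                     decreasing = TRUE) else
                                               order(c(out[cL, 1L], out[cR, 1L]))
    list(intercondylar_notch = Point(out[notch, 1L], out[notch, 2L]),
         medial_condyle = condyles[[medialFirst[1L]]],
         lateral_condyle = condyles[[medialFirst[2L]]])
  }, error = function(e) {
    if (.isLandmarkFailure(e)) stop(e)
    .landmarkFailure("distal_femur", conditionMessage(e), e)
  })
}

#' Tibial spine centre
#'
#' Detects the two tibial-spine peaks on the outline ([findTwoPeaks()]), takes
#' their midpoint, constructs the line through the midpoint orthogonal to the
#' peak-to-peak segment, and returns the outline point on the arc between the
#' peaks closest to that orthogonal line.
#'
#' @param mask binary proximal-tibia mask.
#' @return A [Point()].
#' @export
tibialSpineCenter <- function(mask) {
  tryCatch({
    out <- extractOutline(mask)
    pk <- findTwoPeaks(out)
    mid <- (pk$left + pk$right) / 2
    d <- pk$right - pk$left
    orth <- Line(mid, mid + c(-d["y"], d["x"]))
    bottom <- which.max(out[, 2L])
    arc <- .arcBetween(nrow(out), pk$indices[1L], pk$indices[2L], avoiding = bottom)
    closestPointOnOutline(out, orth, region = arc)
  }, error = function(e) {
    if (.isLandmarkFailure(e)) stop(e)
    .landmarkFailure("proximal_tibia", conditionMessage(e), e)
  })
}

## Shared rule for articular surface corner points (proximal tibia and talus):
## candidate points are the convex-hull vertices of the outline lying above the
## component centroid; the surface line joins the candidates closest to the
## upper-left and upper-right corners of the outline's bounding box.
.surfaceCornerPoints <- function(mask) {
  out <- extractOutline(mask)
  ctr <- .maskCentroid(.largestComponent(mask))
  hull <- convexHullPoints(out)
  cand <- hull$indices[out[hull$indices, 2L] < ctr["y"]]
  if (length(cand) == 0L) stop("no convex-hull candidate points above the centroid")
  bb <- boundingBox(out)
  nearest <- function(corner) {
    d2 <- (out[cand, 1L] - corner[1L])^2 + (out[cand, 2L] - corner[2L])^2
    hit <- cand[d2 == min(d2)]
    min(hit)
  }
  iL <- nearest(c(bb["xmin"], bb["ymin"]))
  iR <- nearest(c(bb["xmax"], bb["ymin"]))
  if (iL == iR) stop("surface corner points are not distinct")
  list(left = Point(out[iL, 1L], out[iL, 2L]),
       right = Point(out[iR, 1L], out[iR, 2L]))
}

#' Tibial plateau surface points
#'
#' Convex-hull candidates above the centroid, nearest to the upper corners of
#' the outline's bounding box; one point per plateau.
#'
#' @param mask binary proximal-tibia mask.
#' @param side patient side (resolves the medial/lateral labels).
#' @return List with points `medial_plateau` and `lateral_plateau`.
#' @export
plateauSurfacePoints <- function(mask, side = "right") {
  tryCatch({
    sc <- .surfaceCornerPoints(mask)
    if (.medialIsLargerX(side))
      list(medial_plateau = sc$right, lateral_plateau = sc$left)
    else
      list(medial_plateau = sc$left, lateral_plateau = sc$right)
  }, error = function(e) {
    if (.isLandmarkFailure(e)) stop(e)
    .landmarkFailure("proximal_tibia_surface", conditionMessage(e), e)
  })
}

#' Ankle centre (mid-malleolar point)
#'
#' Two talus feature points are found with the same rule as the tibial plateau
#' surface (hull candidates above the centroid, nearest the upper bounding-box
#' corners). The line through their midpoint orthogonal to the segment joining
#' them is intersected with the distal-tibia outline: the outline point of the
#' lower arc (below the tibial centroid) closest to that line is the ankle
#' centre.
#'
#' @param distal_tibia_mask,talus_mask binary masks on the shared grid.
#' @return A [Point()].
#' @export
ankleCenter <- function(distal_tibia_mask, talus_mask) {
  tryCatch({
    tp <- .surfaceCornerPoints(talus_mask)
    mid <- (tp$left + tp$right) / 2
    d <- tp$right - tp$left
    orth <- Line(mid, mid + c(-d["y"], d["x"]))
    out <- extractOutline(distal_tibia_mask)
    ctr <- .maskCentroid(.largestComponent(distal_tibia_mask))
    region <- which(out[, 2L] > ctr["y"])
    closestPointOnOutline(out, orth, region = region)
  }, error = function(e) {
    if (.isLandmarkFailure(e)) stop(e)
    .landmarkFailure("ankle", conditionMessage(e), e)
  })
}

#' Extract the eight-point LandmarkSet from per-bone masks
#'
#' Composes [femoralHeadCenter()], [distalFemurLandmarks()],
#' [tibialSpineCenter()], [plateauSurfacePoints()] and [ankleCenter()] into a
#' [LandmarkSet-class]. Failures of individual regions are aggregated into a
#' single error naming every failed region.
#'
#' @param masks a [LimbMasks-class] object.
#' @return A [LandmarkSet-class].
#' @export
extractLandmarks <- function(masks) {
  stopifnot(is(masks, "LimbMasks"))
  side <- masks@side
  failures <- character(0)
  grab <- function(expr) {
    tryCatch(expr, limbAlign_landmark_failure = function(e) {
      failures <<- c(failures, e$region); NULL
    })
  }
  fhc <- grab(femoralHeadCenter(boneMask(masks, "femoral_head")))
  df <- grab(distalFemurLandmarks(boneMask(masks, "distal_femur"), side))
  spine <- grab(tibialSpineCenter(boneMask(masks, "proximal_tibia")))
  plateau <- grab(plateauSurfacePoints(boneMask(masks, "proximal_tibia"), side))
  ankle <- grab(ankleCenter(boneMask(masks, "distal_tibia"), boneMask(masks, "talus")))
  if (length(failures))
    .laStop("limbAlign_landmark_failure",
            sprintf("landmark extraction failed for: %s",
                    paste(unique(failures), collapse = ", ")),
            region = unique(failures))
  LandmarkSet(list(
    femoral_head_center = fhc,
    intercondylar_notch = df$intercondylar_notch,
    tibial_spine_center = spine,
    medial_condyle = df$medial_condyle,
    lateral_condyle = df$lateral_condyle,
    medial_plateau = plateau$medial_plateau,
    lateral_plateau = plateau$lateral_plateau,
    ankle_center = ankle
  ), side = side)
}

#' Split a both-legs radiograph at the vertical midline
#'
#' Plumbing for images showing both legs: the image is cut at the midline
#' column; in a standard AP radiograph the patient's right leg appears in the
#' left half. Each half is returned with the side it should be processed as.
#'
#' @param image grayscale raster (matrix `m[y, x]`).
#' @return List of two lists, `right` and `left`, each with elements `image`
#'   and `side`.
#' @export
splitLegImage <- function(image) {
  W <- ncol(image)
  mid <- W %/% 2L
  list(right = list(image = image[, seq_len(mid), drop = FALSE], side = "right"),
       left = list(image = image[, (mid + 1L):W, drop = FALSE], side = "left"))
}
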