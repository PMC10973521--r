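## External interfaces: masks as single-channel PNG (0 = background, 255 =
## foreground), five-bone label PNG (femoral_head = 1 ... talus = 5, stored
## as value k/255), landmarks and per-leg reports as JSON, batch export as
## CSV.

#' Read / write a binary mask PNG
#'
#' @param path file path.
#' @return `readMask`: binary integer matrix (`m[y, x]`).
#' @export
readMask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  matrix(as.integer(m > 0.5), nrow(m), ncol(m))
}

#' @rdname readMask
#' @param mask binary matrix.
#' @export
writeMask <- function(mask, path) {
  png::writePNG((mask > 0) * 1, path)
  invisible(path)
}

#' Read / write the five bone masks of one leg
#'
#' `writeLimbMasks` writes one PNG per bone (`<bone>.png`) into a directory;
#' `writeLimbLabelPNG`/`readLimbLabelPNG` use a single integer label image
#' with the label map femoral_head = 1, distal_femur = 2, proximal_tibia = 3,
#' distal_tibia = 4, talus = 5 (pixel value k/255).
#'
#' @param masks a [LimbMasks-class].
#' @param dir output directory (created if missing).
#' @return `readLimbMasks`: a [LimbMasks-class].
#' @export
writeLimbMasks <- function(masks, dir) {
  stopifnot(is(masks, "LimbMasks"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (bone in .boneNames) writeMask(boneMask(masks, bone), file.path(dir, paste0(bone, ".png")))
  invisible(dir)
}

#' @rdname writeLimbMasks
#' @param side patient side of the stored leg.
#' @param pixelSpacing optional mm/px.
#' @export
readLimbMasks <- function(dir, side = "right", pixelSpacing = NA_real_) {
  ms <- lapply(.boneNames, function(bone) readMask(file.path(dir, paste0(bone, ".png"))))
  names(ms) <- .boneNames
  do.call(LimbMasks, c(ms, list(side = side, pixelSpacing = pixelSpacing)))
}

#' @rdname writeLimbMasks
#' @param path label-PNG path.
#' @export
writeLimbLabelPNG <- function(masks, path) {
  stopifnot(is(masks, "LimbMasks"))
  lab <- .labelRaster(masks)
  png::writePNG(lab / 255, path)
  invisible(path)
}

#' @rdname writeLimbMasks
#' @export
readLimbLabelPNG <- function(path, side = "right", pixelSpacing = NA_real_) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  lab <- round(m * 255)
  ms <- lapply(seq_along(.boneNames), function(k) matrix(as.integer(lab == k), nrow(lab), ncol(lab)))
  names(ms) <- .boneNames
  do.call(LimbMasks, c(ms, list(side = side, pixelSpacing = pixelSpacing)))
}

#' Write landmarks or a per-leg alignment report as JSON
#'
#' Landmarks are stored as a `{name: [x, y]}` map in pixel coordinates
#' (x = column, y = row, origin at the top-left pixel centre).
#'
#' @param landmarks a [LandmarkSet-class].
#' @param path output path.
#' @export
writeLandmarksJSON <- function(landmarks, path) {
  stopifnot(is(landmarks, "LandmarkSet"))
  p <- landmarkPoints(landmarks)
  obj <- lapply(seq_len(nrow(p)), function(i) unname(p[i, ]))
  names(obj) <- rownames(p)
  jsonlite::write_json(c(list(side = landmarks@side), obj), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeLandmarksJSON
#' @param report output of [measureAlignment()].
#' @export
writeAlignmentJSON <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Batch alignment export
#'
#' @param reports list of [measureAlignment()] outputs.
#' @return data.frame with one row per leg (side, four angles,
#'   classification, flags), ready for [utils::write.csv()].
#' @export
alignmentBatch <- function(reports) {
  do.call(rbind, lapply(reports, function(r) {
    data.frame(side = r$side, mTFA = r$angles$mTFA, mLDFA = r$angles$mLDFA,
               MPTA = r$angles$MPTA, JLCA = r$angles$JLCA,
               classification = r$classification,
               quality_flags = paste(r$quality_flags, collapse = ";"))
  }))
}
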