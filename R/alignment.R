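## The four alignment angles, built from directed angles between the axis
## directions in a canonical frame in which the medial side is at +x (the
## right-leg frame; left-leg inputs are mirrored by negating x-components of
## the direction vectors). With A(u, v) the signed CCW angle from u to v,
## fm/tm the distal-pointing mechanical-axis directions and fa/ta the
## medial-to-lateral articular directions:
##
##   mTFA        = 180 + A(tm, fm)        (varus deviation positive)
##   mLDFA       = A(fa, -fm)             (lateral-side angle at the femur)
##   MPTA        = A(-ta, tm)             (medial-side angle at the tibia)
##   JLCA_signed = A(ta, fa)              (positive = lateral joint opening)
##
## which makes the composition identity
##   mTFA = mLDFA + JLCA_signed + (180 - MPTA)
## exact (to floating point), since the directed angles telescope.

#' Assemble the four axis lines from the eight feature points
#'
#' Femoral mechanical axis: femoral head centre to intercondylar notch.
#' Tibial mechanical axis: tibial spine centre to ankle centre. Femoral
#' articular line: medial to lateral condyle. Tibial articular line: medial to
#' lateral plateau.
#'
#' @param landmarks a [LandmarkSet-class].
#' @return An [AxisSet-class].
#' @export
buildAxes <- function(landmarks) {
  stopifnot(is(landmarks, "LandmarkSet"))
  p <- landmarks@points
  mkLine <- function(a, b, axis) {
    tryCatch(Line(p[a, ], p[b, ]),
             limbAlign_degenerate_line = function(e)
               .laStop("limbAlign_degenerate_axis",
                       sprintf("degenerate-axis(%s): endpoints coincide", axis),
                       axis = axis))
  }
  new("AxisSet",
      femoral_mech = mkLine("femoral_head_center", "intercondylar_notch", "femoral_mech"),
      tibial_mech = mkLine("tibial_spine_center", "ankle_center", "tibial_mech"),
      femoral_articular = mkLine("medial_condyle", "lateral_condyle", "femoral_articular"),
      tibial_articular = mkLine("medial_plateau", "lateral_plateau", "tibial_articular"),
      side = landmarks@side)
}

#' Compute the four coronal alignment angles
#'
#' Computes mLDFA (lateral-side angle between femoral mechanical axis and
#' condylar line), MPTA (medial-side angle between tibial mechanical axis and
#' plateau line), the signed JLCA (positive = lateral joint-line opening) and
#' the mTFA, all from directed angles so that the identity
#' `mTFA = mLDFA + JLCA_signed + (180 - MPTA)` holds exactly.
#'
#' Under the default `"varus_gt_180"` convention a varus knee reports
#' mTFA > 180; `"varus_lt_180"` reports the complementary value `360 - mTFA`
#' (the hip-knee-ankle reading on which varus is < 180).
#'
#' @param axes an [AxisSet-class].
#' @param mTFAConvention `"varus_gt_180"` (default) or `"varus_lt_180"`.
#' @return An [AlignmentAngles-class]. Sanity-bound violations (mTFA outside
#'   150-210, mLDFA/MPTA outside 60-120, JLCA above 30) are recorded in
#'   `qualityFlags`, not raised as errors.
#' @export
computeAngles <- function(axes, mTFAConvention = c("varus_gt_180", "varus_lt_180")) {
  stopifnot(is(axes, "AxisSet"))
  mTFAConvention <- match.arg(mTFAConvention)
  flip <- if (identical(axes@side, "left")) c(-1, 1) else c(1, 1)
  dirOf <- function(line) .lineDir(line) * flip
  fm <- dirOf(axes@femoral_mech)       # distal: head -> notch
  tm <- dirOf(axes@tibial_mech)        # distal: spines -> ankle
  fa <- dirOf(axes@femoral_articular)  # medial -> lateral
  ta <- dirOf(axes@tibial_articular)   # medial -> lateral
  mLDFA <- .dirAngle(fa, -fm)
  MPTA <- .dirAngle(-ta, tm)
  jlcaS <- .dirAngle(ta, fa)
  mTFA <- 180 + .dirAngle(tm, fm)
  flags <- character(0)
  if (mTFA < 150 || mTFA > 210) flags <- c(flags, "mTFA_outside_sanity_bounds")
  if (mLDFA < 60 || mLDFA > 120) flags <- c(flags, "mLDFA_outside_sanity_bounds")
  if (MPTA < 60 || MPTA > 120) flags <- c(flags, "MPTA_outside_sanity_bounds")
  if (abs(jlcaS) > 30) flags <- c(flags, "JLCA_outside_sanity_bounds")
  reported <- if (mTFAConvention == "varus_gt_180") mTFA else 360 - mTFA
  new("AlignmentAngles", mTFA = unname(reported), mLDFA = unname(mLDFA),
      MPTA = unname(MPTA), JLCA_signed = unname(jlcaS), JLCA = abs(unname(jlcaS)),
      convention = mTFAConvention, qualityFlags = flags)
}

#' Classify coronal alignment as varus / neutral / valgus
#'
#' Varus if the varus deviation of the mTFA from 180 degrees exceeds the
#' threshold, valgus if the valgus deviation exceeds it, neutral otherwise.
#' The conventional 3-degree threshold corresponds to the hip-knee-ankle
#' varus cut-off of 177 degrees.
#'
#' @param angles an [AlignmentAngles-class].
#' @param varusThreshold deviation threshold in degrees (> 0).
#' @return `"varus"`, `"neutral"` or `"valgus"`.
#' @export
classifyAlignment <- function(angles, varusThreshold = 3) {
  stopifnot(is(angles, "AlignmentAngles"))
  if (!is.numeric(varusThreshold) || length(varusThreshold) != 1L || varusThreshold <= 0)
    .laStop("limbAlign_config_error", "varusThreshold must be a positive scalar")
  dev <- if (angles@convention == "varus_gt_180") angles@mTFA - 180 else 180 - angles@mTFA
  if (dev > varusThreshold) "varus"
  else if (dev < -varusThreshold) "valgus"
  else "neutral"
}

#' Per-leg alignment report
#'
#' Bundles the measurement of one leg (landmarks, angles, classification,
#' quality flags) into a plain list ready for JSON export with
#' [writeAlignmentJSON()].
#'
#' @param masks a [LimbMasks-class].
#' @param mTFAConvention passed to [computeAngles()].
#' @param varusThreshold passed to [classifyAlignment()].
#' @return List with `side`, `landmarks`, `angles`, `classification`,
#'   `quality_flags`.
#' @export
measureAlignment <- function(masks, mTFAConvention = "varus_gt_180", varusThreshold = 3) {
  lm <- extractLandmarks(masks)
  ang <- computeAngles(buildAxes(lm), mTFAConvention)
  av <- angleValues(ang)
  list(side = masks@side,
       landmarks = lapply(seq_len(nrow(lm@points)), function(i) unname(lm@points[i, ])) |>
         stats::setNames(rownames(lm@points)),
       angles = as.list(av[c("mTFA", "mLDFA", "MPTA", "JLCA")]),
       JLCA_signed = unname(av["JLCA_signed"]),
       classification = classifyAlignment(ang, varusThreshold),
       quality_flags = ang@qualityFlags)
}
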