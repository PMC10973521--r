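## Synthetic limb-phantom generator. Bones are stylised 2D silhouettes built
## from disks and convex polygons around analytically placed ground-truth
## landmarks, so the truth is exact by construction:
##
##   * tibial mechanical axis vertical (spine centre above ankle centre);
##   * plateau line rotated to the MPTA target about the plateau centre;
##   * condylar line rotated from the plateau line by the signed JLCA;
##   * femoral mechanical axis rotated to the mLDFA target about the notch.
##
## All construction happens in the canonical right-leg frame (medial = +x);
## left-side phantoms are produced by mirroring masks and landmarks about the
## vertical canvas midline. The silhouettes carry exactly the topological
## features the landmark rules assume: two condylar lobes with an
## intercondylar notch, two tibial spines flanking an inter-spine valley, a
## tilted plateau block with sharp surface corners, a plafond with a small
## mid-malleolar concavity, and a talar dome with flat upper corners.

## ---- rasterisation helpers ------------------------------------------------

.rasterDisk <- function(canvas, cx, cy, r) {
  H <- nrow(canvas); W <- ncol(canvas)
  ys <- max(1L, floor(cy - r)):min(H, ceiling(cy + r))
  xs <- max(1L, floor(cx - r)):min(W, ceiling(cx + r))
  if (length(ys) == 0L || length(xs) == 0L) return(canvas)
  dy2 <- (ys - cy)^2
  dx2 <- (xs - cx)^2
  canvas[ys, xs] <- canvas[ys, xs] | (outer(dy2, dx2, "+") <= r^2)
  canvas
}

## Fill (or erase) a convex polygon given as an m x 2 vertex matrix.
.rasterConvexPoly <- function(canvas, verts, erase = FALSE) {
  H <- nrow(canvas); W <- ncol(canvas)
  ys <- max(1L, floor(min(verts[, 2L]))):min(H, ceiling(max(verts[, 2L])))
  xs <- max(1L, floor(min(verts[, 1L]))):min(W, ceiling(max(verts[, 1L])))
  if (length(ys) == 0L || length(xs) == 0L) return(canvas)
  m <- nrow(verts)
  ## orient clockwise in image coordinates so all edge cross-products share sign
  area2 <- sum(verts[, 1L] * verts[c(2:m, 1L), 2L] - verts[c(2:m, 1L), 1L] * verts[, 2L])
  if (area2 < 0) verts <- verts[m:1, , drop = FALSE]
  X <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  Y <- matrix(ys, length(ys), length(xs))
  inside <- TRUE
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    ex <- verts[j, 1L] - verts[i, 1L]; ey <- verts[j, 2L] - verts[i, 2L]
    inside <- inside & (ex * (Y - verts[i, 2L]) - ey * (X - verts[i, 1L]) >= 0)
  }
  if (erase) canvas[ys, xs] <- canvas[ys, xs] & !inside
  else canvas[ys, xs] <- canvas[ys, xs] | inside
  canvas
}

.rot90cw <- function(v) c(-v[2L], v[1L])   # +90 deg CCW in image coords

.unit <- function(deg) c(cos(deg * pi / 180), sin(deg * pi / 180))

## ---- spec constructor -----------------------------------------------------

#' Construct a phantom specification
#'
#' Defaults emulate a standing AP long-leg field of view at roughly 0.25
#' mm/px: a 560 x 1600 canvas with a 700 px femoral and 660 px tibial
#' mechanical axis. The default angle targets are the physiologic values
#' mLDFA 85.8 and MPTA 85.6 degrees with a closed joint line (JLCA 0).
#'
#' @param imageWidth,imageHeight canvas size (px).
#' @param side `"left"` or `"right"`.
#' @param femurLength,tibiaLength mechanical-axis lengths (px).
#' @param femoralHeadRadius radius of the femoral head disk (px).
#' @param condyleRadius radius of each condylar lobe (px).
#' @param condyleSeparation distance between the condylar contact points (px).
#' @param spineHeight tibial spine height above the inter-spine valley (px).
#' @param spineSeparation distance between the spine tips (px).
#' @param mLDFA,MPTA,JLCA_signed angle targets (degrees; JLCA positive =
#'   lateral joint-line opening).
#' @param boundaryJitterP Bernoulli boundary-noise probability applied to the
#'   masks (0 = pristine ground truth).
#' @param intensitySigma Gaussian image-noise SD in 8-bit gray levels.
#' @param seed RNG seed of the case.
#' @return A [PhantomSpec-class].
#' @export
phantomSpec <- function(imageWidth = 560, imageHeight = 1600, side = "right",
                        femurLength = 700, tibiaLength = 660,
                        femoralHeadRadius = 70, condyleRadius = 32,
                        condyleSeparation = 160, spineHeight = 24,
                        spineSeparation = 40, mLDFA = 85.8, MPTA = 85.6,
                        JLCA_signed = 0, boundaryJitterP = 0,
                        intensitySigma = 4, seed = 1) {
  new("PhantomSpec", imageWidth = imageWidth, imageHeight = imageHeight,
      side = side, femurLength = femurLength, tibiaLength = tibiaLength,
      femoralHeadRadius = femoralHeadRadius, condyleRadius = condyleRadius,
      condyleSeparation = condyleSeparation, spineHeight = spineHeight,
      spineSeparation = spineSeparation, mLDFA = mLDFA, MPTA = MPTA,
      JLCA_signed = JLCA_signed, boundaryJitterP = boundaryJitterP,
      intensitySigma = intensitySigma, seed = seed)
}

## Internal shape constants, proportional to the named spec fields.
.phantomShape <- function(spec) {
  cs <- spec@condyleSeparation / 2
  list(
    ankleMargin = round(0.056 * spec@imageHeight),       # 90 at default height
    jointGap = 26, notchDepth = 40, plateauDrop = 12,
    plateauHalfWidth = cs + 8,
    plateauThickness = 44,
    ## inner V of the metaphysis: the shoulder plane sits 16 px above the
    ## condylar line so that at the maximal joint-line tilt (~12 deg) the
    ## condylar lobes remain the most distal structures of each half
    notchHalfWidth = 40, notchShoulder = 16,
    metaphHalfWidth = cs + 12, metaphTop = 80,
    femShaftHalfWidth = 26, femShaftLength = 240,
    tibShaftHalfWidth = 30, tibShaftLength = 200,
    plafondHalfWidth = 46, plafondTop = 18, plafondBottom = 8,
    ankleNotchHalfWidth = 10, ankleNotchDepth = 10,
    talusGap = 16, talusTopHalfWidth = 50, talusBottomHalfWidth = 34,
    talusHeight = 44,
    dtShaftHalfWidth = 22, dtShaftLength = 150
  )
}

## ---- generator ------------------------------------------------------------

#' Generate one synthetic limb phantom
#'
#' Builds the ground-truth landmark set analytically from the angle targets,
#' rasterises the five stylised bone masks around it, renders a grayscale
#' pseudo-radiograph (bone 200, soft-tissue halo 120, background 30, vertical
#' illumination gradient, Gaussian noise), and returns everything as a
#' [PhantomCase-class]. Deterministic given `spec@seed`.
#'
#' @param spec a [PhantomSpec-class].
#' @return A [PhantomCase-class].
#' @export
generatePhantom <- function(spec) {
  validObject(spec)
  sh <- .phantomShape(spec)
  W <- spec@imageWidth; H <- spec@imageHeight
  cx <- (W + 1) / 2
  yA <- H - sh$ankleMargin
  yK <- yA - spec@tibiaLength
  cs <- spec@condyleSeparation / 2
  rc <- spec@condyleRadius

  ## --- analytic truth (canonical right-leg frame, medial = +x) ---
  phiTaMed <- 90 - spec@MPTA                    # direction angle of the medial plateau ray
  phiFaMed <- phiTaMed + spec@JLCA_signed       # medial condylar ray
  phiFm <- 90 + (spec@mLDFA - spec@MPTA + spec@JLCA_signed)  # distal femoral mech axis
  taMed <- .unit(phiTaMed); faMed <- .unit(phiFaMed); fm <- .unit(phiFm)
  nUp <- -.rot90cw(faMed)                       # perpendicular to condylar line, image-up

  S <- c(cx, yK)                                # tibial spine centre
  A <- c(cx, yA)                                # ankle centre
  P0 <- c(cx, yK + sh$plateauDrop)              # plateau line centre
  Ct0 <- c(cx, yK - sh$jointGap)                # condylar line centre
  N <- Ct0 + sh$notchDepth * nUp                # intercondylar notch
  Hd <- N - spec@femurLength * fm               # femoral head centre
  medPlateau <- P0 + sh$plateauHalfWidth * taMed
  latPlateau <- P0 - sh$plateauHalfWidth * taMed
  medCondyle <- Ct0 + cs * faMed
  latCondyle <- Ct0 - cs * faMed

  ## canvas containment
  allPts <- rbind(Hd + c(-1, -1) * spec@femoralHeadRadius,
                  Hd + c(1, 1) * spec@femoralHeadRadius,
                  medPlateau, latPlateau, medCondyle, latCondyle,
                  c(cx + sh$talusTopHalfWidth, yA + sh$talusGap + sh$talusHeight),
                  c(cx - sh$talusTopHalfWidth, yA + sh$talusGap))
  if (min(allPts[, 1L]) < 2 || max(allPts[, 1L]) > W - 1 ||
      min(allPts[, 2L]) < 2 || max(allPts[, 2L]) > H - 1)
    .laStop("limbAlign_canvas_overflow", "limb geometry exceeds the canvas")

  blank <- matrix(FALSE, H, W)
  localPt <- function(s, t) Ct0 + s * faMed + t * nUp   # condylar-line frame

  ## --- femoral head: disk ---
  mFH <- .rasterDisk(blank, Hd[1L], Hd[2L], spec@femoralHeadRadius)

  ## --- distal femur: shaft + metaphysis with notch V + condylar lobes ---
  mDF <- blank
  quadLocal <- function(s1, t1, s2, t2, s3, t3, s4, t4)
    rbind(localPt(s1, t1), localPt(s2, t2), localPt(s3, t3), localPt(s4, t4))
  nw <- sh$notchHalfWidth; ns <- sh$notchShoulder; mt <- sh$metaphTop
  mw <- sh$metaphHalfWidth; nd <- sh$notchDepth
  ## notch V with a piecewise profile: steep (45 deg) near the apex so the
  ## rasterised apex pixel localises the notch to ~1 px even under maximal
  ## joint-line tilt, shallower toward the shoulders
  kink <- nd - 12   # t-level where the steep inner segment meets the outer one
  mDF <- .rasterConvexPoly(mDF, quadLocal(-12, mt, 0, mt, 0, nd, -12, kink))
  mDF <- .rasterConvexPoly(mDF, quadLocal(0, mt, 12, mt, 12, kink, 0, nd))
  mDF <- .rasterConvexPoly(mDF, quadLocal(-nw, mt, -12, mt, -12, kink, -nw, ns))
  mDF <- .rasterConvexPoly(mDF, quadLocal(12, mt, nw, mt, nw, ns, 12, kink))
  ## outer metaphysis wings (their outer ends hide inside the condylar lobes)
  mDF <- .rasterConvexPoly(mDF, quadLocal(-mw, mt, -nw + 2, mt, -nw + 2, ns, -mw, ns))
  mDF <- .rasterConvexPoly(mDF, quadLocal(nw - 2, mt, mw, mt, mw, ns, nw - 2, ns))
  ## condylar lobes: disks with a slightly pointed distal tip, so the most
  ## distal (image-lowest) pixel of each lobe is exactly the truth condyle
  ## point (a flat rasterised disk bottom would leave the lowest row ambiguous
  ## over several pixels)
  for (cpt in list(medCondyle, latCondyle)) {
    mDF <- .rasterDisk(mDF, cpt[1L], cpt[2L] - rc - 4, rc)
    mDF <- .rasterConvexPoly(mDF, rbind(cpt, cpt + c(-6, -8), cpt + c(6, -8)))
  }
  ## shaft along the femoral mechanical axis
  fmPerp <- .rot90cw(fm)
  s1 <- Ct0 + (mt - 10) * nUp
  s2 <- s1 - sh$femShaftLength * fm
  shaftQuad <- rbind(s1 + sh$femShaftHalfWidth * fmPerp, s1 - sh$femShaftHalfWidth * fmPerp,
                     s2 - sh$femShaftHalfWidth * fmPerp, s2 + sh$femShaftHalfWidth * fmPerp)
  mDF <- .rasterConvexPoly(mDF, shaftQuad)

  ## --- proximal tibia: plateau block + spines + shaft ---
  mPT <- blank
  ext <- c(0, sh$plateauThickness)
  mPT <- .rasterConvexPoly(mPT, rbind(medPlateau, latPlateau, latPlateau + ext, medPlateau + ext))
  ss <- spec@spineSeparation / 2
  tipL <- c(cx - ss, yK - spec@spineHeight); tipR <- c(cx + ss, yK - spec@spineHeight)
  mPT <- .rasterConvexPoly(mPT, rbind(tipL, S, c(cx - ss - 10, yK + sh$plateauDrop + 6)))
  mPT <- .rasterConvexPoly(mPT, rbind(tipR, S, c(cx + ss + 10, yK + sh$plateauDrop + 6)))
  mPT <- .rasterConvexPoly(mPT, rbind(
    c(cx - sh$tibShaftHalfWidth, yK + sh$plateauDrop + 10),
    c(cx + sh$tibShaftHalfWidth, yK + sh$plateauDrop + 10),
    c(cx + sh$tibShaftHalfWidth - 6, yK + sh$plateauDrop + sh$tibShaftLength),
    c(cx - sh$tibShaftHalfWidth + 6, yK + sh$plateauDrop + sh$tibShaftLength)))

  ## --- distal tibia: shaft + plafond with mid-malleolar concavity ---
  mDT <- blank
  mDT <- .rasterConvexPoly(mDT, rbind(
    c(cx - sh$plafondHalfWidth, yA - sh$plafondTop),
    c(cx + sh$plafondHalfWidth, yA - sh$plafondTop),
    c(cx + sh$plafondHalfWidth, yA + sh$plafondBottom),
    c(cx - sh$plafondHalfWidth, yA + sh$plafondBottom)))
  mDT <- .rasterConvexPoly(mDT, rbind(
    c(cx - sh$dtShaftHalfWidth, yA - sh$dtShaftLength),
    c(cx + sh$dtShaftHalfWidth, yA - sh$dtShaftLength),
    c(cx + sh$dtShaftHalfWidth, yA - sh$plafondTop + 4),
    c(cx - sh$dtShaftHalfWidth, yA - sh$plafondTop + 4)))
  ## carve the concavity whose apex is the ankle centre
  mDT <- .rasterConvexPoly(mDT, rbind(
    A, c(cx - sh$ankleNotchHalfWidth, yA + sh$ankleNotchDepth),
    c(cx + sh$ankleNotchHalfWidth, yA + sh$ankleNotchDepth)), erase = TRUE)

  ## --- talus: trapezoidal dome with flat upper corners ---
  yT <- yA + sh$talusGap
  mTA <- .rasterConvexPoly(blank, rbind(
    c(cx - sh$talusTopHalfWidth, yT), c(cx + sh$talusTopHalfWidth, yT),
    c(cx + sh$talusBottomHalfWidth, yT + sh$talusHeight),
    c(cx - sh$talusBottomHalfWidth, yT + sh$talusHeight)))

  masks <- list(femoral_head = mFH, distal_femur = mDF, proximal_tibia = mPT,
                distal_tibia = mDT, talus = mTA)
  truth <- rbind(femoral_head_center = Hd, intercondylar_notch = N,
                 tibial_spine_center = S, medial_condyle = medCondyle,
                 lateral_condyle = latCondyle, medial_plateau = medPlateau,
                 lateral_plateau = latPlateau, ankle_center = A)

  if (identical(spec@side, "left")) {   # mirror about the vertical midline
    masks <- lapply(masks, function(m) m[, W:1, drop = FALSE])
    truth[, 1L] <- W + 1 - truth[, 1L]
  }

  ## --- image rendering + optional boundary noise (seeded) ---
  oldSeed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, envir = globalenv()))
  set.seed(spec@seed)

  bone <- Reduce(`|`, masks)
  halo <- t(EBImage::imageData(EBImage::dilate(
    EBImage::Image(t(bone * 1)), EBImage::makeBrush(25, shape = "disc")))) > 0
  img <- matrix(30, H, W)
  img[halo] <- 120
  img[bone] <- 200
  img <- img + matrix(seq(-15, 15, length.out = H), H, W)   # illumination gradient
  if (spec@intensitySigma > 0) img <- img + matrix(stats::rnorm(H * W, 0, spec@intensitySigma), H, W)
  img <- pmin(pmax(round(img), 0), 255)

  lm <- LandmarkSet(truth, side = spec@side)
  limb <- do.call(LimbMasks, c(masks, list(side = spec@side)))
  if (spec@boundaryJitterP > 0)
    limb <- corruptMasks(limb, spec@boundaryJitterP, seed = spec@seed + 1)
  ang <- computeAngles(buildAxes(lm))
  new("PhantomCase", image = img, masks = limb, truthLandmarks = lm,
      truthAngles = ang, spec = spec)
}

## ---- population sampling --------------------------------------------------

#' Sample a population of phantoms with Gaussian angle marginals
#'
#' Draws i.i.d. (mLDFA, MPTA, signed JLCA) triples from independent Gaussian
#' marginals truncated to the sanity bounds, and instantiates one phantom per
#' draw. The default marginals are the automated-measurement population
#' statistics of the internal test cohort the method was evaluated on
#' (mLDFA 87.73 +/- 1.86, MPTA 86.99 +/- 3.29, JLCA 1.67 +/- 1.41 degrees).
#'
#' @param n number of cases.
#' @param means,sds named numeric vectors over `mLDFA`, `MPTA`, `JLCA_signed`.
#' @param seed RNG seed (case seeds are derived from it).
#' @param baseSpec template [PhantomSpec-class]; angle targets and seed are
#'   overwritten per case.
#' @param generate if `FALSE`, return the per-case [PhantomSpec-class]s
#'   instead of generated cases (useful for streaming large populations).
#' @return List of [PhantomCase-class] (or of [PhantomSpec-class]).
#' @export
samplePopulation <- function(n,
                             means = c(mLDFA = 87.73, MPTA = 86.99, JLCA_signed = 1.67),
                             sds = c(mLDFA = 1.86, MPTA = 3.29, JLCA_signed = 1.41),
                             seed = 1, baseSpec = phantomSpec(),
                             generate = TRUE) {
  if (!is.numeric(n) || n < 1) .laStop("limbAlign_config_error", "n must be >= 1")
  nms <- c("mLDFA", "MPTA", "JLCA_signed")
  means <- means[nms]; sds <- sds[nms]
  if (any(is.na(means)) || any(is.na(sds)) || any(sds < 0))
    .laStop("limbAlign_config_error", "means/sds must be named over mLDFA, MPTA, JLCA_signed with sds >= 0")
  oldSeed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, envir = globalenv()))
  set.seed(seed)
  rtrunc <- function(m, s, lo, hi) {
    x <- stats::rnorm(n, m, s)
    bad <- which(x < lo | x > hi)
    while (length(bad)) {
      x[bad] <- stats::rnorm(length(bad), m, s)
      bad <- bad[x[bad] < lo | x[bad] > hi]
    }
    x
  }
  draws <- cbind(mLDFA = rtrunc(means["mLDFA"], sds["mLDFA"], 60, 120),
                 MPTA = rtrunc(means["MPTA"], sds["MPTA"], 60, 120),
                 JLCA_signed = rtrunc(means["JLCA_signed"], sds["JLCA_signed"], -29.9, 29.9))
  caseSeeds <- sample.int(.Machine$integer.max - 1L, n)
  specs <- lapply(seq_len(n), function(i) {
    s <- baseSpec
    s@mLDFA <- draws[i, "mLDFA"]; s@MPTA <- draws[i, "MPTA"]
    s@JLCA_signed <- draws[i, "JLCA_signed"]; s@seed <- caseSeeds[i]
    validObject(s)
    s
  })
  if (!generate) return(specs)
  lapply(specs, generatePhantom)
}

## ---- boundary corruption --------------------------------------------------

#' Apply Bernoulli boundary jitter to limb masks
#'
#' Each boundary pixel (foreground pixels 4-adjacent to background are eroded;
#' background pixels 4-adjacent to foreground are dilated) flips with
#' probability `p`. Connectivity of each bone is re-checked; on violation the
#' corruption is resampled, up to 10 attempts.
#'
#' @param masks a [LimbMasks-class].
#' @param p flip probability in `[0, 0.5)`.
#' @param seed RNG seed.
#' @return A corrupted [LimbMasks-class].
#' @export
corruptMasks <- function(masks, p, seed = 1) {
  stopifnot(is(masks, "LimbMasks"))
  if (!is.numeric(p) || p < 0 || p >= 0.5)
    .laStop("limbAlign_config_error", "p must be in [0, 0.5)")
  if (p == 0) return(masks)
  oldSeed <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, envir = globalenv()))
  set.seed(seed)
  corruptOne <- function(m) {
    m <- m > 0
    H <- nrow(m); W <- ncol(m)
    pad <- matrix(FALSE, H + 2L, W + 2L); pad[2:(H + 1), 2:(W + 1)] <- m
    n4 <- pad[1:H, 2:(W + 1)] + pad[3:(H + 2), 2:(W + 1)] +
          pad[2:(H + 1), 1:W] + pad[2:(H + 1), 3:(W + 2)]
    for (try in 1:10) {
      cand <- (m & n4 < 4L) | (!m & n4 > 0L)
      flip <- cand & matrix(stats::runif(H * W) < p, H, W)
      out <- xor(m, flip)
      if (any(out)) {
        lab <- .label8(out)
        if (max(lab) == 1L) return(out * 1)
      }
    }
    .laStop("limbAlign_corruption_failure",
            "could not corrupt mask without breaking connectivity")
  }
  masks@masks <- lapply(masks@masks, corruptOne)
  validObject(masks)
  masks
}
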