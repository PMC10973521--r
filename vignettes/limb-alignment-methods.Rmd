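---
title: "Measuring lower-limb alignment from bone segmentations: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring lower-limb alignment from bone segmentations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(LimbAlign)
```

## The measurement problem

Coronal alignment of the lower limb is summarised by four angles measured on a
standing AP long-leg radiograph:

* **mTFA** — the mechanical tibiofemoral angle between the femoral and tibial
  mechanical axes (neutral ≈ 180°);
* **mLDFA** — the lateral angle between the femoral mechanical axis and the
  distal femoral articular (condylar) line (physiologic ≈ 85.8°);
* **MPTA** — the medial angle between the tibial mechanical axis and the
  proximal tibial articular (plateau) line (physiologic ≈ 85.6°);
* **JLCA** — the joint line convergence angle between the two articular lines
  (normally 0–3°).

All four derive from eight anatomic feature points: the femoral head centre,
the intercondylar notch, the centre of the tibial spines, the two most distal
femoral condyle points, the two most proximal tibial plateau points, and the
mid-malleolar (ankle) centre. `LimbAlign` extracts these points from per-bone
binary segmentation masks with deterministic geometric rules, assembles the
four axis lines, and computes the angles.

## Rule-based landmark extraction

Each rule works on the traced outline of the largest connected component of a
mask (Moore neighbour tracing, 8-connected foreground, clockwise in image
coordinates, interior holes ignored):

* **Femoral head**: least-squares circle fit to the outline (algebraic Kåsa
  formulation — closed-form, deterministic, and exact on noiseless circles).
* **Distal femur**: per lateral half of the lower outline arc (split at the
  centroid column), the point closest to the bottom line of the bounding box
  gives one condylar contact point; the intercondylar notch is the highest
  point of the arc strictly between the two condyle points and below the
  centroid. Requiring at least 2 px of relief between the notch and the
  condyles rejects convex (notch-free) lower borders.
* **Proximal tibia**: the two most prominent upward outline peaks are the
  tibial spines (a peak is a local y-minimum with prominence at least 5% of
  the outline's bounding-box height — robust to pixel jitter); the landmark is
  the outline point, on the arc between the peaks, closest to the line through
  their midpoint orthogonal to the peak-to-peak segment.
* **Plateau surface**: convex-hull vertices above the centroid are candidates;
  the two candidates nearest the upper corners of the bounding box define the
  plateau line.
* **Ankle**: the talus is processed with the same upper-corner rule; the ankle
  centre is the distal-tibia outline point (below the tibial centroid) closest
  to the line through the talus points' midpoint orthogonal to their segment.

Ties are always broken by the smallest outline index, then the smallest x, so
the procedure is fully deterministic. Medial/lateral labels come from the
`side` flag: in a standard AP image, medial is larger x for the right leg and
smaller x for the left. Restricting the notch, spine-centre and ankle searches
to the arc between their reference points prevents the rules from latching
onto the shaft; the unrestricted variants are not exposed.

## Angle conventions

All angles are computed from directed angles between axis directions in a
canonical frame with medial at +x (left-leg inputs are mirrored). With
$A(u,v)$ the signed CCW angle from $u$ to $v$ (y down), $f_m, t_m$ the
distal-pointing mechanical-axis directions and $f_a, t_a$ the
medial-to-lateral articular directions:

$$\mathrm{mLDFA} = A(f_a, -f_m),\quad
  \mathrm{MPTA} = A(-t_a, t_m),\quad
  \mathrm{JLCA}_s = A(t_a, f_a),\quad
  \mathrm{mTFA} = 180^\circ + A(t_m, f_m).$$

Because directed angles telescope, the identity
$\mathrm{mTFA} = \mathrm{mLDFA} + \mathrm{JLCA}_s + (180^\circ - \mathrm{MPTA})$
holds to floating-point precision; it is verified on random configurations to
1e-9°. Angles depend only on directions, so they are exactly invariant to
translation, rotation and uniform scaling of the landmarks — pixel spacing is
never needed.

Published cohorts report mean mTFA near 181.8° in varus-leaning populations,
while the common hip–knee–ankle convention calls a knee varus below 177°;
the two conventions are complementary (they sum to 360°). The package
defaults to `varus_gt_180` (varus deviation positive above 180°) and exposes
`varus_lt_180` as a configuration switch; `classifyAlignment()` applies the
conventional 3° deviation threshold under either convention. The JLCA is
reported as a magnitude, matching how cohorts publish it, with the signed
value retained for the identity above.

## The synthetic phantom

Because clinical radiographs cannot be redistributed, the package generates
stylised long-leg phantoms whose ground truth is exact by construction. The
generator places the truth landmarks analytically — tibial mechanical axis
vertical, plateau line rotated to the MPTA target, condylar line rotated from
it by the signed JLCA, femoral mechanical axis rotated to the mLDFA target
about the notch — and rasterises simple silhouettes around them: a disk for
the femoral head; shaft, metaphysis with a V-shaped notch, and two condylar
lobes for the distal femur; a tilted plateau block with two triangular spines
for the proximal tibia; a plafond with a small mid-malleolar concavity; and a
trapezoidal talar dome. Bone renders at gray level 200 over a soft-tissue
halo (120) and background (30), with a vertical illumination gradient and
Gaussian noise (σ = 4 by default, 8-bit).

Two rasterisation details matter for accuracy and are deliberate:

* each condylar lobe carries a slightly pointed distal tip ending exactly at
  the truth condyle point, because a rasterised disk has a flat bottom row
  that would leave the "most distal pixel" ambiguous over several pixels;
* the notch V is piecewise — 45° near the apex, shallower toward the
  shoulders — so that the apex pixel localises the notch to ~1 px even when
  the joint line is tilted by its maximal ~12°.

The default canvas is 560 × 1600 px (≈ 0.25 mm/px field of view; femoral
mechanical axis 700 px, tibial 660 px, condylar separation 160 px). These
sizes were chosen once from an error budget: a 1-px quantisation error across
a 160-px articular baseline is ≈ 0.36°, which keeps every recovered angle
comfortably inside a 1° round-trip tolerance. On a 63-case deformity sweep
(mLDFA = MPTA ∈ 84–92°, JLCA 0–6°) the landmark RMS error is below 1 px and
the worst angle error ≈ 0.3–0.8°.

`samplePopulation()` draws (mLDFA, MPTA, signed JLCA) from independent
Gaussians truncated to sanity bounds; the defaults are the automated-arm
population statistics of the internal-cohort evaluation this design follows
(87.73 ± 1.86, 86.99 ± 3.29, 1.67 ± 1.41 degrees). `corruptMasks()` adds
Bernoulli erosion/dilation noise on boundary pixels, preserving per-bone
connectivity, for robustness testing.

What the phantom deliberately does **not** emulate: X-ray physics (scatter,
beam hardening), anatomical shape variation beyond the angle targets,
osteophytes, implants, overlapping bones, and rotated or flexed limbs. A
passing phantom suite therefore demonstrates the correctness and stability of
the geometry and learning machinery, not clinical-grade performance on
radiographs.

## Two-step segmentation at two scales

The segmentation pipeline mirrors the published two-step design: step 1
resizes the whole image to a fixed working size (311 × 932 at full scale) and
locates one region of interest per bone from a multi-class prediction
(bounding box of the largest predicted component, mapped back through the
resize transform, padded by 10%); step 2 segments each bone inside its crop
at a per-bone size (femoral head 470 × 470, distal femur 740 × 540, proximal
tibia 720 × 470, distal tibia 470 × 430, talus 370 × 220). Images are resized
bilinearly, masks nearest-neighbour; every crop records its affine transform
so predictions map back to raw coordinates. Predicted masks keep the largest
connected component and have interior holes filled — unglamorous but
necessary for stable outlines.

The model is an encoder–decoder with max-pooling-index unpooling. At
`scale = "full"` the encoder mirrors the first 13 convolutional layers of
VGG16 (13 more in the decoder); at `scale = "desk"` the same topology is
reduced to 4 single-convolution blocks of 8/16/24/32 channels so that it
trains on one CPU core, with working sizes scaled down proportionally
(stage 1 48 × 128; crops 48 × 48 to 64 × 80, all divisible by the pooling
factor 16). Every convolution except the logits layer is followed by
per-channel feature normalisation and ReLU; the normalisation (the
batch-normalisation role in this family of architectures) is computed over
the pixels of the image being processed, which makes training and inference
deterministic and identical. Grayscale inputs are replicated to the expected
channel count where needed (the full-scale encoder expects three channels).

Training is plain SGD with momentum 0.9, learning rate 1e-2 and mini-batches
of 4 on the per-pixel cross-entropy, with per-epoch training/validation loss
recorded and the best-validation parameters kept. Two desk-scale choices
deserve justification:

* **Class weighting for stage 1 only.** The whole-limb image is ~90%
  background and the talus is ~0.5% of pixels. With the unweighted loss the
  rare classes' argmax provably fails to leave the background within any
  CPU-feasible step budget (a 2000-step probe flipped only two of five bone
  classes). `trainConfig(classWeights = "balanced")` applies median-frequency
  class balancing — the standard remedy for exactly this situation — and
  flips all five classes within ~100 steps. Stage-2 binary training stays
  unweighted and converges without help.
* **Reduced epochs.** The desk tasks converge in far fewer than 120 epochs;
  the study defaults are 24 (stage 1) and 8 (stage 2), chosen from loss-curve
  plateaus and held-out ROI-containment checks during development (stage 1
  needs roughly 900 gradient steps before the rarest class's region proposals
  stabilise).

## The desk-scale study

`runDeskSegmentationStudy()` generates 200 phantoms, splits them 80/10/10
(seeded shuffle), trains stage 1 on whole-limb images and one stage-2 model
per bone on ground-truth-derived crops, then runs the full two-step pipeline
on the held-out 10% and scores predicted against ground-truth masks with the
Dice similarity coefficient per bone, at raw resolution. A DSC of at least
0.7 is the conventional threshold for excellent agreement between two
segmented regions; the held-out means at desk scale sit well above it. A
bone whose stage-1 ROI is missing scores 0 for that case — no silent
exclusions. The clinical Dice values published for this design (0.89–0.97 on
hospital radiographs with full-scale training) are not reproducible without
those radiographs and are not claimed; the desk study demonstrates the same
machinery end-to-end under the printed threshold.

Problem sizes throughout the test-suite (63-case sweep, 200-case study, 1000
random axis sets, 500-subject ICC simulations) are the package's own choices
balancing statistical resolution against a single-CPU run.

## Agreement statistics

`confusionScores()` reports global accuracy, mean per-class accuracy, mean
and frequency-weighted IoU, and mean DSC (foreground classes only, since a
background DSC would inflate the average; the accuracy/IoU means include
background). The identity DSC = 2·IoU/(1 + IoU) is checked per class to
1e-12 in the tests. Empty-vs-empty masks score DSC 1 with a flag (the 0/0
case).

`iccAgreement()` implements ICC(2,1) — two-way random effects, absolute
agreement, single measurement — from the two-way ANOVA mean squares, the
standard choice for comparing an algorithm's measurements with human raters
on the same subjects. Confidence bounds follow McGraw & Wong; the F-test is
against ICC = 0. The qualitative band uses the Altman cut-points (0.81–1 very
good, 0.61–0.80 good, 0.41–0.60 moderate, below fair or poor), applied to the
ICC rounded to two decimals so the published band edges are honoured. Zero
between-subject variance yields a flagged, undefined result rather than a
spurious coefficient. The implementation is validated against `stats::aov`
mean squares on a worked table and by parameter recovery on simulated
two-way data.

## Degenerate inputs and numerical conventions

* Pixel centres sit at integer coordinates starting at (1, 1), x = column,
  y = row, y increasing downward; all angle math lives in this frame.
* Empty masks, collinear circle/hull input, missing peaks, empty search
  regions, coincident axis endpoints, canvas overflow and unrecoverable mask
  corruption each raise a typed condition (`limbAlign_*`); landmark failures
  carry the anatomic region and are aggregated across bones by
  `extractLandmarks()`.
* Angle sanity bounds (mTFA 150–210°, mLDFA/MPTA 60–120°, JLCA ≤ 30°) raise
  quality flags, never errors: out-of-range measurements on degraded masks
  should be visible, not hidden.
* Constant images normalise to zero with a flag; ROIs clipped at the canvas
  are flagged; a degenerate (one-pixel) stage-1 component still yields a
  minimum-extent crop.

## Known limitations

* The phantom's stylised geometry cannot certify performance on clinical
  radiographs; it certifies the measurement rules and the learning machinery.
* The landmark rules assume one leg per image; `splitLegImage()` provides the
  midline split for both-legs images but does not handle severely rotated
  acquisitions.
* The desk-scale network is deliberately small; its held-out Dice (~0.9) is
  below what full-scale training achieves on real data, and the full-scale
  configuration, while constructible and runnable, is not practical to train
  without a GPU.
* Mirror equivariance of landmark extraction holds only to 1 px: discrete
  tie-breaking by outline index is not mirror-symmetric.
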