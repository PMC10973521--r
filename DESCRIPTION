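Package: LimbAlign
Title: Automated Lower-Limb Alignment Measurement from Radiograph Segmentations
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
        role = c("aut", "cre"))
Description: Rule-based extraction of the eight anatomic feature points of the
        lower limb (femoral head centre, intercondylar notch, tibial spine
        centre, femoral condyles, tibial plateaus, ankle centre) from per-bone
        segmentation masks of standing long-leg radiographs, and computation of
        the four coronal alignment angles: mechanical tibiofemoral angle (mTFA),
        mechanical lateral distal femoral angle (mLDFA), medial proximal tibial
        angle (MPTA) and joint line convergence angle (JLCA). Includes a two-step
        encoder-decoder semantic segmentation pipeline with pooling-index
        unpooling (trainable at a reduced desk scale on the CPU), a parametric
        synthetic limb-phantom generator with exact ground-truth masks, landmarks
        and angles, and the agreement statistics used to evaluate such systems
        (Dice similarity coefficient, intersection-over-union family, and the
        intraclass correlation coefficient ICC(2,1) with Altman bands).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, grDevices, EBImage, png, jsonlite
Suggests: testthat (>= 3.0.0), optparse
biocViews: Software, BiomedicalInformatics, Segmentation, FeatureExtraction
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
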