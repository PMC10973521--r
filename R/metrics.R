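## Segmentation-quality and measurement-agreement statistics.

#' Dice similarity coefficient of two binary masks
#'
#' `2|A n B| / (|A| + |B|)`. Two empty masks score 1 by convention (the 0/0
#' case), with attribute `"flag" = "both_empty"`.
#'
#' @param a,b binary matrices of identical dimensions.
#' @return DSC in `[0, 1]`.
#' @export
diceCoefficient <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    .laStop("limbAlign_dimension_mismatch", "masks have different dimensions")
  a <- a > 0; b <- b > 0
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(structure(1, flag = "both_empty"))
  2 * sum(a & b) / (na + nb)
}

#' Confusion-matrix segmentation scores
#'
#' Global accuracy, mean accuracy (unweighted mean per-class recall), mean
#' IoU, frequency-weighted IoU, and mean DSC over foreground classes, for a
#' predicted vs. reference label raster (binary masks are the 2-class case).
#' The accuracy/IoU means include the background class; the mean DSC averages
#' over foreground classes only.
#'
#' @param pred,truth label matrices of identical dimensions (0 = background).
#' @return Named list of class `"SegmentationScores"` with `global_accuracy`,
#'   `mean_accuracy`, `mean_iou`, `weighted_iou`, `mean_dsc`.
#' @export
confusionScores <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)))
    .laStop("limbAlign_dimension_mismatch", "rasters have different dimensions")
  classes <- sort(unique(c(as.vector(pred), as.vector(truth))))
  tp <- fp <- fn <- stats::setNames(numeric(length(classes)), classes)
  for (i in seq_along(classes)) {
    k <- classes[i]
    tp[i] <- sum(pred == k & truth == k)
    fp[i] <- sum(pred == k & truth != k)
    fn[i] <- sum(pred != k & truth == k)
  }
  npx <- length(truth)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  iou <- ifelse(tp + fp + fn > 0, tp / (tp + fp + fn), NA_real_)
  dsc <- ifelse(2 * tp + fp + fn > 0, 2 * tp / (2 * tp + fp + fn), NA_real_)
  freq <- (tp + fn) / npx
  fg <- classes > 0
  structure(list(
    global_accuracy = sum(tp) / npx,
    mean_accuracy = mean(recall, na.rm = TRUE),
    mean_iou = mean(iou, na.rm = TRUE),
    weighted_iou = sum(freq * iou, na.rm = TRUE),
    mean_dsc = if (any(fg)) mean(dsc[fg], na.rm = TRUE) else NA_real_
  ), class = "SegmentationScores")
}

#' @export
print.SegmentationScores <- function(x, ...) {
  cat(sprintf("SegmentationScores: globalAcc %.4f  meanAcc %.4f  meanIoU %.4f  weightedIoU %.4f  meanDSC %.4f\n",
              x$global_accuracy, x$mean_accuracy, x$mean_iou, x$weighted_iou, x$mean_dsc))
  invisible(x)
}

#' Intraclass correlation coefficient ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single measurement: the
#' standard model for comparing an algorithm's measurements with human raters
#' on the same subjects. Computed from the two-way ANOVA mean squares with
#' the McGraw-Wong confidence bounds and an F-test against ICC = 0. The
#' qualitative band follows the Altman cut-points: 0.81-1 very good,
#' 0.61-0.80 good, 0.41-0.60 moderate, below fair or poor (applied to the
#' ICC rounded to two decimals).
#'
#' @param ratings numeric matrix, subjects in rows, raters/methods in columns
#'   (n >= 5 subjects, k >= 2 raters, no missing cells).
#' @param alpha confidence level complement for the CI (default 0.05).
#' @return List of class `"ICCResult"`: `icc`, `ci_low`, `ci_high`,
#'   `p_value`, `band`, `n`, `k`, and `flag` (non-`NA` when between-subject
#'   variance vanishes and the ICC is undefined).
#' @export
iccAgreement <- function(ratings, alpha = 0.05) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 5L || k < 2L)
    .laStop("limbAlign_config_error", "need >= 5 subjects and >= 2 raters")
  if (any(!is.finite(ratings)))
    .laStop("limbAlign_config_error", "ratings must be complete (no missing cells)")
  rowM <- rowMeans(ratings); colM <- colMeans(ratings); gm <- mean(ratings)
  MSR <- k * sum((rowM - gm)^2) / (n - 1)                      # between subjects
  MSC <- n * sum((colM - gm)^2) / (k - 1)                      # between raters
  SSE <- sum((ratings - outer(rowM, colM, "+") + gm)^2)
  MSE <- SSE / ((n - 1) * (k - 1))                             # residual
  denom <- MSR + (k - 1) * MSE + k * (MSC - MSE) / n
  flag <- NA_character_
  if (denom <= 0 || (MSR <= MSE && MSR - MSE == 0 && denom == 0)) flag <- "undefined"
  icc <- (MSR - MSE) / denom
  if (!is.finite(icc)) { icc <- NA_real_; flag <- "undefined" }
  ## McGraw & Wong (1996) bounds for ICC(A,1)
  if (is.na(icc)) {
    lo <- hi <- p <- NA_real_
  } else {
    a <- (k * icc) / (n * (1 - icc)); b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * MSC + b * MSE)^2 /
      ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
    FL <- stats::qf(1 - alpha / 2, n - 1, v)
    FU <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (MSR - FL * MSE) / (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
    hi <- n * (FU * MSR - MSE) / (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
    if (icc == 1) { lo <- min(lo, 1, na.rm = TRUE); hi <- 1; p <- 0 }
    else p <- stats::pf(MSR / MSE, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  }
  band <- if (is.na(icc)) NA_character_ else {
    r <- round(icc, 2)
    if (r >= 0.81) "very_good" else if (r >= 0.61) "good"
    else if (r >= 0.41) "moderate" else "fair_or_poor"
  }
  structure(list(icc = icc, ci_low = lo, ci_high = hi, p_value = p, band = band,
                 n = n, k = k, flag = flag), class = "ICCResult")
}

#' @export
print.ICCResult <- function(x, ...) {
  cat(sprintf("ICC(2,1) = %.4f  95%% CI [%.4f, %.4f]  p = %.3g  band = %s  (n = %d, k = %d)\n",
              x$icc, x$ci_low, x$ci_high, x$p_value, x$band, x$n, x$k))
  if (!is.na(x$flag)) cat("  flag:", x$flag, "\n")
  invisible(x)
}

#' Agreement report between two sets of angle measurements
#'
#' Per-angle mean and SD of the paired differences (a - b), plus per-method
#' mean and SD. Swapping the arguments flips the sign of every mean
#' difference and leaves the SDs unchanged.
#'
#' @param a,b data.frames or matrices with one row per subject and one column
#'   per angle; identical dimensions and column names.
#' @return data.frame of class `"AgreementReport"` with one row per angle:
#'   `mean_diff`, `sd_diff`, `mean_a`, `sd_a`, `mean_b`, `sd_b`.
#' @export
agreementReport <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!identical(dim(a), dim(b)) || !identical(colnames(a), colnames(b)))
    .laStop("limbAlign_subject_mismatch", "a and b must cover the same subjects and angles")
  d <- a - b
  out <- data.frame(
    angle = colnames(a) %||% paste0("angle", seq_len(ncol(a))),
    mean_diff = colMeans(d), sd_diff = apply(d, 2L, stats::sd),
    mean_a = colMeans(a), sd_a = apply(a, 2L, stats::sd),
    mean_b = colMeans(b), sd_b = apply(b, 2L, stats::sd),
    row.names = NULL
  )
  class(out) <- c("AgreementReport", "data.frame")
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Qualitative band for a Dice score
#'
#' A DSC of at least 0.7 is conventionally reported as excellent agreement
#' between two segmented regions.
#'
#' @param dsc Dice similarity coefficient in `[0, 1]`.
#' @return `"excellent"` or `"not_excellent"`.
#' @export
dscBand <- function(dsc) {
  if (!is.numeric(dsc) || any(dsc < 0 | dsc > 1))
    .laStop("limbAlign_config_error", "dsc must be in [0, 1]")
  ifelse(dsc >= 0.7, "excellent", "not_excellent")
}
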