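# Two-level validation of a segmentation against a manual ground truth:
# pixel-by-pixel confusion counts inside the ROI, region-by-region counts
# over connected lesions, the derived conditional probabilities, and
# paired-area agreement statistics (Pearson, ICC, Bland-Altman).

#' Pixel-by-pixel confusion counts within an ROI
#'
#' Compares every pixel of the predicted and true masks inside the ROI.
#'
#' @param pred,truth Logical masks of equal dimensions.
#' @param roi Logical mask restricting the comparison (nonempty).
#' @return A `confusion_counts` object with `tp`, `fp`, `tn`, `fn` and
#'   `mode = "pixel"`.
#' @export
confusion_pixelwise <- function(pred, truth, roi) {
  assert_mask(pred, "pred"); assert_mask(truth, "truth"); assert_mask(roi, "roi")
  assert_same_dim(pred, truth, "masks"); assert_same_dim(pred, roi, "masks")
  if (!any(roi)) druscan_abort("empty ROI", "druscan_empty_region")
  p <- pred[roi]; t <- truth[roi]
  structure(list(tp = sum(p & t), fp = sum(p & !t),
                 tn = sum(!p & !t), fn = sum(!p & t),
                 mode = "pixel"),
            class = "confusion_counts")
}

#' Region-by-region confusion counts within an ROI
#'
#' Labels the connected components (8-connectivity) of the true and
#' predicted masks inside the ROI and counts lesions rather than pixels: a
#' true lesion overlapped by at least `min_overlap_fraction` of its area
#' (at least one pixel when 0, the default) counts as a true positive,
#' otherwise a false negative; a predicted component touching no true
#' lesion pixel is a false positive. True negatives are undefined at the
#' region level (`tn = NA`).
#'
#' @param pred,truth,roi Logical masks of equal dimensions.
#' @param min_overlap_fraction Fraction of a true lesion's area that must
#'   be covered to count as detected (default 0: any overlap).
#' @return A `confusion_counts` with `mode = "region"` and `tn = NA`.
#' @export
confusion_regionwise <- function(pred, truth, roi, min_overlap_fraction = 0) {
  assert_mask(pred, "pred"); assert_mask(truth, "truth"); assert_mask(roi, "roi")
  assert_same_dim(pred, truth, "masks"); assert_same_dim(pred, roi, "masks")
  if (!any(roi)) druscan_abort("empty ROI", "druscan_empty_region")
  pred <- pred & roi; truth <- truth & roi
  lab_t <- label_components(truth, 8)
  lab_p <- label_components(pred, 8)
  n_t <- max(lab_t); n_p <- max(lab_p)
  tp <- 0L; fn <- 0L
  if (n_t > 0) {
    for (i in seq_len(n_t)) {
      comp <- lab_t == i
      need <- max(1, ceiling(min_overlap_fraction * sum(comp)))
      if (sum(pred & comp) >= need) tp <- tp + 1L else fn <- fn + 1L
    }
  }
  fp <- 0L
  if (n_p > 0) {
    for (j in seq_len(n_p)) {
      if (!any(truth & (lab_p == j))) fp <- fp + 1L
    }
  }
  structure(list(tp = tp, fp = fp, tn = NA_integer_, fn = fn, mode = "region"),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> [%s] tp=%s fp=%s tn=%s fn=%s\n",
              x$mode, x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Conditional probabilities from confusion counts
#'
#' Sensitivity, specificity and accuracy as percentages, and the Dice
#' similarity coefficient `2tp / (2tp + fp + fn)`. In region mode
#' specificity and accuracy are undefined (no true negatives) and returned
#' as `NA`; any metric with a zero denominator is `NA` rather than 0.
#'
#' @param counts A `confusion_counts`.
#' @return A `conditional_probabilities` object with fields `sensitivity`,
#'   `specificity`, `accuracy` (percent) and `dsc` (in \[0, 1\]).
#' @export
conditional_probabilities <- function(counts) {
  if (!inherits(counts, "confusion_counts")) {
    druscan_abort("`counts` must be confusion_counts", "druscan_invalid_parameter")
  }
  safe_div <- function(num, den) if (is.na(den) || den == 0) NA_real_ else num / den
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  sens <- 100 * safe_div(tp, tp + fn)
  if (counts$mode == "pixel") {
    spec <- 100 * safe_div(tn, tn + fp)
    acc <- 100 * safe_div(tp + tn, tp + fp + tn + fn)
  } else {
    spec <- NA_real_; acc <- NA_real_
  }
  dsc <- safe_div(2 * tp, 2 * tp + fp + fn)
  structure(list(sensitivity = sens, specificity = spec,
                 accuracy = acc, dsc = dsc, mode = counts$mode),
            class = "conditional_probabilities")
}

#' @export
print.conditional_probabilities <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "-" else sprintf("%.2f", v)
  cat(sprintf(
    "<conditional_probabilities> [%s] sensitivity %s%% specificity %s%% accuracy %s%% DSC %s\n",
    x$mode, fmt(x$sensitivity), fmt(x$specificity), fmt(x$accuracy), fmt(x$dsc)))
  invisible(x)
}

# Two-way random-effects, absolute-agreement, single-measures ICC (the
# standard agreement ICC for two raters measuring the same subjects), with
# its 95% confidence interval. Mean squares come from the two-way ANOVA of
# measurement ~ subject + rater.
icc_agreement <- function(manual, auto, conf_level = 0.95) {
  n <- length(manual); k <- 2
  long <- data.frame(
    y = c(manual, auto),
    subject = factor(rep(seq_len(n), times = k)),
    rater = factor(rep(c("manual", "auto"), each = n))
  )
  ms <- summary(stats::aov(y ~ subject + rater, data = long))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  if (icc >= 1 - 1e-12) {
    # perfect agreement: the interval degenerates to the point estimate
    return(list(estimate = icc, lower = icc, upper = icc,
                msr = msr, msc = msc, mse = mse))
  }
  # confidence interval (two-way random, absolute agreement, single measures)
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  alpha <- 1 - conf_level
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  list(estimate = icc, lower = lower, upper = upper,
       msr = msr, msc = msc, mse = mse)
}

#' Agreement statistics between manual and automatic area measurements
#'
#' Pearson correlation, intraclass correlation (two-way random effects,
#' absolute agreement, single measures) with a 95% confidence interval, and
#' Bland-Altman limits of agreement (mean difference +/- 1.96 SD of the
#' differences, automatic minus manual) on paired lesion-area measurements.
#'
#' @param manual_areas,auto_areas Equal-length numeric vectors of paired
#'   areas (pixels), `n >= 3`.
#' @return An `agreement_stats` object: `pearson_r`, `pearson_p`, `icc`
#'   (list: estimate, lower, upper), `bland_altman` (list: mean_diff,
#'   sd_diff, lower, upper, fraction_within), and `areas` (paired matrix).
#' @export
agreement_stats <- function(manual_areas, auto_areas) {
  n <- length(manual_areas)
  if (length(auto_areas) != n) {
    druscan_abort("area vectors must have equal length", "druscan_invalid_parameter")
  }
  if (n < 3) {
    druscan_abort("need at least 3 paired areas", "druscan_invalid_parameter")
  }
  if (stats::sd(manual_areas) == 0 || stats::sd(auto_areas) == 0) {
    druscan_abort("zero variance in an area vector: correlation undefined",
                  "druscan_degenerate_data")
  }
  ct <- stats::cor.test(manual_areas, auto_areas, method = "pearson")
  icc <- icc_agreement(manual_areas, auto_areas)
  d <- auto_areas - manual_areas
  md <- mean(d); sdd <- stats::sd(d)
  lo <- md - 1.96 * sdd; hi <- md + 1.96 * sdd
  ba <- list(mean_diff = md, sd_diff = sdd, lower = lo, upper = hi,
             fraction_within = mean(d >= lo & d <= hi))
  structure(list(pearson_r = unname(ct$estimate), pearson_p = ct$p.value,
                 icc = icc, bland_altman = ba,
                 areas = cbind(manual = manual_areas, auto = auto_areas)),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf("<agreement_stats> n = %d pairs\n", nrow(x$areas)))
  cat(sprintf("  Pearson r = %.3f (p = %.3g)\n", x$pearson_r, x$pearson_p))
  cat(sprintf("  ICC(A,1) = %.3f (95%% CI %.3f-%.3f)\n",
              x$icc$estimate, x$icc$lower, x$icc$upper))
  cat(sprintf("  Bland-Altman: mean diff %.2f, limits [%.2f, %.2f], %.0f%% within\n",
              x$bland_altman$mean_diff, x$bland_altman$lower,
              x$bland_altman$upper, 100 * x$bland_altman$fraction_within))
  invisible(x)
}
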