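#' Center-point matching of detections against ground truth
#'
#' The MICCAI endoscopic-vision convention: a prediction is a true
#' positive when its box center falls inside (edges inclusive) any
#' ground-truth box, a false positive otherwise.  A false negative is
#' scored once per image when no prediction box appears at all
#' (`fn_mode = "image"`, the default); `fn_mode = "per_gt"` instead
#' counts one FN per ground-truth box whose interior receives no
#' prediction center, for multi-polyp frames.  True negatives are not
#' defined for box matching.
#'
#' @param preds detection table (needs `x_min`, `y_min`, `width`,
#'   `height`).
#' @param gts ground-truth box table, same coordinate frame.
#' @param fn_mode `"image"` or `"per_gt"`.
#' @return list with counts `tp`, `fp`, `fn`.
#' @export
match_by_center <- function(preds, gts, fn_mode = c("image", "per_gt")) {
  fn_mode <- match.arg(fn_mode)
  np <- nrow(preds); ng <- nrow(gts)
  if (np == 0L) {
    fn <- if (fn_mode == "image") as.integer(ng > 0L) else ng
    return(list(tp = 0L, fp = 0L, fn = fn))
  }
  ctr <- bbox_center(preds)
  inside <- matrix(FALSE, np, max(ng, 1L))
  if (ng > 0L) for (j in seq_len(ng)) {
    g <- gts[j, ]
    inside[, j] <- ctr[, "x"] >= g$x_min & ctr[, "x"] <= g$x_min + g$width &
                   ctr[, "y"] >= g$y_min & ctr[, "y"] <= g$y_min + g$height
  }
  hit <- if (ng > 0L) rowSums(inside) > 0 else rep(FALSE, np)
  fn <- if (fn_mode == "image") 0L else
    if (ng > 0L) sum(colSums(inside) == 0L) else 0L
  list(tp = sum(hit), fp = sum(!hit), fn = fn)
}

#' Image-level detection accuracy
#'
#' The number of correctly detected polyp images divided by the total
#' number of polyp images, as a percentage.  For normal (polyp-free)
#' frames, "correct" means zero detections were emitted.
#'
#' @param detected count of correctly handled images.
#' @param total total images (> 0).
#' @param digits decimals in the reported percentage (default 1).
#' @return Percentage, rounded.
#' @examples
#' image_level_accuracy(859, 900)    # 95.4
#' image_level_accuracy(1712, 1800)  # 95.1
#' @export
image_level_accuracy <- function(detected, total, digits = 1) {
  if (total <= 0) stop("total must be positive")
  round(100 * detected / total, digits)
}

#' Two-by-two confusion matrix for polyp classification
#'
#' Positive class is neoplastic: `tp` = neoplastic called neoplastic,
#' `fn` = neoplastic called hyperplastic, `fp` = hyperplastic called
#' neoplastic, `tn` = hyperplastic called hyperplastic.
#'
#' @param tp,fn,fp,tn non-negative counts.
#' @return list of the four counts, class `confusion2x2`.
#' @export
confusion2x2 <- function(tp, fn, fp, tn) {
  v <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(v < 0)) stop("counts must be non-negative")
  structure(as.list(v), class = "confusion2x2")
}

#' Classification performance metrics
#'
#' Accuracy `(TP+TN)/total`, precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)`, `F1 = 2PR/(P+R)` and `F2 = 5PR/(4P+R)` (the F-beta
#' score with beta = 2, weighting recall over precision), reported as
#' percentages rounded to one decimal.  A metric whose denominator is
#' zero is returned as `NA` and flagged with a warning.
#'
#' @param cm a [confusion2x2()].
#' @param digits decimals (default 1).
#' @return named numeric vector `Acc`, `Prec`, `Rec`, `F1`, `F2`.
#' @examples
#' compute_metrics(confusion2x2(110, 14, 36, 20))  # 72.2 75.3 88.7 81.5 85.7
#' @export
compute_metrics <- function(cm, digits = 1) {
  tot <- cm$tp + cm$fn + cm$fp + cm$tn
  if (tot == 0) stop("all-zero confusion matrix")
  sdiv <- function(num, den, what) {
    if (den == 0) { warning(what, " undefined (zero denominator)"); NA_real_ }
    else num / den
  }
  P <- sdiv(cm$tp, cm$tp + cm$fp, "precision")
  R <- sdiv(cm$tp, cm$tp + cm$fn, "recall")
  f1 <- if (is.na(P) || is.na(R) || P + R == 0) NA_real_ else
    2 * P * R / (P + R)
  f2 <- if (is.na(P) || is.na(R) || 4 * P + R == 0) NA_real_ else
    5 * P * R / (4 * P + R)
  round(100 * c(Acc = (cm$tp + cm$tn) / tot, Prec = P, Rec = R,
                F1 = f1, F2 = f2), digits)
}

#' Negative predictive value
#'
#' `NPV = TN / (TN + FN)`, the fraction of hyperplastic calls that are
#' truly hyperplastic — the quantity governing the diagnose-and-leave
#' strategy (ASGE threshold >= 90 percent for adenoma).
#'
#' @param cm a [confusion2x2()].
#' @param digits decimals (default 0, matching clinical reporting).
#' @return Percentage.
#' @examples
#' npv(confusion2x2(118, 6, 25, 31))  # 84:  31 / (31 + 6)
#' @export
npv <- function(cm, digits = 0) {
  den <- cm$tn + cm$fn
  if (den == 0) { warning("NPV undefined (no negative calls)"); return(NA_real_) }
  round(100 * cm$tn / den, digits)
}

#' Exact McNemar test on paired discordant counts
#'
#' Two-sided exact binomial test on the discordant pairs of two methods
#' evaluated on the same images: under the null the `a + b` discordant
#' outcomes split Binomial(a+b, 1/2), and
#' `p = min(1, 2 * P(X <= min(a, b)))`.  With no discordant pairs the
#' test is vacuous and `p = 1`.  The exact form is used because
#' discordant counts in paired detector comparisons are typically tiny,
#' where the chi-square approximation is invalid.
#'
#' @param only_a images the first method alone got right.
#' @param only_b images the second method alone got right.
#' @return Two-sided p-value.
#' @examples
#' mcnemar_exact(0, 3)   # 0.25
#' mcnemar_exact(0, 16)  # 3.05e-05
#' @export
mcnemar_exact <- function(only_a, only_b) {
  if (only_a < 0 || only_b < 0) stop("counts must be non-negative")
  n <- only_a + only_b
  if (n == 0) return(1)
  min(1, 2 * pbinom(min(only_a, only_b), n, 0.5))
}

#' Exact binomial confidence interval
#'
#' Clopper-Pearson interval (beta-quantile form) by default; the Wilson
#' score interval is available as an option.  Endpoints are returned as
#' percentages rounded to one decimal.
#'
#' @param successes,n counts, `0 <= successes <= n`, `n > 0`.
#' @param level confidence level (default 0.95).
#' @param method `"clopper-pearson"` (default) or `"wilson"`.
#' @param digits decimals (default 1).
#' @return numeric `c(low, high)` in percent.
#' @examples
#' binomial_ci(859, 900)  # 93.9 96.7
#' binomial_ci(843, 900)  # 91.9 95.2
#' @export
binomial_ci <- function(successes, n, level = 0.95,
                        method = c("clopper-pearson", "wilson"), digits = 1) {
  method <- match.arg(method)
  if (n <= 0) stop("n must be positive")
  if (successes < 0 || successes > n) stop("successes must lie in [0, n]")
  a <- 1 - level
  if (method == "clopper-pearson") {
    lo <- if (successes == 0) 0 else qbeta(a / 2, successes, n - successes + 1)
    hi <- if (successes == n) 1 else qbeta(1 - a / 2, successes + 1, n - successes)
  } else {
    z <- stats::qnorm(1 - a / 2)
    ph <- successes / n
    den <- 1 + z^2 / n
    ctr <- (ph + z^2 / (2 * n)) / den
    hw <- z * sqrt(ph * (1 - ph) / n + z^2 / (4 * n^2)) / den
    lo <- max(0, ctr - hw); hi <- min(1, ctr + hw)
  }
  round(100 * c(low = lo, high = hi), digits)
}

#' Paired outcome cross-tabulation
#'
#' Cross-tabulates per-image success of two methods run on the identical
#' image set, in the layout feeding the McNemar test.
#'
#' @param outcomes_a,outcomes_b logical vectors, same length and order.
#' @return list with `both`, `only_a`, `only_b`, `neither`, `n`, and the
#'   McNemar `p_value`.
#' @export
paired_table <- function(outcomes_a, outcomes_b) {
  if (length(outcomes_a) != length(outcomes_b))
    stop("outcome vectors must have the same length")
  both <- sum(outcomes_a & outcomes_b)
  oa <- sum(outcomes_a & !outcomes_b)
  ob <- sum(!outcomes_a & outcomes_b)
  nei <- sum(!outcomes_a & !outcomes_b)
  list(both = both, only_a = oa, only_b = ob, neither = nei,
       n = length(outcomes_a), p_value = mcnemar_exact(oa, ob))
}

#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) formulation with tie correction: the probability
#' that a randomly chosen positive scores above a randomly chosen
#' negative, ties counting one half.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels logical or 0/1 vector, `TRUE` = positive class; both
#'   classes must be present.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Partition annotated records by polyp pixel area
#'
#' Splits records at the area (width x height) of their largest
#' ground-truth box: strictly below the threshold versus at-or-above
#' (a 40 x 40 = 1600-pixel box sits in the upper stratum).  Downstream
#' metrics are then computable per stratum, e.g. re-deriving NPV after
#' excluding sub-threshold lesions.
#'
#' @param records list whose elements carry a `gt_boxes` box table
#'   (e.g. [annotated_image()] records).
#' @param threshold_px area threshold in pixels (1600 and 1800 are the
#'   operating points of interest).
#' @return list with elements `below` and `at_or_above`, each a list of
#'   records.
#' @export
stratify_by_area <- function(records, threshold_px) {
  areas <- vapply(records, function(r) {
    if (is.null(r$gt_boxes) || nrow(r$gt_boxes) == 0L)
      stop("record without ground-truth boxes cannot be stratified")
    max(bbox_area(r$gt_boxes))
  }, 1.0)
  list(below = records[areas < threshold_px],
       at_or_above = records[areas >= threshold_px])
}
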