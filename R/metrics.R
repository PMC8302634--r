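#' Dice similarity coefficient
#'
#' `2|A n B| / (|A| + |B|)`: the ratio of the overlap to the mean area of
#' the two segmentations. Two empty masks score 1 by convention (vacuous
#' perfect agreement; flagged via the `"both_empty"` attribute). Values
#' above 0.70 are conventionally read as excellent agreement.
#'
#' @param ground_truth,prediction logical (or 0/1) masks of identical
#'   shape.
#' @return scalar in `[0, 1]`.
#' @export
dice <- function(ground_truth, prediction) {
  gt <- as_binary_mask(ground_truth, "ground_truth")
  pr <- as_binary_mask(prediction, "prediction")
  check_mask_shapes(gt, pr)
  a <- sum(gt)
  b <- sum(pr)
  if (a + b == 0L) {
    return(structure(1, both_empty = TRUE))
  }
  2 * sum(gt & pr) / (a + b)
}

#' Pixel-wise accuracy, sensitivity and specificity
#'
#' Confusion-matrix rates over the full image frame, as percentages:
#' sensitivity `TP/(TP+FN)*100`, specificity `TN/(TN+FP)*100`, accuracy
#' `(TP+TN)/total*100`. An empty denominator (no positive or no negative
#' ground-truth pixels) yields `NA` with the `undefined` field set, never
#' a silent zero.
#'
#' @param ground_truth,prediction logical masks of identical shape.
#' @return list with `accuracy`, `sensitivity`, `specificity` (percent),
#'   the confusion counts `tp`, `fp`, `tn`, `fn`, and `undefined`
#'   (character vector naming any undefined rates).
#' @export
pixel_classification_metrics <- function(ground_truth, prediction) {
  gt <- as_binary_mask(ground_truth, "ground_truth")
  pr <- as_binary_mask(prediction, "prediction")
  check_mask_shapes(gt, pr)
  tp <- sum(gt & pr)
  fp <- sum(!gt & pr)
  fn <- sum(gt & !pr)
  tn <- sum(!gt & !pr)
  total <- tp + fp + fn + tn
  undefined <- character(0)
  sens <- if (tp + fn > 0) 100 * tp / (tp + fn) else {
    undefined <- c(undefined, "sensitivity")
    NA_real_
  }
  spec <- if (tn + fp > 0) 100 * tn / (tn + fp) else {
    undefined <- c(undefined, "specificity")
    NA_real_
  }
  list(
    accuracy = 100 * (tp + tn) / total,
    sensitivity = sens,
    specificity = spec,
    tp = tp, fp = fp, tn = tn, fn = fn,
    undefined = undefined
  )
}

#' Relative area difference (RAD)
#'
#' Signed percentage by which the prediction's area deviates from the
#' ground truth: `(|A_gt| - |A_pred|) / |A_gt| * 100`. Positive means the
#' prediction underestimates the region, negative overestimates. The
#' unsigned variant takes the absolute value.
#'
#' @param ground_truth,prediction logical masks; ground truth must be
#'   nonempty.
#' @param signed if `FALSE`, return the absolute value.
#' @return scalar percentage.
#' @export
relative_area_difference <- function(ground_truth, prediction,
                                     signed = TRUE) {
  gt <- as_binary_mask(ground_truth, "ground_truth")
  pr <- as_binary_mask(prediction, "prediction")
  check_mask_shapes(gt, pr)
  a <- sum(gt)
  if (a == 0L) stop("ground-truth mask is empty", call. = FALSE)
  rad <- (a - sum(pr)) / a * 100
  if (signed) rad else abs(rad)
}

#' Occupation ratio of the supraspinatus muscle
#'
#' Muscle area over fossa area on the Y-view slice; the standard index of
#' supraspinatus atrophy. Areas are pixel counts (the ratio is unitless,
#' so pixel spacing cancels on a single slice).
#'
#' @param masks a [region_masks()] object, or the fossa mask when `muscle`
#'   is given separately.
#' @param muscle optional muscle mask when `masks` is a bare fossa mask.
#' @return scalar ratio; `<= 1` whenever the muscle lies inside the fossa.
#' @export
occupation_ratio <- function(masks, muscle = NULL) {
  if (inherits(masks, "region_masks")) {
    fossa <- masks$fossa
    muscle <- masks$muscle
  } else {
    fossa <- as_binary_mask(masks, "fossa")
    muscle <- as_binary_mask(muscle, "muscle")
    check_mask_shapes(fossa, muscle)
  }
  fa <- sum(fossa)
  if (fa == 0L) stop("fossa mask is empty", call. = FALSE)
  sum(muscle) / fa
}

#' Full agreement report for one region pair
#'
#' Bundles the Dice coefficient, pixel-classification rates and the
#' relative area difference for one ground-truth/prediction mask pair, in
#' the layout used for per-region result tables.
#'
#' @param ground_truth,prediction logical masks of identical shape.
#' @param region label for the report row, e.g. `"fossa"` or `"muscle"`.
#' @return An object of class `seg_metric_report`: list with `region`,
#'   `dsc`, `accuracy`, `sensitivity`, `specificity`, `rad_pct`,
#'   `excellent` (`dsc > 0.70`), and the confusion counts.
#' @export
seg_metric_report <- function(ground_truth, prediction, region = "region") {
  d <- dice(ground_truth, prediction)
  pcm <- pixel_classification_metrics(ground_truth, prediction)
  rad <- relative_area_difference(ground_truth, prediction)
  structure(
    list(
      region = region,
      dsc = as.numeric(d),
      accuracy = pcm$accuracy,
      sensitivity = pcm$sensitivity,
      specificity = pcm$specificity,
      rad_pct = rad,
      excellent = as.numeric(d) > 0.70,
      tp = pcm$tp, fp = pcm$fp, tn = pcm$tn, fn = pcm$fn
    ),
    class = "seg_metric_report"
  )
}

#' @export
print.seg_metric_report <- function(x, ...) {
  cat(sprintf(
    "<seg_metric_report %s> DSC %.4f%s, acc %.2f%%, sens %.2f%%, spec %.2f%%, RAD %+.2f%%\n",
    x$region, x$dsc, if (x$excellent) " (excellent)" else "",
    x$accuracy, x$sensitivity, x$specificity, x$rad_pct
  ))
  invisible(x)
}

#' Collect region reports into a results table
#'
#' @param reports list of `seg_metric_report` objects.
#' @return data frame with one row per report and columns region, dsc,
#'   accuracy, sensitivity, specificity, rad_pct.
#' @export
metric_table <- function(reports) {
  do.call(rbind, lapply(reports, function(r) {
    data.frame(
      region = r$region, dsc = r$dsc, accuracy = r$accuracy,
      sensitivity = r$sensitivity, specificity = r$specificity,
      rad_pct = r$rad_pct, stringsAsFactors = FALSE
    )
  }))
}
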