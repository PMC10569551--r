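#' Voxelwise confusion counts
#'
#' Counts true/false positives/negatives of a segmentation against the
#' ground truth over the evaluation region only (voxels where `eval_mask` is
#' 1, i.e. the brain); voxels outside it are never counted.
#'
#' @param pred predicted `vs_mask` segmentation.
#' @param gt ground-truth `vs_mask`.
#' @param eval_mask evaluation-region `vs_mask` (the brain mask).
#' @return a `vs_confusion`: `list(tp, tn, fp, fn)`, summing to the number of
#'   evaluated voxels.
#' @export
confusion_counts <- function(pred, gt, eval_mask) {
  if (!identical(dim(pred), dim(gt)) || !identical(dim(pred), dim(eval_mask)))
    stop("pred, gt and eval_mask shapes differ")
  m <- bare(unclass(eval_mask)) == 1L
  p <- bare(unclass(pred))[m] == 1L
  g <- bare(unclass(gt))[m] == 1L
  structure(list(tp = sum(p & g), tn = sum(!p & !g),
                 fp = sum(p & !g), fn = sum(!p & g)),
            class = "vs_confusion")
}

#' Metrics from confusion counts
#'
#' `accuracy = (tp+tn)/total`, `recall = tp/(tp+fn)`,
#' `precision = tp/(tp+fp)`, `dsc = 2tp/(2tp+fp+fn)` (the Dice coefficient,
#' the harmonic mean of precision and recall). Ratios with zero denominator
#' are reported as 0.
#'
#' @param counts a `vs_confusion` or anything with fields `tp`,`tn`,`fp`,`fn`.
#' @return a one-row [tibble::tibble] with columns
#'   `accuracy`, `recall`, `precision`, `dsc` (fractions in `[0, 1]`).
#' @export
compute_metrics <- function(counts) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  total <- tp + tn + fp + fn
  if (total == 0) stop("no evaluated voxels")
  safe <- function(num, den) if (den == 0) 0 else num / den
  tibble::tibble(accuracy = (tp + tn) / total,
                 recall = safe(tp, tp + fn),
                 precision = safe(tp, tp + fp),
                 dsc = safe(2 * tp, 2 * tp + fp + fn))
}

#' Dice score from precision and recall
#'
#' The harmonic-mean identity `dsc = 2 P R / (P + R)`; accepts either
#' fractions or percentages (returned on the same scale).
#'
#' @param precision,recall precision and recall.
#' @return the Dice score.
#' @export
dice_from_precision_recall <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Row-normalised confusion matrix
#'
#' The reporting convention of the reference evaluation: each ground-truth
#' row is normalised to 100%, so the `FG(GT) -> FG` entry equals recall and
#' the `BG(GT) -> BG` entry equals specificity.
#'
#' @param counts a `vs_confusion`.
#' @return a 2x2 matrix of percentages with rows `BG(GT)`, `FG(GT)` and
#'   columns `BG`, `FG`; a row with an empty ground-truth class is `NA`.
#' @export
confusion_rows <- function(counts) {
  bg <- counts$tn + counts$fp
  fg <- counts$fn + counts$tp
  m <- matrix(NA_real_, 2, 2,
              dimnames = list(c("BG(GT)", "FG(GT)"), c("BG", "FG")))
  if (bg > 0) m[1, ] <- 100 * c(counts$tn, counts$fp) / bg
  if (fg > 0) m[2, ] <- 100 * c(counts$fn, counts$tp) / fg
  m
}

#' Average metrics across stacks
#'
#' Unweighted arithmetic mean of each metric column (the "Average" column of
#' a per-stack metric table), not voxel-pooled.
#'
#' @param per_stack a data frame of per-stack metrics (numeric columns are
#'   averaged), or a list of one-row metric tibbles.
#' @return a one-row tibble of column means.
#' @export
aggregate_metrics <- function(per_stack) {
  if (is.list(per_stack) && !is.data.frame(per_stack))
    per_stack <- do.call(rbind, per_stack)
  if (!nrow(per_stack)) stop("empty metrics list")
  num <- vapply(per_stack, is.numeric, logical(1))
  tibble::as_tibble(as.list(colMeans(per_stack[, num, drop = FALSE])))
}

#' Round percentages the way the reference tables print them
#'
#' Two decimals, half-up.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 2) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' @export
print.vs_confusion <- function(x, ...) {
  cat(sprintf("<vs_confusion> tp %d  fp %d  fn %d  tn %d\n",
              x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}
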