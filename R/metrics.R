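SEG_CLASSES <- c("main_stem", "branch", "boll")

#' Per-class confusion counts
#'
#' True positives, false positives, and false negatives per part class for a
#' predicted labeling against a reference labeling.
#'
#' @param pred,truth equal-length integer label vectors with values in
#'   \{0, 1, 2\}.
#' @return A data.frame with one row per class and columns `class`, `tp`,
#'   `fp`, `fn`.
#' @export
#' @examples
#' confusion_counts(c(0L, 1L, 2L), c(0L, 0L, 2L))
confusion_counts <- function(pred, truth) {
  if (length(pred) != length(truth))
    stop("pred and truth must have the same length")
  pred <- as.integer(pred)
  truth <- as.integer(truth)
  if (!all(pred %in% 0:2) || !all(truth %in% 0:2))
    stop("labels must be in {0, 1, 2}")
  tab <- table(factor(pred, 0:2), factor(truth, 0:2))
  tp <- diag(tab)
  data.frame(class = SEG_CLASSES,
             tp = as.integer(tp),
             fp = as.integer(rowSums(tab) - tp),
             fn = as.integer(colSums(tab) - tp),
             row.names = NULL)
}

metric_or_one <- function(num, den) ifelse(den == 0, 1, num / den)

#' Segmentation metrics from confusion counts
#'
#' Precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, IoU `TP/(TP+FP+FN)` and the F1
#' score per class, overall accuracy (correct points over all points), and the
#' class-mean IoU of the cloud. A class absent from both prediction and
#' reference contributes 1.0 by convention (vacuously perfect); such classes
#' are flagged in the `vacuous` column.
#'
#' @param counts per-class counts from [confusion_counts()].
#' @return A `seg_report` object: `per_class` data.frame (with `precision`,
#'   `recall`, `iou`, `f1`, `vacuous`), `accuracy`, `mean_iou`, `n_points`,
#'   `n_clouds = 1`.
#' @export
class_metrics <- function(counts) {
  stopifnot(is.data.frame(counts), all(c("tp", "fp", "fn") %in% names(counts)))
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  per <- data.frame(
    class = counts$class,
    tp = tp, fp = fp, fn = fn,
    precision = metric_or_one(tp, tp + fp),
    recall = metric_or_one(tp, tp + fn),
    iou = metric_or_one(tp, tp + fp + fn),
    vacuous = tp + fp + fn == 0
  )
  per$f1 <- ifelse(per$precision + per$recall == 0, 0,
                   2 * per$precision * per$recall / (per$precision + per$recall))
  structure(list(per_class = per,
                 accuracy = sum(tp) / max(1L, sum(tp + fn)),
                 mean_iou = mean(per$iou),
                 n_points = sum(tp + fn),
                 n_clouds = 1L),
            class = "seg_report")
}

#' Evaluate one predicted labeling
#'
#' Convenience wrapper: [confusion_counts()] followed by [class_metrics()].
#'
#' @inheritParams confusion_counts
#' @return A `seg_report`, see [class_metrics()].
#' @export
evaluate_segmentation <- function(pred, truth) {
  class_metrics(confusion_counts(pred, truth))
}

#' Aggregate segmentation reports over clouds
#'
#' Per-class metrics are pooled: counts are summed over clouds before the
#' ratios are formed. Accuracy is pooled correct points over pooled points.
#' The mean IoU follows the per-cloud convention: the class-mean IoU of each
#' cloud is computed first, then averaged over clouds.
#'
#' @param reports non-empty list of `seg_report`s.
#' @return An aggregate `seg_report`.
#' @export
summarize_reports <- function(reports) {
  if (length(reports) == 0) stop("no reports to summarize")
  stopifnot(all(vapply(reports, inherits, TRUE, "seg_report")))
  pooled <- Reduce(function(a, b) {
    a$tp <- a$tp + b$tp; a$fp <- a$fp + b$fp; a$fn <- a$fn + b$fn; a
  }, lapply(reports, function(r) r$per_class[c("tp", "fp", "fn")]))
  pooled$class <- SEG_CLASSES
  agg <- class_metrics(pooled)
  agg$mean_iou <- mean(vapply(reports, `[[`, 0, "mean_iou"))
  agg$n_clouds <- sum(vapply(reports, `[[`, 0L, "n_clouds"))
  agg
}

#' @export
print.seg_report <- function(x, ...) {
  cat(sprintf("<seg_report> %d cloud(s), %d points\n", x$n_clouds, x$n_points))
  cat(sprintf("  mean IoU %.2f%%   accuracy %.2f%%\n",
              100 * x$mean_iou, 100 * x$accuracy))
  p <- x$per_class
  for (i in seq_len(nrow(p)))
    cat(sprintf("  %-9s IoU %6.2f%%  precision %6.2f%%  recall %6.2f%%  F1 %6.2f%%%s\n",
                p$class[i], 100 * p$iou[i], 100 * p$precision[i],
                100 * p$recall[i], 100 * p$f1[i],
                if (p$vacuous[i]) "  (absent)" else ""))
  invisible(x)
}
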