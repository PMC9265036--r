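#' Pixel-wise confusion counts between a predicted and a true mask
#'
#' @param pred,truth Binary matrices of identical shape.
#' @return An object of class `confusion_counts` with fields `tp`, `fp`,
#'   `fn`, `tn`; they always sum to the pixel count.
#' @export
confusion_counts <- function(pred, truth) {
  pred <- as_binary_mask(pred)
  truth <- as_binary_mask(truth)
  if (!identical(dim(pred), dim(truth))) {
    stop("pred and truth must have the same shape", call. = FALSE)
  }
  p <- pred > 0; t <- truth > 0
  structure(list(
    tp = sum(p & t), fp = sum(p & !t),
    fn = sum(!p & t), tn = sum(!p & !t)
  ), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP %d  FP %d  FN %d  TN %d\n",
              x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Dice coefficient, 2TP / (2TP + FP + FN)
#'
#' Returns 1 when both masks are empty (2TP + FP + FN = 0): a correct
#' prediction of absence is a perfect prediction.
#'
#' @param c A [confusion_counts()].
#' @return Score in [0, 1].
#' @export
dice <- function(c) {
  den <- 2 * c$tp + c$fp + c$fn
  if (den == 0) return(1)
  2 * c$tp / den
}

#' Intersection over union, TP / (TP + FP + FN)
#'
#' Returns 1 when the denominator is 0 (both masks empty).
#'
#' @inheritParams dice
#' @return Score in [0, 1].
#' @export
iou <- function(c) {
  den <- c$tp + c$fp + c$fn
  if (den == 0) return(1)
  c$tp / den
}

#' Sensitivity (recall), TP / (TP + FN)
#'
#' Undefined when the truth mask is empty (TP + FN = 0); returns `NA` with
#' attribute `undefined = TRUE` rather than a silent 0, so dataset
#' aggregates are not biased.
#'
#' @inheritParams dice
#' @return Score in [0, 1], or flagged `NA`.
#' @export
sensitivity <- function(c) {
  den <- c$tp + c$fn
  if (den == 0) return(structure(NA_real_, undefined = TRUE))
  c$tp / den
}

#' Specificity, TN / (TN + FP)
#'
#' Undefined when there are no true-background pixels (TN + FP = 0);
#' returns flagged `NA` as for [sensitivity()].
#'
#' @inheritParams dice
#' @return Score in [0, 1], or flagged `NA`.
#' @export
specificity <- function(c) {
  den <- c$tn + c$fp
  if (den == 0) return(structure(NA_real_, undefined = TRUE))
  c$tn / den
}

#' All four segmentation scores for one mask pair
#'
#' @inheritParams confusion_counts
#' @return A named numeric vector `dice`, `iou`, `sensitivity`,
#'   `specificity` (undefined entries are `NA`).
#' @export
seg_scores <- function(pred, truth) {
  cc <- confusion_counts(pred, truth)
  c(dice = dice(cc), iou = iou(cc),
    sensitivity = as.numeric(sensitivity(cc)),
    specificity = as.numeric(specificity(cc)))
}

#' Score a dataset of mask pairs with mean +/- SD aggregation
#'
#' Computes per-image Dice, IoU, sensitivity and specificity and aggregates
#' each metric as the unweighted mean and sample standard deviation
#' (n - 1 denominator) over images, the usual "mean +/- SD" presentation
#' for segmentation benchmarks. Undefined per-image entries are skipped
#' with a warning; a single image yields SD 0 with a warning.
#'
#' @param pred_masks,truth_masks Aligned lists of binary matrices.
#' @return A list of class `seg_report`:
#'   \describe{
#'     \item{per_image}{data.frame, one row per image.}
#'     \item{summary}{data.frame with metric, mean, sd, n_used.}
#'   }
#' @export
score_dataset <- function(pred_masks, truth_masks) {
  if (length(pred_masks) != length(truth_masks)) {
    stop("pred and truth lists must have equal length", call. = FALSE)
  }
  rows <- t(vapply(seq_along(pred_masks), function(i) {
    seg_scores(pred_masks[[i]], truth_masks[[i]])
  }, numeric(4)))
  per_image <- data.frame(image = seq_len(nrow(rows)) - 1L, rows)

  metrics <- c("dice", "iou", "sensitivity", "specificity")
  summ <- lapply(metrics, function(m) {
    v <- per_image[[m]]
    if (anyNA(v)) {
      warning(sprintf("%d image(s) with undefined %s skipped in aggregation",
                      sum(is.na(v)), m))
      v <- v[!is.na(v)]
    }
    s <- if (length(v) >= 2) stats::sd(v) else {
      warning(sprintf("fewer than 2 defined values for %s; SD reported as 0", m))
      0
    }
    data.frame(metric = m, mean = mean(v), sd = s, n_used = length(v))
  })
  structure(list(per_image = per_image, summary = do.call(rbind, summ)),
            class = "seg_report")
}

#' @export
print.seg_report <- function(x, digits = 3, ...) {
  cat(sprintf("<seg_report> %d images\n", nrow(x$per_image)))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-12s %.*f +/- %.*f  (n = %d)\n",
                s$metric[i], digits, s$mean[i], digits, s$sd[i], s$n_used[i]))
  }
  invisible(x)
}
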