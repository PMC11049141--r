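# Compound training loss (binary cross-entropy + Dice) and the
# pixel-count based evaluation metrics (IoU, Dice).

#' Loss weights
#'
#' Weights of the compound loss `lambda1 * BCE + lambda2 * Dice` and the
#' smoothing constant used in the Dice term and the evaluation metrics.
#' Defaults follow the standard setting `lambda1 = 0.5`, `lambda2 = 1`.
#'
#' @param lambda1 Weight on the binary cross-entropy term.
#' @param lambda2 Weight on the Dice term.
#' @param epsilon Positive smoothing constant.
#' @return A list of class `"loss_weights"`.
#' @export
loss_weights <- function(lambda1 = 0.5, lambda2 = 1, epsilon = 1e-5) {
  if (epsilon <= 0) stop("epsilon must be positive", call. = FALSE)
  structure(list(lambda1 = lambda1, lambda2 = lambda2, epsilon = epsilon),
            class = "loss_weights")
}

check_fields <- function(o, t) {
  if (!identical(dim(o), dim(t)) && length(o) != length(t))
    stop("probability map and mask must have identical shape", call. = FALSE)
  if (any(t != 0 & t != 1))
    stop("ground-truth mask must be binary", call. = FALSE)
}

clamp01 <- function(o, eps) pmin(pmax(o, eps), 1 - eps)

#' Binary cross-entropy loss
#'
#' Mean negative log-likelihood over all pixels,
#' `-(1/N) * sum(t*log(o) + (1-t)*log(1-o))`, with probabilities clamped
#' to `[eps, 1-eps]` before the logarithms.
#'
#' @param o Probability map (values in (0, 1)).
#' @param t Binary ground-truth mask of the same shape.
#' @param eps Clamping constant.
#' @return Non-negative scalar.
#' @examples
#' bce_loss(array(0.5, c(2, 2)), array(c(0, 1, 0, 1), c(2, 2))) # log(2)
#' @export
bce_loss <- function(o, t, eps = 1e-5) {
  check_fields(o, t)
  o <- clamp01(o, eps)
  -mean(t * log(o) + (1 - t) * log(1 - o))
}

#' Dice loss
#'
#' `1 - (2 * sum(o*t) + eps) / (sum(o) + sum(t) + eps)`; zero for a
#' perfect binary prediction and, by the smoothing convention, zero when
#' both prediction and mask are empty.
#'
#' @inheritParams bce_loss
#' @return Scalar in [0, 1].
#' @export
dice_loss <- function(o, t, eps = 1e-5) {
  check_fields(o, t)
  1 - (2 * sum(o * t) + eps) / (sum(o) + sum(t) + eps)
}

#' Compound segmentation loss
#'
#' `lambda1 * BCE + lambda2 * Dice`.
#'
#' @inheritParams bce_loss
#' @param w A [loss_weights()] object.
#' @return Non-negative scalar.
#' @export
combined_loss <- function(o, t, w = loss_weights()) {
  w$lambda1 * bce_loss(o, t, w$epsilon) + w$lambda2 * dice_loss(o, t, w$epsilon)
}

# gradient of the compound loss with respect to the probability map
combined_loss_grad <- function(o, t, w = loss_weights()) {
  eps <- w$epsilon
  oc <- clamp01(o, eps)
  inside <- (o > eps) & (o < 1 - eps)
  dbce <- (-t / oc + (1 - t) / (1 - oc)) / length(o) * inside
  num <- 2 * sum(o * t) + eps
  den <- sum(o) + sum(t) + eps
  ddice <- -(2 * t * den - num) / den^2
  w$lambda1 * dbce + w$lambda2 * ddice
}

#' Pixel confusion counts
#'
#' Tallies true positives, false positives and false negatives between a
#' binary predicted mask and a binary reference mask. By construction
#' `TP + FP = sum(pred)` and `TP + FN = sum(true)`.
#'
#' @param pred_mask,true_mask Binary arrays of identical shape.
#' @return List with integer `TP`, `FP`, `FN`.
#' @examples
#' confusion_counts(c(1, 1, 0, 0), c(1, 0, 1, 0)) # TP 1, FP 1, FN 1
#' @export
confusion_counts <- function(pred_mask, true_mask) {
  if (length(pred_mask) != length(true_mask))
    stop("masks must have identical shape", call. = FALSE)
  if (any(pred_mask != 0 & pred_mask != 1) || any(true_mask != 0 & true_mask != 1))
    stop("masks must be binary", call. = FALSE)
  tp <- sum(pred_mask == 1 & true_mask == 1)
  fp <- sum(pred_mask == 1 & true_mask == 0)
  fn <- sum(pred_mask == 0 & true_mask == 1)
  list(TP = as.integer(tp), FP = as.integer(fp), FN = as.integer(fn))
}

#' IoU and Dice from confusion counts
#'
#' `IoU = TP / (TP + FP + FN)` and `Dice = 2 TP / (FP + 2 TP + FN)`,
#' smoothed by `eps`; an empty prediction compared with an empty
#' reference scores a perfect (1, 1) -- the conservative convention for
#' lesion-free patches.
#'
#' @param counts A list with non-negative `TP`, `FP`, `FN` (as from
#'   [confusion_counts()]).
#' @param eps Smoothing constant.
#' @return List with `iou` and `dice`.
#' @examples
#' evaluate_counts(list(TP = 6, FP = 2, FN = 2)) # IoU 0.6, Dice 0.75
#' @export
evaluate_counts <- function(counts, eps = 1e-5) {
  tp <- counts$TP; fp <- counts$FP; fn <- counts$FN
  if (any(c(tp, fp, fn) < 0)) stop("counts must be non-negative", call. = FALSE)
  if (tp + fp + fn == 0) return(list(iou = 1, dice = 1))
  list(iou = (tp + eps) / (tp + fp + fn + eps),
       dice = (2 * tp + eps) / (fp + 2 * tp + fn + eps))
}

#' Per-image segmentation metrics
#'
#' Computes IoU and Dice per image (prediction thresholded at 0.5) and
#' their dataset means. Metrics are averaged over images, not pooled over
#' pixels.
#'
#' @param probs List of probability maps (or a single map).
#' @param masks List of binary reference masks (or a single mask).
#' @param ids Optional character ids for the per-image rows.
#' @param threshold Binarisation threshold for predictions (default 0.5;
#'   values `>= threshold` are foreground).
#' @return List with `per_image` (data frame: id, iou, dice) and `summary`
#'   (named means).
#' @export
segmentation_metrics <- function(probs, masks, ids = NULL, threshold = 0.5) {
  if (!is.list(probs)) probs <- list(probs)
  if (!is.list(masks)) masks <- list(masks)
  stopifnot(length(probs) == length(masks))
  if (is.null(ids)) ids <- sprintf("img%03d", seq_along(probs))
  rows <- lapply(seq_along(probs), function(i) {
    cc <- confusion_counts((probs[[i]] >= threshold) * 1, masks[[i]])
    m <- evaluate_counts(cc)
    data.frame(id = ids[i], iou = m$iou, dice = m$dice,
               stringsAsFactors = FALSE)
  })
  per_image <- do.call(rbind, rows)
  list(per_image = per_image,
       summary = c(mean_iou = mean(per_image$iou),
                   mean_dice = mean(per_image$dice)))
}

#' Write a metrics report
#'
#' Serialises per-image metrics as CSV and the dataset means as JSON.
#'
#' @param metrics Result of [segmentation_metrics()].
#' @param csv_path,json_path Output file paths.
#' @return Invisibly, the summary vector.
#' @export
write_metrics_report <- function(metrics, csv_path, json_path) {
  utils::write.csv(metrics$per_image, csv_path, row.names = FALSE)
  jsonlite::write_json(as.list(metrics$summary), json_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(metrics$summary)
}
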