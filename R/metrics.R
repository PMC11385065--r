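#' Dice score from confusion counts
#'
#' `2 TP / (2 TP + FN + FP)`, the overlap statistic between a predicted and
#' a ground-truth mask: 0 means no overlap, 1 perfect overlap. When both
#' masks are empty the score is conventionally 1 and the result carries the
#' attribute `degenerate = TRUE`.
#'
#' @param tp,fp,fn Nonnegative counts (true positives, false positives,
#'   false negatives).
#' @return Dice score in `[0, 1]`.
#' @examples
#' dice_score(2, 1, 1)  # 0.6667
#' @export
dice_score <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0)) stop("counts must be nonnegative", call. = FALSE)
  denom <- 2 * tp + fn + fp
  if (denom == 0) {
    return(structure(1, degenerate = TRUE))
  }
  2 * tp / denom
}

#' @rdname dice_score
#' @param pred,truth Logical matrices of identical shape.
#' @export
dice_from_masks <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth))) {
    stop("alignment error: masks must have identical shape", call. = FALSE)
  }
  p <- as.logical(pred); t <- as.logical(truth)
  dice_score(tp = sum(p & t), fp = sum(p & !t), fn = sum(!p & t))
}

#' Qualitative band for a Dice score
#'
#' Scores above 0.8 are conventionally "good", 0.6-0.8 "acceptable", and
#' below 0.6 "bad".
#'
#' @param dice Dice score(s) in `[0, 1]`.
#' @return Character vector of bands.
#' @export
dice_band <- function(dice) {
  ifelse(dice > 0.8, "good", ifelse(dice >= 0.6, "acceptable", "bad"))
}

#' Pixel-level confusion matrix between two label maps
#'
#' Rows are the predicted class, columns the actual (ground-truth) class.
#' With `normalize = TRUE` each column is divided by its sum, so a column
#' reads as "where did pixels of this true class go".
#'
#' @param pred,truth [label_map()] objects (or integer/character matrices)
#'   of identical shape.
#' @param classes Character vector of class labels to evaluate; pixels whose
#'   true and predicted labels are both outside this set are ignored.
#' @param normalize Column-normalize (default `TRUE`).
#' @return A square numeric matrix with `dimnames` `(predicted, actual)`.
#' @export
confusion_matrix <- function(pred, truth, classes = class_labels(),
                             normalize = TRUE) {
  pm <- if (inherits(pred, "label_map")) pred$labels else pred
  tm <- if (inherits(truth, "label_map")) truth$labels else truth
  if (!identical(dim(pm), dim(tm))) {
    stop("alignment error: rasters must have identical shape", call. = FALSE)
  }
  to_name <- function(m) {
    if (is.character(m)) as.vector(m) else class_labels()[as.vector(m) + 1L]
  }
  p <- factor(to_name(pm), levels = classes)
  t <- factor(to_name(tm), levels = classes)
  keep <- !is.na(p) | !is.na(t)
  cm <- table(predicted = p[keep], actual = t[keep])
  cm <- matrix(as.numeric(cm), nrow = length(classes),
               dimnames = list(predicted = classes, actual = classes))
  if (normalize) {
    cs <- colSums(cm)
    nz <- cs > 0
    cm[, nz] <- sweep(cm[, nz, drop = FALSE], 2, cs[nz], "/")
  }
  cm
}

#' Per-class confusion counts for one class of a label map pair
#'
#' @param pred,truth [label_map()] objects or class rasters.
#' @param class Class label to score one-vs-rest.
#' @return Named list with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(pred, truth, class) {
  pm <- if (inherits(pred, "label_map")) label_mask(pred, class) else pred == label_code(class)
  tm <- if (inherits(truth, "label_map")) label_mask(truth, class) else truth == label_code(class)
  if (!identical(dim(pm), dim(tm))) {
    stop("alignment error: rasters must have identical shape", call. = FALSE)
  }
  list(tp = sum(pm & tm), fp = sum(pm & !tm),
       fn = sum(!pm & tm), tn = sum(!pm & !tm))
}

#' COCO-style thresholds 0.50, 0.55, ..., 0.95
#' @return Numeric vector of the ten IoU matching thresholds.
#' @export
coco_iou_thresholds <- function() seq(0.5, 0.95, by = 0.05)

# greedy matching + all-point interpolated AP at one IoU threshold.
# preds sorted by (score desc, then larger best-IoU, then input order).
ap_at_threshold <- function(iou_mat, scores, n_truth, thr) {
  n_pred <- length(scores)
  if (n_truth == 0L) return(if (n_pred == 0L) NA_real_ else 0)
  if (n_pred == 0L) return(0)
  best_iou <- apply(iou_mat, 1, max)
  ord <- order(-scores, -best_iou, seq_len(n_pred))
  taken <- rep(FALSE, n_truth)
  tp <- logical(n_pred)
  for (k in seq_len(n_pred)) {
    i <- ord[k]
    ious <- iou_mat[i, ]
    ious[taken] <- -1
    j <- which.max(ious)
    if (ious[j] >= thr) {
      taken[j] <- TRUE
      tp[k] <- TRUE
    }
  }
  cum_tp <- cumsum(tp)
  precision <- cum_tp / seq_len(n_pred)
  recall <- cum_tp / n_truth
  # all-point interpolation: precision envelope, integrate over recall steps
  prec_env <- rev(cummax(rev(precision)))
  rec_prev <- c(0, recall[-n_pred])
  sum((recall - rec_prev) * prec_env)
}

#' Average precision for one class of instances
#'
#' Greedy matching of predictions (in descending score) to unmatched
#' ground-truth instances at each IoU threshold, then the area under the
#' all-point interpolated precision-recall curve; the class AP is the mean
#' over thresholds. With no ground truth and no predictions the AP is
#' undefined (`NA`); with predictions but no truth it is 0.
#'
#' @param preds List of scored [instance_mask()] predictions (one class).
#' @param truths List of ground-truth [instance_mask()] objects (same class).
#' @param iou_thresholds IoU matching thresholds; default COCO 0.5:0.95.
#' @return A tibble with one row per threshold (`iou_threshold`, `ap`) plus
#'   attribute `class_ap`, the mean over thresholds.
#' @export
average_precision <- function(preds, truths,
                              iou_thresholds = coco_iou_thresholds()) {
  cls <- unique(c(vapply(preds, `[[`, character(1), "class_label"),
                  vapply(truths, `[[`, character(1), "class_label")))
  if (length(cls) > 1L) {
    stop("all instances in one call must share one class; got: ",
         paste(cls, collapse = ", "), call. = FALSE)
  }
  n_pred <- length(preds); n_truth <- length(truths)
  iou_mat <- matrix(0, n_pred, n_truth)
  if (n_pred && n_truth) {
    for (i in seq_len(n_pred)) {
      for (j in seq_len(n_truth)) {
        iou_mat[i, j] <- instance_iou(preds[[i]], truths[[j]], "iou")
      }
    }
  }
  scores <- vapply(preds, `[[`, numeric(1), "score")
  ap <- vapply(iou_thresholds, function(thr) {
    ap_at_threshold(iou_mat, scores, n_truth, thr)
  }, numeric(1))
  out <- tibble::tibble(iou_threshold = iou_thresholds, ap = ap)
  attr(out, "class_ap") <- if (all(is.na(ap))) NA_real_ else mean(ap)
  out
}

#' Mean average precision over classes
#'
#' Splits predictions and truths by class, computes each class AP averaged
#' over the IoU thresholds, and returns their arithmetic mean. Classes with
#' neither truths nor predictions are recorded as undefined and excluded
#' from the mean.
#'
#' @param preds,truths Lists of [instance_mask()] objects (mixed classes).
#' @param classes Classes to evaluate; default the structure classes.
#' @param iou_thresholds IoU matching thresholds.
#' @return A list with `per_class` (tibble: class, ap, n_truth, n_pred),
#'   `n_classes` (classes with defined AP) and `map`.
#' @export
mean_average_precision <- function(preds, truths,
                                   classes = structure_classes(),
                                   iou_thresholds = coco_iou_thresholds()) {
  rows <- purrr::map_dfr(classes, function(cl) {
    p <- purrr::keep(preds, ~ .x$class_label == cl)
    t <- purrr::keep(truths, ~ .x$class_label == cl)
    ap <- attr(average_precision(p, t, iou_thresholds), "class_ap")
    tibble::tibble(class_label = cl, ap = ap,
                   n_truth = length(t), n_pred = length(p))
  })
  defined <- !is.na(rows$ap)
  list(per_class = rows,
       n_classes = sum(defined),
       map = if (any(defined)) mean(rows$ap[defined]) else NA_real_)
}
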