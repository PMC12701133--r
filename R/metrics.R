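# Detection metrics (IoU, per-class all-point-interpolated AP, AR, mAP over
# a COCO-style IoU threshold grid) and threshold-based classification
# metrics with a rank-statistic AUC.

#' Intersection over union of two boxes
#'
#' Boxes are `(x_min, y_min, x_max, y_max)` in half-open corner coordinates,
#' so areas are plain side products.
#'
#' @param box_a,box_b Numeric length-4 vectors.
#' @return IoU in `[0, 1]`; 0 for disjoint boxes.
#' @export
iou <- function(box_a, box_b) {
  box_a <- as.numeric(box_a)[1:4]; box_b <- as.numeric(box_b)[1:4]
  if (box_a[3L] <= box_a[1L] || box_a[4L] <= box_a[2L] ||
      box_b[3L] <= box_b[1L] || box_b[4L] <= box_b[2L]) {
    stop("degenerate box: non-positive width or height")
  }
  ix <- max(0, min(box_a[3L], box_b[3L]) - max(box_a[1L], box_b[1L]))
  iy <- max(0, min(box_a[4L], box_b[4L]) - max(box_a[2L], box_b[2L]))
  inter <- ix * iy
  un <- (box_a[3L] - box_a[1L]) * (box_a[4L] - box_a[2L]) +
    (box_b[3L] - box_b[1L]) * (box_b[4L] - box_b[2L]) - inter
  inter / un
}

# Greedy confidence-ordered matching of single-class detections to ground
# truth at one IoU threshold; ties in confidence keep input order.
match_detections <- function(det, gt, iou_threshold) {
  nd <- nrow(det)
  tp <- logical(nd)
  if (nd == 0L) return(tp)
  db <- corner_matrix(det)
  gb <- corner_matrix(gt)
  dimg <- det$image_id
  gimg <- gt$image_id
  used <- logical(nrow(gt))
  for (img in unique(dimg)) {
    di <- which(dimg == img)      # already in confidence order
    gi <- which(gimg == img)
    if (!length(gi)) next
    m <- iou_matrix(db[di, , drop = FALSE], gb[gi, , drop = FALSE])
    for (r in seq_along(di)) {
      avail <- which(!used[gi])
      if (!length(avail)) break
      j <- avail[which.max(m[r, avail])]
      if (m[r, j] >= iou_threshold) {
        tp[di[r]] <- TRUE
        used[gi[j]] <- TRUE
      }
    }
  }
  tp
}

#' Average precision at one IoU threshold
#'
#' Detections are sorted by decreasing confidence (ties broken by input
#' order) and matched greedily to unmatched ground truth of the same image
#' at the given IoU threshold; AP is the area under the all-point
#' interpolated precision-recall curve.
#'
#' @param detections Data frame with `image_id`, corner columns and
#'   `confidence` (one class).
#' @param gt Ground-truth data frame with `image_id` and corner columns
#'   (one class).
#' @param iou_threshold Matching IoU threshold.
#' @return List with `ap`, `precision`, `recall`, `n_gt` and `defined`
#'   (FALSE when there is neither ground truth nor detections).
#' @export
average_precision <- function(detections, gt, iou_threshold = 0.5) {
  n_gt <- if (is.null(gt)) 0L else nrow(gt)
  nd <- if (is.null(detections)) 0L else nrow(detections)
  if (n_gt == 0L && nd == 0L) {
    return(list(ap = NA_real_, precision = numeric(0), recall = numeric(0),
                n_gt = 0L, defined = FALSE))
  }
  if (nd == 0L) {
    return(list(ap = 0, precision = numeric(0), recall = numeric(0),
                n_gt = n_gt, defined = TRUE))
  }
  det <- detections[order(-detections$confidence), , drop = FALSE]
  tp <- if (n_gt) match_detections(det, gt, iou_threshold) else logical(nd)
  ctp <- cumsum(tp)
  prec <- ctp / seq_len(nd)
  rec <- if (n_gt) ctp / n_gt else rep(0, nd)
  # all-point interpolation: precision envelope from the right
  env <- rev(cummax(rev(prec)))
  ap <- if (n_gt) sum(diff(c(0, rec)) * env) else 0
  list(ap = ap, precision = prec, recall = rec, n_gt = n_gt, defined = TRUE)
}

#' Summarize detection performance
#'
#' COCO-style protocol: per class, AP and final recall are computed at every
#' IoU threshold in the grid and averaged; `ap` and `ar` then average over
#' classes, and `map` is the mean of the per-class threshold-averaged AP
#' values. `ap50` reports the plain AP at IoU 0.5 and `precision` the
#' detection precision at the operating score threshold (matching at IoU
#' 0.5). Classes absent from the ground truth are skipped.
#'
#' @param detections Data frame of detections with a `class` column.
#' @param gt Ground-truth data frame with a `class` column.
#' @param iou_thresholds Numeric grid (default 0.5 to 0.95 step 0.05).
#' @param operating_score Score threshold for the reported precision.
#' @return List of class `"detection_metrics"`.
#' @export
summarize_detection <- function(detections, gt,
                                iou_thresholds = seq(0.5, 0.95, by = 0.05),
                                operating_score = 0.5) {
  stopifnot(nrow(gt) >= 1L, !is.unsorted(iou_thresholds, strictly = TRUE))
  classes <- sort(unique(as.character(gt$class)))
  ap_class <- ar_class <- ap50_class <- stats::setNames(numeric(length(classes)),
                                                        classes)
  for (cl in classes) {
    dcl <- detections[detections$class == cl, , drop = FALSE]
    gcl <- gt[gt$class == cl, , drop = FALSE]
    aps <- recs <- numeric(length(iou_thresholds))
    for (ti in seq_along(iou_thresholds)) {
      r <- average_precision(dcl, gcl, iou_thresholds[ti])
      aps[ti] <- r$ap
      recs[ti] <- if (length(r$recall)) max(r$recall) else 0
    }
    ap_class[cl] <- mean(aps)
    ar_class[cl] <- mean(recs)
    ap50_class[cl] <- average_precision(dcl, gcl, 0.5)$ap
  }
  # operating-point precision: detections above the score cut, matched at 0.5
  dop <- detections[detections$confidence >= operating_score, , drop = FALSE]
  ntp <- 0L
  for (cl in classes) {
    dcl <- dop[dop$class == cl, , drop = FALSE]
    gcl <- gt[gt$class == cl, , drop = FALSE]
    if (nrow(dcl)) {
      dcl <- dcl[order(-dcl$confidence), , drop = FALSE]
      ntp <- ntp + sum(match_detections(dcl, gcl, 0.5))
    }
  }
  structure(list(ap_per_class = ap_class, ar_per_class = ar_class,
                 ap50_per_class = ap50_class,
                 ap = mean(ap_class), ar = mean(ar_class),
                 map = mean(ap_class), ap50 = mean(ap50_class),
                 precision = if (nrow(dop)) ntp / nrow(dop) else NA_real_,
                 iou_thresholds = iou_thresholds),
            class = "detection_metrics")
}

#' @export
print.detection_metrics <- function(x, ...) {
  cat(sprintf("Detection metrics over IoU %.2f-%.2f:\n",
              min(x$iou_thresholds), max(x$iou_thresholds)))
  cat(sprintf("  AP %.3f  AR %.3f  mAP %.3f  AP@0.5 %.3f  precision %.3f\n",
              x$ap, x$ar, x$map, x$ap50, x$precision))
  for (cl in names(x$ap_per_class)) {
    cat(sprintf("  %-6s AP %.3f  AR %.3f\n", cl, x$ap_per_class[cl],
                x$ar_per_class[cl]))
  }
  invisible(x)
}

#' Threshold-based classification metrics
#'
#' Confusion counts at the given probability threshold; AUC is the
#' Mann-Whitney rank statistic (probability that a random positive outranks
#' a random negative, ties counted one half). ROC and precision-recall
#' arrays over all score cutoffs are included.
#'
#' @param labels Binary 0/1 vector.
#' @param scores Numeric scores in `[0, 1]`.
#' @param threshold Decision threshold for the hard label.
#' @return List of class `"classification_metrics"`.
#' @export
classification_metrics <- function(labels, scores, threshold = 0.5) {
  stopifnot(length(labels) == length(scores), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) {
    stop("AUC undefined: labels contain a single class")
  }
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0); fn <- sum(pred == 0 & labels == 1)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- tp / (tp + fn)
  f1 <- if (!is.na(precision) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  r <- rank(scores)   # average ranks handle ties as 1/2
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  cuts <- sort(unique(scores), decreasing = TRUE)
  roc <- t(vapply(c(Inf, cuts), function(ct) {
    c(fpr = sum(scores >= ct & labels == 0) / n0,
      tpr = sum(scores >= ct & labels == 1) / n1)
  }, c(fpr = 0, tpr = 0)))
  pr <- t(vapply(cuts, function(ct) {
    p <- sum(scores >= ct)
    c(recall = sum(scores >= ct & labels == 1) / n1,
      precision = if (p) sum(scores >= ct & labels == 1) / p else 1)
  }, c(recall = 0, precision = 0)))
  structure(list(accuracy = (tp + tn) / length(labels), precision = precision,
                 recall = recall, f1 = f1, auc = auc,
                 confusion = c(TP = tp, FP = fp, TN = tn, FN = fn),
                 roc = as.data.frame(roc), pr = as.data.frame(pr),
                 threshold = threshold),
            class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf(paste0("Classification at threshold %.2f: accuracy %.3f, ",
                     "precision %.3f, recall %.3f, F1 %.3f, AUC %.3f\n"),
              x$threshold, x$accuracy, x$precision, x$recall, x$f1, x$auc))
  cat(sprintf("  confusion: TP %d  FP %d  TN %d  FN %d\n",
              x$confusion["TP"], x$confusion["FP"], x$confusion["TN"],
              x$confusion["FN"]))
  invisible(x)
}
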