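# Detection evaluation: precision/recall from confusion counts, greedy
# score-descending matching at an IoU threshold, COCO-style 101-point
# interpolated average precision, and mAP@50 / mAP@50:95. Evaluation
# matching always uses plain IoU (the community convention), never the
# training-time IACD-IoU.

#' Precision and recall from confusion counts
#'
#' `P = TP / (TP + FP)`, `R = TP / (TP + FN)`; a zero denominator returns 0.
#'
#' @param TP,FP,FN nonnegative counts.
#' @return named numeric vector `c(precision, recall)`.
#' @examples
#' precision_recall(TP = 9, FP = 1, FN = 1)   # 0.9, 0.9
#' @export
precision_recall <- function(TP, FP, FN) {
  stopifnot(TP >= 0, FP >= 0, FN >= 0)
  p <- if (TP + FP == 0) 0 else TP / (TP + FP)
  r <- if (TP + FN == 0) 0 else TP / (TP + FN)
  c(precision = p, recall = r)
}

# greedy score-descending matching of one image's detections to its gts at
# a fixed IoU threshold; returns logical TP flag per detection (score order)
match_greedy <- function(det, gt, iou_threshold) {
  nd <- nrow(det)
  if (nd == 0) return(logical(0))
  ord <- order(-det$score)
  tp <- logical(nd)
  ng <- nrow(gt)
  if (ng == 0) return(tp)
  dm <- as.matrix(det[, c("cx", "cy", "w", "h")])
  gm <- as.matrix(gt[, c("cx", "cy", "w", "h")])
  iou_full <- matrix(iou_mat(dm[rep(seq_len(nd), times = ng), , drop = FALSE],
                             gm[rep(seq_len(ng), each = nd), , drop = FALSE]),
                     nd, ng)
  used <- logical(ng)
  for (i in ord) {
    ious <- iou_full[i, ]
    ious[used] <- -1
    j <- which.max(ious)
    if (length(j) && ious[j] >= iou_threshold) {
      tp[i] <- TRUE
      used[j] <- TRUE
    }
  }
  tp
}

#' Average precision at one IoU threshold
#'
#' Detections across images are pooled, matched greedily in descending
#' score order (each ground truth matched at most once, within its image
#' and class), and the area under the precision-recall curve is taken with
#' 101-point interpolation (COCO convention).
#'
#' @param dets data frame with `image_id, class_id, cx, cy, w, h, score`.
#' @param gts data frame with `image_id, class_id, cx, cy, w, h`.
#' @param iou_threshold matching threshold.
#' @return AP in `[0, 1]` (0 when there are no ground truths).
#' @export
average_precision <- function(dets, gts, iou_threshold = 0.5) {
  n_gt <- nrow(gts)
  if (n_gt == 0) return(0)
  if (nrow(dets) == 0) return(0)
  tp_all <- logical(nrow(dets))
  key <- interaction(dets$image_id, dets$class_id, drop = TRUE)
  for (k in levels(key)) {
    sel <- which(key == k)
    d1 <- dets[sel, , drop = FALSE]
    g1 <- gts[gts$image_id == d1$image_id[1] &
                gts$class_id == d1$class_id[1], , drop = FALSE]
    tp_all[sel] <- match_greedy(d1, g1, iou_threshold)
  }
  ord <- order(-dets$score)
  tp <- cumsum(tp_all[ord])
  fp <- cumsum(!tp_all[ord])
  recall <- tp / n_gt
  precision <- tp / (tp + fp)
  # 101-point interpolation: p_interp(r) = max precision at recall >= r
  p_env <- rev(cummax(rev(precision)))
  rgrid <- seq(0, 1, by = 0.01)
  pi_ <- vapply(rgrid, function(r) {
    i <- which(recall >= r)
    if (length(i)) p_env[i[1]] else 0
  }, 1.0)
  mean(pi_)
}

#' mAP at 0.5 and averaged over 0.50:0.95
#'
#' Mean AP over classes at IoU 0.5, and the mean over the ten thresholds
#' 0.50, 0.55, ..., 0.95.
#'
#' @param dets,gts as in [average_precision()].
#' @return named vector `c(map50, map5095)`.
#' @export
map_range <- function(dets, gts) {
  classes <- sort(unique(gts$class_id))
  if (!length(classes)) return(c(map50 = 0, map5095 = 0))
  thrs <- seq(0.5, 0.95, by = 0.05)
  ap_mat <- sapply(thrs, function(t)
    vapply(classes, function(cl)
      average_precision(dets[dets$class_id == cl, , drop = FALSE],
                        gts[gts$class_id == cl, , drop = FALSE], t), 1.0))
  ap_mat <- matrix(ap_mat, nrow = length(classes))
  c(map50 = mean(ap_mat[, 1]), map5095 = mean(ap_mat))
}

#' Frames per second from stage timings
#' @param t_pre,t_inf,t_post per-frame stage times in milliseconds.
#' @return `1000 / (t_pre + t_inf + t_post)`.
#' @examples
#' fps_from_timings(2, 5, 1)   # 125
#' @export
fps_from_timings <- function(t_pre, t_inf, t_post) {
  stopifnot(t_pre >= 0, t_inf >= 0, t_post >= 0)
  tot <- t_pre + t_inf + t_post
  if (tot == 0) stop("total time must be positive")
  1000 / tot
}
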