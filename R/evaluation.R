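#' Detection and count evaluation metrics
#'
#' Greedy IoU matching of predicted and ground-truth boxes, precision /
#' recall / F1, all-point-interpolated average precision (AP, mAP over
#' classes) at an IoU threshold, and count-regression metrics (R2, RMSE,
#' relative RMSE).
#'
#' @name evaluation
NULL

box_cols <- c("x_min", "y_min", "x_max", "y_max")

assert_boxes <- function(boxes, what = "box") {
  if (nrow(boxes)) {
    if (any(boxes$x_max <= boxes$x_min) || any(boxes$y_max <= boxes$y_min)) {
      stop("malformed ", what, ": non-positive extent", call. = FALSE)
    }
  }
  invisible(boxes)
}

#' Intersection-over-union of two sets of pixel boxes
#'
#' Boxes are half-open rectangles `(x_min, y_min, x_max, y_max)`.
#'
#' @param a,b Data frames of boxes.
#' @return `nrow(a)` x `nrow(b)` matrix of IoU values.
#' @export
box_iou <- function(a, b) {
  out <- matrix(0, nrow(a), nrow(b))
  for (j in seq_len(nrow(b))) {
    ix <- pmax(0, pmin(a$x_max, b$x_max[j]) - pmax(a$x_min, b$x_min[j]))
    iy <- pmax(0, pmin(a$y_max, b$y_max[j]) - pmax(a$y_min, b$y_min[j]))
    inter <- ix * iy
    area_a <- (a$x_max - a$x_min) * (a$y_max - a$y_min)
    area_b <- (b$x_max[j] - b$x_min[j]) * (b$y_max[j] - b$y_min[j])
    out[, j] <- inter / (area_a + area_b - inter)
  }
  out
}

#' Match detections to ground truth
#'
#' Greedy one-to-one matching: predictions are visited in descending
#' confidence order and each takes the still-unmatched ground-truth box of
#' highest IoU, provided IoU >= `iou_threshold`. Remaining predictions are
#' false positives, remaining ground truths false negatives.
#'
#' @param preds Data frame of pixel boxes with a `confidence` column
#'   (missing confidences default to 1).
#' @param gts Data frame of ground-truth pixel boxes.
#' @param iou_threshold Matching threshold (default 0.5).
#' @return Object of class `match_result`: list with `TP`, `FP`, `FN` and
#'   `pairs` (data frame `pred_idx`, `gt_idx`, `iou`).
#' @export
match_detections <- function(preds, gts, iou_threshold = 0.5) {
  assert_boxes(preds, "prediction"); assert_boxes(gts, "ground truth")
  conf <- if ("confidence" %in% names(preds)) preds$confidence else
    rep(1, nrow(preds))
  ord <- order(-conf)
  taken <- rep(FALSE, nrow(gts))
  pairs <- data.frame(pred_idx = integer(0), gt_idx = integer(0),
                      iou = numeric(0))
  if (nrow(preds) && nrow(gts)) {
    iou <- box_iou(preds, gts)
    for (i in ord) {
      cand <- which(!taken & iou[i, ] >= iou_threshold)
      if (length(cand)) {
        j <- cand[which.max(iou[i, cand])]
        taken[j] <- TRUE
        pairs <- rbind(pairs, data.frame(pred_idx = i, gt_idx = j,
                                         iou = iou[i, j]))
      }
    }
  }
  structure(list(TP = nrow(pairs), FP = nrow(preds) - nrow(pairs),
                 FN = nrow(gts) - nrow(pairs), pairs = pairs),
            class = "match_result")
}

#' Precision, recall and F1 from a match result
#'
#' P = TP/(TP+FP), R = TP/(TP+FN), F1 = 2PR/(P+R); any 0/0 is defined
#' as 0 so batch evaluation never fails.
#'
#' @param match A `match_result`, or a list with `TP`, `FP`, `FN`.
#' @return Named numeric vector `c(P =, R =, F1 =)`.
#' @export
detection_metrics <- function(match) {
  safe <- function(num, den) if (den > 0) num / den else 0
  P <- safe(match$TP, match$TP + match$FP)
  R <- safe(match$TP, match$TP + match$FN)
  F1 <- if (P + R > 0) 2 * P * R / (P + R) else 0
  c(P = P, R = R, F1 = F1)
}

#' Average precision at an IoU threshold
#'
#' Sweeps the precision-recall curve over predictions sorted by descending
#' confidence (greedy one-to-one IoU matching decides which predictions are
#' true positives) and integrates the all-point precision envelope:
#' AP = sum over recall steps of (R_k - R_{k-1}) * max precision at
#' recall >= R_k.
#'
#' @param preds Data frame of pixel boxes with `confidence`.
#' @param gts Data frame of ground-truth pixel boxes.
#' @param iou_threshold Matching threshold (default 0.5).
#' @return AP in \[0, 1\] (0 when there is no ground truth).
#' @export
average_precision <- function(preds, gts, iou_threshold = 0.5) {
  assert_boxes(preds, "prediction"); assert_boxes(gts, "ground truth")
  n_gt <- nrow(gts)
  if (n_gt == 0) return(0)
  if (nrow(preds) == 0) return(0)
  conf <- if ("confidence" %in% names(preds)) preds$confidence else
    rep(1, nrow(preds))
  ord <- order(-conf)
  iou <- box_iou(preds, gts)
  taken <- rep(FALSE, n_gt)
  tp <- logical(length(ord))
  for (k in seq_along(ord)) {
    i <- ord[k]
    cand <- which(!taken & iou[i, ] >= iou_threshold)
    if (length(cand)) {
      j <- cand[which.max(iou[i, cand])]
      taken[j] <- TRUE
      tp[k] <- TRUE
    }
  }
  cum_tp <- cumsum(tp)
  precision <- cum_tp / seq_along(tp)
  recall <- cum_tp / n_gt
  # all-point interpolation: running max of precision from the right
  env <- rev(cummax(rev(precision)))
  rec_prev <- c(0, recall[-length(recall)])
  sum((recall - rec_prev) * env)
}

#' Mean average precision over classes
#'
#' @param preds Data frame of pixel boxes with `confidence` and `class_id`.
#' @param gts Data frame of ground-truth pixel boxes with `class_id`.
#' @param classes Class universe; defaults to the classes present in `gts`.
#' @param iou_threshold Matching threshold.
#' @return List with `AP_per_class` (named) and `mAP` (their mean).
#' @export
map_over_classes <- function(preds, gts, classes = NULL,
                             iou_threshold = 0.5) {
  if (is.null(classes)) classes <- sort(unique(gts$class_id))
  pc <- if ("class_id" %in% names(preds)) preds$class_id else
    rep(classes[1], nrow(preds))
  if (nrow(preds) && !all(pc %in% classes)) {
    stop("prediction class outside the class universe", call. = FALSE)
  }
  ap <- vapply(classes, function(cl) {
    average_precision(preds[pc == cl, , drop = FALSE],
                      gts[gts$class_id == cl, , drop = FALSE],
                      iou_threshold)
  }, numeric(1))
  names(ap) <- classes
  list(AP_per_class = ap, mAP = mean(ap))
}

#' Count-regression metrics
#'
#' For true per-image counts Y and predicted counts X:
#' R2 = 1 - sum((Y-X)^2)/sum((Y-mean(Y))^2), RMSE = sqrt(mean((Y-X)^2)),
#' and RRMSE = RMSE / mean(Y) expressed as a percentage.
#'
#' @param Y True counts (length >= 2, not all equal).
#' @param X Predicted counts, same length.
#' @return Named numeric vector `c(R2 =, RMSE =, RRMSE =)` with RRMSE
#'   in percent.
#' @export
count_metrics <- function(Y, X) {
  if (length(Y) != length(X)) stop("length mismatch", call. = FALSE)
  if (length(Y) < 2) stop("need at least two images", call. = FALSE)
  sst <- sum((Y - mean(Y))^2)
  if (sst == 0) stop("all true counts equal: R2 undefined", call. = FALSE)
  sse <- sum((Y - X)^2)
  rmse <- sqrt(sse / length(Y))
  c(R2 = 1 - sse / sst, RMSE = rmse, RRMSE = 100 * rmse / mean(Y))
}

#' Score a directory of YOLO prediction files against labels
#'
#' Pairs prediction and ground-truth TXT files by stem, converts normalized
#' boxes to a common pixel frame, and returns pooled detection metrics plus
#' per-image counts.
#'
#' @param pred_paths,gt_paths Parallel vectors of YOLO TXT files
#'   (predictions may carry a sixth confidence column).
#' @param image_sizes Matrix or data frame with per-image `height_px`,
#'   `width_px`.
#' @param iou_threshold Matching threshold (default 0.5).
#' @return List with pooled `P`, `R`, `F1`, `mAP` and the per-image count
#'   vectors `Y` (truth) and `X` (predicted).
#' @export
score_yolo_files <- function(pred_paths, gt_paths, image_sizes,
                             iou_threshold = 0.5) {
  stopifnot(length(pred_paths) == length(gt_paths))
  image_sizes <- as.data.frame(image_sizes)
  TP <- FP <- FN <- 0
  all_preds <- list(); all_gts <- list()
  Y <- X <- integer(length(gt_paths))
  offset <- 0
  for (i in seq_along(gt_paths)) {
    H <- image_sizes[i, 1]; W <- image_sizes[i, 2]
    gt <- yolo_to_pixel(read_yolo_labels(gt_paths[i]), H, W)
    pr <- yolo_to_pixel(read_yolo_labels(pred_paths[i]), H, W)
    m <- match_detections(pr, gt, iou_threshold)
    TP <- TP + m$TP; FP <- FP + m$FP; FN <- FN + m$FN
    Y[i] <- nrow(gt); X[i] <- nrow(pr)
    # offset boxes into a disjoint frame so AP pools across images
    shift <- function(b) {
      if (!"confidence" %in% names(b)) b$confidence <- rep(1, nrow(b))
      b$x_min <- b$x_min + offset; b$x_max <- b$x_max + offset
      b
    }
    all_preds[[i]] <- shift(pr); all_gts[[i]] <- shift(gt)
    offset <- offset + W + 10
  }
  pooled_p <- do.call(rbind, all_preds)
  pooled_g <- do.call(rbind, all_gts)
  pm <- detection_metrics(list(TP = TP, FP = FP, FN = FN))
  mAP <- map_over_classes(pooled_p, pooled_g,
                          iou_threshold = iou_threshold)$mAP
  list(P = unname(pm["P"]), R = unname(pm["R"]), F1 = unname(pm["F1"]),
       mAP = mAP, Y = Y, X = X)
}
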