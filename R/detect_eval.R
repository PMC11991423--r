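#' Intersection over union of two boxes
#'
#' Boxes are length-4 numeric vectors, either corner form
#' `c(x0, y0, x1, y1)` or normalized center form `c(xc, yc, w, h)`.
#' Degenerate (zero-area) boxes have IoU 0 by definition.
#'
#' @param boxA,boxB Numeric length-4 vectors.
#' @param form `"corner"` or `"center"`.
#' @return IoU in `[0, 1]`.
#' @export
#' @examples
#' iou(c(0, 0, 2, 2), c(1, 0, 3, 2))   # 2/6
iou <- function(boxA, boxB, form = c("corner", "center")) {
  form <- match.arg(form)
  if (form == "center") {
    boxA <- center_to_corner(boxA)
    boxB <- center_to_corner(boxB)
  }
  ax0 <- boxA[1]; ay0 <- boxA[2]; ax1 <- boxA[3]; ay1 <- boxA[4]
  bx0 <- boxB[1]; by0 <- boxB[2]; bx1 <- boxB[3]; by1 <- boxB[4]
  areaA <- max(0, ax1 - ax0) * max(0, ay1 - ay0)
  areaB <- max(0, bx1 - bx0) * max(0, by1 - by0)
  if (areaA == 0 || areaB == 0) return(0)
  iw <- min(ax1, bx1) - max(ax0, bx0)
  ih <- min(ay1, by1) - max(ay0, by0)
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  inter / (areaA + areaB - inter)
}

#' @rdname iou
#' @param box Center-form box `c(xc, yc, w, h)`.
#' @export
center_to_corner <- function(box) {
  c(box[1] - box[3] / 2, box[2] - box[4] / 2,
    box[1] + box[3] / 2, box[2] + box[4] / 2)
}

#' Match detections to ground truth at an IoU threshold
#'
#' Pascal-VOC style greedy matching: detections are processed in
#' descending confidence (ties broken by higher IoU with their best
#' remaining truth, then input order); each ground-truth box can be
#' consumed at most once; a match requires the same class and IoU at or
#' above the threshold (`boundary = "geq"`, the default reading of
#' "exceeds 0.5"; use `"gt"` for a strict inequality). Unmatched
#' detections are false positives, unmatched truths false negatives.
#'
#' @param preds Data frame with columns `class_id, confidence, xc, yc, w, h`
#'   (see [read_detections()]).
#' @param truth Data frame with columns `class_id, xc, yc, w, h`
#'   (see [read_yolo_labels()]).
#' @param iou_threshold Overlap threshold in (0, 1).
#' @param boundary `"geq"` or `"gt"`.
#' @return A list of class `match_result`: `per_class` data frame with
#'   `class_id, tp, fp, fn`; `matches` data frame (`pred` row, `truth` row,
#'   `iou`); logical `pred_tp` aligned with `preds` in confidence order
#'   along with that order.
#' @export
match_detections <- function(preds, truth, iou_threshold = 0.5,
                             boundary = c("geq", "gt")) {
  boundary <- match.arg(boundary)
  stopifnot(iou_threshold > 0, iou_threshold < 1)
  ok <- function(v) if (boundary == "geq") v >= iou_threshold else v > iou_threshold
  np <- nrow(preds); nt <- nrow(truth)
  pbox <- as.matrix(preds[, c("xc", "yc", "w", "h"), drop = FALSE])
  tbox <- as.matrix(truth[, c("xc", "yc", "w", "h"), drop = FALSE])
  # confidence-descending processing order; ties broken by the prediction's
  # best IoU against any same-class truth, then by input order
  best_iou <- if (np > 0) vapply(seq_len(np), function(p) {
    cand <- which(truth$class_id == preds$class_id[p])
    if (length(cand) == 0L) return(0)
    max(vapply(cand, function(t) iou(pbox[p, ], tbox[t, ], form = "center"),
               numeric(1)))
  }, numeric(1)) else numeric(0)
  ord <- if (np > 0) order(-preds$confidence, -best_iou, seq_len(np)) else integer(0)
  truth_used <- rep(FALSE, nt)
  pred_tp <- rep(FALSE, np)
  matches <- list()
  for (p in ord) {
    cand <- which(!truth_used & truth$class_id == preds$class_id[p])
    if (length(cand) == 0L) next
    ious <- vapply(cand, function(t) iou(pbox[p, ], tbox[t, ], form = "center"),
                   numeric(1))
    best <- which.max(ious)
    if (ok(ious[best])) {
      t <- cand[best]
      truth_used[t] <- TRUE
      pred_tp[p] <- TRUE
      matches[[length(matches) + 1L]] <-
        data.frame(pred = p, truth = t, iou = ious[best])
    }
  }
  classes <- sort(unique(c(preds$class_id, truth$class_id)))
  per_class <- do.call(rbind, lapply(classes, function(cl) {
    tp <- sum(pred_tp & preds$class_id == cl)
    data.frame(class_id = cl, tp = tp,
               fp = sum(preds$class_id == cl) - tp,
               fn = sum(truth$class_id == cl) - tp)
  }))
  if (is.null(per_class)) {
    per_class <- data.frame(class_id = integer(0), tp = integer(0),
                            fp = integer(0), fn = integer(0))
  }
  structure(list(per_class = per_class,
                 matches = if (length(matches)) do.call(rbind, matches)
                           else data.frame(pred = integer(0), truth = integer(0),
                                           iou = numeric(0)),
                 pred_tp = pred_tp, order = ord,
                 iou_threshold = iou_threshold),
            class = "match_result")
}

#' Precision and recall over a confidence sweep
#'
#' Evaluates precision `TP/(TP+FP)` and recall `TP/(TP+FN)` at every
#' distinct confidence cut (detections with confidence at or above the cut
#' kept), pooled over classes. Matching is re-derived once at full depth
#' and truncated per cut, so recall is non-decreasing along the sweep.
#'
#' @inheritParams match_detections
#' @return Data frame with columns `confidence, tp, fp, fn, precision,
#'   recall`, ordered by decreasing confidence cut.
#' @export
pr_curve <- function(preds, truth, iou_threshold = 0.5) {
  if (nrow(truth) == 0L) {
    stop("recall is undefined for an empty ground-truth set", call. = FALSE)
  }
  m <- match_detections(preds, truth, iou_threshold)
  conf <- preds$confidence[m$order]
  tp_flags <- m$pred_tp[m$order]
  cuts <- sort(unique(preds$confidence), decreasing = TRUE)
  nt <- nrow(truth)
  out <- lapply(cuts, function(cv) {
    keep <- conf >= cv
    tp <- sum(tp_flags[keep]); fp <- sum(keep) - tp
    data.frame(confidence = cv, tp = tp, fp = fp, fn = nt - tp,
               precision = if (tp + fp > 0) tp / (tp + fp) else 1,
               recall = tp / nt)
  })
  do.call(rbind, out)
}

#' Average precision by all-point interpolation
#'
#' Area under the precision envelope as a function of recall: at each
#' achieved recall level the precision is replaced by the maximum precision
#' at any equal-or-higher recall, and the envelope is integrated over
#' recall increments (no 11-point sampling).
#'
#' @param pr A data frame with `precision` and `recall` columns
#'   (e.g. from [pr_curve()]), or a ranked logical vector of per-detection
#'   TP flags plus `n_truth`.
#' @param n_truth Required when `pr` is a logical TP vector.
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(pr, n_truth = NULL) {
  if (is.logical(pr)) {
    stopifnot(!is.null(n_truth), n_truth > 0)
    tp_cum <- cumsum(pr)
    fp_cum <- cumsum(!pr)
    rec <- tp_cum / n_truth
    prec <- tp_cum / (tp_cum + fp_cum)
  } else {
    rec <- pr$recall
    prec <- pr$precision
    o <- order(rec, -prec)
    rec <- rec[o]; prec <- prec[o]
  }
  if (length(rec) == 0L || max(rec) == 0) return(0)
  r <- c(0, rec)
  p <- c(0, prec)
  # precision envelope: running max from the right
  for (i in (length(p) - 1L):1L) p[i] <- max(p[i], p[i + 1L])
  sum(diff(r) * p[-1L])
}

#' Mean average precision at IoU 0.5 (mAP@0.5)
#'
#' Per-class AP from confidence-ranked matching, averaged (unweighted)
#' over the classes present in the ground truth. A class with truths but
#' no true positives contributes AP 0.
#'
#' @inheritParams match_detections
#' @return A list with `map`, and `per_class` (class_id, ap, precision at
#'   full depth, counts).
#' @export
map50 <- function(preds, truth, iou_threshold = 0.5) {
  if (nrow(truth) == 0L) stop("empty ground-truth set", call. = FALSE)
  m <- match_detections(preds, truth, iou_threshold)
  classes <- sort(unique(truth$class_id))
  rows <- lapply(classes, function(cl) {
    nt <- sum(truth$class_id == cl)
    sel <- m$order[preds$class_id[m$order] == cl]
    flags <- m$pred_tp[sel]
    ap <- if (length(flags)) average_precision(flags, n_truth = nt) else 0
    tp <- sum(flags); fp <- length(flags) - tp
    data.frame(class_id = cl, n_truth = nt, tp = tp, fp = fp,
               precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               ap = ap)
  })
  per_class <- do.call(rbind, rows)
  list(map = mean(per_class$ap), per_class = per_class)
}
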