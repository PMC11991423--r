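# small constructors for readable cases
det <- function(class_id, confidence, xc, yc, w, h) {
  data.frame(class_id = as.integer(class_id), confidence = confidence,
             xc = xc, yc = yc, w = w, h = h)
}
tru <- function(class_id, xc, yc, w, h) {
  data.frame(class_id = as.integer(class_id), xc = xc, yc = yc, w = w, h = h)
}

test_that("iou matches hand-computed areas", {
  expect_equal(iou(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1)
  expect_equal(iou(c(0, 0, 1, 1), c(2, 2, 3, 3)), 0)
  expect_equal(iou(c(0, 0, 2, 2), c(1, 0, 3, 2)), 2 / 6)
  # boxes touching along an edge do not intersect
  expect_equal(iou(c(0, 0, 1, 1), c(1, 0, 2, 1)), 0)
  # degenerate zero-area box
  expect_equal(iou(c(0, 0, 0, 1), c(0, 0, 1, 1)), 0)
  # center form agrees with the equivalent corner form
  expect_equal(iou(c(0.5, 0.5, 0.2, 0.2), c(0.55, 0.5, 0.2, 0.2), form = "center"),
               iou(c(0.4, 0.4, 0.6, 0.6), c(0.45, 0.4, 0.65, 0.6)))
})

test_that("perfect predictions give FP = 0 and precision 1", {
  truth <- tru(c(0, 1, 2), c(0.2, 0.5, 0.8), c(0.2, 0.5, 0.8), 0.1, 0.1)
  preds <- cbind(truth, confidence = c(0.9, 0.8, 0.7))
  m <- match_detections(preds, truth)
  expect_equal(sum(m$per_class$fp), 0)
  expect_equal(sum(m$per_class$tp), 3)
  expect_equal(sum(m$per_class$fn), 0)
  r <- map50(preds, truth)
  expect_equal(r$map, 1)
  expect_true(all(r$per_class$precision == 1))
  expect_equal(r$per_class$ap, rep(1, 3))
})

test_that("no predictions means zero recall; all-wrong means zero precision", {
  truth <- tru(c(0, 0), c(0.3, 0.7), 0.5, 0.1, 0.1)
  none <- det(integer(0), numeric(0), numeric(0), numeric(0), numeric(0), numeric(0))
  m <- match_detections(none, truth)
  expect_equal(sum(m$per_class$tp), 0)
  expect_equal(sum(m$per_class$fn), 2)
  wrong <- det(c(0, 0), c(0.9, 0.8), c(0.1, 0.9), 0.9, 0.05, 0.05)
  pr <- pr_curve(wrong, truth)
  expect_true(all(pr$precision == 0))
  expect_equal(map50(wrong, truth)$map, 0)
})

test_that("sub-threshold overlap counts as a false positive", {
  truth <- tru(c(0, 0), c(0.30, 0.70), 0.5, 0.2, 0.2)
  # pred 1 hits truth 1 exactly; pred 2 overlaps truth 2 at IoU 1/3;
  # pred 3 is far away
  preds <- det(c(0, 0, 0), c(0.9, 0.8, 0.7),
               c(0.30, 0.70 + 0.1, 0.95), c(0.5, 0.5, 0.95),
               c(0.2, 0.2, 0.05), c(0.2, 0.2, 0.05))
  expect_equal(iou(c(preds$xc[2], preds$yc[2], 0.2, 0.2),
                   c(0.70, 0.5, 0.2, 0.2), form = "center"), 1 / 3,
               tolerance = 1e-9)
  m <- match_detections(preds, truth, iou_threshold = 0.5)
  expect_equal(m$per_class$tp, 1)
  expect_equal(m$per_class$fp, 2)
  expect_equal(m$per_class$fn, 1)
  # at threshold 1/3 with geq semantics the second pred becomes a TP
  m2 <- match_detections(preds, truth, iou_threshold = 1 / 3)
  expect_equal(m2$per_class$tp, 2)
  m3 <- match_detections(preds, truth, iou_threshold = 1 / 3, boundary = "gt")
  expect_equal(m3$per_class$tp, 1)
})

test_that("class labels must agree for a true positive", {
  truth <- tru(1, 0.5, 0.5, 0.2, 0.2)
  preds <- det(2, 0.9, 0.5, 0.5, 0.2, 0.2)
  m <- match_detections(preds, truth)
  expect_equal(m$per_class$tp, c(0, 0))
  expect_equal(sum(m$per_class$fp), 1)
  expect_equal(sum(m$per_class$fn), 1)
})

test_that("counting identities hold at every confidence cut", {
  set.seed(23)
  truth <- tru(sample(0:1, 6, TRUE), stats::runif(6, 0.2, 0.8),
               stats::runif(6, 0.2, 0.8), 0.08, 0.08)
  # jittered copies plus noise detections
  preds <- rbind(
    cbind(truth[1:4, ], confidence = stats::runif(4, 0.5, 1)),
    det(sample(0:1, 3, TRUE), stats::runif(3), stats::runif(3, 0.2, 0.8),
        stats::runif(3, 0.2, 0.8), 0.05, 0.05))
  pr <- pr_curve(preds, truth, iou_threshold = 0.5)
  for (k in seq_len(nrow(pr))) {
    expect_equal(pr$tp[k] + pr$fn[k], nrow(truth))
    n_kept <- sum(preds$confidence >= pr$confidence[k])
    expect_equal(pr$tp[k] + pr$fp[k], n_kept)
  }
  expect_true(all(diff(pr$recall) >= 0))
  expect_error(pr_curve(preds, truth[0, ]), "empty")
})

test_that("PR points and AP match the brute-force enumeration oracle", {
  # ranked case: TP, FP, TP over 2 truths
  flags <- c(TRUE, FALSE, TRUE)
  expect_equal(average_precision(flags, n_truth = 2), oracle_ap(flags, 2))
  expect_equal(average_precision(flags, n_truth = 2), 5 / 6)

  # a 4-prediction hand case swept over all cuts
  truth <- tru(c(0, 0, 0), c(0.2, 0.5, 0.8), 0.5, 0.1, 0.1)
  preds <- det(c(0, 0, 0, 0), c(0.9, 0.7, 0.6, 0.4),
               c(0.2, 0.9, 0.5, 0.8), c(0.5, 0.1, 0.5, 0.5),
               c(0.1, 0.1, 0.1, 0.1), c(0.1, 0.1, 0.1, 0.1))
  pr <- pr_curve(preds, truth)
  want <- oracle_pr_points(c(TRUE, FALSE, TRUE, TRUE), 3)
  expect_equal(pr$precision, want$precision)
  expect_equal(pr$recall, want$recall)
  expect_equal(average_precision(pr), oracle_ap(c(TRUE, FALSE, TRUE, TRUE), 3))

  # randomized agreement between implementation and oracle
  set.seed(29)
  for (i in 1:50) {
    n <- sample(1:12, 1)
    flags <- stats::runif(n) > 0.5
    nt <- sum(flags) + sample(0:3, 1)
    if (nt == 0) nt <- 1
    expect_equal(average_precision(flags, n_truth = nt), oracle_ap(flags, nt))
  }
})

test_that("AP is monotone non-increasing in the IoU threshold", {
  set.seed(33)
  truth <- tru(rep(0, 5), seq(0.1, 0.9, 0.2), 0.5, 0.12, 0.12)
  preds <- det(rep(0, 5), stats::runif(5, 0.5, 1),
               seq(0.1, 0.9, 0.2) + stats::runif(5, 0, 0.05), 0.5, 0.12, 0.12)
  aps <- vapply(c(0.3, 0.5, 0.7, 0.9),
                function(th) map50(preds, truth, iou_threshold = th)$map,
                numeric(1))
  expect_true(all(diff(aps) <= 1e-12))
})

test_that("mAP is invariant to permutations with deterministic tie-breaks", {
  truth <- tru(c(0, 1), c(0.3, 0.7), 0.5, 0.2, 0.2)
  preds <- det(c(0, 1, 0), c(0.8, 0.8, 0.8),
               c(0.3, 0.7, 0.31), c(0.5, 0.5, 0.5),
               c(0.2, 0.2, 0.2), c(0.2, 0.2, 0.2))
  m1 <- map50(preds, truth)$map
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    expect_equal(map50(preds[perm, ], truth)$map, m1)
  }
})
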