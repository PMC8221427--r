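test_that("a perfect single detection is a true positive with no errors", {
  gt <- boxes(0, 0, 10, 10)
  det <- dplyr::mutate(gt, score = 0.9)
  m <- match_detections(det, gt, "default")
  expect_equal(c(m$tp, m$fp, m$fn), c(1, 0, 0))
  expect_equal(as.character(m$detections$verdict), "TP")
  expect_true(all(m$ground_truth$matched))
})

test_that("empty detections or ground truths are legal", {
  gt <- boxes(0, 0, 10, 10)
  det <- dplyr::mutate(gt, score = 0.9)
  m <- match_detections(det[0, ], gt, "default")
  expect_equal(c(m$tp, m$fp, m$fn), c(0, 0, 1))
  m2 <- match_detections(det, gt[0, ], "default")
  expect_equal(c(m2$tp, m2$fp, m2$fn), c(0, 1, 0))
  m3 <- match_detections(det[0, ], gt[0, ], "default")
  expect_equal(c(m3$tp, m3$fp, m3$fn), c(0, 0, 0))
})

test_that("below-score detections are excluded from every count", {
  gt <- boxes(0, 0, 10, 10)
  det <- tibble::tibble(xmin = c(0, 0), ymin = c(0, 0),
                        xmax = c(10, 10), ymax = c(10, 10),
                        score = c(0.05, 0.9))
  m <- match_detections(det, gt, "customized") # min_score 0.1
  expect_equal(as.character(m$detections$verdict), c("BELOW_SCORE", "TP"))
  expect_equal(c(m$tp, m$fp, m$fn), c(1, 0, 0))
  # verdict accounting: tp + fp + dropped + below_score = n detections
  g <- glance(m)
  expect_equal(g$tp + g$fp + g$dropped + g$below_score, nrow(det))
})

test_that("duplicates are FP under the default policy and dropped under the customized one", {
  gt <- boxes(0, 0, 10, 10)
  det <- tibble::tibble(xmin = 0, ymin = 0, xmax = 10, ymax = 10,
                        score = c(0.9, 0.8))
  m_fp <- match_detections(det, gt, eval_protocol("custom",
    matching_iou_threshold = 0.5, min_score = 0, duplicate_policy = "count_as_fp"))
  expect_equal(as.character(m_fp$detections$verdict), c("TP", "FP"))
  m_drop <- match_detections(det, gt, eval_protocol("custom",
    matching_iou_threshold = 0.5, min_score = 0, duplicate_policy = "drop"))
  expect_equal(as.character(m_drop$detections$verdict), c("TP", "DUP_DROPPED"))
  expect_equal(glance(m_drop)$precision, 1)
})

test_that("matching is invariant to detection permutation when scores are distinct", {
  withr::local_seed(101)
  for (rep in 1:20) {
    gts <- random_int_boxes(4)
    dets <- random_int_boxes(5)
    dets$score <- sample(seq(0.1, 0.9, length.out = 5))
    m1 <- glance(match_detections(dets, gts, "customized"))
    perm <- sample(5)
    m2 <- glance(match_detections(dets[perm, ], gts, "customized"))
    expect_equal(m1, m2)
  }
})

test_that("switching duplicates from count_as_fp to drop never decreases precision, never changes recall", {
  withr::local_seed(202)
  for (rep in 1:25) {
    gts <- random_int_boxes(3)
    dets <- random_int_boxes(6)
    dets$score <- runif(6)
    thr <- sample(c(0.1, 0.3, 0.5), 1)
    g_fp <- glance(match_detections(dets, gts, eval_protocol("custom",
      matching_iou_threshold = thr, min_score = 0, duplicate_policy = "count_as_fp")))
    g_dr <- glance(match_detections(dets, gts, eval_protocol("custom",
      matching_iou_threshold = thr, min_score = 0, duplicate_policy = "drop")))
    expect_identical(g_fp$recall, g_dr$recall)
    if (!is.na(g_fp$precision) && !is.na(g_dr$precision)) {
      expect_gte(g_dr$precision, g_fp$precision)
    }
  }
})

test_that("lowering the IoU threshold never decreases the true-positive count", {
  withr::local_seed(303)
  for (rep in 1:25) {
    gts <- random_int_boxes(4)
    dets <- random_int_boxes(5)
    dets$score <- runif(5)
    tps <- vapply(c(0.7, 0.5, 0.3, 0.1), function(thr) {
      match_detections(dets, gts, eval_protocol("custom",
        matching_iou_threshold = thr, min_score = 0,
        duplicate_policy = "drop"))$tp
    }, numeric(1))
    expect_true(all(diff(tps) >= 0))
  }
})

test_that("greedy matching counts agree with an independent brute-force oracle", {
  withr::local_seed(404)
  for (rep in 1:30) {
    n_det <- sample(0:5, 1)
    n_gt <- sample(0:4, 1)
    gts <- random_int_boxes(max(n_gt, 1))[seq_len(n_gt), ]
    dets <- random_int_boxes(max(n_det, 1))[seq_len(n_det), ]
    dets$score <- if (n_det > 0) sample(seq(0.2, 0.95, length.out = n_det)) else numeric(0)
    drop_dups <- sample(c(TRUE, FALSE), 1)
    thr <- sample(c(0.3, 0.5), 1)
    proto <- eval_protocol("custom", matching_iou_threshold = thr,
                           min_score = 0.1,
                           duplicate_policy = if (drop_dups) "drop" else "count_as_fp")
    m <- match_detections(dets, gts, proto)
    o <- oracle_match_counts(dets, gts, thr, 0.1, drop_dups)
    expect_equal(m$tp, o$tp)
    expect_equal(m$fp, o$fp)
    expect_equal(m$fn, o$fn)
    expect_equal(sum(m$detections$verdict == "DUP_DROPPED"), o$dropped)
  }
})

test_that("precision and recall follow the counts, with NA for empty denominators", {
  pr <- precision_recall(1, fp = 7, fn = 4)
  expect_equal(pr$precision, 0.125)
  expect_equal(pr$recall, 0.2)
  pr0 <- precision_recall(0, fp = 0, fn = 0)
  expect_true(is.na(pr0$precision))
  expect_true(is.na(pr0$recall))
  pr2 <- precision_recall(4, fp = 1, fn = 1)
  expect_equal(c(pr2$precision, pr2$recall), c(0.8, 0.8))
})

test_that("f1 is the harmonic mean, undefined at p = r = 0, and between min and max", {
  expect_equal(f1_score(1, 1), 1)
  expect_true(is.na(f1_score(0, 0)))
  expect_true(is.na(f1_score(NA_real_, 0.5)))
  withr::local_seed(9)
  p <- runif(200)
  r <- runif(200)
  f <- f1_score(p, r)
  expect_equal(f, 2 * p * r / (p + r))
  expect_true(all(f >= pmin(p, r) - 1e-12))
  expect_true(all(f <= pmax(p, r) + 1e-12))
})

test_that("average precision matches hand-enumerated PR curves", {
  gt <- boxes(0, 0, 10, 10)
  det1 <- dplyr::mutate(gt, score = 0.9)
  expect_equal(average_precision(det1, gt), 1)
  # no detection above min_score
  det_low <- dplyr::mutate(gt, score = 0.05)
  expect_equal(average_precision(det_low, gt, "customized"), 0)
  # no ground truth: undefined
  expect_true(is.na(average_precision(det1, gt[0, ])))
  # TP at 0.9 then FP at 0.8 on one gt: curve (r=1,p=1),(r=1,p=0.5) -> AP 1
  det2 <- tibble::tibble(xmin = c(0, 50), ymin = c(0, 50),
                         xmax = c(10, 60), ymax = c(10, 60),
                         score = c(0.9, 0.8))
  expect_equal(average_precision(det2, gt), 1)
  # FP at 0.9 then TP at 0.8: precision at recall 1 is 0.5 -> AP 0.5
  det3 <- det2
  det3$score <- c(0.8, 0.9)
  expect_equal(average_precision(det3, gt), 0.5)
  # worked-example fixture, default protocol: the single TP sits at the
  # bottom of the 8-detection ranking, so the curve has one step of height
  # 1/8 at recall 0.2 -> AP = 0.2 * 0.125
  fx <- build_table1_fixture()
  expect_equal(average_precision(fx$detections, fx$ground_truth, "default"),
               0.2 * 0.125)
})
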