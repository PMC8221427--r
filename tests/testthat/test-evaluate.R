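make_two_image_case <- function() {
  fx <- build_table1_fixture()
  det1 <- dplyr::mutate(fx$detections, image_id = "img1")
  gt1 <- dplyr::mutate(fx$ground_truth, image_id = "img1")
  det2 <- tibble::tibble(image_id = "img2", xmin = 0, ymin = 0,
                         xmax = 50, ymax = 50, score = 0.9)
  gt2 <- tibble::tibble(image_id = "img2", xmin = 0, ymin = 0,
                        xmax = 50, ymax = 50)
  list(det = dplyr::bind_rows(det1, det2), gt = dplyr::bind_rows(gt1, gt2))
}

test_that("micro-averaged pooled metrics equal metrics on the concatenation", {
  cs <- make_two_image_case()
  ev <- evaluate_detections(cs$det, cs$gt, "customized")
  micro <- ev$summary[ev$summary$average == "micro", ]
  # concatenate both images into one (they occupy disjoint coordinates after
  # shifting image 2 far away)
  det_all <- cs$det
  det_all[det_all$image_id == "img2", c("xmin", "xmax")] <-
    det_all[det_all$image_id == "img2", c("xmin", "xmax")] + 5000
  gt_all <- cs$gt
  gt_all[gt_all$image_id == "img2", c("xmin", "xmax")] <-
    gt_all[gt_all$image_id == "img2", c("xmin", "xmax")] + 5000
  m <- match_detections(
    det_all[, c("xmin", "ymin", "xmax", "ymax", "score")],
    gt_all[, c("xmin", "ymin", "xmax", "ymax")], "customized")
  g <- glance(m)
  expect_equal(micro$tp, g$tp)
  expect_equal(micro$fp, g$fp)
  expect_equal(micro$fn, g$fn)
  expect_equal(micro$precision, g$precision)
  expect_equal(micro$recall, g$recall)
})

test_that("per-image rows and macro averages are reported alongside micro", {
  cs <- make_two_image_case()
  ev <- evaluate_detections(cs$det, cs$gt, "default")
  expect_equal(nrow(ev$per_image), 2)
  r1 <- ev$per_image[ev$per_image$image_id == "img1", ]
  expect_equal(r1$precision, 0.125)
  expect_equal(r1$recall, 0.2)
  macro <- ev$summary[ev$summary$average == "macro", ]
  expect_equal(macro$precision, mean(c(0.125, 1)))
  expect_equal(macro$recall, mean(c(0.2, 1)))
  g <- glance(ev)
  expect_equal(g$tp, 2)
})

test_that("annotation sets work as ground truth and missing images error", {
  fx <- build_table1_fixture()
  ann <- annotation_set("table1", 1000, 1000,
                        dplyr::mutate(fx$ground_truth, class = "tassel"))
  det <- dplyr::mutate(fx$detections, image_id = "table1")
  ev <- evaluate_detections(det, list(ann), "default")
  expect_equal(glance(ev)$recall, 0.2)
  det_bad <- dplyr::mutate(det, image_id = "unlabelled_image")
  expect_error(evaluate_detections(det_bad, list(ann)), "unlabelled_image")
})

test_that("an empty detection file gives recall 0 and undefined precision", {
  fx <- build_table1_fixture()
  gt <- dplyr::mutate(fx$ground_truth, image_id = "img1")
  det <- tibble::tibble(image_id = character(), xmin = numeric(),
                        ymin = numeric(), xmax = numeric(),
                        ymax = numeric(), score = numeric())
  ev <- evaluate_detections(det, gt, "default")
  g <- glance(ev)
  expect_equal(g$recall, 0)
  expect_true(is.na(g$precision))
})

test_that("optional AP is computed over the pooled score sweep", {
  cs <- make_two_image_case()
  ev <- evaluate_detections(cs$det, cs$gt, "customized", with_ap = TRUE)
  expect_true(ev$ap >= 0 && ev$ap <= 1)
  expect_equal(ev$ap,
               average_precision(cs$det, cs$gt, "customized"))
})

test_that("the end-to-end runner is seed-reproducible and reports every metric", {
  cfg <- field_config(width = 512, height = 512, n_tassels = 8)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  r1 <- run_tassel_pipeline(seed = 5, out_dir = d1, n_per_class = 12, cfg = cfg)
  r2 <- run_tassel_pipeline(seed = 5, out_dir = d2, n_per_class = 12, cfg = cfg)
  expect_identical(readLines(file.path(d1, "summary.csv")),
                   readLines(file.path(d2, "summary.csv")))
  expect_identical(readLines(file.path(d1, "summary.txt")),
                   readLines(file.path(d2, "summary.txt")))
  expect_true(all(c("patch_accuracy", "patch_precision", "patch_recall",
                    "patch_f1", "detect_precision", "detect_recall",
                    "detect_f1") %in% names(r1$summary)))
  expect_true(file.exists(file.path(d1, "detection.png")))
  expect_true(file.exists(file.path(d1, "model.txt")))
  # stage outputs reload cleanly
  dets <- read_detections(file.path(d1, "tassel_patches.csv"))
  expect_true(all(dets$score >= 0 & dets$score <= 1))
  gt <- read_voc_xml(file.path(d1, "ground_truth.xml"))
  expect_equal(nrow(gt$objects), 8)
})

test_that("autoplot methods return ggplot objects", {
  fx <- build_table1_fixture()
  m <- match_detections(fx$detections, fx$ground_truth, "customized")
  expect_s3_class(autoplot(m), "ggplot")
  p <- plot_pr_curve(fx$detections, fx$ground_truth, "customized")
  expect_s3_class(p, "ggplot")
  f <- generate_field(field_config(width = 256, height = 256, n_tassels = 3,
                                   seed = 2))
  expect_s3_class(autoplot(f), "ggplot")
})
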