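#' Evaluate detections against ground truth across images
#'
#' Matches every image's detections to its ground truth under a protocol and
#' reports per-image and aggregate precision / recall / F1. The default
#' aggregate is micro-averaged: tp/fp/fn are pooled across images before the
#' metrics are computed (identical to evaluating the concatenation of all
#' images). Macro averaging (mean of per-image metrics, undefined values
#' dropped) is reported alongside.
#'
#' @param detections a tibble with `image_id`, box columns and `score`.
#' @param ground_truth either a tibble with `image_id` + box columns, or a
#'   list of [annotation_set()] objects. Every `image_id` appearing in
#'   `detections` must have ground truth present (possibly with zero boxes);
#'   a missing image is an error naming it.
#' @param protocol an [eval_protocol()] or preset name (default
#'   `"default"`).
#' @param with_ap also compute pooled [average_precision()].
#' @return an object of class `tassel_eval` with `per_image` (tibble of
#'   counts and metrics per image) and `summary` (micro and macro rows).
#'   `tidy()` returns `per_image`; `glance()` the micro row.
#' @export
evaluate_detections <- function(detections, ground_truth,
                                protocol = "default", with_ap = FALSE) {
  if (is.character(protocol)) protocol <- eval_protocol(protocol)
  detections <- tibble::as_tibble(detections)
  if (!"image_id" %in% names(detections)) detections$image_id <- "image"

  if (is.list(ground_truth) && !is.data.frame(ground_truth) &&
      all(vapply(ground_truth, inherits, TRUE, "annotation_set"))) {
    ground_truth <- dplyr::bind_rows(purrr::map(ground_truth, function(a) {
      g <- a$objects[, c("xmin", "ymin", "xmax", "ymax"), drop = FALSE]
      g$image_id <- a$image_id
      # keep zero-box images visible in the gt table
      if (nrow(g) == 0) {
        g <- tibble::tibble(xmin = NA_real_, ymin = NA_real_,
                            xmax = NA_real_, ymax = NA_real_,
                            image_id = a$image_id)
      }
      g
    }))
  }
  ground_truth <- tibble::as_tibble(ground_truth)
  if (!"image_id" %in% names(ground_truth)) ground_truth$image_id <- "image"

  missing_ids <- setdiff(unique(detections$image_id),
                         unique(ground_truth$image_id))
  if (length(missing_ids) > 0) {
    stop("no ground truth for image_id(s): ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }

  ids <- unique(ground_truth$image_id)
  per_image <- purrr::map_dfr(ids, function(img) {
    gts <- ground_truth[ground_truth$image_id == img, , drop = FALSE]
    gts <- gts[!is.na(gts$xmin), c("xmin", "ymin", "xmax", "ymax"),
               drop = FALSE]
    dets <- detections[detections$image_id == img,
                       c("xmin", "ymin", "xmax", "ymax", "score"),
                       drop = FALSE]
    m <- match_detections(dets, gts, protocol)
    dplyr::bind_cols(tibble::tibble(image_id = img), glance(m))
  })

  tp <- sum(per_image$tp); fp <- sum(per_image$fp); fn <- sum(per_image$fn)
  pr <- precision_recall(tp, fp = fp, fn = fn)
  micro <- tibble::tibble(
    average = "micro", tp = tp, fp = fp, fn = fn,
    precision = pr$precision, recall = pr$recall,
    f1 = f1_score(pr$precision, pr$recall)
  )
  macro <- tibble::tibble(
    average = "macro", tp = tp, fp = fp, fn = fn,
    precision = mean(per_image$precision, na.rm = TRUE),
    recall = mean(per_image$recall, na.rm = TRUE),
    f1 = mean(per_image$f1, na.rm = TRUE)
  )
  macro[, c("precision", "recall", "f1")] <-
    lapply(macro[, c("precision", "recall", "f1")],
           function(v) ifelse(is.nan(v), NA_real_, v))

  out <- list(per_image = per_image,
              summary = dplyr::bind_rows(micro, macro),
              protocol = protocol)
  if (with_ap) {
    gt_ap <- ground_truth[!is.na(ground_truth$xmin), , drop = FALSE]
    out$ap <- average_precision(detections, gt_ap, protocol)
  }
  structure(out, class = "tassel_eval")
}

#' @export
print.tassel_eval <- function(x, ...) {
  cat("<tassel_eval> protocol: ", x$protocol$protocol, ", ",
      nrow(x$per_image), " image(s)\n", sep = "")
  print(x$summary)
  if (!is.null(x$ap)) cat("AP:", format(x$ap, digits = 4), "\n")
  invisible(x)
}

#' @export
tidy.tassel_eval <- function(x, ...) x$per_image

#' @export
glance.tassel_eval <- function(x, ...) {
  g <- x$summary[x$summary$average == "micro",
                 c("tp", "fp", "fn", "precision", "recall", "f1")]
  if (!is.null(x$ap)) g$ap <- x$ap
  g
}

#' Run the whole pipeline end to end on synthetic data
#'
#' generate -> extract patches -> train -> detect -> evaluate, all driven by
#' one seed: builds a patch dataset from synthetic fields, trains the
#' reference classifier, reports its held-out metrics, runs the patch-based
#' detector on a fresh synthetic field, scores the patch labels against the
#' reference labels derived from ground truth, and (optionally) writes the
#' rendered detection image, detection CSV and a summary report.
#'
#' @param seed master seed; every stage derives from it.
#' @param out_dir optional output directory (created if needed).
#' @param n_per_class training patches per class (default 200).
#' @param cfg [field_config()] template for the generated fields.
#' @return a list of class `tassel_run` with `patch_eval`, `detection`,
#'   `field`, `patch_confusion`, and a one-row `summary` tibble (patch
#'   accuracy / precision / recall / F1 and detection patch-level metrics).
#' @export
run_tassel_pipeline <- function(seed = 0, out_dir = NULL, n_per_class = 200,
                                cfg = field_config()) {
  ds <- generate_patch_dataset(cfg, n_per_class = n_per_class, seed = seed)
  model <- train_patch_classifier(ds, seed = seed)
  pe <- evaluate_patch_classifier(model, ds)

  fcfg <- cfg
  fcfg$seed <- seed
  fld <- generate_field(fcfg)
  det <- detect_tassels(fld$image, model)

  ref <- patch_labels_from_gt(det$patches, fld$annotations$objects)
  tp <- sum(det$patches$label == "tassel" & ref == "tassel")
  fp <- sum(det$patches$label == "tassel" & ref == "no_tassel")
  fn <- sum(det$patches$label == "no_tassel" & ref == "tassel")
  tn <- sum(det$patches$label == "no_tassel" & ref == "no_tassel")
  dpr <- precision_recall(tp, fp = fp, fn = fn)

  summary <- tibble::tibble(
    seed = seed,
    patch_accuracy = pe$metrics$accuracy,
    patch_precision = pe$metrics$precision,
    patch_recall = pe$metrics$recall,
    patch_f1 = pe$metrics$f1,
    detect_tp = tp, detect_fp = fp, detect_fn = fn, detect_tn = tn,
    detect_precision = dpr$precision,
    detect_recall = dpr$recall,
    detect_f1 = f1_score(dpr$precision, dpr$recall)
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_image(det$image, file.path(out_dir, "detection.png"))
    write_detections(
      dplyr::mutate(det$tassel_patches, image_id = fld$annotations$image_id),
      file.path(out_dir, "tassel_patches.csv"))
    write_voc_xml(fld$annotations, file.path(out_dir, "ground_truth.xml"))
    save_patch_classifier(model, file.path(out_dir, "model.txt"))
    readr::write_csv(summary, file.path(out_dir, "summary.csv"))
    writeLines(c(
      paste0("tasselcv pipeline run, seed ", seed),
      sprintf("patch classifier: accuracy %.4f precision %.4f recall %.4f f1 %.4f",
              summary$patch_accuracy, summary$patch_precision,
              summary$patch_recall, summary$patch_f1),
      sprintf("detector (patch level): tp %d fp %d fn %d tn %d", tp, fp, fn, tn),
      sprintf("detector: precision %.4f recall %.4f f1 %.4f",
              summary$detect_precision, summary$detect_recall,
              summary$detect_f1)
    ), file.path(out_dir, "summary.txt"))
  }

  structure(list(patch_eval = pe, model = model, field = fld,
                 detection = det, summary = summary),
            class = "tassel_run")
}

#' @export
print.tassel_run <- function(x, ...) {
  cat("<tassel_run> seed", x$summary$seed, "\n")
  print(x$summary)
  invisible(x)
}
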