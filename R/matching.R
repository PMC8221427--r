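#' Evaluation protocol configuration
#'
#' Bundles the three knobs that decide how detections are scored against
#' ground truth:
#' \describe{
#'   \item{matching_iou_threshold}{minimum IoU at which a detection may claim
#'     a ground-truth box.}
#'   \item{min_score}{detections with confidence below this are ignored
#'     entirely (verdict `BELOW_SCORE`).}
#'   \item{duplicate_policy}{what happens to a second (or later) detection of
#'     an already-matched ground truth: `"count_as_fp"` (the PASCAL default)
#'     or `"drop"` (ignored in all counts).}
#' }
#'
#' Two presets cover the common cases. `protocol = "default"` is the standard
#' PASCAL VOC rule set (IoU 0.5, no score cut, duplicates are false
#' positives). `protocol = "customized"` is the agricultural variant motivated
#' by tassel detection, where a partial detection of a thin tassel is already
#' useful to a breeder and inconsistent grouping of adjacent tassels into one
#' annotation makes duplicate detections innocuous: IoU threshold 0.3, score
#' threshold 0.1, duplicates dropped.
#'
#' @param protocol `"default"`, `"customized"`, or `"custom"` (use the
#'   explicit arguments).
#' @param matching_iou_threshold real in (0, 1].
#' @param min_score real in \[0, 1\].
#' @param duplicate_policy `"count_as_fp"` or `"drop"`.
#' @return an object of class `eval_protocol`.
#' @examples
#' eval_protocol("customized")
#' eval_protocol("custom", matching_iou_threshold = 0.4, min_score = 0.2,
#'               duplicate_policy = "drop")
#' @export
eval_protocol <- function(protocol = c("default", "customized", "custom"),
                          matching_iou_threshold = NULL,
                          min_score = NULL,
                          duplicate_policy = NULL) {
  protocol <- match.arg(protocol)
  preset <- switch(protocol,
    default    = list(matching_iou_threshold = 0.5, min_score = 0.0,
                      duplicate_policy = "count_as_fp"),
    customized = list(matching_iou_threshold = 0.3, min_score = 0.1,
                      duplicate_policy = "drop"),
    custom     = list(matching_iou_threshold = 0.5, min_score = 0.0,
                      duplicate_policy = "count_as_fp")
  )
  cfg <- list(
    protocol = protocol,
    matching_iou_threshold = matching_iou_threshold %||% preset$matching_iou_threshold,
    min_score = min_score %||% preset$min_score,
    duplicate_policy = (duplicate_policy %||% preset$duplicate_policy)
  )
  cfg$duplicate_policy <- match.arg(cfg$duplicate_policy, c("count_as_fp", "drop"))
  stopifnot(
    cfg$matching_iou_threshold > 0, cfg$matching_iou_threshold <= 1,
    cfg$min_score >= 0, cfg$min_score <= 1
  )
  structure(cfg, class = "eval_protocol")
}

#' @export
print.eval_protocol <- function(x, ...) {
  cat("<eval_protocol> ", x$protocol, "\n",
      "  matching_iou_threshold: ", x$matching_iou_threshold, "\n",
      "  min_score:              ", x$min_score, "\n",
      "  duplicate_policy:       ", x$duplicate_policy, "\n", sep = "")
  invisible(x)
}

validate_detections <- function(dets) {
  if (nrow(dets) > 0) {
    validate_boxes(dets)
    if (!"score" %in% names(dets)) {
      stop("detection table needs a `score` column", call. = FALSE)
    }
    if (any(dets$score < 0 | dets$score > 1 | !is.finite(dets$score))) {
      stop("detection scores must lie in [0, 1]", call. = FALSE)
    }
  }
  tibble::as_tibble(dets)
}

#' Match detections to ground-truth boxes
#'
#' Greedy score-ordered assignment, the procedure underlying PASCAL-style
#' detector evaluation. Detections below `min_score` are set aside with
#' verdict `BELOW_SCORE` and enter no count. The remaining detections are
#' visited in descending score order (ties: input order); each is assigned to
#' the ground-truth box of maximal IoU (ties: lowest ground-truth index).
#' If that IoU reaches `matching_iou_threshold` and the ground truth is not
#' yet matched the detection is a true positive and the ground truth becomes
#' matched; if the ground truth was already matched the detection is a
#' duplicate — a false positive under `count_as_fp`, or set aside with verdict
#' `DUP_DROPPED` under `drop`. A detection whose best IoU is below the
#' threshold is a false positive. Every ground truth never matched is a false
#' negative.
#'
#' @param detections a tibble with box columns plus `score` (rows may be
#'   empty: an image with no detections is legal).
#' @param ground_truth a box tibble (possibly empty).
#' @param protocol an [eval_protocol()] object, or a string preset name.
#' @return an object of class `tassel_match`: a list with
#'   \describe{
#'     \item{detections}{the input detections with `verdict` (factor:
#'       TP / FP / DUP_DROPPED / BELOW_SCORE), `matched_gt` (1-based index of
#'       the claimed ground truth, NA otherwise) and `best_iou` columns,
#'       in the original input order;}
#'     \item{ground_truth}{input boxes with a logical `matched` column;}
#'     \item{tp, fp, fn}{the pooled counts;}
#'     \item{protocol}{the protocol used.}
#'   }
#' @examples
#' gt <- boxes(0, 0, 10, 10)
#' det <- dplyr::mutate(gt, score = 0.9)
#' match_detections(det, gt, "default")
#' @export
match_detections <- function(detections, ground_truth, protocol = "default") {
  if (is.character(protocol)) protocol <- eval_protocol(protocol)
  stopifnot(inherits(protocol, "eval_protocol"))
  detections <- validate_detections(detections)
  if (nrow(ground_truth) > 0) ground_truth <- validate_boxes(ground_truth)
  ground_truth <- tibble::as_tibble(ground_truth)

  n_det <- nrow(detections)
  n_gt <- nrow(ground_truth)
  verdict <- character(n_det)
  matched_gt <- rep(NA_integer_, n_det)
  best_iou <- rep(NA_real_, n_det)
  gt_matched <- logical(n_gt)

  if (n_det > 0) {
    below <- detections$score < protocol$min_score
    verdict[below] <- "BELOW_SCORE"
    active <- which(!below)
    # descending score, ties by input order (order() is stable)
    active <- active[order(-detections$score[active])]
    M <- iou_matrix(detections, ground_truth)
    for (i in active) {
      if (n_gt == 0) {
        verdict[i] <- "FP"
        next
      }
      ious <- M[i, ]
      j <- which.max(ious) # lowest index on ties
      best_iou[i] <- ious[j]
      if (ious[j] >= protocol$matching_iou_threshold) {
        if (!gt_matched[j]) {
          verdict[i] <- "TP"
          matched_gt[i] <- j
          gt_matched[j] <- TRUE
        } else if (protocol$duplicate_policy == "drop") {
          verdict[i] <- "DUP_DROPPED"
          matched_gt[i] <- j
        } else {
          verdict[i] <- "FP"
        }
      } else {
        verdict[i] <- "FP"
      }
    }
  }

  det_out <- detections
  det_out$verdict <- factor(verdict,
                            levels = c("TP", "FP", "DUP_DROPPED", "BELOW_SCORE"))
  det_out$matched_gt <- matched_gt
  det_out$best_iou <- best_iou
  gt_out <- ground_truth
  gt_out$matched <- gt_matched

  structure(
    list(
      detections = det_out,
      ground_truth = gt_out,
      tp = sum(verdict == "TP"),
      fp = sum(verdict == "FP"),
      fn = sum(!gt_matched),
      protocol = protocol
    ),
    class = "tassel_match"
  )
}

#' @export
print.tassel_match <- function(x, ...) {
  cat("<tassel_match> protocol: ", x$protocol$protocol,
      " (IoU >= ", x$protocol$matching_iou_threshold,
      ", score >= ", x$protocol$min_score,
      ", duplicates ", x$protocol$duplicate_policy, ")\n", sep = "")
  cat("  detections: ", nrow(x$detections),
      "  ground truths: ", nrow(x$ground_truth), "\n", sep = "")
  cat("  tp = ", x$tp, ", fp = ", x$fp, ", fn = ", x$fn,
      ", dropped = ", sum(x$detections$verdict == "DUP_DROPPED"),
      ", below score = ", sum(x$detections$verdict == "BELOW_SCORE"),
      "\n", sep = "")
  g <- glance(x)
  cat(sprintf("  precision = %s, recall = %s, f1 = %s\n",
              format(g$precision, digits = 4),
              format(g$recall, digits = 4),
              format(g$f1, digits = 4)))
  invisible(x)
}

#' @rdname match_detections
#' @param x a `tassel_match` object.
#' @param ... unused.
#' @return `tidy()`: the per-detection verdict tibble, input order.
#' @export
tidy.tassel_match <- function(x, ...) {
  x$detections
}

#' @rdname match_detections
#' @return `glance()`: a one-row tibble with `tp`, `fp`, `fn`, `dropped`,
#'   `below_score`, `precision`, `recall`, `f1`. Undefined metrics (zero
#'   denominator) are `NA`, never 0.
#' @export
glance.tassel_match <- function(x, ...) {
  pr <- precision_recall(x)
  tibble::tibble(
    tp = x$tp, fp = x$fp, fn = x$fn,
    dropped = sum(x$detections$verdict == "DUP_DROPPED"),
    below_score = sum(x$detections$verdict == "BELOW_SCORE"),
    precision = pr$precision,
    recall = pr$recall,
    f1 = f1_score(pr$precision, pr$recall)
  )
}

#' Precision and recall from a match result or raw counts
#'
#' Precision is tp / (tp + fp): how many reported tassels are actual tassels.
#' Recall is tp / (tp + fn): how many actual tassels were found. Dropped
#' duplicates and below-score detections appear in neither numerator nor
#' denominator. A zero denominator yields `NA` ("not defined"), never a
#' silent 0.
#'
#' @param x a `tassel_match` object, or the tp count.
#' @param fp,fn counts, when `x` is given as a number.
#' @return a one-row tibble with columns `precision` and `recall`.
#' @examples
#' precision_recall(1, fp = 7, fn = 4) # 0.125, 0.2
#' @export
precision_recall <- function(x, fp = NULL, fn = NULL) {
  if (inherits(x, "tassel_match")) {
    tp <- x$tp; fp <- x$fp; fn <- x$fn
  } else {
    tp <- x
    stopifnot(!is.null(fp), !is.null(fn))
  }
  tibble::tibble(
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_
  )
}

#' F1 score
#'
#' Harmonic mean of precision and recall, `2 p r / (p + r)`. With
#' `p = r = 0` (or either input `NA`) the score is not defined and `NA` is
#' returned.
#'
#' @param precision,recall numeric vectors in \[0, 1\].
#' @return numeric vector of F1 values (NA where undefined).
#' @examples
#' f1_score(0.972, 0.946) # ~0.959
#' @export
f1_score <- function(precision, recall) {
  out <- rep(NA_real_, length(precision))
  ok <- !is.na(precision) & !is.na(recall) & (precision + recall) > 0
  out[ok] <- 2 * precision[ok] * recall[ok] / (precision[ok] + recall[ok])
  out
}

#' Average precision over a score sweep
#'
#' All-points interpolated AP: detections from all images are pooled, sorted
#' by descending score, and each is marked TP or FP by the greedy matching
#' rule of [match_detections()] under `protocol` within its own image. The
#' precision–recall curve is swept over this ranking and AP is the area under
#' the interpolated curve (at each recall level, the maximum precision at any
#' equal-or-higher recall). Dropped duplicates and below-score detections do
#' not enter the ranking.
#'
#' @param detections a tibble of detections with an `image_id` column (a
#'   single unnamed image is assumed when absent).
#' @param ground_truth a box tibble, `image_id` matching `detections`.
#' @param protocol an [eval_protocol()] or preset name.
#' @return a scalar AP in \[0, 1\]; `NA` when there are no ground truths;
#'   0 when no detection survives the score threshold.
#' @export
average_precision <- function(detections, ground_truth, protocol = "default") {
  if (is.character(protocol)) protocol <- eval_protocol(protocol)
  detections <- tibble::as_tibble(detections)
  ground_truth <- tibble::as_tibble(ground_truth)
  if (!"image_id" %in% names(detections)) detections$image_id <- "image"
  if (!"image_id" %in% names(ground_truth)) ground_truth$image_id <- "image"
  n_gt <- nrow(ground_truth)
  if (n_gt == 0) return(NA_real_)

  per_image <- lapply(
    split(seq_len(nrow(detections)), detections$image_id),
    function(idx) {
      img <- detections$image_id[idx[1]]
      gts <- ground_truth[ground_truth$image_id == img,
                          c("xmin", "ymin", "xmax", "ymax")]
      m <- match_detections(detections[idx, setdiff(names(detections), "image_id")],
                            gts, protocol)
      tibble::tibble(score = m$detections$score,
                     verdict = as.character(m$detections$verdict))
    }
  )
  ranked <- dplyr::bind_rows(per_image)
  ranked <- ranked[ranked$verdict %in% c("TP", "FP"), , drop = FALSE]
  if (nrow(ranked) == 0) return(0)
  ranked <- ranked[order(-ranked$score), , drop = FALSE]
  tp_cum <- cumsum(ranked$verdict == "TP")
  fp_cum <- cumsum(ranked$verdict == "FP")
  recall <- tp_cum / n_gt
  precision <- tp_cum / (tp_cum + fp_cum)
  # all-points interpolation: precision envelope from the right
  prec_interp <- rev(cummax(rev(precision)))
  d_recall <- diff(c(0, recall))
  sum(d_recall * prec_interp)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
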