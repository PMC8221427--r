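image_raster_df <- function(img) {
  d <- dim(img)
  tibble::tibble(
    x = rep(seq_len(d[2]) - 0.5, each = d[1]),
    y = rep(seq_len(d[1]) - 0.5, times = d[2]),
    fill = grDevices::rgb(img[, , 1] / 255, img[, , 2] / 255, img[, , 3] / 255)
  )
}

#' Plot a synthetic field with its ground-truth boxes
#'
#' @param object a `synthetic_field`.
#' @param ... unused.
#' @return a ggplot: the rendered scene with ground-truth boxes outlined.
#' @export
autoplot.synthetic_field <- function(object, ...) {
  df <- image_raster_df(object$image)
  gt <- object$annotations$objects
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_void()
  if (nrow(gt) > 0) {
    p <- p + ggplot2::geom_rect(
      data = gt,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = .data$ymin, ymax = .data$ymax),
      inherit.aes = FALSE, colour = "red", fill = NA, linewidth = 0.4)
  }
  p
}

#' Plot a detection rendering with its tassel patches
#'
#' @param object a `tassel_detection` from [detect_tassels()].
#' @param ... unused.
#' @return a ggplot: the colour/grayscale composite with tassel patch
#'   windows outlined.
#' @export
autoplot.tassel_detection <- function(object, ...) {
  df <- image_raster_df(object$image)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::theme_void()
  if (nrow(object$tassel_patches) > 0) {
    p <- p + ggplot2::geom_rect(
      data = object$tassel_patches,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = .data$ymin, ymax = .data$ymax),
      inherit.aes = FALSE, colour = "yellow", fill = NA, linewidth = 0.3)
  }
  p
}

#' Plot a matching result: boxes coloured by verdict
#'
#' @param object a `tassel_match` from [match_detections()].
#' @param ... unused.
#' @return a ggplot of ground-truth (dashed) and detection boxes, detections
#'   coloured by verdict.
#' @export
autoplot.tassel_match <- function(object, ...) {
  det <- object$detections
  gt <- object$ground_truth
  ggplot2::ggplot() +
    ggplot2::geom_rect(
      data = gt,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = .data$ymin, ymax = .data$ymax),
      colour = "grey30", fill = NA, linetype = "dashed") +
    ggplot2::geom_rect(
      data = det,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = .data$ymin, ymax = .data$ymax,
                   colour = .data$verdict),
      fill = NA, linewidth = 0.6) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(colour = "verdict", x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Precision–recall curve under a protocol
#'
#' Sweeps the pooled detections by descending score under the matching rules
#' of `protocol` and plots the resulting precision–recall curve.
#'
#' @param detections tibble with `image_id`, box columns and `score`.
#' @param ground_truth tibble with `image_id` + box columns.
#' @param protocol an [eval_protocol()] or preset name.
#' @return a ggplot with the PR curve and the all-points AP in the subtitle.
#' @export
plot_pr_curve <- function(detections, ground_truth, protocol = "default") {
  if (is.character(protocol)) protocol <- eval_protocol(protocol)
  detections <- tibble::as_tibble(detections)
  ground_truth <- tibble::as_tibble(ground_truth)
  if (!"image_id" %in% names(detections)) detections$image_id <- "image"
  if (!"image_id" %in% names(ground_truth)) ground_truth$image_id <- "image"
  n_gt <- nrow(ground_truth)
  stopifnot(n_gt > 0)

  verdicts <- purrr::map_dfr(unique(detections$image_id), function(img) {
    gts <- ground_truth[ground_truth$image_id == img,
                        c("xmin", "ymin", "xmax", "ymax")]
    dets <- detections[detections$image_id == img,
                       c("xmin", "ymin", "xmax", "ymax", "score")]
    m <- match_detections(dets, gts, protocol)
    tibble::tibble(score = m$detections$score,
                   verdict = as.character(m$detections$verdict))
  })
  verdicts <- verdicts[verdicts$verdict %in% c("TP", "FP"), ]
  verdicts <- verdicts[order(-verdicts$score), ]
  curve <- tibble::tibble(
    recall = cumsum(verdicts$verdict == "TP") / n_gt,
    precision = cumsum(verdicts$verdict == "TP") /
      seq_len(nrow(verdicts))
  )
  ap <- average_precision(detections, ground_truth, protocol)
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_point(size = 1) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      title = "Precision–recall curve",
      subtitle = sprintf("protocol: %s, all-points AP = %.3f",
                         protocol$protocol, ap),
      x = "recall", y = "precision") +
    ggplot2::theme_minimal()
}
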