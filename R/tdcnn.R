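#' Convert RGB values to Rec. 601 luma
#'
#' Luminance `0.299 R + 0.587 G + 0.114 B`, rounded half-up.
#'
#' @param img a `height x width x 3` array in \[0, 255\], or a numeric
#'   vector of length 3.
#' @return for an array input: a `height x width x 3` array with
#'   `R = G = B = luma`; for a vector: the grey triplet.
#' @examples
#' rgb_to_gray(c(255, 0, 0)) # 76 76 76
#' @export
rgb_to_gray <- function(img) {
  if (is.null(dim(img))) {
    stopifnot(length(img) == 3)
    g <- floor(0.299 * img[1] + 0.587 * img[2] + 0.114 * img[3] + 0.5)
    return(rep(g, 3))
  }
  lum <- floor(0.299 * img[, , 1] + 0.587 * img[, , 2] +
                 0.114 * img[, , 3] + 0.5)
  array(rep(lum, 3), dim = dim(img))
}

#' Run the patch-based tassel detector over an image
#'
#' The tassel detection pipeline: lay a patch grid over the image, classify
#' every patch once, keep patches classified as tassel in their original
#' colour and render everything else in grayscale, and report the tassel
#' patch windows in source coordinates. Where flush-edge patches overlap, a
#' pixel stays coloured if any covering patch is classified tassel (the
#' recall-favouring rule).
#'
#' @param img a `height x width x 3` array in \[0, 255\].
#' @param model a trained [train_patch_classifier()] model (or any object
#'   with a `predict` method returning tassel scores and a `threshold`).
#' @param patch_size patch edge length (default 128).
#' @param edge_mode passed to [patch_grid()].
#' @return an object of class `tassel_detection`: a list with
#'   \describe{
#'     \item{image}{the rendered output array (same size as input);}
#'     \item{patches}{the patch grid tibble with `score` and `label` columns;}
#'     \item{tassel_patches}{a detection tibble (box + score) of the patches
#'       classified tassel, in source coordinates.}
#'   }
#' @export
detect_tassels <- function(img, model, patch_size = 128,
                           edge_mode = "flush") {
  if (!inherits(model, "patch_classifier")) {
    stop("`model` must be a trained patch_classifier", call. = FALSE)
  }
  d <- dim(img)
  grid <- patch_grid(d[2], d[1], patch_size = patch_size,
                     edge_mode = edge_mode)
  crops <- purrr::pmap(grid, function(origin_x, origin_y, patch_size, ...) {
    img[(origin_y + 1):(origin_y + patch_size),
        (origin_x + 1):(origin_x + patch_size), , drop = FALSE]
  })
  score <- predict(model, crops)
  label <- ifelse(score >= model$threshold, "tassel", "no_tassel")
  grid$score <- score
  grid$label <- label

  out <- rgb_to_gray(img)
  for (i in which(label == "tassel")) {
    ys <- (grid$origin_y[i] + 1):(grid$origin_y[i] + patch_size)
    xs <- (grid$origin_x[i] + 1):(grid$origin_x[i] + patch_size)
    out[ys, xs, ] <- img[ys, xs, ]
  }

  keep <- which(label == "tassel")
  tassel_patches <- tibble::tibble(
    xmin = grid$origin_x[keep], ymin = grid$origin_y[keep],
    xmax = grid$origin_x[keep] + patch_size,
    ymax = grid$origin_y[keep] + patch_size,
    score = score[keep]
  )
  structure(
    list(image = out, patches = grid, tassel_patches = tassel_patches),
    class = "tassel_detection"
  )
}

#' @export
print.tassel_detection <- function(x, ...) {
  cat("<tassel_detection> ", nrow(x$tassel_patches), " of ",
      nrow(x$patches), " patches classified tassel\n", sep = "")
  invisible(x)
}

#' @export
tidy.tassel_detection <- function(x, ...) x$patches

#' @export
glance.tassel_detection <- function(x, ...) {
  tibble::tibble(
    n_patches = nrow(x$patches),
    n_tassel = nrow(x$tassel_patches),
    n_no_tassel = nrow(x$patches) - nrow(x$tassel_patches)
  )
}

#' Reference patch labels from ground-truth boxes
#'
#' Labels each patch window of a grid against annotated boxes: a patch is
#' `tassel` iff its intersection with some ground truth covers at least
#' `min_overlap_frac` of that ground truth's area. Used to score the
#' patch-level detector output on synthetic fields.
#'
#' @param grid a [patch_grid()] tibble.
#' @param ground_truth a box tibble.
#' @param min_overlap_frac minimum fraction of a ground-truth box's area that
#'   must fall inside the patch (default 0.1).
#' @return character vector, one label per grid row.
#' @export
patch_labels_from_gt <- function(grid, ground_truth, min_overlap_frac = 0.1) {
  if (nrow(ground_truth) == 0) {
    return(rep("no_tassel", nrow(grid)))
  }
  ground_truth <- validate_boxes(ground_truth)
  pb <- boxes(grid$origin_x, grid$origin_y,
              grid$origin_x + grid$patch_size,
              grid$origin_y + grid$patch_size)
  areas <- box_area(ground_truth)
  lab <- rep("no_tassel", nrow(grid))
  for (j in seq_len(nrow(ground_truth))) {
    inter <- box_intersection(pb, ground_truth[j, ])
    lab[inter >= min_overlap_frac * areas[j]] <- "tassel"
  }
  lab
}
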