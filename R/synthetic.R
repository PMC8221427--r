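# Anti-aliased coverage window of a line segment of a given width:
# per pixel, clamp(w/2 + 0.5 - dist to segment) within the segment's
# bounding window. Blending into the channel matrices happens at the call
# site with plain subassignment, so the (possibly large) channels are
# modified in place rather than copied per stroke.
stroke_coverage <- function(x0, y0, x1, y1, width, h, w_img) {
  pad <- width / 2 + 1.5
  cx1 <- max(floor(min(x0, x1) - pad), 0)
  cx2 <- min(ceiling(max(x0, x1) + pad), w_img)
  cy1 <- max(floor(min(y0, y1) - pad), 0)
  cy2 <- min(ceiling(max(y0, y1) + pad), h)
  if (cx2 <= cx1 || cy2 <= cy1) return(NULL)
  px <- (cx1:(cx2 - 1)) + 0.5
  py <- (cy1:(cy2 - 1)) + 0.5
  X <- matrix(px, nrow = length(py), ncol = length(px), byrow = TRUE)
  Y <- matrix(py, nrow = length(py), ncol = length(px))
  dx <- x1 - x0; dy <- y1 - y0
  len2 <- dx * dx + dy * dy
  t <- if (len2 == 0) 0 else pmin(pmax(((X - x0) * dx + (Y - y0) * dy) / len2, 0), 1)
  dist <- sqrt((X - (x0 + t * dx))^2 + (Y - (y0 + t * dy))^2)
  cov <- pmin(pmax(width / 2 + 0.5 - dist, 0), 1)
  list(rows = (cy1 + 1):cy2, cols = (cx1 + 1):cx2, cov = cov)
}

# Sample one tassel skeleton (segments relative to its base point) and its
# tight bounding box (including stroke width).
sample_tassel_geometry <- function(cfg) {
  stem_len <- stats::runif(1, cfg$stem_length[1], cfg$stem_length[2])
  stem_angle <- stats::runif(1, -20, 20) * pi / 180 # near vertical
  width <- stats::runif(1, cfg$stroke_width[1], cfg$stroke_width[2])
  tip <- c(stem_len * sin(stem_angle), -stem_len * cos(stem_angle))
  segs <- list(c(0, 0, tip))
  n_br <- sample(seq(cfg$n_branches[1], cfg$n_branches[2]), 1)
  for (b in seq_len(n_br)) {
    at <- stats::runif(1, 0.5, 1) # on the upper half of the stem
    base <- at * tip
    ang <- stem_angle + stats::runif(1, -1, 1) * cfg$branch_angle_spread * pi / 180
    blen <- stats::runif(1, 0.3, 0.6) * stem_len
    segs <- c(segs, list(c(base, base + c(blen * sin(ang), -blen * cos(ang)))))
  }
  m <- do.call(rbind, segs)
  pad <- width / 2 + 1
  list(
    segments = m, width = width,
    bbox = c(xmin = min(m[, c(1, 3)]) - pad, ymin = min(m[, c(2, 4)]) - pad,
             xmax = max(m[, c(1, 3)]) + pad, ymax = max(m[, c(2, 4)]) + pad)
  )
}

#' Configuration for the synthetic canopy generator
#'
#' Describes a field scene the generator emulates: a textured green maize
#' canopy (multiplicative brightness noise plus lighter leaf-vein streaks)
#' with thin, branched, low-contrast tassel-like structures drawn on top —
#' the regime that makes aerial tassel detection hard.
#'
#' @param width,height scene size in pixels. 1000 x 1000 is the fast-test
#'   default; 3000 x 4000 matches a raw UAV frame.
#' @param n_tassels number of tassels to place.
#' @param stem_length range (px) of the tassel stem.
#' @param n_branches range of branch counts per tassel.
#' @param branch_angle_spread half-spread of branch angles about the stem,
#'   degrees.
#' @param stroke_width range (px) of stroke width.
#' @param canopy_base base canopy RGB (green-dominant).
#' @param noise_amp multiplicative brightness-noise amplitude.
#' @param vein_density leaf-vein streaks per pixel of scene area.
#' @param tassel_contrast fraction of the way from canopy colour to a bright
#'   yellow-green; kept low so tassels have poor contrast with the canopy.
#' @param seed RNG seed; generation is fully deterministic given the config.
#' @return a `field_config` list.
#' @export
field_config <- function(width = 1000, height = 1000, n_tassels = 15,
                         stem_length = c(20, 60), n_branches = c(3, 7),
                         branch_angle_spread = 50, stroke_width = c(1, 3),
                         canopy_base = c(70, 110, 60), noise_amp = 0.12,
                         vein_density = 5e-5, tassel_contrast = 0.4,
                         seed = 0) {
  cfg <- list(width = width, height = height, n_tassels = n_tassels,
              stem_length = stem_length, n_branches = n_branches,
              branch_angle_spread = branch_angle_spread,
              stroke_width = stroke_width, canopy_base = canopy_base,
              noise_amp = noise_amp, vein_density = vein_density,
              tassel_contrast = tassel_contrast, seed = seed)
  stopifnot(width > 0, height > 0, n_tassels >= 0,
            all(stem_length > 0), all(n_branches > 0),
            all(stroke_width > 0), tassel_contrast >= 0)
  structure(cfg, class = "field_config")
}

#' Generate a synthetic canopy image with tassel ground truth
#'
#' Renders a textured canopy, then places `n_tassels` tassel skeletons with
#' rejection sampling so that no two ground-truth boxes overlap by more than
#' half of the smaller box; each structure is drawn fully in-bounds with
#' anti-aliased strokes. The ground-truth box of a tassel is the bounding box
#' of its drawn structure dilated by 2 px (clipped to the image).
#' Deterministic given `cfg$seed`: identical pixels and boxes on every call.
#'
#' @param cfg a [field_config()].
#' @return an object of class `synthetic_field`: a list with `image`
#'   (`height x width x 3` array in \[0, 255\]), `annotations` (an
#'   [annotation_set()] of per-tassel boxes) and `config`.
#' @export
generate_field <- function(cfg = field_config()) {
  stopifnot(inherits(cfg, "field_config"))
  withr::with_seed(cfg$seed, {
    h <- cfg$height; w <- cfg$width
    noise <- 1 + cfg$noise_amp * matrix(stats::rnorm(h * w), h, w)
    chans <- lapply(cfg$canopy_base, function(v) pmin(pmax(v * noise, 0), 255))

    vein_col <- pmin(cfg$canopy_base * 1.3, 255)
    n_veins <- round(cfg$vein_density * h * w)
    for (v in seq_len(n_veins)) {
      x0 <- stats::runif(1, 0, w); y0 <- stats::runif(1, 0, h)
      ang <- stats::runif(1, 0, 2 * pi)
      len <- stats::runif(1, 30, 120)
      st <- stroke_coverage(x0, y0, x0 + len * cos(ang), y0 + len * sin(ang),
                            width = 1, h = h, w_img = w)
      if (is.null(st)) next
      for (k in 1:3) {
        chans[[k]][st$rows, st$cols] <-
          (1 - st$cov) * chans[[k]][st$rows, st$cols] + st$cov * vein_col[k]
      }
    }

    tassel_col <- cfg$canopy_base +
      cfg$tassel_contrast * (c(215, 205, 120) - cfg$canopy_base)
    gt <- NULL
    for (i in seq_len(cfg$n_tassels)) {
      placed <- FALSE
      for (try in seq_len(200)) {
        geom <- sample_tassel_geometry(cfg)
        bw <- geom$bbox["xmax"] - geom$bbox["xmin"]
        bh <- geom$bbox["ymax"] - geom$bbox["ymin"]
        if (bw >= w - 1 || bh >= h - 1) next
        bx <- stats::runif(1, -geom$bbox["xmin"], w - geom$bbox["xmax"])
        by <- stats::runif(1, -geom$bbox["ymin"], h - geom$bbox["ymax"])
        cand <- boxes(floor(bx + geom$bbox["xmin"] - 1),
                      floor(by + geom$bbox["ymin"] - 1),
                      ceiling(bx + geom$bbox["xmax"] + 1),
                      ceiling(by + geom$bbox["ymax"] + 1))
        cand$xmin <- max(cand$xmin, 0); cand$ymin <- max(cand$ymin, 0)
        cand$xmax <- min(cand$xmax, w); cand$ymax <- min(cand$ymax, h)
        ok <- TRUE
        if (!is.null(gt) && nrow(gt) > 0) {
          inter <- box_intersection(gt, cand)
          ok <- all(inter <= 0.5 * pmin(box_area(gt), box_area(cand)))
        }
        if (!ok) next
        for (s in seq_len(nrow(geom$segments))) {
          sg <- geom$segments[s, ]
          st <- stroke_coverage(bx + sg[1], by + sg[2], bx + sg[3],
                                by + sg[4], geom$width, h = h, w_img = w)
          if (is.null(st)) next
          for (k in 1:3) {
            chans[[k]][st$rows, st$cols] <-
              (1 - st$cov) * chans[[k]][st$rows, st$cols] +
              st$cov * tassel_col[k]
          }
        }
        gt <- dplyr::bind_rows(gt, cand)
        placed <- TRUE
        break
      }
      if (!placed) {
        stop("could not place tassel ", i, " without excessive box overlap; ",
             "lower n_tassels or enlarge the scene", call. = FALSE)
      }
    }

    img <- array(c(chans[[1]], chans[[2]], chans[[3]]), dim = c(h, w, 3))
    if (is.null(gt)) {
      gt <- tibble::tibble(xmin = numeric(), ymin = numeric(),
                           xmax = numeric(), ymax = numeric())
    }
    ann <- annotation_set(paste0("synthetic_seed", cfg$seed), w, h,
                          dplyr::mutate(gt, class = "tassel"))
    structure(list(image = img, annotations = ann, config = cfg),
              class = "synthetic_field")
  })
}

#' @export
print.synthetic_field <- function(x, ...) {
  cat("<synthetic_field> ", x$config$width, " x ", x$config$height,
      " px, ", nrow(x$annotations$objects), " tassel(s), seed ",
      x$config$seed, "\n", sep = "")
  invisible(x)
}

#' Generate a labelled, split patch dataset from synthetic fields
#'
#' Mirrors the field protocol for building a binary patch training set:
#' positive 128 x 128 patches are extracted centred on the ground-truth boxes
#' of generated fields; negative patches are sampled from tassel-free fields
#' (so backgrounds can contain canopy texture and vein streaks but never a
#' tassel). Classes are exactly balanced and an 80/20 train/test split is
#' assigned per patch under `seed`.
#'
#' @param cfg a [field_config()] describing the fields to draw from.
#' @param n_per_class patches per class.
#' @param seed RNG seed for sub-field seeds, negative sampling and the split.
#' @param train_frac training fraction (default 0.8).
#' @return a tibble with columns `patch` (list of arrays), `label`,
#'   `split`, `source_seed`, `origin_x`, `origin_y`.
#' @export
generate_patch_dataset <- function(cfg = field_config(), n_per_class = 100,
                                   seed = 0, train_frac = 0.8) {
  stopifnot(n_per_class >= 1)
  sub_seeds <- withr::with_seed(seed, sample.int(1e7, 2000))
  si <- 0
  next_seed <- function() {
    si <<- si + 1
    sub_seeds[si]
  }

  pos <- list()
  n_pos <- 0
  while (n_pos < n_per_class) {
    fcfg <- cfg
    fcfg$seed <- next_seed()
    fld <- generate_field(fcfg)
    p <- extract_positive_patches(fld$image, fld$annotations$objects)
    if (nrow(p) == 0) next
    p$source_seed <- fcfg$seed
    pos <- c(pos, list(p))
    n_pos <- n_pos + nrow(p)
  }
  pos <- utils::head(dplyr::bind_rows(pos), n_per_class)

  neg <- list()
  n_neg <- 0
  per_field <- max(25, ceiling(n_per_class / 4))
  while (n_neg < n_per_class) {
    fcfg <- cfg
    fcfg$n_tassels <- 0
    fcfg$seed <- next_seed()
    fld <- generate_field(fcfg)
    p <- extract_negative_patches(fld$image, n = min(per_field, n_per_class - n_neg),
                                  seed = next_seed())
    p$source_seed <- fcfg$seed
    neg <- c(neg, list(p))
    n_neg <- n_neg + nrow(p)
  }
  neg <- utils::head(dplyr::bind_rows(neg), n_per_class)

  ds <- dplyr::bind_rows(
    dplyr::mutate(pos, label = "tassel"),
    dplyr::mutate(neg, label = "no_tassel")
  )
  n <- nrow(ds)
  n_train <- round(train_frac * n)
  idx <- withr::with_seed(seed, sample.int(n))
  ds$split <- "test"
  ds$split[idx[seq_len(n_train)]] <- "train"
  ds[, c("patch", "label", "split", "source_seed", "origin_x", "origin_y")]
}

#' The worked single-image evaluation fixture
#'
#' A concrete layout of 5 ground-truth boxes and 8 scored detections that
#' reproduces the published worked example contrasting the default and
#' customized evaluation protocols on one test image. The geometry is fixed
#' constants chosen so that (all asserted at construction time with [iou()]):
#' the lowest-scoring detection overlaps one ground truth at IoU >= 0.5; six
#' detections have best IoU in \[0.3, 0.5); one detection is below 0.3 with
#' every ground truth; and exactly one ground truth is covered (>= 0.3) by no
#' detection. Under the default protocol this yields tp = 1, fp = 7, fn = 4
#' (precision 1/8, recall 0.2); under the customized protocol the below-0.3
#' detection is the only false positive.
#'
#' @return a list of class `table1_fixture` with `ground_truth` (box tibble),
#'   `detections` (box + `score` tibble, scores
#'   0.9636, 0.9246, 0.8767, 0.8116, 0.8074, 0.7955, 0.7833, 0.7428) and
#'   `image_id`.
#' @export
build_table1_fixture <- function() {
  gt <- boxes(
    xmin = c(0, 300, 600, 0, 600),
    ymin = c(0, 0, 0, 300, 300),
    xmax = c(100, 400, 700, 100, 700),
    ymax = c(100, 100, 100, 400, 400)
  )
  det <- boxes(
    xmin = c(0, 300, 600, 300, 40, 340, 640, 0),
    ymin = c(40, 40, 40, 300, 0, 0, 0, 300),
    xmax = c(100, 400, 700, 400, 140, 440, 740, 100),
    ymax = c(140, 140, 140, 400, 100, 100, 100, 400)
  )
  det$score <- c(96.36, 92.46, 87.67, 81.16, 80.74, 79.55, 78.33, 74.28) / 100

  M <- iou_matrix(det, gt)
  best <- apply(M, 1, max)
  stopifnot(
    best[8] >= 0.5,                              # lowest score, strong match
    all(best[c(1, 2, 3, 5, 6, 7)] >= 0.3),
    all(best[c(1, 2, 3, 5, 6, 7)] < 0.5),
    best[4] < 0.3,                               # matches nothing
    sum(apply(M, 2, max) < 0.3) == 1             # one uncovered ground truth
  )
  structure(
    list(ground_truth = gt, detections = det, image_id = "table1"),
    class = "table1_fixture"
  )
}
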