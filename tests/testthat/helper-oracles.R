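# Independent oracles and shared fixtures for the suite.

# Pixel-counting IoU oracle for integer half-open boxes: enumerate the lattice
# pixels inside each box and count set intersection / union.
oracle_iou <- function(a, b) {
  px <- function(bx) {
    g <- expand.grid(x = seq(bx$xmin, bx$xmax - 1), y = seq(bx$ymin, bx$ymax - 1))
    paste(g$x, g$y)
  }
  pa <- px(a)
  pb <- px(b)
  length(intersect(pa, pb)) / length(union(pa, pb))
}

# Independent re-implementation of the greedy score-ordered matching rule,
# written with plain nested loops and the pixel-count oracle above.
oracle_match_counts <- function(dets, gts, iou_thr, min_score, drop_dups) {
  ord <- order(-dets$score)
  ord <- ord[dets$score[ord] >= min_score]
  matched <- rep(FALSE, nrow(gts))
  tp <- 0L; fp <- 0L; dropped <- 0L
  for (i in ord) {
    if (nrow(gts) == 0) { fp <- fp + 1L; next }
    best_j <- NA_integer_; best <- -1
    for (j in seq_len(nrow(gts))) {
      v <- oracle_iou(dets[i, ], gts[j, ])
      if (v > best) { best <- v; best_j <- j }
    }
    if (best >= iou_thr) {
      if (!matched[best_j]) {
        tp <- tp + 1L
        matched[best_j] <- TRUE
      } else if (drop_dups) {
        dropped <- dropped + 1L
      } else {
        fp <- fp + 1L
      }
    } else {
      fp <- fp + 1L
    }
  }
  list(tp = tp, fp = fp, fn = sum(!matched), dropped = dropped)
}

random_int_boxes <- function(n, lim = 30) {
  x1 <- sample.int(lim, n, replace = TRUE) - 1L
  y1 <- sample.int(lim, n, replace = TRUE) - 1L
  boxes(x1, y1,
        x1 + sample.int(10, n, replace = TRUE),
        y1 + sample.int(10, n, replace = TRUE))
}

# Shared expensive fixtures, built once per test run.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

small_patch_dataset <- function() {
  cached("small_ds", generate_patch_dataset(
    field_config(), n_per_class = 40, seed = 11))
}

small_model <- function() {
  cached("small_model", train_patch_classifier(small_patch_dataset(), seed = 11))
}

default_patch_dataset <- function() {
  cached("default_ds", generate_patch_dataset(
    field_config(), n_per_class = 200, seed = 0))
}

seed0_field <- function() {
  cached("seed0_field", generate_field(field_config(seed = 0)))
}

# Degenerate classifiers for pipeline edge cases: constant score regardless
# of input.
constant_classifier <- function(score_tassel = TRUE) {
  structure(
    list(intercept = if (score_tassel) 50 else -50,
         coefficients = stats::setNames(rep(0, 9), names(featurize_patch(
           array(0, dim = c(8, 8, 3))))),
         threshold = 0.5, lambda = 0, seed = 0, n_train = 0,
         format_version = 1L),
    class = "patch_classifier"
  )
}
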