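# Local mean filter with edge-clamped windows, via 2-D cumulative sums.
# Exact mean over the intersection of the (2r+1)^2 window with the image.
mean_filter <- function(m, r = 4) {
  h <- nrow(m); w <- ncol(m)
  S <- matrix(0, h + 1, w + 1)
  S[-1, -1] <- apply(apply(m, 2, cumsum), 1, cumsum) |> t()
  y1 <- pmax(seq_len(h) - r, 1); y2 <- pmin(seq_len(h) + r, h)
  x1 <- pmax(seq_len(w) - r, 1); x2 <- pmin(seq_len(w) + r, w)
  tot <- S[y2 + 1, x2 + 1, drop = FALSE] - S[y1, x2 + 1, drop = FALSE] -
    S[y2 + 1, x1, drop = FALSE] + S[y1, x1, drop = FALSE]
  cnt <- outer(y2 - y1 + 1, x2 - x1 + 1)
  tot / cnt
}

#' Summarise a patch as a fixed-length feature vector
#'
#' The reference patch descriptor: per-channel mean and standard deviation
#' (6 values), plus three statistics of a bright-residual mask designed to
#' respond to thin, locally bright structures such as tassel branches. The
#' mask keeps pixels whose luminance exceeds its local (9 x 9) mean by more
#' than `2 * sd(residual)` and by at least 4 grey levels; from it we take the
#' mask fraction, the connected-component count, and the mean component
#' elongation (ratio of principal second-moment axes — high for line-like
#' structures, ~1 for blobs).
#'
#' @param patch a `p x p x 3` array, values in \[0, 255\].
#' @return a named numeric vector of length 9, constant across inputs.
#' @export
featurize_patch <- function(patch) {
  d <- dim(patch)
  if (length(d) != 3 || d[3] != 3) {
    stop("patch must be a height x width x 3 array", call. = FALSE)
  }
  ch_mean <- apply(patch, 3, mean)
  ch_sd <- apply(patch, 3, stats::sd)
  lum <- 0.299 * patch[, , 1] + 0.587 * patch[, , 2] + 0.114 * patch[, , 3]
  resid <- lum - mean_filter(lum, r = 4)
  thr <- max(2 * stats::sd(resid), 4)
  mask <- resid > thr
  frac <- mean(mask)
  n_comp <- 0
  elong <- 0
  if (any(mask)) {
    # label a 3x3-dilated mask so thin anti-aliased strokes (including
    # diagonal runs) group into one component, then measure the original
    # mask pixels per group
    lab_d <- EBImage::bwlabel(
      EBImage::dilate(mask * 1, EBImage::makeBrush(3, shape = "box")))
    lab <- lab_d * mask
    comp_ids <- sort(unique(lab[lab > 0]))
    n_comp <- length(comp_ids)
    el <- vapply(comp_ids, function(k) {
      idx <- which(lab == k, arr.ind = TRUE)
      if (nrow(idx) < 2) return(1)
      # principal-axis ratio of the pixel coordinate cloud; 1/12 regularises
      # single-pixel-wide runs
      cv <- stats::cov(idx) + diag(1 / 12, 2)
      ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
      sqrt(ev[1] / ev[2])
    }, numeric(1))
    elong <- mean(el)
  }
  c(mean_r = ch_mean[1], mean_g = ch_mean[2], mean_b = ch_mean[3],
    sd_r = ch_sd[1], sd_g = ch_sd[2], sd_b = ch_sd[3],
    resid_frac = frac, n_components = n_comp, mean_elongation = elong)
}

featurize_patches <- function(patches) {
  t(vapply(patches, featurize_patch, numeric(9)))
}

#' Train the reference patch classifier
#'
#' Fits only a final decision layer — a ridge-regularised logistic regression
#' on the fixed features of [featurize_patch()] — on the training split of a
#' patch dataset. The heavy feature learning a CNN would do is out of scope
#' here; the classifier is a pluggable contract and any model producing a
#' score in \[0, 1\] per patch can stand in.
#'
#' @param dataset a patch dataset tibble with list-column `patch`, `label`
#'   (`"tassel"` / `"no_tassel"`) and `split` (`"train"` / `"test"`) columns,
#'   as produced by [generate_patch_dataset()].
#' @param seed RNG seed recorded with the model (the fit itself is
#'   deterministic).
#' @param lambda ridge penalty of the decision layer.
#' @param threshold decision threshold on the tassel score (default 0.5; can
#'   be lowered to prioritise recall).
#' @return an object of class `patch_classifier` holding the fitted
#'   coefficients, feature scaling, threshold and seed.
#' @export
train_patch_classifier <- function(dataset, seed = 0, lambda = 1e-2,
                                   threshold = 0.5) {
  train <- dataset[dataset$split == "train", ]
  if (length(unique(train$label)) < 2) {
    stop("training split must contain both classes", call. = FALSE)
  }
  x <- featurize_patches(train$patch)
  y <- as.integer(train$label == "tassel")
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                        lambda = lambda, standardize = TRUE)
  beta <- as.numeric(stats::coef(fit, s = lambda))
  structure(
    list(intercept = beta[1], coefficients = stats::setNames(beta[-1], colnames(x)),
         threshold = threshold, lambda = lambda, seed = seed,
         n_train = nrow(train), format_version = 1L),
    class = "patch_classifier"
  )
}

#' @export
print.patch_classifier <- function(x, ...) {
  cat("<patch_classifier> ridge logistic decision layer on",
      length(x$coefficients), "features\n")
  cat("  trained on", x$n_train, "patches; threshold", x$threshold,
      "; seed", x$seed, "\n")
  invisible(x)
}

#' Score patches with a trained classifier
#'
#' @param object a `patch_classifier`.
#' @param patches a list of patch arrays, or a feature matrix.
#' @param type `"score"` (probability of tassel) or `"label"`.
#' @param ... unused.
#' @return numeric scores in \[0, 1\], or a character vector of labels.
#' @export
predict.patch_classifier <- function(object, patches,
                                     type = c("score", "label"), ...) {
  type <- match.arg(type)
  x <- if (is.matrix(patches)) patches else featurize_patches(patches)
  score <- stats::plogis(object$intercept +
                           drop(x %*% object$coefficients))
  if (type == "score") score
  else ifelse(score >= object$threshold, "tassel", "no_tassel")
}

#' Save / load a patch classifier as a portable text file
#'
#' The model is a handful of coefficients; it is stored as plain
#' tag-and-value text with a format-version header.
#'
#' @param model a `patch_classifier`.
#' @param path file path.
#' @return `path` (save) or the restored `patch_classifier` (load).
#' @export
save_patch_classifier <- function(model, path) {
  stopifnot(inherits(model, "patch_classifier"))
  lines <- c(
    paste0("tasselcv_patch_classifier v", model$format_version),
    paste0("intercept\t", format(model$intercept, digits = 17)),
    paste0("threshold\t", format(model$threshold, digits = 17)),
    paste0("lambda\t", format(model$lambda, digits = 17)),
    paste0("seed\t", model$seed),
    paste0("n_train\t", model$n_train),
    paste0(names(model$coefficients), "\t",
           format(model$coefficients, digits = 17))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname save_patch_classifier
#' @export
load_patch_classifier <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "tasselcv_patch_classifier v")) {
    stop("not a tasselcv patch classifier file: ", path, call. = FALSE)
  }
  kv <- strsplit(lines[-1], "\t", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, `[`, "", 2)
  num <- function(k) as.numeric(vals[keys == k])
  scalar <- c("intercept", "threshold", "lambda", "seed", "n_train")
  coef_keys <- setdiff(keys, scalar)
  structure(
    list(intercept = num("intercept"),
         coefficients = stats::setNames(
           as.numeric(vals[match(coef_keys, keys)]), coef_keys),
         threshold = num("threshold"), lambda = num("lambda"),
         seed = num("seed"), n_train = num("n_train"),
         format_version = 1L),
    class = "patch_classifier"
  )
}

#' Evaluate a patch classifier on the held-out split
#'
#' Positive class is `tassel`. Reports the confusion counts and accuracy,
#' precision, recall and F1 (undefined denominators as `NA`).
#'
#' @param model a `patch_classifier`.
#' @param dataset a patch dataset tibble (see [train_patch_classifier()]);
#'   the `split == "test"` rows are used.
#' @return an object of class `patch_eval` with `confusion` counts and a
#'   `metrics` one-row tibble; `tidy()` gives per-patch predictions,
#'   `glance()` the metrics row.
#' @export
evaluate_patch_classifier <- function(model, dataset) {
  test <- dataset[dataset$split == "test", ]
  if (nrow(test) == 0) stop("empty test split", call. = FALSE)
  score <- predict(model, test$patch)
  pred <- ifelse(score >= model$threshold, "tassel", "no_tassel")
  tp <- sum(pred == "tassel" & test$label == "tassel")
  fp <- sum(pred == "tassel" & test$label == "no_tassel")
  fn <- sum(pred == "no_tassel" & test$label == "tassel")
  tn <- sum(pred == "no_tassel" & test$label == "no_tassel")
  pr <- precision_recall(tp, fp = fp, fn = fn)
  metrics <- tibble::tibble(
    accuracy = (tp + tn) / nrow(test),
    precision = pr$precision, recall = pr$recall,
    f1 = f1_score(pr$precision, pr$recall)
  )
  structure(
    list(confusion = tibble::tibble(tp = tp, fp = fp, fn = fn, tn = tn),
         metrics = metrics,
         predictions = tibble::tibble(label = test$label, score = score,
                                      predicted = pred)),
    class = "patch_eval"
  )
}

#' @export
print.patch_eval <- function(x, ...) {
  cat("<patch_eval> n =", nrow(x$predictions), "\n")
  cat("  tp =", x$confusion$tp, " fp =", x$confusion$fp,
      " fn =", x$confusion$fn, " tn =", x$confusion$tn, "\n")
  m <- x$metrics
  cat(sprintf("  accuracy %.4f  precision %s  recall %s  f1 %s\n",
              m$accuracy, format(m$precision, digits = 4),
              format(m$recall, digits = 4), format(m$f1, digits = 4)))
  invisible(x)
}

#' @export
tidy.patch_eval <- function(x, ...) x$predictions

#' @export
glance.patch_eval <- function(x, ...) {
  dplyr::bind_cols(x$confusion, x$metrics)
}
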