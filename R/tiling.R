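#' Lay out a non-overlapping tile grid over an image
#'
#' Raw UAV frames (typically 3000 x 4000 px) are cut into square subimages
#' before annotation and classification. Tiles are enumerated row-major from
#' the top-left; remainder pixels beyond the last full tile on each axis are
#' dropped. A 3000 x 4000 frame at `tile_size = 1000` gives a 3 x 4 grid of
#' 12 tiles.
#'
#' @param width,height source image size in pixels.
#' @param tile_size tile edge length in pixels (default 1000).
#' @return a tibble with one row per tile: `tile` (1-based row-major index),
#'   `row`, `col` (0-based), `origin_x`, `origin_y` (0-based pixel offsets of
#'   the tile's top-left corner).
#' @examples
#' tile_grid(4000, 3000) # 12 tiles
#' @export
tile_grid <- function(width, height, tile_size = 1000) {
  if (width < tile_size || height < tile_size) {
    stop("image (", width, " x ", height,
         ") is smaller than tile_size = ", tile_size, call. = FALSE)
  }
  rows <- floor(height / tile_size)
  cols <- floor(width / tile_size)
  g <- tidyr::expand_grid(row = seq_len(rows) - 1L, col = seq_len(cols) - 1L)
  tibble::tibble(
    tile = seq_len(nrow(g)),
    row = g$row, col = g$col,
    origin_x = g$col * tile_size,
    origin_y = g$row * tile_size,
    tile_size = tile_size
  )
}

#' Cut an image into subimage tiles
#'
#' @param img a `height x width x 3` array, values in \[0, 255\].
#' @param tile_size tile edge length (default 1000).
#' @return a list with `grid` (the [tile_grid()] tibble) and `tiles` (a list
#'   of `tile_size x tile_size x 3` arrays in grid order).
#' @export
tile_image <- function(img, tile_size = 1000) {
  d <- dim(img)
  grid <- tile_grid(width = d[2], height = d[1], tile_size = tile_size)
  tiles <- purrr::pmap(grid, function(origin_x, origin_y, ...) {
    img[(origin_y + 1):(origin_y + tile_size),
        (origin_x + 1):(origin_x + tile_size), , drop = FALSE]
  })
  list(grid = grid, tiles = tiles)
}

#' Lay out a patch grid over a subimage
#'
#' Fixed-size classification patches (default 128 px) tile a subimage at
#' stride `patch_size`. Because 1000 is not a multiple of 128, the far edge
#' needs a policy: with `edge_mode = "flush"` the last patch on each axis is
#' shifted back so its far edge coincides with the image border (patches may
#' then overlap by up to `patch_size - 1` px and every pixel is covered);
#' with `edge_mode = "drop"` the remainder is left unclassified. A 1000-px
#' axis under `flush` gives offsets 0, 128, ..., 768, 872 — 8 patches.
#'
#' @param width,height subimage size in pixels.
#' @param patch_size patch edge length (default 128).
#' @param edge_mode `"flush"` (default) or `"drop"`.
#' @return a tibble with `patch`, `row`, `col`, `origin_x`, `origin_y`,
#'   `patch_size` columns, row-major enumeration.
#' @examples
#' nrow(patch_grid(1000, 1000)) # 64
#' @export
patch_grid <- function(width, height, patch_size = 128,
                       edge_mode = c("flush", "drop")) {
  edge_mode <- match.arg(edge_mode)
  if (width < patch_size || height < patch_size) {
    stop("subimage (", width, " x ", height,
         ") is smaller than patch_size = ", patch_size, call. = FALSE)
  }
  offsets <- function(extent) {
    k <- floor(extent / patch_size)
    off <- (seq_len(k) - 1L) * patch_size
    if (edge_mode == "flush" && k * patch_size < extent) {
      off <- c(off, extent - patch_size)
    }
    off
  }
  ox <- offsets(width)
  oy <- offsets(height)
  g <- tidyr::expand_grid(row = seq_along(oy) - 1L, col = seq_along(ox) - 1L)
  tibble::tibble(
    patch = seq_len(nrow(g)),
    row = g$row, col = g$col,
    origin_x = ox[g$col + 1L],
    origin_y = oy[g$row + 1L],
    patch_size = patch_size
  )
}

#' Map tile-local box coordinates back to the source image
#'
#' Inverse of cropping: a box expressed in the coordinates of tile (or patch)
#' `index` of `grid` is translated by the tile origin. `map_to_source`
#' composed with cropping is the identity on coordinates.
#'
#' @param grid a [tile_grid()] or [patch_grid()] tibble.
#' @param local_box a box tibble in tile-local coordinates.
#' @param index 1-based tile index into `grid`.
#' @return the translated box tibble in source coordinates.
#' @export
map_to_source <- function(grid, local_box, index) {
  stopifnot(index >= 1, index <= nrow(grid))
  local_box <- validate_boxes(local_box)
  ts_col <- intersect(c("tile_size", "patch_size"), names(grid))[1]
  ts <- grid[[ts_col]][index]
  if (any(local_box$xmin < 0 | local_box$ymin < 0 |
          local_box$xmax > ts | local_box$ymax > ts)) {
    stop("local box outside tile bounds (tile size ", ts, ")", call. = FALSE)
  }
  shift_boxes(local_box, grid$origin_x[index], grid$origin_y[index])
}

#' Crop a box region out of an image array
#'
#' @param img a `height x width x 3` array.
#' @param b a single-row box tibble (0-based half-open, integer coordinates).
#' @return the cropped array.
#' @export
crop_box <- function(img, b) {
  b <- validate_boxes(b)
  stopifnot(nrow(b) == 1)
  d <- dim(img)
  if (b$xmin < 0 || b$ymin < 0 || b$xmax > d[2] || b$ymax > d[1]) {
    stop("crop box outside image bounds", call. = FALSE)
  }
  img[(b$ymin + 1):b$ymax, (b$xmin + 1):b$xmax, , drop = FALSE]
}

#' Extract one positive training patch per annotation
#'
#' For every annotated box a `patch_size` window is centred on the box centre
#' — maximising tassel visibility with minimal background — and translated
#' (never shrunk) to fit inside the subimage when the centred window would
#' overflow an edge.
#'
#' @param img a `height x width x 3` subimage array.
#' @param annotations a box tibble of ground-truth annotations, all inside
#'   the image.
#' @param patch_size patch edge length (default 128).
#' @return a tibble with `origin_x`, `origin_y`, `xmin`, `ymin`, `xmax`,
#'   `ymax` (the patch window) and a list-column `patch` of
#'   `patch_size x patch_size x 3` arrays.
#' @export
extract_positive_patches <- function(img, annotations, patch_size = 128) {
  d <- dim(img)
  if (nrow(annotations) == 0) {
    return(tibble::tibble(origin_x = integer(), origin_y = integer(),
                          xmin = numeric(), ymin = numeric(),
                          xmax = numeric(), ymax = numeric(), patch = list()))
  }
  annotations <- validate_boxes(annotations)
  cx <- (annotations$xmin + annotations$xmax) / 2
  cy <- (annotations$ymin + annotations$ymax) / 2
  ox <- pmin(pmax(round(cx - patch_size / 2), 0), d[2] - patch_size)
  oy <- pmin(pmax(round(cy - patch_size / 2), 0), d[1] - patch_size)
  win <- boxes(ox, oy, ox + patch_size, oy + patch_size)
  patches <- purrr::map(seq_len(nrow(win)), function(i) {
    crop_box(img, win[i, ])
  })
  tibble::tibble(origin_x = as.integer(ox), origin_y = as.integer(oy),
                 win, patch = patches)
}

#' Sample negative (background) training patches
#'
#' Draws `n` patch windows uniformly at random from an image that carries no
#' annotations — the guard keeps label purity: backgrounds may contain grass,
#' soil and leaves, but no tassel. Deterministic given `seed`.
#'
#' @param img a `height x width x 3` array.
#' @param annotations the image's annotation box tibble; must be empty.
#' @param n number of patches.
#' @param seed RNG seed.
#' @param patch_size patch edge length (default 128).
#' @return a tibble shaped like [extract_positive_patches()]'s result.
#' @export
extract_negative_patches <- function(img, annotations = NULL, n, seed,
                                     patch_size = 128) {
  if (!is.null(annotations) && nrow(annotations) > 0) {
    stop("negative patches must come from an image with zero annotations",
         call. = FALSE)
  }
  d <- dim(img)
  if (d[1] < patch_size || d[2] < patch_size) {
    stop("image smaller than patch_size", call. = FALSE)
  }
  if (n == 0) {
    return(tibble::tibble(origin_x = integer(), origin_y = integer(),
                          xmin = numeric(), ymin = numeric(),
                          xmax = numeric(), ymax = numeric(), patch = list()))
  }
  withr::with_seed(seed, {
    ox <- sample.int(d[2] - patch_size + 1L, n, replace = TRUE) - 1L
    oy <- sample.int(d[1] - patch_size + 1L, n, replace = TRUE) - 1L
  })
  win <- boxes(ox, oy, ox + patch_size, oy + patch_size)
  patches <- purrr::map(seq_len(n), function(i) crop_box(img, win[i, ]))
  tibble::tibble(origin_x = as.integer(ox), origin_y = as.integer(oy),
                 win, patch = patches)
}
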