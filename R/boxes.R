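#' Build a tibble of axis-aligned pixel boxes
#'
#' Boxes are the unit of ground truth and detection throughout the package.
#' Coordinates are 0-based, half-open: a box covers the pixel lattice
#' `[xmin, xmax) x [ymin, ymax)` with the origin at the top-left corner of the
#' image and y increasing downward. A valid box has strictly positive area.
#'
#' @param xmin,ymin,xmax,ymax numeric vectors of equal length (recycled by
#'   the usual tibble rules); pixel coordinates.
#' @return a tibble with columns `xmin`, `ymin`, `xmax`, `ymax`.
#' @examples
#' boxes(0, 0, c(10, 20), c(10, 20))
#' @export
boxes <- function(xmin, ymin, xmax, ymax) {
  b <- tibble::tibble(xmin = xmin, ymin = ymin, xmax = xmax, ymax = ymax)
  validate_boxes(b)
}

#' Validate box coordinates
#'
#' Checks the half-open box invariant `xmin < xmax`, `ymin < ymax`
#' (strictly positive area) on every row.
#'
#' @param b a data frame with columns `xmin`, `ymin`, `xmax`, `ymax`.
#' @return `b`, invisibly coerced to a tibble, if valid; otherwise an error.
#' @export
validate_boxes <- function(b) {
  req <- c("xmin", "ymin", "xmax", "ymax")
  missing_cols <- setdiff(req, names(b))
  if (length(missing_cols) > 0) {
    stop("box table is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  b <- tibble::as_tibble(b)
  bad <- which(!(b$xmin < b$xmax & b$ymin < b$ymax))
  if (length(bad) > 0) {
    stop("invalid (zero- or negative-area) box at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(b$xmin) | !is.finite(b$ymin) |
          !is.finite(b$xmax) | !is.finite(b$ymax))) {
    stop("box coordinates must be finite", call. = FALSE)
  }
  b
}

#' Box areas
#'
#' @param b a box tibble (see [boxes()]).
#' @return numeric vector of areas `(xmax - xmin) * (ymax - ymin)`.
#' @export
box_area <- function(b) {
  b <- validate_boxes(b)
  (b$xmax - b$xmin) * (b$ymax - b$ymin)
}

#' Intersection area of paired boxes
#'
#' Vectorised over rows: `a` and `b` must have the same number of rows (or one
#' of them a single row, which is recycled).
#'
#' @param a,b box tibbles.
#' @return numeric vector of intersection areas (0 when disjoint).
#' @export
box_intersection <- function(a, b) {
  a <- validate_boxes(a)
  b <- validate_boxes(b)
  iw <- pmax(0, pmin(a$xmax, b$xmax) - pmax(a$xmin, b$xmin))
  ih <- pmax(0, pmin(a$ymax, b$ymax) - pmax(a$ymin, b$ymin))
  iw * ih
}

#' Intersection over Union of paired boxes
#'
#' The matching criterion between a detection and a ground-truth box: the
#' overlap area of the two boxes divided by the area of their union. Symmetric,
#' bounded in \[0, 1\]; 0 for disjoint boxes and 1 exactly when the boxes are
#' identical.
#'
#' @param a,b box tibbles with equal row counts (or one single-row, recycled).
#' @return numeric vector of IoU values in \[0, 1\].
#' @examples
#' iou(boxes(0, 0, 2, 2), boxes(1, 1, 3, 3)) # 1/7
#' @export
iou <- function(a, b) {
  inter <- box_intersection(a, b)
  u <- box_area(a) + box_area(b) - inter
  inter / u
}

#' IoU matrix between two sets of boxes
#'
#' @param a a box tibble with `n` rows.
#' @param b a box tibble with `m` rows.
#' @return an `n x m` numeric matrix; entry `(i, j)` is `iou(a[i, ], b[j, ])`.
#'   Either input may be empty, giving a 0-row/0-column matrix.
#' @export
iou_matrix <- function(a, b) {
  n <- nrow(a)
  m <- nrow(b)
  if (n == 0 || m == 0) {
    return(matrix(numeric(0), nrow = n, ncol = m))
  }
  a <- validate_boxes(a)
  b <- validate_boxes(b)
  iw <- pmax(0, outer(a$xmax, b$xmax, pmin) - outer(a$xmin, b$xmin, pmax))
  ih <- pmax(0, outer(a$ymax, b$ymax, pmin) - outer(a$ymin, b$ymin, pmax))
  inter <- iw * ih
  u <- outer(box_area(a), box_area(b), `+`) - inter
  inter / u
}

#' Translate boxes by an offset
#'
#' @param b a box tibble.
#' @param dx,dy pixel offsets added to the x and y coordinates.
#' @return the translated box tibble.
#' @export
shift_boxes <- function(b, dx, dy) {
  b <- validate_boxes(b)
  dplyr::mutate(b,
    xmin = .data$xmin + dx, xmax = .data$xmax + dx,
    ymin = .data$ymin + dy, ymax = .data$ymax + dy
  )
}
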