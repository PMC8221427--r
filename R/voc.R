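#' Read a PASCAL VOC XML annotation file (LabelImg dialect)
#'
#' Parses the `annotation/size` and `object/bndbox` elements written by the
#' LabelImg annotation tool. VOC stores 1-based inclusive pixel coordinates;
#' they are converted to the package's 0-based half-open convention as
#' `xmin <- xmin - 1`, `xmax <- xmax` (and likewise for y), which preserves
#' the box width and height.
#'
#' @param path path to the XML file.
#' @return an `annotation_set`: a list with `image_id`, `width`, `height`,
#'   and `objects` — a tibble with columns `class`, `xmin`, `ymin`, `xmax`,
#'   `ymax` (0-based half-open). A file with zero `object` elements yields an
#'   empty tibble (legal: a tassel-free image).
#' @examples
#' a <- annotation_set("img1", 100, 100, boxes(0, 0, 10, 10))
#' f <- tempfile(fileext = ".xml")
#' write_voc_xml(a, f)
#' read_voc_xml(f)$objects
#' @export
read_voc_xml <- function(path) {
  doc <- xml2::read_xml(path)
  fname <- xml2::xml_text(xml2::xml_find_first(doc, "./filename"))
  size <- xml2::xml_find_first(doc, "./size")
  if (inherits(size, "xml_missing")) {
    stop("VOC parse error in '", path, "': missing <size> element", call. = FALSE)
  }
  width <- as.integer(xml2::xml_text(xml2::xml_find_first(size, "./width")))
  height <- as.integer(xml2::xml_text(xml2::xml_find_first(size, "./height")))
  if (is.na(width) || is.na(height)) {
    stop("VOC parse error in '", path, "': missing size/width or size/height",
         call. = FALSE)
  }
  objs <- xml2::xml_find_all(doc, "./object")
  field <- function(node, xp) {
    v <- xml2::xml_find_first(node, xp)
    if (inherits(v, "xml_missing")) {
      stop("VOC parse error in '", path, "': object missing <",
           sub("^.*/", "", xp), ">", call. = FALSE)
    }
    xml2::xml_text(v)
  }
  rows <- purrr::map(objs, function(o) {
    bb <- xml2::xml_find_first(o, "./bndbox")
    if (inherits(bb, "xml_missing")) {
      stop("VOC parse error in '", path, "': object missing <bndbox>",
           call. = FALSE)
    }
    num <- function(tag) {
      v <- xml2::xml_find_first(bb, paste0("./", tag))
      if (inherits(v, "xml_missing")) {
        stop("VOC parse error in '", path, "': bndbox missing <", tag, ">",
             call. = FALSE)
      }
      as.numeric(xml2::xml_text(v))
    }
    tibble::tibble(
      class = field(o, "./name"),
      xmin = num("xmin") - 1, ymin = num("ymin") - 1,
      xmax = num("xmax"), ymax = num("ymax")
    )
  })
  objects <- if (length(rows) == 0) {
    tibble::tibble(class = character(), xmin = numeric(), ymin = numeric(),
                   xmax = numeric(), ymax = numeric())
  } else {
    dplyr::bind_rows(rows)
  }
  if (nrow(objects) > 0) {
    validate_boxes(objects)
    if (any(objects$xmin < 0 | objects$ymin < 0 |
            objects$xmax > width | objects$ymax > height)) {
      stop("VOC validation error in '", path, "': box outside image bounds",
           call. = FALSE)
    }
  }
  image_id <- if (is.na(fname) || fname == "") {
    sub("\\.xml$", "", basename(path))
  } else {
    sub("\\.(png|jpg|jpeg)$", "", fname, ignore.case = TRUE)
  }
  annotation_set(image_id, width, height, objects)
}

#' Construct an annotation set
#'
#' @param image_id identifier of the annotated image (file stem).
#' @param width,height image size in pixels.
#' @param objects a box tibble, optionally with a `class` column (defaults
#'   to `"tassel"`); 0-based half-open coordinates, all inside the image.
#' @return an object of class `annotation_set`.
#' @export
annotation_set <- function(image_id, width, height, objects = NULL) {
  if (is.null(objects)) {
    objects <- tibble::tibble(class = character(), xmin = numeric(),
                              ymin = numeric(), xmax = numeric(),
                              ymax = numeric())
  }
  objects <- tibble::as_tibble(objects)
  if (!"class" %in% names(objects)) objects$class <- "tassel"
  objects <- objects[, c("class", "xmin", "ymin", "xmax", "ymax")]
  if (nrow(objects) > 0) {
    validate_boxes(objects)
    stopifnot(all(nzchar(objects$class)))
    if (any(objects$xmin < 0 | objects$ymin < 0 |
            objects$xmax > width | objects$ymax > height)) {
      stop("annotation box outside image bounds", call. = FALSE)
    }
  }
  structure(
    list(image_id = image_id, width = as.integer(width),
         height = as.integer(height), objects = objects),
    class = "annotation_set"
  )
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("<annotation_set> ", x$image_id, " (", x$width, " x ", x$height,
      " px), ", nrow(x$objects), " object(s)\n", sep = "")
  invisible(x)
}

#' Write an annotation set as LabelImg-dialect VOC XML
#'
#' Inverse of [read_voc_xml()]: internal 0-based half-open coordinates are
#' written back as 1-based inclusive VOC coordinates. Reading a file written
#' by this function reproduces the input annotation set exactly.
#'
#' @param a an [annotation_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_voc_xml <- function(a, path) {
  stopifnot(inherits(a, "annotation_set"))
  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "folder", "images")
  xml2::xml_add_child(doc, "filename", paste0(a$image_id, ".png"))
  size <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(size, "width", as.character(a$width))
  xml2::xml_add_child(size, "height", as.character(a$height))
  xml2::xml_add_child(size, "depth", "3")
  xml2::xml_add_child(doc, "segmented", "0")
  for (i in seq_len(nrow(a$objects))) {
    o <- xml2::xml_add_child(doc, "object")
    xml2::xml_add_child(o, "name", a$objects$class[i])
    xml2::xml_add_child(o, "pose", "Unspecified")
    xml2::xml_add_child(o, "truncated", "0")
    xml2::xml_add_child(o, "difficult", "0")
    bb <- xml2::xml_add_child(o, "bndbox")
    fmt <- function(v) format(v, scientific = FALSE, trim = TRUE)
    xml2::xml_add_child(bb, "xmin", fmt(a$objects$xmin[i] + 1))
    xml2::xml_add_child(bb, "ymin", fmt(a$objects$ymin[i] + 1))
    xml2::xml_add_child(bb, "xmax", fmt(a$objects$xmax[i]))
    xml2::xml_add_child(bb, "ymax", fmt(a$objects$ymax[i]))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read / write detection files
#'
#' Detections travel as comma-delimited UTF-8 text with the header
#' `image_id,xmin,ymin,xmax,ymax,score`. Row order is preserved and a
#' write-then-read round trip is lossless (scores are written with 6 decimal
#' places).
#'
#' @param path file path.
#' @return `read_detections()`: a tibble with the six columns above; a file
#'   holding only the header yields an empty tibble.
#' @export
read_detections <- function(path) {
  d <- readr::read_csv(path, col_types = readr::cols(
    image_id = readr::col_character(),
    xmin = readr::col_double(), ymin = readr::col_double(),
    xmax = readr::col_double(), ymax = readr::col_double(),
    score = readr::col_double()
  ))
  prob <- readr::problems(d)
  if (nrow(prob) > 0) {
    stop("malformed detection file '", path, "' at line ", prob$row[1] + 1,
         ": ", prob$expected[1], call. = FALSE)
  }
  need <- c("image_id", "xmin", "ymin", "xmax", "ymax", "score")
  if (!identical(names(d)[seq_along(need)], need)) {
    stop("detection file '", path, "' must have header ",
         paste(need, collapse = ","), call. = FALSE)
  }
  if (nrow(d) > 0) {
    validate_boxes(d)
    if (any(d$score < 0 | d$score > 1)) {
      stop("detection scores in '", path, "' must lie in [0, 1]", call. = FALSE)
    }
  }
  d
}

#' @rdname read_detections
#' @param d a detection tibble (`image_id`, box columns, `score`).
#' @export
write_detections <- function(d, path) {
  d <- tibble::as_tibble(d)
  if (!"image_id" %in% names(d)) d$image_id <- "image"
  d <- d[, c("image_id", "xmin", "ymin", "xmax", "ymax", "score")]
  d$score <- round(d$score, 6)
  readr::write_csv(d, path)
  invisible(path)
}

#' Read / write RGB images
#'
#' Thin wrappers over the PNG codec. Images are represented throughout the
#' package as numeric arrays `height x width x 3` with channel values in
#' \[0, 255\].
#'
#' @param path file path.
#' @return `read_image()`: the image array.
#' @export
read_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) {
    img <- array(rep(img, 3), dim = c(dim(img), 3))
  }
  img[, , 1:3, drop = FALSE] * 255
}

#' @rdname read_image
#' @param img a `height x width x 3` array, values in \[0, 255\].
#' @export
write_image <- function(img, path) {
  stopifnot(length(dim(img)) == 3)
  png::writePNG(pmin(pmax(img / 255, 0), 1), path)
  invisible(path)
}
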