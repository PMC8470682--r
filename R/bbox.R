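#' Axis-aligned bounding boxes
#'
#' Boxes are the detector's input/output currency.  A box table is a
#' `data.frame` with integer-valued columns `x_min`, `y_min`, `width`,
#' `height` (pixels).  Coordinates are 0-based with a top-left origin and
#' half-open extent: the box covers `x_min <= x < x_min + width` and
#' `y_min <= y < y_min + height`.  `bbox()` builds a validated one-row
#' table; `bbox_table()` validates a many-row table.
#'
#' @param x_min,y_min top-left corner (pixels, 0-based).
#' @param width,height box extent in pixels, both >= 1.
#' @return A `data.frame` with columns `x_min`, `y_min`, `width`, `height`.
#' @examples
#' b <- bbox(10, 20, 40, 30)
#' bbox_area(b)       # 1200
#' bbox_center(b)     # (30, 35)
#' @export
bbox <- function(x_min, y_min, width, height) {
  bbox_table(data.frame(x_min = x_min, y_min = y_min,
                        width = width, height = height))
}

#' @rdname bbox
#' @param boxes a data.frame of boxes.
#' @param image_width,image_height optional image bounds; when given,
#'   every box must lie inside them.
#' @export
bbox_table <- function(boxes, image_width = NULL, image_height = NULL) {
  need <- c("x_min", "y_min", "width", "height")
  if (!all(need %in% names(boxes)))
    stop("box table needs columns ", paste(need, collapse = ", "))
  if (nrow(boxes) > 0) {
    if (any(boxes$width < 1) || any(boxes$height < 1))
      stop("box width and height must be >= 1")
    if (any(boxes$x_min < 0) || any(boxes$y_min < 0))
      stop("box coordinates must be >= 0")
    if (!is.null(image_width) &&
        (any(boxes$x_min + boxes$width > image_width) ||
         any(boxes$y_min + boxes$height > image_height)))
      stop("box outside image bounds")
  }
  boxes
}

#' @rdname bbox
#' @param box a box table (any number of rows).
#' @export
bbox_area <- function(box) box$width * box$height

#' @rdname bbox
#' @export
bbox_center <- function(box)
  cbind(x = box$x_min + box$width / 2, y = box$y_min + box$height / 2)

#' Intersection-over-union of two boxes
#'
#' @param a,b one-row box tables (or lists with the four fields).
#' @return IoU in \[0, 1\].
#' @export
bbox_iou <- function(a, b) {
  ix <- max(0, min(a$x_min + a$width, b$x_min + b$width) - max(a$x_min, b$x_min))
  iy <- max(0, min(a$y_min + a$height, b$y_min + b$height) - max(a$y_min, b$y_min))
  inter <- ix * iy
  inter / (a$width * a$height + b$width * b$height - inter)
}

#' Convert a binary ground-truth mask to bounding boxes
#'
#' One box per 8-connected white component: the tight minimum/maximum
#' row and column extent of the component, following the convention of
#' mask-annotated polyp datasets where the boundaries of the white
#' region become the four sides of the box.
#'
#' @param mask binary matrix (values 0/1 or logical), same orientation as
#'   the image (`mask[row, col]`).
#' @param connectivity 8 (default) or 4.
#' @return A box table with one row per component and a `component`
#'   column; zero rows for an all-black mask (a normal frame).
#' @export
mask_to_bboxes <- function(mask, connectivity = 8) {
  if (is.array(mask) && length(dim(mask)) == 3L) mask <- mask[, , 1]
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  if (!all(m %in% c(0L, 1L))) stop("mask must be binary")
  lab <- cpp_label_components(m, as.integer(connectivity))
  k <- max(lab)
  if (k == 0L)
    return(data.frame(x_min = integer(), y_min = integer(),
                      width = integer(), height = integer(),
                      component = integer()))
  rows <- row(lab)[lab > 0]; cols <- col(lab)[lab > 0]; ids <- lab[lab > 0]
  y0 <- tapply(rows, ids, min) - 1L; y1 <- tapply(rows, ids, max) - 1L
  x0 <- tapply(cols, ids, min) - 1L; x1 <- tapply(cols, ids, max) - 1L
  data.frame(x_min = as.integer(x0), y_min = as.integer(y0),
             width = as.integer(x1 - x0 + 1L), height = as.integer(y1 - y0 + 1L),
             component = seq_len(k))
}
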