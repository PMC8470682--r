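#' Annotated image records
#'
#' An annotation set links image files to ground-truth boxes and optional
#' class labels.  On disk it is a tab-separated table, one row per box,
#' with columns `image_path`, `x_min`, `y_min`, `width`, `height`,
#' `class_label` (may be empty), `modality`.  A polyp-free (normal) frame
#' is recorded as a single row with empty box fields.
#'
#' @param path image file path.
#' @param gt_boxes box table (see [bbox_table()]); zero rows for a normal
#'   frame.
#' @param class_label `"neoplastic"`, `"hyperplastic"`, or `NA` when the
#'   record is not a classification sample.
#' @param modality one of `"WL"`, `"NBI"`, `"synthetic-WL"`,
#'   `"synthetic-NBI"`, `"grayscale"`.
#' @return An object of class `annotated_image`.
#' @export
annotated_image <- function(path, gt_boxes = NULL, class_label = NA_character_,
                            modality = "WL") {
  if (is.null(gt_boxes))
    gt_boxes <- data.frame(x_min = integer(), y_min = integer(),
                           width = integer(), height = integer())
  gt_boxes <- bbox_table(gt_boxes)
  mods <- c("WL", "NBI", "synthetic-WL", "synthetic-NBI", "grayscale")
  if (!modality %in% mods)
    stop("modality must be one of ", paste(mods, collapse = ", "))
  if (!is.na(class_label) &&
      !class_label %in% c("neoplastic", "hyperplastic"))
    stop("class_label must be neoplastic, hyperplastic or NA")
  structure(list(path = path, gt_boxes = gt_boxes,
                 class_label = class_label, modality = modality),
            class = "annotated_image")
}

#' @export
print.annotated_image <- function(x, ...) {
  cat(sprintf("<annotated_image %s: %d box(es), label=%s, %s>\n",
              x$path, nrow(x$gt_boxes), x$class_label, x$modality))
  invisible(x)
}

ann_columns <- c("image_path", "x_min", "y_min", "width", "height",
                 "class_label", "modality")

#' Read and write annotation tables
#'
#' `write_annotations()` followed by `read_annotations()` reproduces the
#' records exactly.  Malformed rows are rejected with their row number.
#'
#' @param records list of [annotated_image()] objects.
#' @param path file path of the tab-separated annotation table.
#' @return `read_annotations()` returns a list of `annotated_image`
#'   records, grouped by image in first-appearance order.
#' @export
write_annotations <- function(records, path) {
  rows <- lapply(records, function(r) {
    if (nrow(r$gt_boxes) == 0L)
      data.frame(image_path = r$path, x_min = NA_integer_, y_min = NA_integer_,
                 width = NA_integer_, height = NA_integer_,
                 class_label = r$class_label, modality = r$modality)
    else
      data.frame(image_path = r$path,
                 x_min = r$gt_boxes$x_min, y_min = r$gt_boxes$y_min,
                 width = r$gt_boxes$width, height = r$gt_boxes$height,
                 class_label = r$class_label, modality = r$modality)
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    as.data.frame(setNames(rep(list(character(0)), length(ann_columns)),
                           ann_columns))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = c(image_path = "character",
                                   class_label = "character",
                                   modality = "character"),
                    na.strings = "")
  if (!identical(names(tab), ann_columns))
    stop("annotation file must have columns ",
         paste(ann_columns, collapse = ", "))
  if (nrow(tab) == 0L) return(list())
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    has_box <- !is.na(r$x_min)
    if (has_box && (is.na(r$y_min) || is.na(r$width) || is.na(r$height)))
      stop("malformed annotation row ", i, ": incomplete box")
    if (has_box && (r$width < 1 || r$height < 1 || r$x_min < 0 || r$y_min < 0))
      stop("malformed annotation row ", i, ": invalid box geometry")
    if (is.na(r$modality)) stop("malformed annotation row ", i, ": no modality")
  }
  paths <- unique(tab$image_path)
  lapply(paths, function(p) {
    sub <- tab[tab$image_path == p, ]
    boxes <- sub[!is.na(sub$x_min), c("x_min", "y_min", "width", "height")]
    rownames(boxes) <- NULL
    annotated_image(p, boxes,
                    class_label = sub$class_label[1],
                    modality = sub$modality[1])
  })
}
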