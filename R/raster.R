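#' Raster image container
#'
#' An 8-bit raster image stored as an integer array with dimensions
#' `c(height, width, channels)`, values in 0..255.  Channels is 1
#' (grayscale) or 3 (red, green, blue, in that order).  Pixel coordinates
#' throughout the package are 0-based with the origin at the top-left
#' corner, x running rightward (columns) and y downward (rows).
#'
#' @param pixels numeric or integer array; a matrix is promoted to a
#'   single-channel array.
#' @return An object of class `raster_image`: an integer `(H, W, C)` array.
#' @examples
#' img <- raster_image(matrix(0:255, 16, 16))
#' image_height(img); image_width(img); image_channels(img)
#' @export
raster_image <- function(pixels) {
  if (is.matrix(pixels)) dim(pixels) <- c(dim(pixels), 1L)
  if (!is.array(pixels) || length(dim(pixels)) != 3L)
    stop("pixels must be an H x W x C array or an H x W matrix")
  d <- dim(pixels)
  if (!d[3] %in% c(1L, 3L)) stop("channel count must be 1 or 3")
  if (d[1] < 1L || d[2] < 1L) stop("image must be at least 1 x 1")
  if (anyNA(pixels)) stop("pixels contain NA")
  if (min(pixels) < 0 || max(pixels) > 255)
    stop("pixel values must lie in [0, 255]")
  storage.mode(pixels) <- "integer"
  class(pixels) <- c("raster_image", "array")
  pixels
}

#' @rdname raster_image
#' @param img a `raster_image`.
#' @export
image_height <- function(img) dim(img)[1]

#' @rdname raster_image
#' @export
image_width <- function(img) dim(img)[2]

#' @rdname raster_image
#' @export
image_channels <- function(img) dim(img)[3]

#' @export
print.raster_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<raster_image %d x %d, %d channel%s, range [%d, %d]>\n",
              d[1], d[2], d[3], if (d[3] > 1) "s" else "",
              min(x), max(x)))
  invisible(x)
}

# clamp + round a numeric array into 8-bit integer range;
# rounding is half-away-from-zero, the usual 8-bit image convention
quantize_u8 <- function(x) {
  x <- floor(abs(x) + 0.5) * sign(x)
  x[x < 0] <- 0
  x[x > 255] <- 255
  x
}

#' Convert a color image to grayscale luma
#'
#' Weighted sum of the red, green and blue channels,
#' `gray = cR*R + cG*G + cB*B`, rounded half-away-from-zero and clipped
#' to 0..255.  Two built-in coefficient sets are provided:
#' `"standard"` is ITU-R BT.601 (0.299, 0.587, 0.114); `"paper"` is the
#' variant (0.229, 0.587, 0.117) found in some of the polyp-detection
#' literature, kept for fidelity reruns.  Its weights sum to 0.933, so
#' pure white maps to 238 rather than 255.
#'
#' @param img 3-channel `raster_image`.
#' @param coefficients `"standard"`, `"paper"`, or a numeric triple of
#'   non-negative weights `(cR, cG, cB)`.
#' @return Single-channel `raster_image` of the same height and width.
#' @examples
#' img <- raster_image(array(120L, c(4, 4, 3)))
#' rgb_to_grayscale(img)
#' @export
rgb_to_grayscale <- function(img, coefficients = "standard") {
  co <- grayscale_coefficients(coefficients)
  if (image_channels(img) != 1L && !inherits(img, "raster_image"))
    img <- raster_image(img)
  if (image_channels(img) == 1L) stop("already grayscale")
  g <- co[1] * img[, , 1] + co[2] * img[, , 2] + co[3] * img[, , 3]
  raster_image(matrix(quantize_u8(g), dim(img)[1], dim(img)[2]))
}

#' @rdname rgb_to_grayscale
#' @export
grayscale_coefficients <- function(coefficients = "standard") {
  if (is.character(coefficients)) {
    coefficients <- match.arg(coefficients, c("standard", "paper"))
    return(switch(coefficients,
                  standard = c(0.299, 0.587, 0.114),
                  paper    = c(0.229, 0.587, 0.117)))
  }
  if (length(coefficients) != 3 || any(coefficients < 0))
    stop("coefficients must be three non-negative weights")
  as.numeric(coefficients)
}

#' Bilinear image resize
#'
#' Resamples to the target size with bilinear interpolation.  Sample
#' points use the pixel-center (align-corners = false) convention:
#' output pixel `(i, j)` samples source coordinate
#' `((i + 0.5) * H/target_h - 0.5, (j + 0.5) * W/target_w - 0.5)`,
#' clamped to the image.  Values are rounded back to 0..255.
#'
#' @param img a `raster_image`.
#' @param target_h,target_w output dimensions in pixels (>= 1).
#' @return A `raster_image` of dimension `(target_h, target_w, C)`.
#' @export
resize_image <- function(img, target_h, target_w) {
  if (target_h < 1 || target_w < 1) stop("target dimensions must be >= 1")
  raster_image(quantize_u8(resize_bilinear_num(unclass(img), target_h, target_w)))
}

# numeric-core bilinear resize on an (H, W, C) array, no quantization
resize_bilinear_num <- function(x, target_h, target_w) {
  d <- dim(x)
  if (d[1] == target_h && d[2] == target_w) return(x)
  sy <- pmin(pmax((seq_len(target_h) - 0.5) * d[1] / target_h - 0.5, 0), d[1] - 1)
  sx <- pmin(pmax((seq_len(target_w) - 0.5) * d[2] / target_w - 0.5, 0), d[2] - 1)
  y0 <- pmin(floor(sy), d[1] - 1); y1 <- pmin(y0 + 1, d[1] - 1)
  x0 <- pmin(floor(sx), d[2] - 1); x1 <- pmin(x0 + 1, d[2] - 1)
  fy <- sy - y0; fx <- sx - x0
  out <- array(0, c(target_h, target_w, d[3]))
  wyl <- 1 - fy; wxl <- 1 - fx
  for (c in seq_len(d[3])) {
    ch <- x[, , c]
    a <- ch[cbind(rep(y0 + 1, target_w), rep(x0 + 1, each = target_h))]
    b <- ch[cbind(rep(y0 + 1, target_w), rep(x1 + 1, each = target_h))]
    cc <- ch[cbind(rep(y1 + 1, target_w), rep(x0 + 1, each = target_h))]
    dd <- ch[cbind(rep(y1 + 1, target_w), rep(x1 + 1, each = target_h))]
    top <- a * rep(wxl, each = target_h) + b * rep(fx, each = target_h)
    bot <- cc * rep(wxl, each = target_h) + dd * rep(fx, each = target_h)
    out[, , c] <- matrix(top * wyl + bot * fy, target_h, target_w)
  }
  out
}

#' Read and write raster images
#'
#' TIFF is the primary interchange format; PNG is accepted for small
#' fixtures.  The format is chosen from the file extension.
#'
#' @param path file path ending in `.tif`, `.tiff` or `.png`.
#' @return `read_image` returns a `raster_image`.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
               tif = , tiff = tiff::readTIFF(path),
               png = png::readPNG(path),
               stop("unsupported image format: ", ext))
  if (length(dim(px)) == 3L && dim(px)[3] == 4L) px <- px[, , 1:3]  # drop alpha
  if (length(dim(px)) == 2L) dim(px) <- c(dim(px), 1L)
  raster_image(quantize_u8(px * 255))
}

#' @rdname read_image
#' @param img a `raster_image` to write.
#' @export
write_image <- function(img, path) {
  px <- unclass(img) / 255
  if (dim(px)[3] == 1L) dim(px) <- dim(px)[1:2]
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         tif = , tiff = tiff::writeTIFF(px, path, bits.per.sample = 8L,
                                        compression = "LZW"),
         png = png::writePNG(px, path),
         stop("unsupported image format: ", ext))
  invisible(path)
}
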