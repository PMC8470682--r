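test_that("grayscale conversion follows the weighted-luma rule", {
  # pure white under the printed (paper-mode) weights: 255 * 0.933 -> 238
  white <- raster_image(array(255L, c(2, 2, 3)))
  expect_equal(rgb_to_grayscale(white, "paper")[1, 1, 1], 238L)
  # channel-constant pixels are fixed points of unit-sum weights
  for (g in c(0L, 1L, 77L, 128L, 254L, 255L)) {
    img <- raster_image(array(g, c(3, 3, 3)))
    expect_true(all(rgb_to_grayscale(img, "standard") == g))
  }
  # independent per-pixel evaluation: (100,50,200) -> 22.9+29.35+23.4 -> 76
  px <- raster_image(array(rep(c(100L, 50L, 200L), each = 1), c(1, 1, 3)))
  expect_equal(px[1, 1, ], c(100L, 50L, 200L))
  expect_equal(rgb_to_grayscale(px, "paper")[1, 1, 1], 76L)
  # random pixels against a direct scalar oracle, both coefficient sets
  set.seed(11)
  arr <- array(sample(0:255, 3 * 60, TRUE), c(5, 4, 3))
  img <- raster_image(arr)
  for (mode in c("standard", "paper")) {
    co <- grayscale_coefficients(mode)
    want <- round(co[1] * arr[, , 1] + co[2] * arr[, , 2] + co[3] * arr[, , 3])
    got <- rgb_to_grayscale(img, mode)
    expect_equal(as.integer(got), as.integer(want))
  }
})

test_that("grayscale conversion rejects bad inputs", {
  gray <- raster_image(matrix(5L, 4, 4))
  expect_error(rgb_to_grayscale(gray), "already grayscale")
  rgb <- raster_image(array(1L, c(2, 2, 3)))
  expect_error(rgb_to_grayscale(rgb, c(-0.1, 0.5, 0.5)), "non-negative")
})

test_that("mask_to_bboxes finds tight component extents", {
  # all-white mask -> one full-frame box
  full <- mask_to_bboxes(matrix(1L, 7, 9))
  expect_equal(nrow(full), 1L)
  expect_equal(unlist(full[1, 1:4], use.names = FALSE), c(0L, 0L, 9L, 7L))
  # single white pixel at (row 3, col 5) -> 1x1 box at (4, 2)
  m <- matrix(0L, 6, 8); m[3, 5] <- 1L
  one <- mask_to_bboxes(m)
  expect_equal(unlist(one[1, 1:4], use.names = FALSE), c(4L, 2L, 1L, 1L))
  # all-zero mask -> empty table (a normal frame)
  expect_equal(nrow(mask_to_bboxes(matrix(0L, 5, 5))), 0L)
  # diagonal touching merges under 8-connectivity
  d <- matrix(0L, 4, 4); d[1, 1] <- 1L; d[2, 2] <- 1L
  expect_equal(nrow(mask_to_bboxes(d)), 1L)
  expect_equal(nrow(mask_to_bboxes(d, connectivity = 4)), 2L)
})

test_that("mask_to_bboxes equals the brute-force component scan", {
  set.seed(7)
  for (i in 1:25) {
    m <- matrix(rbinom(30 * 40, 1, runif(1, 0.05, 0.5)), 30, 40)
    got <- mask_to_bboxes(m)[, 1:4]
    want <- oracle_component_boxes(m)
    key <- function(b) do.call(order, b)
    expect_equal(got[key(got), ], want[key(want), ], ignore_attr = TRUE)
  }
})

test_that("bilinear resize matches identity, constants and the oracle", {
  set.seed(3)
  img <- raster_image(array(sample(0:255, 48, TRUE), c(4, 4, 3)))
  expect_identical(resize_image(img, 4, 4), img)
  flat <- raster_image(array(119L, c(6, 5, 1)))
  for (dims in list(c(3, 9), c(12, 2), c(6, 5)))
    expect_true(all(resize_image(flat, dims[1], dims[2]) == 119L))
  # checkerboard upsample against the scalar oracle
  chk <- array(c(0, 255, 255, 0), c(2, 2, 1))
  got <- resize_image(raster_image(chk), 4, 4)
  want <- oracle_resize_bilinear(chk, 4, 4)
  expect_equal(as.numeric(got), as.numeric(polypgray:::quantize_u8(want)))
  # random images, up and down scaling
  for (i in 1:5) {
    arr <- array(runif(7 * 9, 0, 255), c(7, 9, 1))
    th <- sample(2:15, 1); tw <- sample(2:15, 1)
    got <- polypgray:::resize_bilinear_num(arr, th, tw)
    expect_equal(got, oracle_resize_bilinear(arr, th, tw), tolerance = 1e-12)
  }
  expect_error(resize_image(img, 0, 5), ">= 1")
})

test_that("TIFF and PNG image round-trips are lossless", {
  set.seed(5)
  img <- raster_image(array(sample(0:255, 30 * 20 * 3, TRUE), c(20, 30, 3)))
  for (ext in c("tif", "png")) {
    f <- tempfile(fileext = paste0(".", ext))
    write_image(img, f)
    expect_identical(unclass(read_image(f)), unclass(img))
    unlink(f)
  }
})

test_that("annotation tables round-trip exactly", {
  f <- tempfile(fileext = ".tsv")
  # empty record list -> header-only file -> empty list
  write_annotations(list(), f)
  expect_equal(read_annotations(f), list())
  # one record with two boxes plus a normal frame
  recs <- list(
    annotated_image("a.tif", data.frame(x_min = c(3L, 100L), y_min = c(4L, 50L),
                                        width = c(10L, 40L), height = c(12L, 44L)),
                    class_label = "neoplastic", modality = "WL"),
    annotated_image("b.tif", modality = "synthetic-NBI"))
  write_annotations(recs, f)
  back <- read_annotations(f)
  expect_equal(length(back), 2L)
  expect_equal(back[[1]]$gt_boxes, recs[[1]]$gt_boxes)
  expect_equal(back[[1]]$class_label, "neoplastic")
  expect_equal(nrow(back[[2]]$gt_boxes), 0L)
  expect_equal(back[[2]]$modality, "synthetic-NBI")
  # many random records
  set.seed(9)
  recs <- lapply(seq_len(40), function(i) {
    nb <- sample(0:3, 1)
    b <- random_boxes(nb)
    b$x_min <- floor(b$x_min); b$y_min <- floor(b$y_min)
    annotated_image(sprintf("img_%03d.tif", i), b,
                    class_label = sample(c(NA, "neoplastic", "hyperplastic"), 1),
                    modality = sample(c("WL", "NBI"), 1))
  })
  write_annotations(recs, f)
  back <- read_annotations(f)
  expect_equal(length(back), length(recs))
  for (i in seq_along(recs)) {
    expect_equal(back[[i]]$path, recs[[i]]$path)
    expect_equal(back[[i]]$gt_boxes, recs[[i]]$gt_boxes, ignore_attr = TRUE)
    expect_equal(back[[i]]$class_label, recs[[i]]$class_label)
    expect_equal(back[[i]]$modality, recs[[i]]$modality)
  }
  unlink(f)
})

test_that("malformed annotation rows are rejected with their row number", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c(paste(c("image_path", "x_min", "y_min", "width", "height",
                       "class_label", "modality"), collapse = "\t"),
               paste(c("a.tif", "5", "", "10", "10", "", "WL"),
                     collapse = "\t")), f)
  expect_error(read_annotations(f), "row 1")
  writeLines(c(paste(c("image_path", "x_min", "y_min", "width", "height",
                       "class_label", "modality"), collapse = "\t"),
               paste(c("a.tif", "5", "5", "10", "10", "", "WL"), collapse = "\t"),
               paste(c("b.tif", "5", "5", "0", "10", "", "WL"), collapse = "\t")),
             f)
  expect_error(read_annotations(f), "row 2")
  unlink(f)
})

test_that("bounding-box helpers respect the half-open pixel convention", {
  b <- bbox(10, 20, 40, 30)
  expect_equal(bbox_area(b), 1200)
  expect_equal(as.numeric(bbox_center(b)), c(30, 35))
  expect_equal(bbox_iou(b, b), 1)
  expect_equal(bbox_iou(b, bbox(50, 20, 40, 30)), 0)  # edge-adjacent
  expect_error(bbox(0, 0, 0, 5), ">= 1")
  expect_error(bbox_table(bbox(600, 0, 50, 5), image_width = 640,
                          image_height = 480), "outside image")
})
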