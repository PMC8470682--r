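#' The eight anchor boxes
#'
#' Fixed prior box shapes, in original-frame pixels, attached to every
#' cell of the 16 x 16 detection grid: (16,16), (32,32), (24,48),
#' (48,24), (60,80), (108,72), (216,144), (180,180).  Anchors live in
#' the original image space (e.g. 640 x 480); grid-cell coordinates are
#' mapped to the frame by the cell stride `(W/16, H/16)`.
#'
#' @return data.frame with columns `width`, `height`, one row per anchor.
#' @export
anchor_set <- function() {
  data.frame(width  = c(16, 32, 24, 48, 60, 108, 216, 180),
             height = c(16, 32, 48, 24, 80,  72, 144, 180))
}

grid_channels <- function(k) c(obj = 3 * k - 2, tx = 3 * k - 1, ty = 3 * k)

#' Decode the detection grid into scored boxes
#'
#' The head emits a `16 x 16 x 24` raw grid: for each cell, 8 anchors
#' with (objectness, x-offset, y-offset) logits.  For every cell
#' `(r, c)` (0-based) and anchor `k` whose `sigmoid(objectness)` clears
#' the cutoff, the box center is
#' `((c + sigmoid(tx)) * W/16, (r + sigmoid(ty)) * H/16)` and the box
#' dimensions are the anchor's.  Boxes are clipped to the image; greedy
#' overlap suppression (IoU 0.5) removes duplicates by default;
#' detections are sorted by descending score.
#'
#' @param grid numeric `16 x 16 x 24` array of raw head outputs.
#' @param image_w,image_h original frame dimensions in pixels.
#' @param cutoff objectness cutoff in \[0, 1\] (the operating point for
#'   polyp detection is 0.2).
#' @param anchors anchor table, by default [anchor_set()].
#' @param nms apply greedy suppression (default `TRUE`).
#' @param nms_iou IoU threshold for suppression.
#' @return data.frame of detections: `x_min`, `y_min`, `width`, `height`,
#'   `score`, `anchor`, `cell_row`, `cell_col`.
#' @export
decode_detections <- function(grid, image_w, image_h, cutoff = 0.2,
                              anchors = anchor_set(), nms = TRUE,
                              nms_iou = 0.5) {
  if (!is.array(grid) || !all(dim(grid) == c(16, 16, 24)))
    stop("grid must be a 16 x 16 x 24 array")
  if (cutoff < 0 || cutoff > 1) stop("cutoff must lie in [0, 1]")
  cell_w <- image_w / 16; cell_h <- image_h / 16
  out <- list()
  for (k in seq_len(nrow(anchors))) {
    ch <- grid_channels(k)
    s <- sigmoid(grid[, , ch["obj"]])
    hit <- which(s >= cutoff, arr.ind = TRUE)
    if (nrow(hit) == 0L) next
    r <- hit[, 1] - 1L; cl <- hit[, 2] - 1L
    cx <- (cl + sigmoid(grid[, , ch["tx"]][hit])) * cell_w
    cy <- (r + sigmoid(grid[, , ch["ty"]][hit])) * cell_h
    x0 <- pmax(0, cx - anchors$width[k] / 2)
    x1 <- pmin(image_w, cx + anchors$width[k] / 2)
    y0 <- pmax(0, cy - anchors$height[k] / 2)
    y1 <- pmin(image_h, cy + anchors$height[k] / 2)
    out[[k]] <- data.frame(x_min = x0, y_min = y0,
                           width = x1 - x0, height = y1 - y0,
                           score = s[hit], anchor = k,
                           cell_row = r, cell_col = cl)
  }
  det <- if (length(out)) do.call(rbind, out) else
    data.frame(x_min = numeric(), y_min = numeric(), width = numeric(),
               height = numeric(), score = numeric(), anchor = integer(),
               cell_row = integer(), cell_col = integer())
  det <- det[order(-det$score), , drop = FALSE]
  rownames(det) <- NULL
  if (nms && nrow(det) > 1L) det <- greedy_nms(det, nms_iou)
  det
}

greedy_nms <- function(det, iou_thr) {
  x0 <- det$x_min; y0 <- det$y_min
  x1 <- x0 + det$width; y1 <- y0 + det$height
  area <- det$width * det$height
  alive <- rep(TRUE, nrow(det))
  keep <- logical(nrow(det))
  for (i in seq_len(nrow(det))) {
    if (!alive[i]) next
    keep[i] <- TRUE
    iw <- pmax(0, pmin(x1[i], x1) - pmax(x0[i], x0))
    ih <- pmax(0, pmin(y1[i], y1) - pmax(y0[i], y0))
    iou <- iw * ih / (area[i] + area - iw * ih)
    alive <- alive & !(iou > iou_thr & seq_along(alive) > i)
  }
  out <- det[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build training targets for the detection grid
#'
#' For each ground-truth box, the grid cell containing its center is
#' positive for the single anchor with the highest
#' intersection-over-union against the box (shapes compared co-centered;
#' ties break to the lowest anchor index).  Offset targets are the
#' center's fractional position within its cell.  All other cell/anchor
#' slots are negative.
#'
#' @param gt_boxes box table (may have zero rows).
#' @param image_w,image_h frame dimensions; GT centers must fall inside.
#' @param anchors anchor table.
#' @return list of `16 x 16 x 8` arrays `obj`, `tx`, `ty` and the count
#'   `n_pos`.
#' @export
assign_targets <- function(gt_boxes, image_w, image_h, anchors = anchor_set()) {
  obj <- array(0, c(16, 16, 8))
  tx <- array(0, c(16, 16, 8)); ty <- array(0, c(16, 16, 8))
  if (nrow(gt_boxes) > 0) for (i in seq_len(nrow(gt_boxes))) {
    b <- gt_boxes[i, ]
    cx <- b$x_min + b$width / 2; cy <- b$y_min + b$height / 2
    if (cx < 0 || cx > image_w || cy < 0 || cy > image_h)
      stop("ground-truth center outside image")
    cell_w <- image_w / 16; cell_h <- image_h / 16
    col <- min(15L, as.integer(cx %/% cell_w))
    row <- min(15L, as.integer(cy %/% cell_h))
    iou <- vapply(seq_len(nrow(anchors)), function(k) {
      inter <- min(anchors$width[k], b$width) * min(anchors$height[k], b$height)
      inter / (anchors$width[k] * anchors$height[k] + b$width * b$height - inter)
    }, 1.0)
    k <- which.max(iou)  # ties resolve to the lowest index
    obj[row + 1L, col + 1L, k] <- 1
    tx[row + 1L, col + 1L, k] <- cx / cell_w - col
    ty[row + 1L, col + 1L, k] <- cy / cell_h - row
  }
  list(obj = obj, tx = tx, ty = ty, n_pos = sum(obj))
}

#' Detection loss
#'
#' Binary cross-entropy on objectness over every cell/anchor slot
#' (positives up-weighted by `pos_weight`), plus squared error on the
#' sigmoid-activated offsets over positive slots.  The loss is zero
#' exactly when the activated objectness matches the 0/1 targets
#' everywhere and the activated offsets match on positives.
#'
#' @param grid raw `16 x 16 x 24` head output.
#' @param targets result of [assign_targets()].
#' @param pos_weight weight on positive-slot objectness terms.
#' @param lambda_offset weight of the offset term.
#' @return Non-negative scalar (attribute `"parts"` carries the two
#'   components).
#' @export
detection_loss <- function(grid, targets, pos_weight = 5, lambda_offset = 1) {
  z <- grid_split(grid)
  t <- targets$obj
  # stable BCE with logits; positives and negatives normalized
  # separately so a handful of positives is not drowned by the ~2000
  # negative slots
  bce <- pmax(z$obj, 0) - z$obj * t + log1p(exp(-abs(z$obj)))
  npos <- max(1, targets$n_pos)
  nneg <- max(1, length(t) - targets$n_pos)
  l_obj <- pos_weight * sum(bce[t > 0]) / npos + sum(bce[t == 0]) / nneg
  pos <- t > 0
  l_off <- (sum((sigmoid(z$tx[pos]) - targets$tx[pos])^2) +
            sum((sigmoid(z$ty[pos]) - targets$ty[pos])^2)) / npos
  out <- l_obj + lambda_offset * l_off
  attr(out, "parts") <- c(objectness = l_obj, offsets = l_off)
  out
}

grid_split <- function(grid) {
  list(obj = grid[, , seq(1, 24, by = 3), drop = FALSE],
       tx = grid[, , seq(2, 24, by = 3), drop = FALSE],
       ty = grid[, , seq(3, 24, by = 3), drop = FALSE])
}

# gradient of detection_loss with respect to the raw grid
detection_loss_grad <- function(grid, targets, pos_weight = 5,
                                lambda_offset = 1) {
  z <- grid_split(grid)
  t <- targets$obj
  npos <- max(1, targets$n_pos)
  nneg <- max(1, length(t) - targets$n_pos)
  w <- ifelse(t > 0, pos_weight / npos, 1 / nneg)
  dobj <- w * (sigmoid(z$obj) - t)
  pos <- t > 0
  dtx <- array(0, dim(t)); dty <- array(0, dim(t))
  sx <- sigmoid(z$tx[pos]); sy <- sigmoid(z$ty[pos])
  dtx[pos] <- lambda_offset * 2 * (sx - targets$tx[pos]) * sx * (1 - sx) / npos
  dty[pos] <- lambda_offset * 2 * (sy - targets$ty[pos]) * sy * (1 - sy) / npos
  g <- array(0, c(16, 16, 24))
  g[, , seq(1, 24, by = 3)] <- dobj
  g[, , seq(2, 24, by = 3)] <- dtx
  g[, , seq(3, 24, by = 3)] <- dty
  g
}

#' Detector training configuration
#'
#' @param epochs passes over the training set.
#' @param batch_size images per optimizer update (gradients accumulated).
#' @param lr Adam learning rate.
#' @param pos_weight positive/negative objectness weighting.
#' @param lambda_offset weight of the offset regression term.
#' @param modality `"grayscale"` (luma-converted single channel) or
#'   `"color"`.
#' @param coefficients grayscale coefficient set, see
#'   [grayscale_coefficients()].
#' @param combine multi-kernel combination rule.
#' @param cutoff default objectness cutoff for [detect()].
#' @return list of settings for [train_detector()].
#' @export
detector_config <- function(epochs = 10, batch_size = 2, lr = 1e-3,
                            pos_weight = 1, lambda_offset = 1,
                            modality = c("grayscale", "color"),
                            coefficients = "standard", combine = "sum",
                            cutoff = 0.2) {
  list(epochs = epochs, batch_size = batch_size, lr = lr,
       pos_weight = pos_weight, lambda_offset = lambda_offset,
       modality = match.arg(modality), coefficients = coefficients,
       combine = combine, cutoff = cutoff)
}

# load + preprocess one sample image to the detector input tensor;
# `image` may be a raster_image, a plain array, or a file path
prepare_input <- function(image, target_h, target_w, modality,
                          coefficients = "standard") {
  img <- if (is.character(image)) read_image(image) else
    if (inherits(image, "raster_image")) image else raster_image(image)
  if (modality == "grayscale" && image_channels(img) == 3L)
    img <- rgb_to_grayscale(img, coefficients)
  if (modality == "color" && image_channels(img) != 3L)
    stop("color modality requires a 3-channel image")
  x <- resize_bilinear_num(as_featmap(img), target_h, target_w)
  x / 255
}

#' Train the polyp detector
#'
#' Adam training of the detection network on annotated frames.  Fully
#' reproducible: the same `dataset`, `config` and `seed` give an
#' identical model and training log.
#'
#' @param dataset list of samples; each is an [annotated_image()] (path
#'   on disk) or a list with elements `image` (path, `raster_image` or
#'   array) and `gt_boxes` (box table, zero rows for a normal frame).
#' @param config see [detector_config()].
#' @param seed integer RNG seed.
#' @param verbose print per-epoch loss.
#' @return A `polyp_detector`: list with the trained `net`, the `config`,
#'   the `seed` and a training `log` data.frame (`epoch`, `step`,
#'   `loss`).
#' @export
train_detector <- function(dataset, config = detector_config(), seed = 1L,
                           verbose = FALSE) {
  if (length(dataset) == 0L) stop("dataset is empty")
  set.seed(seed)
  in_ch <- if (config$modality == "grayscale") 1L else 3L
  net <- build_detector(in_channels = in_ch, combine = config$combine)
  prep <- lapply(dataset, function(s) {
    img <- if (inherits(s, "annotated_image")) s$path else s$image
    if (is.character(img)) img <- read_image(img)
    gt <- s$gt_boxes
    x <- prepare_input(img, 128, 128, config$modality, config$coefficients)
    dims <- original_dims(img)
    list(x = x, targets = assign_targets(gt, dims[2], dims[1]))
  })
  st <- adam_init(net$params)
  log <- list()
  step <- 0L
  for (ep in seq_len(config$epochs)) {
    ord <- sample(length(prep))
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    ep_loss <- numeric(0)
    for (b in batches) {
      acc <- NULL
      bl <- 0
      for (i in b) {
        fw <- net_forward(net, prep[[i]]$x, want_cache = TRUE)
        bl <- bl + as.numeric(detection_loss(fw$out, prep[[i]]$targets,
                                             config$pos_weight,
                                             config$lambda_offset))
        dg <- detection_loss_grad(fw$out, prep[[i]]$targets,
                                  config$pos_weight, config$lambda_offset)
        bk <- net_backward(net, fw$caches, dg)
        acc <- if (is.null(acc)) bk$grads else grads_add(acc, bk$grads)
      }
      acc <- grads_scale(acc, 1 / length(b))
      step <- step + 1L
      upd <- adam_step(net$params, acc, st, lr = config$lr)
      net$params <- upd$params; st <- upd$state
      log[[length(log) + 1L]] <- data.frame(epoch = ep, step = step,
                                            loss = bl / length(b))
      ep_loss <- c(ep_loss, bl / length(b))
    }
    if (verbose)
      message(sprintf("epoch %d: mean loss %.5f", ep, mean(ep_loss)))
  }
  structure(list(net = net, config = config, seed = seed,
                 log = do.call(rbind, log)),
            class = "polyp_detector")
}

original_dims <- function(image) {
  if (is.character(image)) {
    img <- read_image(image)
    c(image_height(img), image_width(img))
  } else if (length(dim(image)) >= 2L) {
    dim(image)[1:2]
  } else stop("cannot determine image dimensions")
}

#' Run the detector on a frame
#'
#' Resizes the frame to the network input, runs the forward pass and
#' decodes the anchor grid back to boxes in original-frame pixels.
#'
#' @param detector a `polyp_detector` from [train_detector()].
#' @param image frame (path, `raster_image` or array).
#' @param cutoff objectness cutoff; defaults to the trained config's
#'   value (0.2).
#' @param nms,nms_iou overlap-suppression controls.
#' @return Detection table as in [decode_detections()].
#' @export
detect <- function(detector, image, cutoff = detector$config$cutoff,
                   nms = TRUE, nms_iou = 0.5) {
  dims <- original_dims(image)
  x <- prepare_input(image, 128, 128, detector$config$modality,
                     detector$config$coefficients)
  grid <- net_forward(detector$net, x)
  decode_detections(grid, image_w = dims[2], image_h = dims[1],
                    cutoff = cutoff, nms = nms, nms_iou = nms_iou)
}

#' @export
print.polyp_detector <- function(x, ...) {
  cat(sprintf("<polyp_detector (%s, cutoff %.2f): trained %d epochs, final loss %.4f>\n",
              x$config$modality, x$config$cutoff, max(x$log$epoch),
              x$log$loss[nrow(x$log)]))
  invisible(x)
}
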