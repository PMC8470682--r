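#' Classifier training configuration
#'
#' @param epochs passes over the training set.
#' @param batch_size images per optimizer update.
#' @param lr Adam learning rate.
#' @param modality `"grayscale"` or `"color"`.
#' @param coefficients grayscale coefficient set.
#' @param combine multi-kernel combination rule.
#' @param cutoff softmax cutoff on the neoplastic probability (0.5).
#' @param crop when `TRUE`, classify a margin-expanded crop around the
#'   polyp box (the detector's output feeds the classifier); when
#'   `FALSE` (default) the full frame is resized to the network input.
#' @param crop_margin multiplicative margin around the box in crop mode.
#' @param class_weights `"balanced"` (inverse-frequency), or a named
#'   numeric vector over `c(neoplastic, hyperplastic)`.
#' @return list of settings for [train_classifier()].
#' @export
classifier_config <- function(epochs = 2, batch_size = 2, lr = 1e-3,
                              modality = c("grayscale", "color"),
                              coefficients = "standard", combine = "sum",
                              cutoff = 0.5, crop = FALSE, crop_margin = 1.6,
                              class_weights = "balanced") {
  list(epochs = epochs, batch_size = batch_size, lr = lr,
       modality = match.arg(modality), coefficients = coefficients,
       combine = combine, cutoff = cutoff, crop = crop,
       crop_margin = crop_margin, class_weights = class_weights)
}

class_levels <- c("neoplastic", "hyperplastic")

# classifier input tensor: full frame (transposed if portrait) or a
# margin-expanded crop around `box`, bilinearly resized to 480 x 640
prepare_class_input <- function(image, config, box = NULL) {
  img <- if (is.character(image)) read_image(image) else
    if (inherits(image, "raster_image")) image else raster_image(image)
  if (config$modality == "grayscale" && image_channels(img) == 3L)
    img <- rgb_to_grayscale(img, config$coefficients)
  x <- as_featmap(img)
  if (config$crop && !is.null(box) && nrow(box) > 0) {
    b <- box[1, ]
    cx <- b$x_min + b$width / 2; cy <- b$y_min + b$height / 2
    w <- max(32, b$width * config$crop_margin)
    h <- max(32, b$height * config$crop_margin)
    x0 <- max(0, round(cx - w / 2)); x1 <- min(dim(x)[2], round(cx + w / 2))
    y0 <- max(0, round(cy - h / 2)); y1 <- min(dim(x)[1], round(cy + h / 2))
    x <- x[(y0 + 1):y1, (x0 + 1):x1, , drop = FALSE]
  }
  if (dim(x)[1] > dim(x)[2]) x <- aperm(x, c(2, 1, 3))  # portrait: transpose
  resize_bilinear_num(x, 480, 640) / 255
}

#' Classify a polyp frame
#'
#' Forward pass of the classification network followed by softmax; the
#' frame is called neoplastic when the neoplastic softmax probability is
#' at or above the cutoff (a tie at exactly 0.5 resolves to neoplastic,
#' the clinically conservative direction).
#'
#' @param classifier a `polyp_classifier` from [train_classifier()].
#' @param image frame (path, `raster_image` or array).
#' @param box optional polyp box for crop-mode classification.
#' @param cutoff decision cutoff on the neoplastic probability.
#' @return list with `label`, `probability` (of the predicted class) and
#'   the two-element softmax vector `p`.
#' @export
classify <- function(classifier, image, box = NULL,
                     cutoff = classifier$config$cutoff) {
  x <- prepare_class_input(image, classifier$config, box)
  logits <- net_forward(classifier$net, x)
  class_decision(logits, cutoff)
}

class_decision <- function(logits, cutoff = 0.5) {
  p <- softmax(logits)
  names(p) <- class_levels
  label <- if (p["neoplastic"] >= cutoff) "neoplastic" else "hyperplastic"
  list(label = label, probability = unname(p[label]), p = p)
}

#' Train the polyp classifier
#'
#' Class-weighted softmax cross-entropy training; reproducible from the
#' seed.  Both classes must be present in the dataset.
#'
#' @param dataset list of samples: each an [annotated_image()] with a
#'   `class_label`, or a list with `image`, `class_label` and optional
#'   `gt_boxes` (used in crop mode).
#' @param config see [classifier_config()].
#' @param seed integer RNG seed.
#' @param verbose print per-epoch loss.
#' @return A `polyp_classifier`: list with `net`, `config`, `seed` and
#'   training `log`.
#' @export
train_classifier <- function(dataset, config = classifier_config(), seed = 1L,
                             verbose = FALSE) {
  if (length(dataset) == 0L) stop("dataset is empty")
  labels <- vapply(dataset, function(s) s$class_label, "")
  if (!all(labels %in% class_levels)) stop("unknown class label in dataset")
  if (length(unique(labels)) < 2L)
    stop("dataset must contain both classes")
  set.seed(seed)
  wts <- if (identical(config$class_weights, "balanced")) {
    tab <- table(factor(labels, class_levels))
    setNames(as.numeric(length(labels) / (2 * tab)), class_levels)
  } else config$class_weights[class_levels]
  in_ch <- if (config$modality == "grayscale") 1L else 3L
  net <- build_classifier(in_channels = in_ch, combine = config$combine)
  prep <- lapply(dataset, function(s) {
    img <- if (inherits(s, "annotated_image")) s$path else s$image
    box <- s$gt_boxes
    list(x = prepare_class_input(img, config, box),
         y = match(s$class_label, class_levels))
  })
  st <- adam_init(net$params)
  log <- list(); step <- 0L
  for (ep in seq_len(config$epochs)) {
    ord <- sample(length(prep))
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    ep_loss <- numeric(0)
    for (b in batches) {
      acc <- NULL; bl <- 0
      for (i in b) {
        fw <- net_forward(net, prep[[i]]$x, want_cache = TRUE)
        p <- softmax(fw$out)
        y <- prep[[i]]$y
        w <- wts[class_levels[y]]
        bl <- bl + w * -log(max(p[y], 1e-12))
        dlogits <- w * (p - as.numeric(seq_len(2) == y))
        bk <- net_backward(net, fw$caches, dlogits)
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
            class = "polyp_classifier")
}

#' @export
print.polyp_classifier <- function(x, ...) {
  cat(sprintf("<polyp_classifier (%s%s, cutoff %.2f): trained %d epochs>\n",
              x$config$modality, if (x$config$crop) ", crop mode" else "",
              x$config$cutoff, max(x$log$epoch)))
  invisible(x)
}
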