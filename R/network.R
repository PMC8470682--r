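#' Build the polyp detection network
#'
#' A single-stage grid detector over a 128 x 128 input (1 channel for
#' grayscale, 3 for color).  Three multi-kernel convolution blocks
#' (16, 32, 64 filters), each followed by batch normalization, ReLU and
#' 2x2/2 max pooling, reduce the map to 16 x 16; three further 128-filter
#' blocks (BN + ReLU, no pooling) deepen it; a final 1x1 convolution with
#' 24 channels emits, for each of the 16 x 16 cells, 8 anchors x
#' (objectness, x-offset, y-offset) raw logits.
#'
#' @param in_channels 1 (grayscale) or 3 (color).
#' @param combine multi-kernel combination rule, `"sum"` (default) or
#'   `"project"`; see [multi_kernel_conv_forward()].
#' @param seed optional integer seed for weight initialization; when
#'   `NULL` the current RNG stream is used.
#' @return A `polyp_net` object.
#' @seealso [audit_shapes()], [n_parameters()], [detect()], [train_detector()]
#' @export
build_detector <- function(in_channels = 1, combine = "sum", seed = NULL) {
  if (!in_channels %in% c(1, 3)) stop("in_channels must be 1 or 3")
  spec <- c(
    mk_block(16, pool_stride = 2), mk_block(32, pool_stride = 2),
    mk_block(64, pool_stride = 2),
    mk_block(128), mk_block(128), mk_block(128),
    list(list(type = "conv1x1", filters = 24))
  )
  net <- new_polyp_net("detector", c(128L, 128L, as.integer(in_channels)),
                       spec, combine, seed)
  # objectness bias starts at a low-prior logit so the untrained head is
  # silent and training spends its first steps on the positives
  head <- length(net$spec)
  net$params[[head]]$b[seq(1, 24, by = 3)] <- -4
  net
}

#' Build the polyp classification network
#'
#' Classifies a 480 x 640 (H x W) polyp frame as neoplastic versus
#' hyperplastic.  Six multi-kernel convolution blocks (16, 16, 32, 32,
#' 64, 64 filters) with BN/ReLU and max pooling at strides
#' 2, 2, 3, 3, 3 reduce the map to 4 x 6; a final 2x2 pool brings it to
#' 2 x 3 (the tabulated stride of 1 cannot produce 2 x 3 from 4 x 6, so
#' stride 2 is used, the printed output shape being binding); a fully
#' connected layer emits the two class logits.
#'
#' @inheritParams build_detector
#' @return A `polyp_net` object.
#' @seealso [classify()], [train_classifier()]
#' @export
build_classifier <- function(in_channels = 1, combine = "sum", seed = NULL) {
  if (!in_channels %in% c(1, 3)) stop("in_channels must be 1 or 3")
  spec <- c(
    mk_block(16, pool_stride = 2), mk_block(16, pool_stride = 2),
    mk_block(32, pool_stride = 3), mk_block(32, pool_stride = 3),
    mk_block(64, pool_stride = 3), mk_block(64, pool_stride = 2),
    list(list(type = "fc", units = 2))
  )
  new_polyp_net("classifier", c(480L, 640L, as.integer(in_channels)),
                spec, combine, seed)
}

mk_block <- function(filters, pool_stride = NULL) {
  b <- list(list(type = "mkconv", filters = filters),
            list(type = "bn"), list(type = "relu"))
  if (!is.null(pool_stride))
    b <- c(b, list(list(type = "pool", size = 2, stride = pool_stride)))
  b
}

new_polyp_net <- function(kind, input_shape, spec, combine, seed) {
  combine <- match.arg(combine, c("sum", "project"))
  if (!is.null(seed)) set.seed(seed)
  params <- vector("list", length(spec))
  shape <- input_shape
  for (i in seq_along(spec)) {
    ly <- spec[[i]]
    C <- shape[3]
    params[[i]] <- switch(ly$type,
      mkconv = init_mkconv(C, ly$filters, combine),
      bn = list(gamma = rep(1, C), beta = rep(0, C)),
      relu = list(),
      pool = list(),
      conv1x1 = list(w = matrix(rnorm(C * ly$filters, sd = sqrt(2 / C)),
                                C, ly$filters),
                     b = rep(0, ly$filters)),
      fc = {
        len <- prod(shape)
        list(w = matrix(rnorm(len * ly$units, sd = sqrt(2 / len)),
                        ly$units, len),
             b = rep(0, ly$units))
      })
    shape <- layer_out_shape(ly, shape)
  }
  structure(list(kind = kind, input_shape = input_shape, combine = combine,
                 spec = spec, params = params, output_shape = shape),
            class = "polyp_net")
}

init_mkconv <- function(C, F_, combine) {
  s <- sqrt(2 / (15 * C))
  p <- list(k33 = array(rnorm(9 * C * F_, sd = s), c(3, 3, C, F_)),
            k31 = array(rnorm(3 * C * F_, sd = s), c(3, 1, C, F_)),
            k13 = array(rnorm(3 * C * F_, sd = s), c(1, 3, C, F_)),
            bias = rep(0, F_))
  if (combine == "project")
    p$proj <- matrix(rnorm(3 * F_ * F_, sd = sqrt(2 / (3 * F_))), 3 * F_, F_)
  p
}

layer_out_shape <- function(ly, shape) {
  switch(ly$type,
    mkconv = c(shape[1:2], ly$filters),
    bn = , relu = shape,
    pool = c((shape[1] - ly$size) %/% ly$stride + 1L,
             (shape[2] - ly$size) %/% ly$stride + 1L, shape[3]),
    conv1x1 = c(shape[1:2], ly$filters),
    fc = c(ly$units))
}

#' Shape audit of a network
#'
#' Walks the layer list computing every intermediate output shape, for
#' comparison against the tabulated architecture row by row.
#'
#' @param net a `polyp_net`.
#' @return data.frame with columns `layer`, `filters`, `size_stride`,
#'   `output` (as `"H x W"`), plus the numeric `out_h`, `out_w`, `out_c`.
#' @export
audit_shapes <- function(net) {
  shape <- net$input_shape
  rows <- list(data.frame(layer = "Input", filters = NA, size_stride = "",
                          output = sprintf("%d x %d", shape[1], shape[2]),
                          out_h = shape[1], out_w = shape[2], out_c = shape[3]))
  for (ly in net$spec) {
    shape <- layer_out_shape(ly, shape)
    rows[[length(rows) + 1L]] <- data.frame(
      layer = switch(ly$type, mkconv = "Convolutional",
                     bn = "Batch Normalization", relu = "ReLU",
                     pool = "Max pooling", conv1x1 = "Convolutional",
                     fc = "Fully Connected"),
      filters = if (!is.null(ly$filters)) ly$filters else
                if (!is.null(ly$units)) ly$units else NA,
      size_stride = switch(ly$type,
                           mkconv = "(3x3 + 3x1 + 1x3)/1",
                           pool = sprintf("2x2/%d", ly$stride),
                           conv1x1 = "1x1/1", ""),
      output = if (length(shape) == 3L)
        sprintf("%d x %d", shape[1], shape[2]) else sprintf("%d", shape[1]),
      out_h = shape[1], out_w = if (length(shape) == 3L) shape[2] else NA,
      out_c = if (length(shape) == 3L) shape[3] else NA)
  }
  do.call(rbind, rows)
}

#' @rdname audit_shapes
#' @return `n_parameters()` returns the trainable parameter count.
#' @export
n_parameters <- function(net) sum(vapply(net$params, function(p)
  sum(vapply(p, length, 1L)), 1))

#' @export
print.polyp_net <- function(x, ...) {
  cat(sprintf("<polyp_net %s: input %s, %s combine, %s parameters>\n",
              x$kind, paste(x$input_shape, collapse = "x"), x$combine,
              format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

# ---- forward / backward engine ------------------------------------------

net_forward <- function(net, x, want_cache = FALSE) {
  x <- as_featmap(x)
  if (!all(dim(x) == net$input_shape))
    stop("input shape ", paste(dim(x), collapse = "x"),
         " does not match network input ",
         paste(net$input_shape, collapse = "x"))
  caches <- if (want_cache) vector("list", length(net$spec)) else NULL
  for (i in seq_along(net$spec)) {
    ly <- net$spec[[i]]; p <- net$params[[i]]
    if (ly$type == "mkconv") {
      if (want_cache) caches[[i]] <- list(x = x)
      x <- multi_kernel_conv_forward(x, p, net$combine)
    } else if (ly$type == "bn") {
      r <- cpp_bn_forward(x, p$gamma, p$beta, 1e-5)
      if (want_cache) caches[[i]] <- list(xhat = r$xhat, istd = r$istd)
      x <- r$y
    } else if (ly$type == "relu") {
      x <- cpp_relu(as_featmap(x))
      if (want_cache) caches[[i]] <- list(y = x)
    } else if (ly$type == "pool") {
      r <- cpp_maxpool_forward(x, as.integer(ly$size), as.integer(ly$stride))
      if (want_cache) caches[[i]] <- list(argmax = r$argmax, dims = dim(x))
      x <- r$y
    } else if (ly$type == "conv1x1") {
      if (want_cache) caches[[i]] <- list(x = x)
      x <- conv1x1_forward(x, p$w, p$b)
    } else if (ly$type == "fc") {
      v <- as.vector(x)
      if (want_cache) caches[[i]] <- list(x = v, dims = dim(x))
      x <- as.numeric(p$w %*% v + p$b)
    }
  }
  if (want_cache) list(out = x, caches = caches) else x
}

# dout has the shape of the network output; returns per-layer gradients
net_backward <- function(net, caches, dout) {
  grads <- vector("list", length(net$spec))
  g <- dout
  for (i in rev(seq_along(net$spec))) {
    ly <- net$spec[[i]]; p <- net$params[[i]]; cc <- caches[[i]]
    if (ly$type == "mkconv") {
      if (net$combine == "sum") {
        kf <- mk_effective_kernel(p)
        bk <- cpp_mk_conv_backward(cc$x, kf, as_featmap(g))
        dke <- array(bk$dk, c(3, 3, dim(p$k33)[3], dim(p$k33)[4]))
        grads[[i]] <- list(k33 = dke,
                           k31 = dke[, 2, , , drop = FALSE],
                           k13 = dke[2, , , , drop = FALSE],
                           bias = as.numeric(bk$db))
        dim(grads[[i]]$k31) <- dim(p$k31)
        dim(grads[[i]]$k13) <- dim(p$k13)
        g <- bk$dx
      } else {
        bk <- mkconv_project_backward(p, cc, g)
        grads[[i]] <- bk$grad
        g <- bk$dx
      }
    } else if (ly$type == "bn") {
      r <- cpp_bn_backward(cc$xhat, cc$istd, p$gamma, as_featmap(g))
      grads[[i]] <- list(gamma = as.numeric(r$dgamma),
                         beta = as.numeric(r$dbeta))
      g <- r$dx
    } else if (ly$type == "relu") {
      g <- cpp_relu_backward(as_featmap(g), cc$y)
      grads[[i]] <- list()
    } else if (ly$type == "pool") {
      g <- cpp_maxpool_backward(cc$argmax, as_featmap(g),
                                as.integer(cc$dims[1]), as.integer(cc$dims[2]))
      grads[[i]] <- list()
    } else if (ly$type == "conv1x1") {
      d <- dim(cc$x)
      xm <- matrix(cc$x, ncol = d[3])
      gm <- matrix(g, ncol = ncol(p$w))
      grads[[i]] <- list(w = crossprod(xm, gm), b = colSums(gm))
      g <- array(gm %*% t(p$w), d)
    } else if (ly$type == "fc") {
      gv <- as.numeric(g)
      grads[[i]] <- list(w = outer(gv, cc$x), b = gv)
      g <- array(as.numeric(crossprod(p$w, gv)), cc$dims)
    }
  }
  list(grads = grads, dx = g)
}

# backward for the concatenate-then-project variant
mkconv_project_backward <- function(p, cc, g) {
  x <- cc$x
  F_ <- dim(p$k33)[4]; d <- dim(x)
  f3 <- lapply(c("k33", "k31", "k13"), function(nm)
    cpp_mk_conv_forward(x, embed_kernel_flat(p[[nm]]), numeric(F_)))
  ycat <- array(c(f3[[1]], f3[[2]], f3[[3]]), c(d[1], d[2], 3L * F_))
  gm <- matrix(g, ncol = F_)
  ym <- matrix(ycat, ncol = 3L * F_)
  dproj <- crossprod(ym, gm)
  db <- colSums(gm)
  dycat <- array(gm %*% t(p$proj), c(d[1], d[2], 3L * F_))
  dx <- array(0, d)
  dk <- list()
  nms <- c("k33", "k31", "k13")
  for (j in 1:3) {
    part <- dycat[, , ((j - 1) * F_ + 1):(j * F_), drop = FALSE]
    bk <- cpp_mk_conv_backward(x, embed_kernel_flat(p[[nms[j]]]),
                               as_featmap(part))
    dke <- array(bk$dk, c(3, 3, d[3], F_))
    dkj <- switch(nms[j], k33 = dke,
                  k31 = dke[, 2, , , drop = FALSE],
                  k13 = dke[2, , , , drop = FALSE])
    dim(dkj) <- dim(p[[nms[j]]])
    dk[[nms[j]]] <- dkj
    dx <- dx + bk$dx
  }
  list(dx = dx, grad = c(dk, list(bias = db, proj = dproj)))
}

#' Save and load network weights
#'
#' Weights are serialized with R's native format; a sibling plain-text
#' layer manifest (`<path>.manifest.txt`) records the architecture and
#' per-layer parameter counts for portability audits.
#'
#' @param net a `polyp_net`.
#' @param path output file (conventionally `.rds`).
#' @export
save_network <- function(net, path) {
  saveRDS(net, path)
  aud <- audit_shapes(net)
  aud$params <- c(0, vapply(net$params, function(p)
    sum(vapply(p, length, 1L)), 1))
  write.table(aud[, c("layer", "filters", "size_stride", "output", "params")],
              paste0(path, ".manifest.txt"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  net <- readRDS(path)
  if (!inherits(net, "polyp_net")) stop("not a polyp_net checkpoint")
  net
}
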