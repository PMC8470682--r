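#' Multi-kernel convolution forward pass
#'
#' The convolutional blocks use three parallel same-padded kernels of
#' shapes 3x3, 3x1 and 1x3 per output filter, each convolved with the
#' full input and combined.  Under the default `"sum"` combination the
#' three responses are added elementwise, which is algebraically one
#' 3x3 convolution whose kernel is the 3x3 kernel plus the 3x1 kernel
#' embedded in the middle column plus the 1x3 kernel embedded in the
#' middle row; the implementation exploits this (one im2col + one BLAS
#' gemm per block).  A concatenate-then-project variant (`"project"`)
#' keeps the three responses as 3F channels and mixes them with a
#' learned 1x1 projection.
#'
#' @param x numeric `(H, W, C)` array, the input feature map.
#' @param weights list with elements `k33` `(3,3,C,F)`, `k31` `(3,1,C,F)`,
#'   `k13` `(1,3,C,F)`, `bias` length-F, and for the `"project"` variant
#'   additionally `proj` `(3F, F)`.
#' @param combine `"sum"` (default) or `"project"`.
#' @return `(H, W, F)` numeric array; spatial dimensions are preserved.
#' @export
multi_kernel_conv_forward <- function(x, weights, combine = "sum") {
  x <- as_featmap(x)
  C <- dim(x)[3]
  if (dim(weights$k33)[3] != C) stop("input/kernel channel mismatch")
  if (combine == "sum") {
    kf <- mk_effective_kernel(weights)
    cpp_mk_conv_forward(x, kf, as.numeric(weights$bias))
  } else if (combine == "project") {
    f3 <- lapply(c("k33", "k31", "k13"), function(nm)
      cpp_mk_conv_forward(x, embed_kernel_flat(weights[[nm]]),
                          numeric(dim(weights[[nm]])[4])))
    ycat <- array(c(f3[[1]], f3[[2]], f3[[3]]),
                  c(dim(x)[1], dim(x)[2], 3L * dim(weights$k33)[4]))
    conv1x1_forward(ycat, weights$proj, weights$bias)
  } else stop("combine must be 'sum' or 'project'")
}

as_featmap <- function(x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  storage.mode(x) <- "double"
  unclass(x)
}

# fold (3x3, 3x1, 1x3) kernels into one effective 3x3 kernel, flattened
# to a (9C x F) matrix in (ky, kx, c) column-major order
mk_effective_kernel <- function(w) {
  k <- w$k33
  k[, 2, , ] <- k[, 2, , ] + w$k31[, 1, , ]
  k[2, , , ] <- k[2, , , ] + w$k13[1, , , ]
  dim(k) <- c(9L * dim(k)[3], dim(k)[4])
  k
}

# zero-embed a single (kh, kw, C, F) kernel into flattened 3x3 form
embed_kernel_flat <- function(w) {
  d <- dim(w)
  k <- array(0, c(3, 3, d[3], d[4]))
  ry <- if (d[1] == 3) 1:3 else 2
  rx <- if (d[2] == 3) 1:3 else 2
  k[ry, rx, , ] <- w
  dim(k) <- c(9L * d[3], d[4])
  k
}

#' Batch-normalization forward rule
#'
#' `y = gamma * (x - mu) / sqrt(sigma2 + eps) + beta`, applied per
#' channel.  `mu` and `sigma2` are the normalization statistics (scalars
#' or one value per channel); within the networks they are computed per
#' channel over the spatial positions of the image being processed.
#'
#' @param x numeric array `(H, W, C)` (or any array whose last dimension
#'   is the channel when `mu` has length > 1).
#' @param mu,sigma2 normalization mean and variance; `sigma2 >= 0`.
#' @param gamma,beta learned scale and shift.
#' @param eps numerical floor added to the variance (default `1e-5`).
#' @return Array of the same shape as `x`.
#' @export
batch_norm_forward <- function(x, mu, sigma2, gamma = 1, beta = 0, eps = 1e-5) {
  if (any(sigma2 < 0)) stop("sigma2 must be >= 0")
  x <- as_featmap(x)
  d <- dim(x); C <- d[length(d)]
  n <- length(mu)
  if (n == 1L) return(gamma * (x - mu) / sqrt(sigma2 + eps) + beta)
  if (n != C) stop("per-channel parameters must match channel count")
  xm <- matrix(x, ncol = C)
  y <- sweep(xm, 2, mu) %*% diag(as.numeric(gamma) / sqrt(sigma2 + eps), C)
  y <- sweep(y, 2, beta, `+`)
  array(y, d)
}

#' ReLU forward rule
#'
#' Clamps negative values to zero, leaving non-negative values unchanged.
#'
#' @param x numeric array.
#' @return Array of the same shape.
#' @export
relu_forward <- function(x) {
  x[x < 0] <- 0
  x
}

#' Max-pooling forward rule
#'
#' Emits the maximum over each `n x n` window; output spatial dimensions
#' are `floor((D - n) / stride) + 1`.
#'
#' @param x numeric `(H, W, C)` array.
#' @param size pooling window side `n` (>= 1).
#' @param stride window step (>= 1); defaults to `size`.
#' @return Pooled `(Ho, Wo, C)` array.
#' @export
max_pool_forward <- function(x, size, stride = size) {
  if (size < 1 || stride < 1) stop("pooling window and stride must be positive")
  x <- as_featmap(x)
  if (size > dim(x)[1] || size > dim(x)[2])
    stop("pooling window larger than input")
  cpp_maxpool_forward(x, as.integer(size), as.integer(stride))$y
}

conv1x1_forward <- function(x, w, b) {
  d <- dim(x)
  y <- matrix(x, ncol = d[3]) %*% w
  y <- sweep(y, 2, b, `+`)
  array(y, c(d[1], d[2], ncol(w)))
}

sigmoid <- function(z) 1 / (1 + exp(-z))

softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}
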