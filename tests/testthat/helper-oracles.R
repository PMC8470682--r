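# Independent brute-force oracles for the numerical operations.  These
# deliberately use naive scalar loops so they share no code with the
# implementation they check.

# same-padded sliding-window weighted sum of a multi-channel map with a
# (kh, kw, C) kernel; scalar quadruple loop
oracle_conv2d <- function(x, k) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  kh <- dim(k)[1]; kw <- dim(k)[2]
  oy <- (kh - 1) %/% 2; ox <- (kw - 1) %/% 2
  out <- matrix(0, H, W)
  for (y in seq_len(H)) for (xx in seq_len(W)) {
    acc <- 0
    for (c in seq_len(C)) for (dy in seq_len(kh)) for (dx in seq_len(kw)) {
      sy <- y + dy - 1 - oy; sx <- xx + dx - 1 - ox
      if (sy >= 1 && sy <= H && sx >= 1 && sx <= W)
        acc <- acc + x[sy, sx, c] * k[dy, dx, c]
    }
    out[y, xx] <- acc
  }
  out
}

# multi-kernel block: three parallel convolutions, summed, plus bias
oracle_mk_conv <- function(x, w) {
  F_ <- dim(w$k33)[4]
  H <- dim(x)[1]; W <- dim(x)[2]
  out <- array(0, c(H, W, F_))
  C <- dim(x)[3]
  for (f in seq_len(F_)) {
    out[, , f] <- oracle_conv2d(x, array(w$k33[, , , f], c(3, 3, C))) +
      oracle_conv2d(x, array(w$k31[, , , f], c(3, 1, C))) +
      oracle_conv2d(x, array(w$k13[, , , f], c(1, 3, C))) +
      w$bias[f]
  }
  out
}

oracle_bn <- function(x, mu, sigma2, gamma, beta, eps = 1e-5) {
  d <- dim(x); C <- d[3]
  out <- x
  for (c in seq_len(C))
    out[, , c] <- gamma[c] * (x[, , c] - mu[c]) / sqrt(sigma2[c] + eps) +
      beta[c]
  out
}

oracle_maxpool <- function(x, n, stride) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  Ho <- (H - n) %/% stride + 1; Wo <- (W - n) %/% stride + 1
  out <- array(0, c(Ho, Wo, C))
  for (c in seq_len(C)) for (i in seq_len(Ho)) for (j in seq_len(Wo)) {
    ys <- (i - 1) * stride + seq_len(n)
    xs <- (j - 1) * stride + seq_len(n)
    out[i, j, c] <- max(x[ys, xs, c])
  }
  out
}

# pixel-center bilinear resampling, scalar loops
oracle_resize_bilinear <- function(x, th, tw) {
  d <- dim(x)
  out <- array(0, c(th, tw, d[3]))
  for (c in seq_len(d[3])) for (i in seq_len(th)) for (j in seq_len(tw)) {
    sy <- min(max((i - 0.5) * d[1] / th - 0.5, 0), d[1] - 1)
    sx <- min(max((j - 0.5) * d[2] / tw - 0.5, 0), d[2] - 1)
    y0 <- floor(sy); x0 <- floor(sx)
    y1 <- min(y0 + 1, d[1] - 1); x1 <- min(x0 + 1, d[2] - 1)
    fy <- sy - y0; fx <- sx - x0
    out[i, j, c] <-
      x[y0 + 1, x0 + 1, c] * (1 - fy) * (1 - fx) +
      x[y0 + 1, x1 + 1, c] * (1 - fy) * fx +
      x[y1 + 1, x0 + 1, c] * fy * (1 - fx) +
      x[y1 + 1, x1 + 1, c] * fy * fx
  }
  out
}

# 8-connected components by repeated neighborhood growing
oracle_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  cur <- 0L
  for (start in which(mask != 0)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      py <- (p - 1) %% H + 1; px <- (p - 1) %/% H + 1
      for (dy in -1:1) for (dx in -1:1) {
        qy <- py + dy; qx <- px + dx
        if (qy < 1 || qy > H || qx < 1 || qx > W) next
        q <- (qx - 1) * H + qy
        if (mask[q] != 0 && lab[q] == 0L) {
          lab[q] <- cur
          queue <- c(queue, q)
        }
      }
    }
  }
  lab
}

oracle_component_boxes <- function(mask) {
  lab <- oracle_components(mask)
  k <- max(lab)
  if (k == 0) return(data.frame(x_min = integer(), y_min = integer(),
                                width = integer(), height = integer()))
  do.call(rbind, lapply(seq_len(k), function(i) {
    rows <- row(lab)[lab == i]; cols <- col(lab)[lab == i]
    data.frame(x_min = min(cols) - 1L, y_min = min(rows) - 1L,
               width = max(cols) - min(cols) + 1L,
               height = max(rows) - min(rows) + 1L)
  }))
}

# point-in-rectangle scan for the center-point criterion
oracle_match_center <- function(preds, gts) {
  tp <- 0L; fp <- 0L
  for (i in seq_len(nrow(preds))) {
    cx <- preds$x_min[i] + preds$width[i] / 2
    cy <- preds$y_min[i] + preds$height[i] / 2
    hit <- FALSE
    for (j in seq_len(nrow(gts))) {
      if (cx >= gts$x_min[j] && cx <= gts$x_min[j] + gts$width[j] &&
          cy >= gts$y_min[j] && cy <= gts$y_min[j] + gts$height[j])
        hit <- TRUE
    }
    if (hit) tp <- tp + 1L else fp <- fp + 1L
  }
  fn <- if (nrow(preds) == 0L && nrow(gts) > 0L) 1L else 0L
  list(tp = tp, fp = fp, fn = fn)
}

# concordant-pair fraction over every positive/negative pair
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

random_boxes <- function(n, w = 640, h = 480) {
  if (n == 0) return(data.frame(x_min = numeric(), y_min = numeric(),
                                width = numeric(), height = numeric()))
  bw <- sample(5:120, n, replace = TRUE)
  bh <- sample(5:120, n, replace = TRUE)
  data.frame(x_min = runif(n, 0, w - bw), y_min = runif(n, 0, h - bh),
             width = bw, height = bh)
}

random_mk_weights <- function(C, F_) {
  list(k33 = array(rnorm(9 * C * F_), c(3, 3, C, F_)),
       k31 = array(rnorm(3 * C * F_), c(3, 1, C, F_)),
       k13 = array(rnorm(3 * C * F_), c(1, 3, C, F_)),
       bias = rnorm(F_))
}
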