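#' Parametric synthetic colonoscopy scene
#'
#' Describes a colonoscopy-like frame: a vignetted lumen over a wrinkled
#' mucosal wall with specular highlights, in a white-light-like (`"WL"`,
#' warm pink) or narrow-band-like (`"NBI"`, red-suppressed, green/blue
#' boosted) palette, plus 0-4 elliptical polyps.  The same spec and seed
#' always reproduce the frame bit for bit.  The generator exercises code
#' paths and the size-threshold analyses; it does not attempt optical
#' realism.
#'
#' @param width,height frame dimensions in pixels (>= 64).
#' @param palette `"WL"` or `"NBI"`.
#' @param vignette_strength 0-1, radial darkening toward the periphery.
#' @param wrinkle_amplitude relative amplitude of the wall ridges.
#' @param wrinkle_frequency base ridge count across the frame.
#' @param specular_count bright highlight spots.
#' @param noise_sd additive pixel noise (gray levels).
#' @param polyps list of [polyp_spec()] objects (0-4).
#' @param seed integer seed controlling every random element.
#' @return list of class `scene_spec`.
#' @export
scene_spec <- function(width = 640, height = 480, palette = c("WL", "NBI"),
                       vignette_strength = 0.55, wrinkle_amplitude = 0.08,
                       wrinkle_frequency = 3, specular_count = 6,
                       noise_sd = 2, polyps = list(), seed = 1L) {
  palette <- match.arg(palette)
  if (width < 64 || height < 64) stop("frame dimensions must be >= 64")
  if (length(polyps) > 4) stop("at most 4 polyps per frame")
  structure(list(width = as.integer(width), height = as.integer(height),
                 palette = palette, vignette_strength = vignette_strength,
                 wrinkle_amplitude = wrinkle_amplitude,
                 wrinkle_frequency = wrinkle_frequency,
                 specular_count = as.integer(specular_count),
                 noise_sd = noise_sd, polyps = polyps,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

#' Synthetic polyp description
#'
#' An elliptical protrusion with one of two surface textures mirroring
#' the optical polyp taxonomy: `"neoplastic"` carries dark tubular /
#' branched vessel strokes, `"hyperplastic"` carries light dots of
#' uniform size.  The semi-axes are derived from `target_area` — the
#' area of the tight bounding box of the rotated ellipse — so pixel-size
#' thresholds (1600, 1800) can be straddled exactly.
#'
#' @param center_x,center_y polyp center in frame pixels.
#' @param target_area tight-box area in pixels.
#' @param aspect semi-axis ratio a/b (>= 1).
#' @param rotation ellipse rotation, degrees.
#' @param texture_class `"neoplastic"` or `"hyperplastic"`.
#' @param contrast 0-1 rendering strength; 0 renders nothing.
#' @return list of class `polyp_spec` with derived semi-axes `a`, `b`.
#' @export
polyp_spec <- function(center_x, center_y, target_area = 2500, aspect = 1.4,
                       rotation = 0, texture_class = c("neoplastic",
                                                       "hyperplastic"),
                       contrast = 0.8) {
  texture_class <- match.arg(texture_class)
  if (aspect < 1) stop("aspect must be >= 1")
  th <- rotation * pi / 180
  # tight box of the rotated ellipse: w = 2 sqrt(a^2 cos^2 + b^2 sin^2), etc.
  # with a = aspect * b the box area scales as b^2; solve for b
  co <- cos(th)^2; si <- sin(th)^2
  unit_area <- 4 * sqrt((aspect^2 * co + si) * (aspect^2 * si + co))
  b <- sqrt(target_area / unit_area)
  a <- aspect * b
  structure(list(center_x = center_x, center_y = center_y,
                 target_area = target_area, aspect = aspect,
                 rotation = rotation, a = a, b = b,
                 texture_class = texture_class, contrast = contrast),
            class = "polyp_spec")
}

# analytic tight box of the rotated ellipse, before pixelization
polyp_analytic_box <- function(p) {
  th <- p$rotation * pi / 180
  w <- 2 * sqrt(p$a^2 * cos(th)^2 + p$b^2 * sin(th)^2)
  h <- 2 * sqrt(p$a^2 * sin(th)^2 + p$b^2 * cos(th)^2)
  c(w = w, h = h)
}

#' Generate the polyp-free background frame
#'
#' Radial lumen vignette, sinusoidal-plus-smoothed-noise wrinkle ridges,
#' and specular highlights, colored by the palette (the NBI-like palette
#' suppresses the red channel and boosts green/blue).
#'
#' @param spec a [scene_spec()].
#' @return 3-channel `raster_image`.
#' @export
generate_background <- function(spec) {
  set.seed(spec$seed)
  H <- spec$height; W <- spec$width
  X <- matrix(rep(seq_len(W) - 1, each = H), H, W)
  Y <- matrix(rep(seq_len(H) - 1, W), H, W)
  cx <- W / 2 + runif(1, -0.08, 0.08) * W
  cy <- H / 2 + runif(1, -0.08, 0.08) * H
  rmax <- sqrt((W / 2)^2 + (H / 2)^2)
  r <- sqrt((X - cx)^2 + (Y - cy)^2) / rmax
  vign <- pmax(1 - spec$vignette_strength * r^2, 0.08)
  # wrinkle ridges: oriented sinusoids + smoothed coarse noise
  wr <- matrix(0, H, W)
  for (i in 1:3) {
    th <- runif(1, 0, pi)
    f <- spec$wrinkle_frequency * runif(1, 0.6, 1.6)
    ph <- runif(1, 0, 2 * pi)
    wr <- wr + sin(2 * pi * f * (X * cos(th) + Y * sin(th)) / W + ph) / 3
  }
  coarse <- array(rnorm(12 * 16), c(12, 16, 1))
  wr <- wr + 0.6 * resize_bilinear_num(coarse, H, W)[, , 1]
  base <- if (spec$palette == "WL") c(186, 114, 100) else c(72, 142, 148)
  px <- array(0, c(H, W, 3))
  for (c in 1:3)
    px[, , c] <- base[c] * vign * (1 + spec$wrinkle_amplitude * wr)
  if (spec$specular_count > 0) for (i in seq_len(spec$specular_count)) {
    sx <- runif(1, 0.12, 0.88) * W; sy <- runif(1, 0.12, 0.88) * H
    sg <- runif(1, 1.5, 4)
    spot <- 235 * exp(-((X - sx)^2 + (Y - sy)^2) / (2 * sg^2))
    for (c in 1:3) px[, , c] <- px[, , c] + spot
  }
  if (spec$noise_sd > 0) {
    nz <- matrix(rnorm(H * W, sd = spec$noise_sd), H, W)
    for (c in 1:3) px[, , c] <- px[, , c] + nz
  }
  raster_image(quantize_u8(px))
}

#' Composite one polyp onto a frame
#'
#' Renders the elliptical protrusion (dome brightening with a darker
#' rim) and its class texture, and returns the tight bounding box of the
#' composited pixels.  The rendered box area stays within 10 percent of
#' the spec's `target_area`.
#'
#' @param frame a `raster_image` to composite onto.
#' @param polyp a [polyp_spec()]; must lie fully inside the frame.
#' @param seed integer seed for the texture randomness.
#' @return list with `frame` (composited image), `box` (one-row box
#'   table), `label` (the texture class).
#' @export
render_polyp <- function(frame, polyp, seed = 1L) {
  set.seed(seed)
  H <- image_height(frame); W <- image_width(frame)
  ab <- polyp_analytic_box(polyp)
  if (polyp$center_x - ab["w"] / 2 < 0 || polyp$center_x + ab["w"] / 2 > W ||
      polyp$center_y - ab["h"] / 2 < 0 || polyp$center_y + ab["h"] / 2 > H)
    stop("polyp crosses the frame edge")
  # local window with a 2-pixel pad
  x0 <- max(0, floor(polyp$center_x - ab["w"] / 2) - 2)
  x1 <- min(W - 1, ceiling(polyp$center_x + ab["w"] / 2) + 2)
  y0 <- max(0, floor(polyp$center_y - ab["h"] / 2) - 2)
  y1 <- min(H - 1, ceiling(polyp$center_y + ab["h"] / 2) + 2)
  xs <- x0:x1; ys <- y0:y1
  nx <- length(xs); ny <- length(ys)
  Xl <- matrix(rep(xs + 0.5, each = ny), ny, nx) - polyp$center_x
  Yl <- matrix(rep(ys + 0.5, nx), ny, nx) - polyp$center_y
  th <- polyp$rotation * pi / 180
  U <- (Xl * cos(th) + Yl * sin(th)) / polyp$a
  V <- (-Xl * sin(th) + Yl * cos(th)) / polyp$b
  rho <- sqrt(U^2 + V^2)
  inside <- rho <= 1
  dome <- ifelse(inside, cos(pmin(rho, 1) * pi / 2)^0.9, 0)
  rim <- ifelse(inside, exp(-((rho - 0.93) / 0.05)^2), 0)
  delta <- polyp$contrast * (65 * dome - 24 * rim)
  # class texture
  if (polyp$contrast > 0) {
    if (polyp$texture_class == "neoplastic") {
      n_str <- max(3L, round(polyp$target_area / 150))
      for (s in seq_len(n_str)) {
        rr <- sqrt(runif(1)) * 0.75; an <- runif(1, 0, 2 * pi)
        u <- rr * cos(an) * polyp$a; v <- rr * sin(an) * polyp$b
        px <- u * cos(th) - v * sin(th) + polyp$center_x - x0 - 0.5
        py <- u * sin(th) + v * cos(th) + polyp$center_y - y0 - 0.5
        dirs <- runif(1, 0, 2 * pi)
        for (st in seq_len(round(runif(1, 5, 12)))) {
          dirs <- dirs + rnorm(1, 0, 0.35)
          px <- px + cos(dirs); py <- py + sin(dirs)
          ix <- round(px) + 1L; iy <- round(py) + 1L
          if (ix < 1 || ix > nx || iy < 1 || iy > ny || rho[iy, ix] > 0.92)
            break
          delta[iy, ix] <- delta[iy, ix] - polyp$contrast * 40
          if (ix < nx) delta[iy, ix + 1L] <- delta[iy, ix + 1L] -
              polyp$contrast * 20
        }
      }
    } else {
      sp <- 4.5
      gx <- seq(1, nx, by = sp) + runif(1, 0, sp)
      gy <- seq(1, ny, by = sp) + runif(1, 0, sp)
      for (dx in gx) for (dy in gy) {
        ix <- round(dx + runif(1, -0.8, 0.8)); iy <- round(dy + runif(1, -0.8, 0.8))
        if (ix < 2 || ix > nx - 1 || iy < 2 || iy > ny - 1) next
        if (rho[iy, ix] > 0.85) next
        for (ox in -1:1) for (oy in -1:1) {
          g <- exp(-(ox^2 + oy^2) / 1.2)
          delta[iy + oy, ix + ox] <- delta[iy + oy, ix + ox] +
            polyp$contrast * 38 * g
        }
      }
    }
  }
  changed <- abs(delta) > 0.5
  if (!any(changed)) stop("degenerate polyp: no pixels composited")
  px <- as_featmap(frame)
  for (c in seq_len(dim(px)[3]))
    px[ys + 1, xs + 1, c] <- px[ys + 1, xs + 1, c] + delta
  rowsc <- which(rowSums(changed) > 0); colsc <- which(colSums(changed) > 0)
  box <- bbox(x_min = x0 + min(colsc) - 1L, y_min = y0 + min(rowsc) - 1L,
              width = diff(range(colsc)) + 1L,
              height = diff(range(rowsc)) + 1L)
  list(frame = raster_image(quantize_u8(px)), box = box,
       label = polyp$texture_class)
}

#' Render a full scene
#'
#' Background plus every polyp in the spec, composited in order with
#' per-polyp seeds derived from the scene seed.
#'
#' @param spec a [scene_spec()].
#' @return list with `image` (`raster_image`), `gt_boxes` (box table with
#'   a `class_label` column; zero rows for a normal frame), and
#'   `palette`.
#' @export
generate_scene <- function(spec) {
  img <- generate_background(spec)
  boxes <- list()
  for (i in seq_along(spec$polyps)) {
    r <- render_polyp(img, spec$polyps[[i]],
                      seed = (spec$seed + 7919L * i) %% 2147483647L)
    img <- r$frame
    boxes[[i]] <- cbind(r$box, class_label = r$label)
  }
  gt <- if (length(boxes)) do.call(rbind, boxes) else
    data.frame(x_min = integer(), y_min = integer(), width = integer(),
               height = integer(), class_label = character())
  list(image = img, gt_boxes = gt, palette = spec$palette)
}

#' Generate a synthetic dataset
#'
#' Draws frame designs (palette, polyp class, size, pose) from the seed,
#' renders each scene, and either writes TIFF frames plus an annotation
#' table and manifest to `out_dir`, or returns the frames in memory
#' (`out_dir = NULL`, for small runs).  Fully reproducible from the
#' seed.
#'
#' @param n_images number of frames (>= 1).
#' @param out_dir output directory (created if needed), or `NULL`.
#' @param seed integer master seed.
#' @param class_mix probability of the neoplastic class for polyp frames.
#' @param size_range target tight-box area range in pixels; a single
#'   value fixes the area exactly.
#' @param negatives_fraction fraction of polyp-free (normal) frames.
#' @param palette_mix probability of the WL-like palette.
#' @param width,height frame dimensions.
#' @param contrast_range polyp rendering strength range.
#' @return A manifest data.frame (one row per frame) with the image
#'   path or index, palette, class label and box geometry; written to
#'   `manifest.tsv` alongside the frames when `out_dir` is given,
#'   together with an [write_annotations()] table `annotations.tsv`.
#'   When `out_dir` is `NULL` the result carries the rendered samples in
#'   attribute `"samples"`.
#' @export
generate_dataset <- function(n_images, out_dir = NULL, seed = 1L,
                             class_mix = 0.5, size_range = c(900, 6400),
                             negatives_fraction = 0.25, palette_mix = 0.5,
                             width = 640, height = 480,
                             contrast_range = c(0.7, 0.95)) {
  if (n_images < 1) stop("n_images must be >= 1")
  set.seed(seed)
  if (length(size_range) == 1L) size_range <- rep(size_range, 2L)
  design <- data.frame(
    idx = seq_len(n_images),
    negative = runif(n_images) < negatives_fraction,
    palette = ifelse(runif(n_images) < palette_mix, "WL", "NBI"),
    class_label = ifelse(runif(n_images) < class_mix,
                         "neoplastic", "hyperplastic"),
    target_area = runif(n_images, size_range[1], size_range[2]),
    aspect = runif(n_images, 1, 1.8),
    rotation = runif(n_images, 0, 180),
    contrast = runif(n_images, contrast_range[1], contrast_range[2]),
    ucx = runif(n_images), ucy = runif(n_images),
    scene_seed = sample.int(2147483646L, n_images))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  rows <- vector("list", n_images)
  samples <- if (is.null(out_dir)) vector("list", n_images) else NULL
  records <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    d <- design[i, ]
    polyps <- list()
    if (!d$negative) {
      p0 <- polyp_spec(0, 0, target_area = d$target_area, aspect = d$aspect,
                       rotation = d$rotation,
                       texture_class = d$class_label, contrast = d$contrast)
      ab <- polyp_analytic_box(p0)
      mx <- ab["w"] / 2 + 8; my <- ab["h"] / 2 + 8
      cx <- mx + d$ucx * (width - 2 * mx)
      cy <- my + d$ucy * (height - 2 * my)
      polyps <- list(polyp_spec(cx, cy, target_area = d$target_area,
                                aspect = d$aspect, rotation = d$rotation,
                                texture_class = d$class_label,
                                contrast = d$contrast))
    }
    sc <- generate_scene(scene_spec(width = width, height = height,
                                    palette = d$palette, polyps = polyps,
                                    seed = d$scene_seed))
    # paths are stored relative to the dataset directory so two runs
    # into different directories stay byte-identical
    path <- sprintf("frame_%04d.tif", i)
    if (!is.null(out_dir)) write_image(sc$image, file.path(out_dir, path))
    else samples[[i]] <- sc$image
    gt <- sc$gt_boxes
    lab <- if (d$negative) NA_character_ else d$class_label
    records[[i]] <- annotated_image(
      path, gt[, c("x_min", "y_min", "width", "height"), drop = FALSE],
      class_label = lab,
      modality = paste0("synthetic-", d$palette))
    rows[[i]] <- data.frame(
      image_path = path, width = width, height = height,
      palette = d$palette, class_label = lab,
      x_min = if (d$negative) NA_integer_ else gt$x_min,
      y_min = if (d$negative) NA_integer_ else gt$y_min,
      box_width = if (d$negative) NA_integer_ else gt$width,
      box_height = if (d$negative) NA_integer_ else gt$height,
      area = if (d$negative) NA_real_ else gt$width * gt$height)
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE, na = "")
    write_annotations(records, file.path(out_dir, "annotations.tsv"))
  } else {
    attr(manifest, "samples") <- samples
  }
  attr(manifest, "dir") <- out_dir
  attr(manifest, "records") <- records
  manifest
}

#' Load a generated dataset for training
#'
#' Turns a manifest (as returned or written by [generate_dataset()])
#' into the sample list consumed by [train_detector()] and
#' [train_classifier()].
#'
#' @param manifest manifest data.frame, or the path of a dataset
#'   directory containing `manifest.tsv`.
#' @param dir directory that image paths are relative to (defaults to
#'   the manifest's own directory when a path is given).
#' @return list of samples with `image`, `gt_boxes`, `class_label`,
#'   `palette`.
#' @export
load_dataset <- function(manifest, dir = NULL) {
  if (is.character(manifest)) {
    dir <- manifest
    manifest <- read.delim(file.path(dir, "manifest.tsv"), sep = "\t",
                           na.strings = "", stringsAsFactors = FALSE)
  }
  if (is.null(dir)) dir <- attr(manifest, "dir")
  samples <- attr(manifest, "samples")
  lapply(seq_len(nrow(manifest)), function(i) {
    m <- manifest[i, ]
    img <- if (!is.null(samples)) samples[[i]] else
      if (!is.null(dir)) file.path(dir, basename(m$image_path)) else
        m$image_path
    gt <- if (is.na(m$x_min))
      data.frame(x_min = integer(), y_min = integer(),
                 width = integer(), height = integer())
    else
      data.frame(x_min = m$x_min, y_min = m$y_min,
                 width = m$box_width, height = m$box_height)
    list(image = img, gt_boxes = gt,
         class_label = m$class_label, palette = m$palette)
  })
}
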