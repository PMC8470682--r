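table3_outputs <- c("128 x 128",                            # input
                    rep("128 x 128", 3), "64 x 64",         # block 1
                    rep("64 x 64", 3), "32 x 32",           # block 2
                    rep("32 x 32", 3), "16 x 16",           # block 3
                    rep("16 x 16", 9),                      # blocks 4-6
                    "16 x 16")                              # 1x1 head

test_that("detector shape audit reproduces the tabulated architecture", {
  for (ch in c(1, 3)) {
    net <- build_detector(in_channels = ch, seed = 1)
    aud <- audit_shapes(net)
    expect_equal(aud$output, table3_outputs)
    # head emits 16 x 16 x 24 and the parameter count is reported
    expect_equal(unlist(aud[nrow(aud), c("out_h", "out_w", "out_c")],
                        use.names = FALSE), c(16, 16, 24))
    expect_gt(n_parameters(net), 1e5)
  }
  expect_error(build_detector(in_channels = 2), "1 or 3")
  # forward pass really produces the audited head shape
  net <- build_detector(seed = 2)
  out <- polypgray:::net_forward(net, array(0.5, c(128, 128, 1)))
  expect_equal(dim(out), c(16, 16, 24))
})

test_that("anchor set holds the eight printed box shapes", {
  a <- anchor_set()
  expect_equal(nrow(a), 8L)
  expect_equal(a$width, c(16, 32, 24, 48, 60, 108, 216, 180))
  expect_equal(a$height, c(16, 32, 48, 24, 80, 72, 144, 180))
})

test_that("decode emits boxes per the anchor-grid formula", {
  # nothing above cutoff -> empty list
  quiet <- array(-10, c(16, 16, 24))
  expect_equal(nrow(decode_detections(quiet, 640, 480)), 0L)
  # single hot anchor 1 at cell row 5 col 7 with tx = ty = 0 (sigmoid 0.5):
  # center (7.5*40, 5.5*30) = (300, 165), box (292, 157, 16, 16)
  g <- array(-10, c(16, 16, 24))
  g[6, 8, 1] <- 10; g[6, 8, 2] <- 0; g[6, 8, 3] <- 0
  d <- decode_detections(g, 640, 480, cutoff = 0.2)
  expect_equal(nrow(d), 1L)
  expect_equal(unlist(d[1, c("x_min", "y_min", "width", "height")],
                      use.names = FALSE), c(292, 157, 16, 16))
  expect_equal(d$anchor, 1L)
  expect_error(decode_detections(array(0, c(8, 8, 24)), 640, 480), "16 x 16")
})

test_that("decode is cutoff-monotone and respects image bounds", {
  set.seed(13)
  g <- array(rnorm(16 * 16 * 24, sd = 2), c(16, 16, 24))
  prev <- Inf
  for (cut in c(0.05, 0.2, 0.5, 0.8)) {
    d <- decode_detections(g, 640, 480, cutoff = cut, nms = FALSE)
    expect_lte(nrow(d), prev)
    prev <- nrow(d)
    if (nrow(d)) {
      expect_true(all(d$score >= cut))
      expect_true(all(d$x_min >= 0 & d$y_min >= 0))
      expect_true(all(d$x_min + d$width <= 640))
      expect_true(all(d$y_min + d$height <= 480))
      expect_equal(order(-d$score), seq_len(nrow(d)))
    }
  }
  # suppression never increases the detection count
  d_all <- decode_detections(g, 640, 480, cutoff = 0.2, nms = FALSE)
  d_nms <- decode_detections(g, 640, 480, cutoff = 0.2, nms = TRUE)
  expect_lte(nrow(d_nms), nrow(d_all))
})

test_that("target assignment picks the center cell and best anchor", {
  # no boxes -> all negative
  t0 <- assign_targets(bbox(1, 1, 1, 1)[0, ], 640, 480)
  expect_equal(sum(t0$obj), 0)
  expect_equal(t0$n_pos, 0)
  # a 16x16 box centered in cell (row 5, col 7) -> anchor 1, offsets 0.5
  b <- bbox(300 - 8, 165 - 8, 16, 16)
  tg <- assign_targets(b, 640, 480)
  expect_equal(tg$n_pos, 1)
  expect_equal(tg$obj[6, 8, 1], 1)
  expect_equal(tg$tx[6, 8, 1], 0.5)
  expect_equal(tg$ty[6, 8, 1], 0.5)
  # two ground truths in distinct cells -> exactly two positives
  b2 <- rbind(b, bbox(40, 40, 60, 80))
  expect_equal(assign_targets(b2, 640, 480)$n_pos, 2)
  expect_error(assign_targets(bbox(630, 470, 40, 40), 640, 480), "outside")
})

test_that("assigned targets decode back to the ground-truth center", {
  set.seed(17)
  for (i in 1:20) {
    b <- random_boxes(1)
    tg <- assign_targets(b, 640, 480)
    # build a raw grid whose activations equal the targets
    g <- array(-30, c(16, 16, 24))
    pos <- which(tg$obj == 1, arr.ind = TRUE)
    k <- pos[1, 3]
    logit <- function(p) log(p / (1 - p))
    g[pos[1, 1], pos[1, 2], 3 * k - 2] <- 30
    g[pos[1, 1], pos[1, 2], 3 * k - 1] <- logit(min(max(tg$tx[pos], 1e-6), 1 - 1e-6))
    g[pos[1, 1], pos[1, 2], 3 * k] <- logit(min(max(tg$ty[pos], 1e-6), 1 - 1e-6))
    d <- decode_detections(g, 640, 480, cutoff = 0.5)
    expect_equal(nrow(d), 1L)
    ctr_gt <- bbox_center(b)
    ctr_dd <- bbox_center(d)
    # within half a cell stride (boxes clipped at frame edges can shift
    # the reported center, so compare pre-clip centers via the cell)
    expect_lt(abs(ctr_dd[1, "x"] - ctr_gt[1, "x"]), 640 / 16 / 2 + 1e-6 +
                abs(d$width[1] - anchor_set()$width[d$anchor[1]]) / 2)
    expect_lt(abs(ctr_dd[1, "y"] - ctr_gt[1, "y"]), 480 / 16 / 2 + 1e-6 +
                abs(d$height[1] - anchor_set()$height[d$anchor[1]]) / 2)
  }
})

test_that("detection loss is zero iff activations match the targets", {
  b <- bbox(100, 100, 32, 32)
  tg <- assign_targets(b, 640, 480)
  g <- array(-80, c(16, 16, 24))
  pos <- which(tg$obj == 1, arr.ind = TRUE)
  k <- pos[1, 3]
  logit <- function(p) log(p / (1 - p))
  g[pos[1, 1], pos[1, 2], 3 * k - 2] <- 80
  g[pos[1, 1], pos[1, 2], 3 * k - 1] <- logit(tg$tx[pos])
  g[pos[1, 1], pos[1, 2], 3 * k] <- logit(tg$ty[pos])
  expect_equal(as.numeric(detection_loss(g, tg)), 0, tolerance = 1e-12)
  # any perturbation raises it
  g2 <- g; g2[3, 3, 4] <- 3
  expect_gt(as.numeric(detection_loss(g2, tg)), 0)
  g3 <- g; g3[pos[1, 1], pos[1, 2], 3 * k - 1] <- logit(0.9)
  expect_gt(as.numeric(detection_loss(g3, tg)), 0)
})

test_that("detector training is seed-reproducible and can overfit", {
  set.seed(99)
  sc <- generate_scene(scene_spec(
    width = 320, height = 240, seed = 51,
    polyps = list(polyp_spec(160, 120, target_area = 2500))))
  ds <- list(list(image = sc$image, gt_boxes = sc$gt_boxes[, 1:4]))
  cfg <- detector_config(epochs = 8, batch_size = 1)
  fit1 <- train_detector(ds, cfg, seed = 5)
  fit2 <- train_detector(ds, cfg, seed = 5)
  expect_identical(fit1$log, fit2$log)
  expect_identical(fit1$net$params, fit2$net$params)
  # loss decreases markedly while overfitting one frame
  expect_lt(mean(tail(fit1$log$loss, 3)), 0.5 * mean(head(fit1$log$loss, 2)))
  expect_error(train_detector(list(), cfg), "empty")
})
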