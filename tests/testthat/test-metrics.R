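test_that("center-point matching scores TP, FP and image-level FN", {
  gt <- bbox(100, 100, 50, 40)
  # one prediction centered inside the only GT
  hit <- bbox(110, 105, 30, 30)
  expect_equal(match_by_center(hit, gt), list(tp = 1L, fp = 0L, fn = 0L))
  # zero predictions, one GT -> one image-level FN
  none <- gt[0, ]
  expect_equal(match_by_center(none, gt)$fn, 1L)
  expect_equal(match_by_center(none, gt, fn_mode = "per_gt")$fn, 1L)
  # center exactly on a GT edge counts as inside
  edge <- bbox(100 - 15, 100, 30, 20)  # center x = 100 = gt left edge
  expect_equal(match_by_center(edge, gt)$tp, 1L)
  # per-GT mode counts unmatched ground truths
  two_gt <- rbind(gt, bbox(400, 300, 60, 60))
  expect_equal(match_by_center(hit, two_gt, fn_mode = "per_gt")$fn, 1L)
  expect_equal(match_by_center(hit, two_gt)$fn, 0L)
})

test_that("center-point matching equals the brute-force scan", {
  set.seed(19)
  for (i in 1:100) {
    preds <- random_boxes(sample(0:6, 1))
    gts <- random_boxes(sample(0:4, 1))
    got <- match_by_center(preds, gts)
    want <- oracle_match_center(preds, gts)
    expect_equal(got[c("tp", "fp")], want[c("tp", "fp")],
                 ignore_attr = TRUE)
    expect_equal(got$fn == 1L, want$fn == 1L)
  }
})

test_that("image-level accuracy reproduces the printed detection ratios", {
  expect_equal(image_level_accuracy(859, 900), 95.4)
  expect_equal(image_level_accuracy(843, 900), 93.7)
  expect_equal(image_level_accuracy(1712, 1800), 95.1)
  expect_equal(image_level_accuracy(1693, 1800), 94.1)
  expect_equal(image_level_accuracy(870, 900, digits = 2), 96.67)
  expect_error(image_level_accuracy(5, 0), "positive")
})

test_that("metric panel reproduces both published confusion matrices", {
  wl <- compute_metrics(confusion2x2(tp = 110, fn = 14, fp = 36, tn = 20))
  expect_equal(unname(wl), c(72.2, 75.3, 88.7, 81.5, 85.7))
  nbi <- compute_metrics(confusion2x2(tp = 118, fn = 6, fp = 25, tn = 31))
  expect_equal(unname(nbi), c(82.8, 82.5, 95.2, 88.4, 92.3))
  # a perfect matrix scores 100 everywhere
  perf <- compute_metrics(confusion2x2(50, 0, 0, 0))
  expect_equal(unname(perf), rep(100, 5))
  expect_error(compute_metrics(confusion2x2(0, 0, 0, 0)), "all-zero")
  # F-measures lie between precision and recall
  set.seed(23)
  for (i in 1:50) {
    cm <- confusion2x2(sample(1:200, 1), sample(0:50, 1),
                       sample(0:50, 1), sample(1:200, 1))
    m <- compute_metrics(cm, digits = 6)
    expect_gte(m["F1"] + 1e-9, min(m["Prec"], m["Rec"]))
    expect_lte(m["F1"] - 1e-9, max(m["Prec"], m["Rec"]))
    expect_gte(m["F2"] + 1e-9, min(m["Prec"], m["Rec"]))
    expect_lte(m["F2"] - 1e-9, max(m["Prec"], m["Rec"]))
  }
})

test_that("NPV matches the published adenoma analysis", {
  expect_equal(npv(confusion2x2(118, 6, 25, 31)), 84)   # 31/37
  expect_equal(npv(confusion2x2(118, 3, 25, 31)), 91)   # 31/34
  expect_equal(npv(confusion2x2(10, 0, 3, 12)), 100)
  expect_warning(v <- npv(confusion2x2(5, 0, 5, 0)), "undefined")
  expect_true(is.na(v))
})

test_that("exact McNemar reproduces published p-values and is principled", {
  expect_equal(mcnemar_exact(0, 3), 0.25)
  expect_equal(mcnemar_exact(0, 0), 1)
  expect_equal(mcnemar_exact(0, 16), 2 * 0.5^16)
  expect_lt(mcnemar_exact(0, 16), 0.001)
  expect_lt(mcnemar_exact(0, 19), 0.001)
  # symmetric, bounded by one, matches the stats package exact binomial
  set.seed(29)
  for (i in 1:40) {
    a <- sample(0:10, 1); b <- sample(0:10, 1)
    p <- mcnemar_exact(a, b)
    expect_equal(p, mcnemar_exact(b, a))
    expect_lte(p, 1)
    if (a + b > 0) {
      want <- stats::binom.test(a, a + b, 0.5)$p.value
      expect_equal(p, want, tolerance = 1e-12)
    }
  }
  # full enumeration of the null for small discordant totals
  for (n in 1:12) for (a in 0:n) {
    mass <- choose(n, 0:n) * 0.5^n
    want <- min(1, 2 * sum(mass[seq_len(min(a, n - a) + 1)]))
    expect_equal(mcnemar_exact(a, n - a), want, tolerance = 1e-12)
  }
})

test_that("Clopper-Pearson interval reproduces the published CIs", {
  expect_equal(unname(binomial_ci(859, 900)), c(93.9, 96.7))
  expect_equal(unname(binomial_ci(843, 900)), c(91.9, 95.2))
  expect_equal(unname(binomial_ci(0, 50))[1], 0)
  expect_equal(unname(binomial_ci(50, 50))[2], 100)
  # agrees with the stats package's exact interval
  set.seed(31)
  for (i in 1:25) {
    n <- sample(10:500, 1); x <- sample(0:n, 1)
    want <- 100 * as.numeric(stats::binom.test(x, n)$conf.int)
    expect_equal(unname(binomial_ci(x, n, digits = 8)), want,
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
  expect_error(binomial_ci(5, 0), "positive")
  expect_error(binomial_ci(7, 5), "successes")
})

test_that("Clopper-Pearson coverage reaches the nominal level", {
  set.seed(37)
  n <- 900; p <- 0.95
  draws <- stats::rbinom(2000, n, p)
  covered <- vapply(draws, function(x) {
    ci <- binomial_ci(x, n, digits = 8)
    ci[1] <= 100 * p && 100 * p <= ci[2]
  }, TRUE)
  expect_gte(mean(covered), 0.94)
})

test_that("paired tables cross-tabulate and feed McNemar", {
  a <- c(TRUE, TRUE, FALSE, TRUE); b <- c(TRUE, FALSE, FALSE, TRUE)
  tab <- paired_table(a, b)
  expect_equal(tab[c("both", "only_a", "only_b", "neither")],
               list(both = 2L, only_a = 1L, only_b = 0L, neither = 1L))
  expect_equal(paired_table(a, a)$p_value, 1)
  n <- 25
  expect_equal(paired_table(rep(TRUE, n), rep(FALSE, n))$only_a, n)
  set.seed(41)
  for (i in 1:20) {
    x <- runif(50) < 0.8; y <- runif(50) < 0.8
    tab <- paired_table(x, y)
    expect_equal(tab$both + tab$only_a + tab$only_b + tab$neither, 50L)
    expect_equal(tab$only_a, sum(x & !y))
  }
  expect_error(paired_table(a, b[1:3]), "length")
})

test_that("AUC equals the exhaustive concordant-pair fraction", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0)), 0)
  set.seed(43)
  # chance level for independent scores
  sc <- runif(4000); lb <- runif(4000) < 0.5
  expect_equal(roc_auc(sc, lb), 0.5, tolerance = 0.03)
  # ties averaged; brute force on small sets
  for (i in 1:30) {
    n <- sample(5:40, 1)
    sc <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # force ties
    lb <- runif(n) < 0.5
    if (length(unique(lb)) < 2) next
    expect_equal(roc_auc(sc, lb), oracle_auc(sc, lb), tolerance = 1e-12)
  }
  expect_error(roc_auc(c(1, 2), c(1, 1)), "both classes")
})

test_that("area stratification splits records at the pixel threshold", {
  rec <- function(w, h) list(gt_boxes = bbox(0, 0, w, h))
  rs <- list(rec(40, 40), rec(39, 41), rec(60, 30), rec(10, 10))
  st <- stratify_by_area(rs, 1600)
  # 40x40 = 1600 is inclusive on the upper stratum; 39x41 = 1599 below
  expect_equal(length(st$at_or_above), 2L)
  expect_equal(length(st$below), 2L)
  areas_lo <- vapply(st$below, function(r) bbox_area(r$gt_boxes), 1)
  expect_true(all(areas_lo < 1600))
  st18 <- stratify_by_area(rs, 1800)
  expect_equal(length(st18$at_or_above), 1L)
  expect_error(stratify_by_area(list(list(gt_boxes = NULL)), 1600),
               "without ground-truth")
})
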