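#' Balanced random cross-validation folds
#'
#' Partitions `1:n_items` into `k` folds whose sizes differ by at most
#' one, reproducibly from the seed.  The fold unit is the image.
#'
#' @param n_items number of items (>= k).
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return A `fold_plan`: list with `k`, `seed` and the integer
#'   `assignment` vector (length `n_items`, values in `1:k`).
#' @export
make_folds <- function(n_items, k = 5, seed = 1L) {
  if (n_items < k) stop("n_items must be >= k")
  set.seed(seed)
  sizes <- rep(seq_len(k), length.out = n_items)
  structure(list(k = k, seed = seed,
                 assignment = sizes[sample.int(n_items)]),
            class = "fold_plan")
}

#' Experiment configuration
#'
#' Bundles every knob of the end-to-end protocol: which modality arms to
#' run, the operating cutoffs (detection 0.2, classification 0.5), the
#' training recipes, and the split topology.
#'
#' @param arms modality arms to run; the first arm is the reference for
#'   paired comparisons.
#' @param detector_epochs,classifier_epochs epochs per training run; a
#'   named vector (e.g. `c(grayscale = 10, color = 1)`) sets them per
#'   arm.
#' @param classifier_arms arms on which the classification stage runs
#'   (the optical-diagnosis analysis operates on grayscale images).
#' @param detector_cutoff,classifier_cutoff operating cutoffs.
#' @param coefficients grayscale coefficient set (`"standard"` or
#'   `"paper"`).
#' @param test_fraction held-out fraction under the holdout topology.
#' @param k_folds when not `NULL`, run k-fold cross-validation instead
#'   of a single holdout split (pooling test outcomes over folds).
#' @param classifier_train_max cap on classifier training frames
#'   (balanced subsample); `Inf` uses all.
#' @param classifier_crop classify margin-expanded polyp crops (`TRUE`)
#'   or full frames (`FALSE`).
#' @param batch_size,lr optimizer settings shared by both trainings.
#' @param run_classifier set `FALSE` to run the detection stage only.
#' @param seed master seed; all stage seeds derive from it.
#' @return list of class `run_config`.
#' @export
run_config <- function(arms = c("grayscale", "color"),
                       detector_epochs = c(grayscale = 10, color = 1),
                       classifier_epochs = 2,
                       detector_cutoff = 0.2, classifier_cutoff = 0.5,
                       coefficients = "standard", test_fraction = 0.25,
                       k_folds = NULL, classifier_train_max = 120,
                       classifier_crop = TRUE, batch_size = 2, lr = 1e-3,
                       run_classifier = TRUE, classifier_arms = "grayscale",
                       seed = 1L) {
  arms <- match.arg(arms, c("grayscale", "color"), several.ok = TRUE)
  cfg <- list(arms = arms, detector_epochs = detector_epochs,
              classifier_epochs = classifier_epochs,
              classifier_arms = classifier_arms,
              detector_cutoff = detector_cutoff,
              classifier_cutoff = classifier_cutoff,
              coefficients = coefficients, test_fraction = test_fraction,
              k_folds = k_folds, classifier_train_max = classifier_train_max,
              classifier_crop = classifier_crop, batch_size = batch_size,
              lr = lr, run_classifier = run_classifier,
              seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

# FNV-1a hash of the serialized configuration, for report provenance
config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  h <- 2166136261
  for (b in utf8ToInt(as.character(s))) {
    # xor into the low 16 bits only (the byte is < 256), keeping h as a
    # double so the 32-bit modular product stays exact
    h <- (h %/% 65536) * 65536 + bitwXor(h %% 65536, b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Run the end-to-end detection/classification experiment
#'
#' Generates or loads a dataset, splits it (holdout or k-fold), trains
#' the detector and classifier per modality arm, evaluates with the
#' center-point criterion, and compares the arms with the exact McNemar
#' test.  Reports image-level detection accuracy with exact binomial
#' CIs, normal-frame specificity, the classification confusion matrix
#' and metric panel, NPV, AUC, and pixel-size-stratified accuracy at
#' the 1600- and 1800-pixel thresholds.
#'
#' @param config a [run_config()].
#' @param dataset samples from [load_dataset()], or a manifest
#'   data.frame, or a dataset directory path.
#' @param verbose print stage progress.
#' @return A `polyp_experiment_report` (list; see its `print` method).
#' @export
run_experiment <- function(config, dataset, verbose = FALSE) {
  if (is.character(dataset) || is.data.frame(dataset))
    dataset <- load_dataset(dataset)
  if (length(dataset) == 0L) stop("dataset is empty")
  note <- function(...) if (verbose) message(sprintf(...))
  is_polyp <- vapply(dataset, function(s) nrow(s$gt_boxes) > 0, TRUE)
  set.seed(config$seed)
  if (is.null(config$k_folds)) {
    n <- length(dataset)
    test_idx <- sort(sample.int(n, round(config$test_fraction * n)))
    splits <- list(list(train = setdiff(seq_len(n), test_idx),
                        test = test_idx))
  } else {
    plan <- make_folds(length(dataset), config$k_folds, config$seed)
    splits <- lapply(seq_len(plan$k), function(f)
      list(train = which(plan$assignment != f),
           test = which(plan$assignment == f)))
  }
  arms <- lapply(setNames(config$arms, config$arms), function(arm) {
    note("arm %s: training detector", arm)
    fold_out <- lapply(seq_along(splits), function(si) {
      sp <- splits[[si]]
      seed_d <- (config$seed + 101L * si) %% 2147483647L
      ep_arm <- function(e) if (!is.null(names(e)) && arm %in% names(e))
        e[[arm]] else e[[1]]
      det <- train_detector(
        dataset[sp$train],
        detector_config(epochs = ep_arm(config$detector_epochs),
                        batch_size = config$batch_size, lr = config$lr,
                        modality = arm, coefficients = config$coefficients,
                        cutoff = config$detector_cutoff),
        seed = seed_d)
      test <- dataset[sp$test]
      test_polyp <- is_polyp[sp$test]
      outs <- lapply(test, function(s) detect(det, s$image))
      polyp_correct <- vapply(which(test_polyp), function(i)
        match_by_center(outs[[i]], test[[i]]$gt_boxes)$tp >= 1, TRUE)
      normal_correct <- vapply(which(!test_polyp), function(i)
        nrow(outs[[i]]) == 0L, TRUE)
      cls <- NULL
      if (config$run_classifier && arm %in% config$classifier_arms &&
          any(test_polyp)) {
        tr_polyp <- dataset[sp$train][is_polyp[sp$train]]
        labs <- vapply(tr_polyp, function(s) s$class_label, "")
        keep <- balanced_subset(labs, config$classifier_train_max)
        note("arm %s: training classifier on %d frames", arm, length(keep))
        clf <- train_classifier(
          tr_polyp[keep],
          classifier_config(epochs = ep_arm(config$classifier_epochs),
                            batch_size = config$batch_size, lr = config$lr,
                            modality = arm, coefficients = config$coefficients,
                            cutoff = config$classifier_cutoff,
                            crop = config$classifier_crop),
          seed = (config$seed + 977L * si) %% 2147483647L)
        tp <- test[test_polyp]
        preds <- lapply(tp, function(s)
          classify(clf, s$image, box = s$gt_boxes))
        cls <- list(
          truth = vapply(tp, function(s) s$class_label, ""),
          label = vapply(preds, function(p) p$label, ""),
          score = vapply(preds, function(p) unname(p$p["neoplastic"]), 1.0),
          area = vapply(tp, function(s) max(bbox_area(s$gt_boxes)), 1.0))
      }
      list(polyp_correct = polyp_correct, normal_correct = normal_correct,
           polyp_area = vapply(test[test_polyp], function(s)
             max(bbox_area(s$gt_boxes)), 1.0),
           cls = cls, detector_seed = seed_d, final_loss = det$log$loss[nrow(det$log)])
    })
    summarize_arm(fold_out)
  })
  paired <- NULL
  if (length(config$arms) >= 2L) {
    a <- arms[[config$arms[1]]]$detection$per_image
    b <- arms[[config$arms[2]]]$detection$per_image
    paired <- paired_table(a, b)
  }
  structure(list(config = config, config_hash = config_hash(config),
                 seed = config$seed,
                 n_images = length(dataset), n_polyp = sum(is_polyp),
                 n_normal = sum(!is_polyp), arms = arms, paired = paired),
            class = "polyp_experiment_report")
}

balanced_subset <- function(labels, max_n) {
  if (!is.finite(max_n) || length(labels) <= max_n)
    return(seq_along(labels))
  per <- max_n %/% length(unique(labels))
  unlist(lapply(unique(labels), function(l)
    head(which(labels == l), per)))
}

summarize_arm <- function(fold_out) {
  pc <- unlist(lapply(fold_out, `[[`, "polyp_correct"))
  nc <- unlist(lapply(fold_out, `[[`, "normal_correct"))
  areas <- unlist(lapply(fold_out, `[[`, "polyp_area"))
  det <- list(
    per_image = pc, n_polyp = length(pc), n_detected = sum(pc),
    accuracy = image_level_accuracy(sum(pc), length(pc)),
    ci = binomial_ci(sum(pc), length(pc)),
    specificity = if (length(nc))
      image_level_accuracy(sum(nc), length(nc), digits = 2) else NA_real_,
    n_normal = length(nc),
    by_area = lapply(setNames(c(1600, 1800), c("px1600", "px1800")),
                     function(thr) {
      lo <- areas < thr
      list(below = if (any(lo))
             image_level_accuracy(sum(pc[lo]), sum(lo)) else NA_real_,
           at_or_above = if (any(!lo))
             image_level_accuracy(sum(pc[!lo]), sum(!lo)) else NA_real_)
    }))
  cls_parts <- lapply(fold_out, `[[`, "cls")
  cls <- NULL
  if (!all(vapply(cls_parts, is.null, TRUE))) {
    truth <- unlist(lapply(cls_parts, `[[`, "truth"))
    label <- unlist(lapply(cls_parts, `[[`, "label"))
    score <- unlist(lapply(cls_parts, `[[`, "score"))
    area <- unlist(lapply(cls_parts, `[[`, "area"))
    cm <- confusion2x2(tp = sum(truth == "neoplastic" & label == "neoplastic"),
                       fn = sum(truth == "neoplastic" & label == "hyperplastic"),
                       fp = sum(truth == "hyperplastic" & label == "neoplastic"),
                       tn = sum(truth == "hyperplastic" & label == "hyperplastic"))
    big <- area >= 1800
    cm_big <- confusion2x2(
      tp = sum(big & truth == "neoplastic" & label == "neoplastic"),
      fn = sum(big & truth == "neoplastic" & label == "hyperplastic"),
      fp = sum(big & truth == "hyperplastic" & label == "neoplastic"),
      tn = sum(big & truth == "hyperplastic" & label == "hyperplastic"))
    cls <- list(
      confusion = cm,
      metrics = suppressWarnings(compute_metrics(cm)),
      accuracy = image_level_accuracy(sum(truth == label), length(truth)),
      npv = suppressWarnings(npv(cm)),
      npv_at_or_above_1800 = suppressWarnings(npv(cm_big)),
      auc = if (length(unique(truth)) == 2L)
        roc_auc(score, truth == "neoplastic") else NA_real_)
  }
  list(detection = det, classification = cls,
       detector_seeds = vapply(fold_out, function(f)
         as.numeric(f$detector_seed), 1.0),
       final_loss = vapply(fold_out, `[[`, 1.0, "final_loss"))
}

#' @export
print.polyp_experiment_report <- function(x, ...) {
  cat(sprintf("Polyp experiment report  [config %s, seed %d]\n",
              x$config_hash, x$seed))
  cat(sprintf("  frames: %d (%d polyp / %d normal)\n",
              x$n_images, x$n_polyp, x$n_normal))
  for (arm in names(x$arms)) {
    a <- x$arms[[arm]]
    cat(sprintf("  [%s] detection accuracy %.1f%% (%d/%d; 95%% CI %.1f-%.1f)",
                arm, a$detection$accuracy, a$detection$n_detected,
                a$detection$n_polyp, a$detection$ci[1], a$detection$ci[2]))
    if (!is.na(a$detection$specificity))
      cat(sprintf(", normal specificity %.2f%%", a$detection$specificity))
    cat("\n")
    if (!is.null(a$classification)) {
      m <- a$classification$metrics
      cat(sprintf("  [%s] classification Acc %.1f Prec %.1f Rec %.1f F1 %.1f F2 %.1f | NPV %.0f%% AUC %.3f\n",
                  arm, m["Acc"], m["Prec"], m["Rec"], m["F1"], m["F2"],
                  a$classification$npv, a$classification$auc))
    }
  }
  if (!is.null(x$paired))
    cat(sprintf("  paired (arm1 vs arm2): both %d / only-1 %d / only-2 %d / neither %d, exact McNemar p = %.4g\n",
                x$paired$both, x$paired$only_a, x$paired$only_b,
                x$paired$neither, x$paired$p_value))
  invisible(x)
}

#' Write an experiment report as JSON
#'
#' @param report a `polyp_experiment_report`.
#' @param path output file.
#' @export
write_report <- function(report, path) {
  out <- report
  for (arm in names(out$arms)) out$arms[[arm]]$detection$per_image <- NULL
  jsonlite::write_json(unclass(out), path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = TRUE)
  invisible(path)
}
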