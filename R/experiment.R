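# Evaluation metrics, the binary-task and cross-validation protocol, and
# the end-to-end experiment harness (simulate/augment -> enhance -> extract
# -> classify -> report).

#' Restrict a manifest to one normal-vs-stage binary task
#'
#' Keeps only `normal` rows and rows of the given stroke stage, relabelling
#' them for binary classification with the stroke stage as the positive
#' class (so recall reads as stroke sensitivity).
#'
#' @param records manifest data.frame.
#' @param stage a non-normal stage from [stroke_stages()].
#' @return the filtered data.frame with an added `label` factor whose
#'   levels are `c("normal", stage)`.
#' @export
binary_task <- function(records, stage) {
  stage <- match.arg(stage, STROKE_STAGES)
  if (stage == "normal") stopf("stage must be a stroke stage, not \"normal\"")
  keep <- records$stage %in% c("normal", stage)
  out <- records[keep, , drop = FALSE]
  if (nrow(out) == 0L || !any(out$stage == stage) || !any(out$stage == "normal"))
    stopf("manifest holds no normal + %s pair to build the task from", stage)
  out$label <- factor(as.character(out$stage), levels = c("normal", stage))
  out
}

# midrank Mann-Whitney AUC: P(score_pos > score_neg) + 0.5 P(equal)
auc_rank <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Binary classification metrics
#'
#' Computes accuracy, precision, recall, F1 and AUC for a binary task. The
#' positive class is the second level of `y_true`. AUC uses the rank-sum
#' (Mann-Whitney) formulation with midranks for ties, so it is invariant
#' under strictly monotone transforms of `scores`. Ratios with a zero
#' denominator (no predicted or no actual positives) are reported as 0 and
#' flagged in the `degenerate` field.
#'
#' @param y_true factor of true labels (2 levels; second level = positive).
#' @param y_pred factor/character of predicted labels.
#' @param scores numeric positive-class scores (for AUC).
#' @return a `metrics_report` list: `accuracy`, `precision`, `recall`,
#'   `f1`, `auc`, `n_samples`, `degenerate`.
#' @export
compute_metrics <- function(y_true, y_pred, scores) {
  if (length(y_true) != length(y_pred) || length(y_true) != length(scores))
    stopf("y_true, y_pred and scores must have equal lengths")
  y_true <- as.factor(y_true)
  if (nlevels(y_true) != 2L) stopf("y_true must have exactly 2 levels")
  pos <- levels(y_true)[2]
  tp <- sum(y_pred == pos & y_true == pos)
  fp <- sum(y_pred == pos & y_true != pos)
  fn <- sum(y_pred != pos & y_true == pos)
  tn <- sum(y_pred != pos & y_true != pos)
  n <- length(y_true)
  degenerate <- FALSE
  ratio <- function(num, den) {
    if (den == 0) { degenerate <<- TRUE; 0 } else num / den
  }
  precision <- ratio(tp, tp + fp)
  recall <- ratio(tp, tp + fn)
  f1 <- if (precision + recall == 0) { degenerate <<- TRUE; 0 } else
    2 * precision * recall / (precision + recall)
  structure(list(accuracy = (tp + tn) / n, precision = precision,
                 recall = recall, f1 = f1,
                 auc = auc_rank(scores, y_true == pos),
                 n_samples = n, degenerate = degenerate),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.4f  precision %.4f  recall %.4f  f1 %.4f  auc %.4f (n=%d)%s\n",
              x$accuracy, x$precision, x$recall, x$f1, x$auc, x$n_samples,
              if (x$degenerate) "  [degenerate ratios set to 0]" else ""))
  invisible(x)
}

#' Stratified k-fold split
#'
#' Partitions `1:n` into `k` disjoint test folds covering every index
#' exactly once, stratified by `y` when every class has at least `k`
#' members (otherwise falls back to a plain shuffled split with a warning).
#' Deterministic given `seed`.
#'
#' @param n number of samples.
#' @param k number of folds (2 <= k <= n).
#' @param seed integer seed.
#' @param y optional label vector for stratification.
#' @return list of `k` lists, each with integer vectors `train` and `test`.
#' @export
kfold_split <- function(n, k, seed = 1L, y = NULL) {
  k <- as.integer(k)
  if (k > n) stopf("k (%d) cannot exceed n (%d)", k, n)
  if (k < 2L) stopf("k must be >= 2")
  assign_fold <- integer(n)
  with_seed(seed, {
    if (!is.null(y) && all(table(y) >= k)) {
      for (cl in unique(y)) {
        idx <- sample(which(y == cl))
        assign_fold[idx] <- rep_len(seq_len(k), length(idx))
      }
    } else {
      if (!is.null(y)) warning("some class has fewer than k members; using a plain split")
      assign_fold[sample.int(n)] <- rep_len(seq_len(k), n)
    }
  })
  lapply(seq_len(k), function(f) {
    test <- which(assign_fold == f)
    list(train = setdiff(seq_len(n), test), test = test)
  })
}

#' Run a cross-validated classification experiment
#'
#' End-to-end harness: reads a manifest, restricts it to a binary
#' normal-vs-stage task (or keeps all five stages for one-vs-rest macro
#' evaluation), optionally quadruples the training images by augmentation,
#' optionally applies SPEM enhancement, extracts features, and evaluates
#' the edRVFL classifier by stratified k-fold cross-validation. With
#' `compare_enhanced = TRUE` both a raw and an enhanced pass are run and a
#' paired comparison table is written.
#'
#' Reports written to `out_dir`: `metrics.csv` (per-fold rows plus a mean
#' row; deterministic given the seed) and `timings.csv` (wall-clock seconds
#' per configuration, informational only). Augmented variants of an image
#' always travel with it into the same fold (the split is over source
#' images), so no augmented copy of a test image leaks into training.
#'
#' @param manifest path to a manifest CSV.
#' @param task a non-normal stage name (binary normal-vs-stage task) or
#'   `"all"` for five-class one-vs-rest evaluation.
#' @param spem optional [spem_config()] (or `NULL` for raw images).
#' @param extractor a `feature_extractor`.
#' @param control an [edrvfl_control()].
#' @param cv_folds number of cross-validation folds.
#' @param augment_data quadruple the dataset by augmentation first?
#' @param compare_enhanced run raw and SPEM passes side by side? Requires
#'   `spem`.
#' @param seed integer master seed.
#' @param out_dir report directory (created if missing); `NULL` skips
#'   writing.
#' @return invisibly, a list with `metrics` (data.frame), `timings`
#'   (data.frame) and the report paths.
#' @export
run_experiment <- function(manifest, task, spem = NULL,
                           extractor = block_stat_extractor(),
                           control = edrvfl_control(), cv_folds = 25L,
                           augment_data = FALSE, compare_enhanced = FALSE,
                           seed = 1L, out_dir = NULL) {
  records <- read_manifest(manifest)
  multiclass <- identical(task, "all")
  if (!multiclass) records <- binary_task(records, task)
  if (compare_enhanced && is.null(spem))
    stopf("compare_enhanced = TRUE requires a spem config")

  images <- lapply(records$image, load_image)
  labels <- if (multiclass) droplevels(records$stage) else records$label
  if (augment_data) {
    aug_images <- list(); aug_labels <- character(0); aug_src <- integer(0)
    for (i in seq_along(images)) {
      vars <- augment(images[[i]], child_seed(seed, 900000L + i))
      aug_images <- c(aug_images, unname(vars))
      aug_labels <- c(aug_labels, rep(as.character(labels[i]), 4L))
      aug_src <- c(aug_src, rep(i, 4L))
    }
    images <- aug_images
    labels <- factor(aug_labels, levels = levels(labels))
  } else {
    aug_src <- seq_along(images)
  }

  passes <- if (compare_enhanced) list(raw = NULL, enhanced = spem)
            else if (is.null(spem)) list(raw = NULL) else list(enhanced = spem)

  all_metrics <- list(); timings <- list()
  for (pname in names(passes)) {
    t0 <- proc.time()[["elapsed"]]
    X <- extract_features_images(images, extractor, enhance = passes[[pname]])
    task_name <- if (multiclass) paste0("all_", pname)
                 else paste0("normal_vs_", task, "_", pname)
    df <- if (multiclass) {
      macro_cv(X, labels, cv_folds, control, seed, task_name, aug_src)
    } else {
      cv_metrics_grouped(X, labels, cv_folds, control, seed, task_name, aug_src)
    }
    all_metrics[[pname]] <- df
    timings[[pname]] <- data.frame(configuration = pname,
                                   wall_time_s = proc.time()[["elapsed"]] - t0)
  }
  metrics <- do.call(rbind, all_metrics)
  rownames(metrics) <- NULL
  timing_df <- do.call(rbind, timings)
  rownames(timing_df) <- NULL

  paths <- list()
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    paths$metrics <- file.path(out_dir, "metrics.csv")
    utils::write.csv(metrics, paths$metrics, row.names = FALSE)
    paths$timings <- file.path(out_dir, "timings.csv")
    utils::write.csv(timing_df, paths$timings, row.names = FALSE)
    if (compare_enhanced) {
      mr <- metrics[is.na(metrics$fold), ]
      paths$comparison <- file.path(out_dir, "comparison.csv")
      utils::write.csv(mr, paths$comparison, row.names = FALSE)
    }
  }
  invisible(list(metrics = metrics, timings = timing_df, paths = paths))
}

# k-fold CV where folds are drawn over source images, then expanded to the
# augmented variants, so variants never straddle the train/test boundary
cv_metrics_grouped <- function(X, label, k, control, seed, task_name, src) {
  groups <- unique(src)
  glabel <- label[match(groups, src)]
  folds <- kfold_split(length(groups), k, seed = child_seed(seed, 7L), y = glabel)
  pos <- levels(label)[2]
  rows <- lapply(seq_along(folds), function(f) {
    tr <- which(src %in% groups[folds[[f]]$train])
    te <- which(src %in% groups[folds[[f]]$test])
    fit <- edrvfl(X[tr, , drop = FALSE], label[tr], control = control,
                  seed = child_seed(seed, 11L + f))
    sc <- predict(fit, X[te, , drop = FALSE], type = "score")
    pred <- predict(fit, X[te, , drop = FALSE], type = "class")
    m <- compute_metrics(label[te], as.character(pred), sc[, pos])
    data.frame(task = task_name, fold = f, accuracy = m$accuracy,
               precision = m$precision, recall = m$recall, f1 = m$f1,
               auc = m$auc, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  mean_row <- data.frame(task = task_name, fold = NA_integer_,
                         t(colMeans(df[, 3:7])), stringsAsFactors = FALSE)
  names(mean_row) <- names(df)
  rbind(df, mean_row)
}

# one-vs-rest macro-averaged CV for the five-class mode
macro_cv <- function(X, labels, k, control, seed, task_name, src) {
  groups <- unique(src)
  glabel <- labels[match(groups, src)]
  folds <- kfold_split(length(groups), k, seed = child_seed(seed, 7L), y = glabel)
  rows <- lapply(seq_along(folds), function(f) {
    tr <- which(src %in% groups[folds[[f]]$train])
    te <- which(src %in% groups[folds[[f]]$test])
    fit <- edrvfl(X[tr, , drop = FALSE], labels[tr], control = control,
                  seed = child_seed(seed, 11L + f))
    sc <- predict(fit, X[te, , drop = FALSE], type = "score")
    pred <- as.character(predict(fit, X[te, , drop = FALSE], type = "class"))
    truth <- as.character(labels[te])
    per_class <- lapply(levels(droplevels(labels)), function(cl) {
      yt <- factor(ifelse(truth == cl, cl, "rest"), levels = c("rest", cl))
      yp <- ifelse(pred == cl, cl, "rest")
      m <- compute_metrics(yt, yp, sc[, cl])
      c(m$accuracy, m$precision, m$recall, m$f1, m$auc)
    })
    mm <- colMeans(do.call(rbind, per_class))
    data.frame(task = task_name, fold = f, accuracy = mean(pred == truth),
               precision = mm[2], recall = mm[3], f1 = mm[4], auc = mm[5],
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  mean_row <- data.frame(task = task_name, fold = NA_integer_,
                         t(colMeans(df[, 3:7])), stringsAsFactors = FALSE)
  names(mean_row) <- names(df)
  rbind(df, mean_row)
}
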