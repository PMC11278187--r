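test_that("binary task extraction filters, relabels and rejects bad input", {
  rec <- data.frame(image = sprintf("i%02d.png", 1:50),
                    stage = factor(rep(stroke_stages(), 10), levels = stroke_stages()),
                    stringsAsFactors = FALSE)
  sub <- binary_task(rec, "chronic")
  expect_true(all(as.character(sub$stage) %in% c("normal", "chronic")))
  expect_equal(sum(sub$label == "chronic"), sum(rec$stage == "chronic"))
  expect_equal(levels(sub$label), c("normal", "chronic"))
  expect_error(binary_task(rec, "normal"), "not \"normal\"")
  only_normal <- rec[rec$stage == "normal", ]
  expect_error(binary_task(only_normal, "acute"), "no normal")
})

test_that("classification metrics match hand arithmetic and a reference AUC", {
  y <- factor(c(rep("normal", 5), rep("chronic", 5)), levels = c("normal", "chronic"))
  sc <- c(1:5 / 100, 6:10 / 10)
  m <- compute_metrics(y, as.character(y), sc)
  expect_equal(unlist(m[c("accuracy", "precision", "recall", "f1", "auc")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1, auc = 1))

  # TP=45 FP=5 FN=5 TN=45
  truth <- factor(c(rep("pos", 50), rep("neg", 50)), levels = c("neg", "pos"))
  pred <- c(rep("pos", 45), rep("neg", 5), rep("pos", 5), rep("neg", 45))
  m2 <- compute_metrics(truth, pred, seq_along(truth))
  expect_equal(m2$accuracy, 0.9)
  expect_equal(m2$precision, 0.9)
  expect_equal(m2$recall, 0.9)
  expect_equal(m2$f1, 0.9)

  skip_if_not_installed("pROC")
  set.seed(31)
  for (i in 1:100) {
    yy <- factor(sample(c("a", "b"), 40, replace = TRUE), levels = c("a", "b"))
    while (nlevels(droplevels(yy)) < 2)
      yy <- factor(sample(c("a", "b"), 40, replace = TRUE), levels = c("a", "b"))
    ss <- round(rnorm(40), 1)  # coarse scores force ties
    ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(yy, ss, levels = c("a", "b"),
                                                           direction = "<"))))
    got <- compute_metrics(yy, sample(c("a", "b"), 40, replace = TRUE), ss)$auc
    expect_lt(abs(got - ref), 1e-10)
  }
})

test_that("AUC is monotone-transform invariant and near 0.5 under the null", {
  set.seed(7)
  y <- factor(sample(c("n", "p"), 2000, replace = TRUE), levels = c("n", "p"))
  sc <- rnorm(2000)
  m1 <- compute_metrics(y, as.character(y), sc)$auc
  m2 <- compute_metrics(y, as.character(y), exp(3 * sc) + 5)$auc
  expect_equal(m1, m2, tolerance = 1e-12)
  expect_lt(abs(m1 - 0.5), 0.05)
})

test_that("degenerate folds flag undefined ratios instead of erroring", {
  y <- factor(c("a", "a", "b", "b"), levels = c("a", "b"))
  m <- compute_metrics(y, rep("a", 4), c(1, 2, 3, 4))
  expect_equal(m$precision, 0)  # no predicted positives
  expect_equal(m$recall, 0)
  expect_true(m$degenerate)
  expect_error(compute_metrics(y, rep("a", 3), 1:4), "equal lengths")
})

test_that("stratified k-fold splits partition deterministically", {
  y <- rep(c("x", "y"), each = 50)
  f1 <- kfold_split(100, 25, seed = 3, y = y)
  f2 <- kfold_split(100, 25, seed = 3, y = y)
  expect_length(f1, 25L)
  expect_identical(f1, f2)
  tests <- lapply(f1, `[[`, "test")
  expect_true(all(lengths(tests) == 4L))
  expect_identical(sort(unlist(tests)), 1:100)          # exact cover
  expect_equal(sum(duplicated(unlist(tests))), 0L)      # disjoint
  for (f in f1) {
    expect_identical(sort(c(f$train, f$test)), 1:100)
    expect_equal(sum(y[f$test] == "x"), 2L)             # stratification
  }
  expect_error(kfold_split(10, 11, 1), "cannot exceed")
  expect_warning(kfold_split(10, 5, 1, y = c(rep("a", 9), "b")), "fewer than k")
})

test_that("the experiment harness writes schema-complete deterministic reports", {
  dir <- tempfile("exp")
  man <- tmp_phantom_dataset(8, seed = 41, dir = dir)
  on.exit(unlink(dir, recursive = TRUE))
  out1 <- file.path(dir, "r1"); out2 <- file.path(dir, "r2")
  r1 <- run_experiment(man, "chronic", cv_folds = 4, seed = 2, out_dir = out1)
  r2 <- run_experiment(man, "chronic", cv_folds = 4, seed = 2, out_dir = out2)

  df <- r1$metrics
  expect_equal(nrow(df), 5L)  # 4 folds + mean row
  num <- as.matrix(df[, c("accuracy", "precision", "recall", "f1", "auc")])
  expect_true(all(num >= 0 & num <= 1))
  mean_row <- df[is.na(df$fold), ]
  fold_rows <- df[!is.na(df$fold), ]
  expect_equal(unlist(mean_row[, 3:7]), colMeans(fold_rows[, 3:7]),
               tolerance = 1e-12)

  expect_identical(readLines(r1$paths$metrics), readLines(r2$paths$metrics))
  expect_true(file.exists(r1$paths$timings))
})

test_that("paired raw-vs-enhanced runs emit a comparison table", {
  dir <- tempfile("exp2")
  man <- tmp_phantom_dataset(6, seed = 51, dir = dir)
  on.exit(unlink(dir, recursive = TRUE))
  r <- run_experiment(man, "chronic", spem = spem_config(), compare_enhanced = TRUE,
                      cv_folds = 3, seed = 4, out_dir = file.path(dir, "rep"))
  expect_setequal(unique(r$metrics$task),
                  c("normal_vs_chronic_raw", "normal_vs_chronic_enhanced"))
  expect_true(file.exists(r$paths$comparison))
  cmp <- utils::read.csv(r$paths$comparison)
  expect_equal(nrow(cmp), 2L)
  expect_error(run_experiment(man, "chronic", compare_enhanced = TRUE),
               "requires a spem config")
})

test_that("augmented experiments keep variants of an image in one fold", {
  dir <- tempfile("exp3")
  man <- tmp_phantom_dataset(6, seed = 61, dir = dir)
  on.exit(unlink(dir, recursive = TRUE))
  r <- run_experiment(man, "acute", cv_folds = 3, augment_data = TRUE, seed = 9,
                      out_dir = NULL)
  df <- r$metrics
  expect_equal(nrow(df), 4L)
  expect_true(all(df$accuracy >= 0 & df$accuracy <= 1))
})

test_that("five-class one-vs-rest mode reports macro metrics", {
  dir <- tempfile("exp4")
  man <- tmp_phantom_dataset(6, seed = 71, dir = dir)
  on.exit(unlink(dir, recursive = TRUE))
  r <- run_experiment(man, "all", cv_folds = 3, seed = 5, out_dir = NULL)
  expect_equal(unique(r$metrics$task), "all_raw")
  expect_true(all(r$metrics$auc >= 0 & r$metrics$auc <= 1))
})
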