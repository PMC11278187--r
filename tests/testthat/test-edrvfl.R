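make_blobs <- function(n_per, gap = 6, d = 3, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per * d, 0), n_per, d),
             matrix(rnorm(n_per * d, gap), n_per, d))
  list(x = x, y = factor(rep(c("a", "b"), each = n_per)))
}

test_that("random layers are seeded, bounded and sized by the control", {
  b <- make_blobs(20)
  f1 <- edrvfl(b$x, b$y, control = edrvfl_control(n_layers = 10), seed = 42)
  f2 <- edrvfl(b$x, b$y, control = edrvfl_control(n_layers = 10), seed = 42)
  f3 <- edrvfl(b$x, b$y, control = edrvfl_control(n_layers = 10), seed = 43)
  expect_length(f1$layers, 10L)
  expect_identical(f1$layers, f2$layers)
  expect_false(identical(f1$layers, f3$layers))
  w_all <- unlist(lapply(f1$layers, function(l) c(l$W, l$b)))
  expect_true(all(w_all >= -1 & w_all <= 1))
  expect_gt(length(w_all), 1000)  # support check over many draws
  expect_error(edrvfl(b$x, factor(rep("a", 40))), "2 classes")
})

test_that("the hidden stack reduces to direct links and matches hand algebra", {
  b <- make_blobs(10, d = 2)
  f0 <- edrvfl(b$x, b$y, control = edrvfl_control(n_nodes = 0, n_layers = 3), seed = 1)
  D <- spemRVFL:::hidden_stack(f0$layers, scale(b$x), "tanh", 0L)
  for (l in 1:3) expect_equal(unname(D[[l]]), unname(cbind(scale(b$x), 1)))

  # L = 1, 3 samples, d = 2, 2 nodes: explicit act(XW + b)
  f1 <- edrvfl(b$x, b$y, control = edrvfl_control(n_nodes = 2, n_layers = 1), seed = 5)
  Xs <- sweep(sweep(b$x, 2, f1$center, "-"), 2, f1$scale, "/")[1:3, ]
  W <- f1$layers[[1]]$W; bb <- f1$layers[[1]]$b
  H_hand <- matrix(0, 3, 2)
  for (i in 1:3) for (k in 1:2)
    H_hand[i, k] <- tanh(Xs[i, 1] * W[1, k] + Xs[i, 2] * W[2, k] + bb[k])
  D1 <- spemRVFL:::hidden_stack(f1$layers, Xs, "tanh", 2L)[[1]]
  expect_lt(max(abs(D1[, 1:2] - H_hand)), 1e-12)
  # tanh hidden activations stay in (-1, 1)
  expect_true(all(abs(D1[, 1:2]) < 1))
})

test_that("the direct-link-only model is exactly ridge regression, both conventions", {
  for (s in 1:20) {
    set.seed(400 + s)
    X <- matrix(rnorm(30), 10, 3)
    y <- factor(sample(c("u", "v", "w"), 10, replace = TRUE))
    while (nlevels(droplevels(y)) < 3) y <- factor(sample(c("u", "v", "w"), 10, replace = TRUE))
    Y <- outer(as.integer(y), 1:3, function(i, j) as.numeric(i == j))
    for (conv in c("inverse_c", "direct_lambda")) {
      C <- 100
      fit <- edrvfl(X, y, control = edrvfl_control(n_nodes = 0, n_layers = 1,
                                                   reg_c = C, ridge_convention = conv),
                    seed = s)
      Xs <- sweep(sweep(X, 2, fit$center, "-"), 2, fit$scale, "/")
      lambda <- if (conv == "inverse_c") 1 / C else C
      expect_lt(max(abs(fit$heads[[1]] - brute_ridge(Xs, Y, lambda))), 1e-8)
    }
  }
})

test_that("infinite regularization drives heads and predictions to the tie-break class", {
  b <- make_blobs(15)
  fit <- edrvfl(b$x, b$y, control = edrvfl_control(reg_c = 1e-12), seed = 3)
  expect_lt(max(abs(unlist(fit$heads))), 1e-6)
  # in the exact limit the heads vanish and every score row ties at zero;
  # realize the tie explicitly and check the deterministic tie-break
  fit$heads <- lapply(fit$heads, function(W) W * 0)
  expect_true(all(predict(fit, b$x) == "a"))
  expect_true(all(predict(fit, b$x, type = "score") == 0))
})

test_that("separable blobs are classified perfectly at the default settings", {
  b <- make_blobs(50)  # 6-sigma gap: linearly separable with margin
  fit <- edrvfl(b$x, b$y, seed = 11)
  expect_equal(mean(predict(fit, b$x) == b$y), 1.0)
  sc <- predict(fit, b$x, type = "score")
  expect_identical(colnames(sc), c("a", "b"))
  expect_true(all(is.finite(sc)))
})

test_that("fitting is invariant to row permutation and bit-stable under a seed", {
  b <- make_blobs(20)
  fit <- edrvfl(b$x, b$y, seed = 9)
  set.seed(1); perm <- sample(nrow(b$x))
  fit_p <- edrvfl(b$x[perm, ], b$y[perm], seed = 9)
  for (l in seq_along(fit$heads))
    expect_lt(max(abs(fit$heads[[l]] - fit_p$heads[[l]])), 1e-10)

  fit2 <- edrvfl(b$x, b$y, seed = 9)
  expect_identical(fit$heads, fit2$heads)
  expect_identical(predict(fit, b$x, type = "score"),
                   predict(fit2, b$x, type = "score"))
})

test_that("mean-score aggregation averages layers and stays in their envelope", {
  b <- make_blobs(10, d = 2)
  fit <- edrvfl(b$x, b$y, control = edrvfl_control(n_nodes = 2, n_layers = 2), seed = 2)
  # hand-set heads: aggregate must equal their average
  fit$heads[[1]][] <- 0; fit$heads[[1]][1, 1] <- 1
  fit$heads[[2]][] <- 0; fit$heads[[2]][1, 1] <- 3
  D <- spemRVFL:::hidden_stack(fit$layers,
                               sweep(sweep(b$x, 2, fit$center, "-"), 2, fit$scale, "/"),
                               "tanh", 2L)
  hand <- (D[[1]] %*% fit$heads[[1]] + D[[2]] %*% fit$heads[[2]]) / 2
  expect_equal(unname(predict(fit, b$x, type = "score")), unname(hand))

  per_layer <- lapply(1:2, function(l) D[[l]] %*% fit$heads[[l]])
  agg <- predict(fit, b$x, type = "score")
  expect_true(all(agg >= pmin(per_layer[[1]], per_layer[[2]]) - 1e-12))
  expect_true(all(agg <= pmax(per_layer[[1]], per_layer[[2]]) + 1e-12))
})

test_that("majority vote returns vote shares summing to one", {
  b <- make_blobs(25)
  fit <- edrvfl(b$x, b$y,
                control = edrvfl_control(aggregation = "majority_vote"), seed = 6)
  sc <- predict(fit, b$x, type = "score")
  expect_equal(unname(rowSums(sc)), rep(1, nrow(sc)))
  expect_true(all(sc >= 0 & sc <= 1))
  expect_equal(mean(predict(fit, b$x) == b$y), 1.0)
})

test_that("hidden nodes add capacity on a radially separable problem", {
  set.seed(99)
  n <- 200
  r <- c(runif(n / 2, 0, 1), runif(n / 2, 2, 3))
  th <- runif(n, 0, 2 * pi)
  x <- cbind(r * cos(th), r * sin(th))
  y <- factor(rep(c("in", "out"), each = n / 2))
  acc <- sapply(c(0L, 10L), function(nodes) {
    accs <- sapply(1:5, function(sd_) {
      folds <- kfold_split(n, 5, seed = 50 + sd_, y = y)
      mean(sapply(folds, function(f) {
        fit <- edrvfl(x[f$train, ], y[f$train],
                      control = edrvfl_control(n_nodes = nodes), seed = sd_)
        mean(predict(fit, x[f$test, ]) == y[f$test])
      }))
    })
    mean(accs)
  })
  expect_gte(acc[2], acc[1])
})

test_that("bagging subsamples rows per layer yet stays deterministic", {
  b <- make_blobs(30)
  ctl <- edrvfl_control(bagging_fraction = 0.6)
  f1 <- edrvfl(b$x, b$y, control = ctl, seed = 4)
  f2 <- edrvfl(b$x, b$y, control = ctl, seed = 4)
  expect_identical(f1$heads, f2$heads)
  full <- edrvfl(b$x, b$y, seed = 4)
  expect_false(identical(f1$heads, full$heads))
})

test_that("the formula interface mirrors the default method", {
  b <- make_blobs(15, d = 2)
  df <- data.frame(y = b$y, x1 = b$x[, 1], x2 = b$x[, 2])
  ff <- edrvfl(y ~ x1 + x2, data = df, seed = 8)
  fd <- edrvfl(b$x, b$y, seed = 8)
  expect_equal(unname(predict(ff, df, type = "score")),
               unname(predict(fd, b$x, type = "score")))
  expect_output(print(ff), "Ensemble deep RVFL")
  expect_output(print(summary(ff)), "Frobenius")
  expect_length(coef(ff), 10L)
})
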