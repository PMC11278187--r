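# Brute-force oracles, written as explicit loops so they share no code path
# with the package implementations they check.

brute_erode <- function(img, radius) {
  m <- nrow(img); n <- ncol(img)
  out <- matrix(0, m, n)
  for (i in seq_len(m)) for (j in seq_len(n)) {
    lo_i <- max(1, i - radius); hi_i <- min(m, i + radius)
    lo_j <- max(1, j - radius); hi_j <- min(n, j + radius)
    # edge replication: out-of-frame samples repeat the border pixel, so the
    # window minimum equals the in-frame window minimum
    out[i, j] <- min(img[lo_i:hi_i, lo_j:hi_j])
  }
  out
}

brute_eme <- function(img, k1, k2, eps) {
  m <- nrow(img); n <- ncol(img)
  w1 <- m %/% k1; w2 <- n %/% k2
  total <- 0
  for (i in seq_len(k1)) for (j in seq_len(k2)) {
    r0 <- (i - 1) * w1 + 1; r1 <- if (i == k1) m else i * w1
    c0 <- (j - 1) * w2 + 1; c1 <- if (j == k2) n else j * w2
    mx <- -Inf; mn <- Inf
    for (r in r0:r1) for (cc in c0:c1) {
      v <- img[r, cc]
      if (v > mx) mx <- v
      if (v < mn) mn <- v
    }
    total <- total + 20 * log10((mx + eps) / (mn + eps))
  }
  total / (k1 * k2)
}

brute_mse <- function(f, g) {
  s <- 0
  for (i in seq_len(nrow(f))) for (j in seq_len(ncol(f))) s <- s + (f[i, j] - g[i, j])^2
  s / (nrow(f) * ncol(f))
}

brute_dsc <- function(a, b) {
  inter <- 0; sa <- 0; sb <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a))) {
    if (a[i, j] == 1) sa <- sa + 1
    if (b[i, j] == 1) sb <- sb + 1
    if (a[i, j] == 1 && b[i, j] == 1) inter <- inter + 1
  }
  if (sa + sb == 0) return(1)
  2 * inter / (sa + sb)
}

# Gaussian blur + 5-point Laplacian by direct 2D convolution with replicate
# padding (independent of the package's separable implementation)
brute_log <- function(img, sigma) {
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  k1d <- exp(-((-r:r)^2) / (2 * sigma^2)); k1d <- k1d / sum(k1d)
  k2d <- outer(k1d, k1d)
  m <- nrow(img); n <- ncol(img)
  at <- function(i, j) img[min(max(i, 1), m), min(max(j, 1), n)]
  g <- matrix(0, m, n)
  for (i in seq_len(m)) for (j in seq_len(n)) {
    acc <- 0
    for (di in -r:r) for (dj in -r:r)
      acc <- acc + k2d[di + r + 1, dj + r + 1] * at(i + di, j + dj)
    g[i, j] <- acc
  }
  gat <- function(i, j) g[min(max(i, 1), m), min(max(j, 1), n)]
  out <- matrix(0, m, n)
  for (i in seq_len(m)) for (j in seq_len(n))
    out[i, j] <- gat(i - 1, j) + gat(i + 1, j) + gat(i, j - 1) + gat(i, j + 1) - 4 * g[i, j]
  out
}

# explicit regularized normal-equations ridge of one-hot Y on [X | 1]
brute_ridge <- function(X, Y, lambda) {
  D <- cbind(X, 1)
  solve(t(D) %*% D + lambda * diag(ncol(D)), t(D) %*% Y)
}

rand_img <- function(m, n, seed) {
  set.seed(seed)
  matrix(sample(0:255, m * n, replace = TRUE), m, n)
}

# small on-disk phantom dataset shared by harness tests; caller cleans up
tmp_phantom_dataset <- function(n_per_class, seed, dir = tempfile("phantoms")) {
  generate_dataset(n_per_class, phantom_config(), seed = seed, out_dir = dir)
}
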