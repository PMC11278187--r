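# Feature extraction feeding the classifier. The deep-CNN embedding stage of
# the full clinical pipeline is kept behind a contract: any object with a
# fixed output dimension and a deterministic image -> vector mapping works.
# Two implementations ship: a block-statistics extractor for desk-scale use,
# and an adapter for embeddings computed externally (e.g. by a pretrained
# DenseNet121) and stored in a CSV.

#' Block-statistics feature extractor
#'
#' Deterministic, training-free image descriptor: the image is partitioned
#' into a `grid` of blocks (last block absorbs remainder pixels, matching
#' the EME partition) and each block contributes its mean and population
#' standard deviation (divide by the block pixel count); a global
#' `hist_bins`-bin intensity histogram, normalized to sum to 1, is appended.
#' Feature dimension is `2 * grid[1] * grid[2] + hist_bins`.
#'
#' @param grid integer pair, block grid.
#' @param hist_bins number of global histogram bins over `[0, 256)`.
#' @return a `feature_extractor` object.
#' @export
block_stat_extractor <- function(grid = c(8L, 8L), hist_bins = 16L) {
  grid <- as.integer(grid); hist_bins <- as.integer(hist_bins)
  if (any(grid < 1L) || hist_bins < 1L) stopf("grid and hist_bins must be >= 1")
  dim_ <- 2L * grid[1] * grid[2] + hist_bins
  extract <- function(image) {
    check_gray(image)
    rb <- block_bounds(nrow(image), grid[1]); cb <- block_bounds(ncol(image), grid[2])
    mu <- sdv <- matrix(0, grid[1], grid[2])
    for (i in seq_len(grid[1])) for (j in seq_len(grid[2])) {
      blk <- image[rb[i]:(rb[i + 1L] - 1L), cb[j]:(cb[j + 1L] - 1L)]
      mu[i, j] <- mean(blk)
      sdv[i, j] <- sqrt(mean((blk - mu[i, j])^2))
    }
    bin <- pmin(floor(image * (hist_bins / 256)), hist_bins - 1L)
    h <- tabulate(as.vector(bin) + 1L, nbins = hist_bins)
    c(as.vector(mu), as.vector(sdv), h / sum(h))
  }
  structure(list(name = sprintf("block_stat_%dx%d_h%d", grid[1], grid[2], hist_bins),
                 kind = "image", dim = dim_, grid = grid, hist_bins = hist_bins,
                 extract = extract),
            class = "feature_extractor")
}

#' Embedding-file feature extractor
#'
#' Adapter for fixed-length embedding vectors computed outside the package
#' (for instance, activations of a pretrained CNN). The file is a CSV whose
#' first column is the sample id — an image path or its basename without
#' extension — and whose remaining columns are the vector.
#'
#' @param path embedding CSV path.
#' @return a `feature_extractor` object with `kind = "embedding"`.
#' @export
embedding_file_extractor <- function(path) {
  if (!file.exists(path)) stopf("embedding file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stopf("embedding file %s must have an id column plus vector columns", path)
  ids <- as.character(df[[1]])
  vecs <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vecs) || anyNA(vecs)) stopf("embedding vectors in %s must be numeric", path)
  rownames(vecs) <- ids
  lookup <- function(image_path) {
    stem <- tools::file_path_sans_ext(basename(image_path))
    for (key in c(image_path, basename(image_path), stem)) {
      if (key %in% ids) return(vecs[key, ])
    }
    stopf("no embedding found for sample \"%s\"", image_path)
  }
  structure(list(name = paste0("embedding:", basename(path)), kind = "embedding",
                 dim = ncol(vecs), lookup = lookup),
            class = "feature_extractor")
}

#' @export
print.feature_extractor <- function(x, ...) {
  cat(sprintf("feature extractor \"%s\" (%s), dim %d\n", x$name, x$kind, x$dim))
  invisible(x)
}

#' Build a feature matrix from manifest records
#'
#' Row i is the extractor's output for record i (order-preserving). For
#' image extractors each image is loaded and, when `enhance` is given, run
#' through [spem_enhance()] first; embedding extractors look rows up by
#' sample id and ignore `enhance`.
#'
#' @param records manifest data.frame from [read_manifest()].
#' @param extractor a `feature_extractor`.
#' @param enhance optional [spem_config()]; applied before extraction.
#' @return numeric matrix, `nrow(records)` x `extractor$dim`.
#' @export
extract_features <- function(records, extractor, enhance = NULL) {
  stopifnot(inherits(extractor, "feature_extractor"))
  out <- matrix(0, nrow(records), extractor$dim)
  for (i in seq_len(nrow(records))) {
    out[i, ] <- if (extractor$kind == "embedding") {
      extractor$lookup(records$image[i])
    } else {
      img <- load_image(records$image[i])
      if (!is.null(enhance)) img <- spem_enhance(img, enhance)$image
      extractor$extract(img)
    }
  }
  out
}

# in-memory variant used by the experiment harness (avoids PNG round-trips
# for augmented variants); images is a list of matrices
extract_features_images <- function(images, extractor, enhance = NULL) {
  out <- matrix(0, length(images), extractor$dim)
  for (i in seq_along(images)) {
    img <- images[[i]]
    if (!is.null(enhance)) img <- spem_enhance(img, enhance)$image
    out[i, ] <- extractor$extract(img)
  }
  out
}
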