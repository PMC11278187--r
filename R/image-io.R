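# Grayscale image I/O, the manifest format, and training-time augmentation.
#
# Conventions used throughout the package:
#   * images are numeric matrices, row = y, column = x, intensities on the
#     8-bit scale [0, 255], stored in double precision;
#   * pixel coordinates are 0-based; bounding boxes are half-open
#     [x_min, x_max) x [y_min, y_max);
#   * PNG is the canonical write format (lossless); JPEG is accepted on read.

STROKE_STAGES <- c("normal", "hyper_acute", "acute", "sub_acute", "chronic")

#' Admissible stroke stages
#'
#' The five stage labels used everywhere in the package, ordered from no
#' lesion to the most conspicuous CT appearance: `normal`, `hyper_acute`,
#' `acute`, `sub_acute`, `chronic`.
#'
#' @return character vector of the five stage names.
#' @export
stroke_stages <- function() STROKE_STAGES

# validate a grayscale image matrix; returns it invisibly
check_gray <- function(x, name = "image") {
  if (!is.matrix(x) || !is.numeric(x)) stopf("`%s` must be a numeric matrix", name)
  if (nrow(x) < 1L || ncol(x) < 1L) stopf("`%s` must have at least one row and column", name)
  if (anyNA(x) || any(!is.finite(x))) stopf("`%s` contains non-finite values", name)
  if (min(x) < 0 || max(x) > 255) stopf("`%s` has intensities outside [0, 255]", name)
  invisible(x)
}

#' Create a bounding box
#'
#' Boxes are 0-based and half-open: a pixel (x, y) is inside when
#' `x_min <= x < x_max` and `y_min <= y < y_max`.
#'
#' @param x_min,y_min,x_max,y_max integer pixel bounds.
#' @return a `bounding_box` object (named integer vector).
#' @export
bounding_box <- function(x_min, y_min, x_max, y_max) {
  b <- as.integer(c(x_min = x_min, y_min = y_min, x_max = x_max, y_max = y_max))
  names(b) <- c("x_min", "y_min", "x_max", "y_max")
  if (anyNA(b)) stopf("box bounds must be integers")
  if (b["x_min"] < 0L || b["y_min"] < 0L) stopf("box bounds must be non-negative")
  if (b["x_min"] >= b["x_max"] || b["y_min"] >= b["y_max"])
    stopf("box must satisfy x_min < x_max and y_min < y_max")
  class(b) <- "bounding_box"
  b
}

format_box <- function(box) paste(unclass(box), collapse = ":")

parse_box <- function(s) {
  parts <- suppressWarnings(as.integer(strsplit(s, ":", fixed = TRUE)[[1]]))
  if (length(parts) != 4L || anyNA(parts))
    stopf("box string must be \"x_min:y_min:x_max:y_max\", got \"%s\"", s)
  bounding_box(parts[1], parts[2], parts[3], parts[4])
}

# bilinear resample with pixel-center alignment; out-of-range samples clamp
# to the border (replicate padding)
resize_bilinear <- function(img, height, width) {
  m <- nrow(img); n <- ncol(img)
  if (height < 1L || width < 1L) stopf("target size must be positive")
  # source coordinates (0-based, pixel centers) of each target pixel center
  ys <- ((seq_len(height) - 0.5) * m / height) - 0.5
  xs <- ((seq_len(width) - 0.5) * n / width) - 0.5
  y0 <- clip01(floor(ys), 0, m - 1); y1 <- clip01(y0 + 1, 0, m - 1)
  x0 <- clip01(floor(xs), 0, n - 1); x1 <- clip01(x0 + 1, 0, n - 1)
  wy <- ys - floor(ys); wy[ys < 0] <- 0; wy[ys > m - 1] <- 0
  wx <- xs - floor(xs); wx[xs < 0] <- 0; wx[xs > n - 1] <- 0
  a <- img[y0 + 1, x0 + 1, drop = FALSE]
  b <- img[y0 + 1, x1 + 1, drop = FALSE]
  c_ <- img[y1 + 1, x0 + 1, drop = FALSE]
  d <- img[y1 + 1, x1 + 1, drop = FALSE]
  wym <- matrix(wy, height, width); wxm <- matrix(wx, height, width, byrow = TRUE)
  (1 - wym) * ((1 - wxm) * a + wxm * b) + wym * ((1 - wxm) * c_ + wxm * d)
}

#' Load an 8-bit grayscale image
#'
#' Reads a PNG or JPEG file as a grayscale intensity matrix on the
#' `[0, 255]` scale. Color images are converted with the ITU-R 601 luma
#' weights (0.299 R + 0.587 G + 0.114 B). When `target_size` is given the
#' image is bilinearly resampled to `target_size[1]` rows by
#' `target_size[2]` columns, then re-quantized to the 8-bit grid.
#'
#' @param path path to a `.png`, `.jpg` or `.jpeg` file.
#' @param target_size optional integer pair `c(height, width)`.
#' @return numeric matrix of intensities in `[0, 255]`.
#' @export
load_image <- function(path, target_size = NULL) {
  if (!file.exists(path)) stopf("image file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  arr <- tryCatch(
    switch(ext,
      png = png::readPNG(path),
      jpg = ,
      jpeg = jpeg::readJPEG(path),
      stopf("unsupported image format \"%s\" for %s (PNG/JPEG only)", ext, path)
    ),
    error = function(e) stopf("failed to read image %s: %s", path, conditionMessage(e))
  )
  if (length(dim(arr)) == 3L) {
    if (dim(arr)[3] >= 3L) {
      arr <- 0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    } else {
      arr <- arr[, , 1]
    }
  }
  img <- arr * 255
  if (!is.null(target_size)) {
    if (length(target_size) != 2L || any(target_size < 1))
      stopf("target_size must be two positive integers")
    img <- quantize8(resize_bilinear(img, target_size[1], target_size[2]))
  } else {
    img <- quantize8(img)
  }
  check_gray(img, path)
  img
}

#' Write an image as PNG
#'
#' Quantizes (round half away from zero, clip to `[0, 255]`) and writes an
#' 8-bit grayscale PNG. Lossless: integer-valued images round-trip exactly
#' through [load_image()].
#'
#' @param image numeric intensity matrix.
#' @param path output path, `.png`.
#' @return `path`, invisibly.
#' @export
save_image <- function(image, path) {
  check_gray(image)
  png::writePNG(quantize8(image) / 255, target = path)
  invisible(path)
}

normalize_stage <- function(s) {
  key <- gsub("[-. ]", "_", tolower(trimws(s)))
  key[key == ""] <- NA_character_
  key
}

#' Read a sample manifest
#'
#' The manifest is a UTF-8 CSV with header columns `image,stage[,mask,box]`.
#' Stage strings are matched case-insensitively with hyphens/spaces treated
#' as underscores (so `"Hyper-Acute"` maps to `hyper_acute`). The `box`
#' column, when present, holds `"x_min:y_min:x_max:y_max"` (0-based,
#' half-open). Relative image/mask paths are resolved against the manifest's
#' directory. Row order is preserved.
#'
#' @param path manifest CSV path.
#' @return data.frame with columns `image` (character), `stage` (factor over
#'   [stroke_stages()]), `mask` (character or `NA`), `box` (list of
#'   `bounding_box` or `NULL`).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stopf("manifest not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("image", "stage") %in% names(df)))
    stopf("manifest %s must have columns image,stage", path)
  base <- dirname(path)
  resolve <- function(p) ifelse(is.na(p) | p == "" | grepl("^(/|[A-Za-z]:)", p),
                                p, file.path(base, p))
  stage_key <- normalize_stage(df$stage)
  bad <- which(!(stage_key %in% STROKE_STAGES))
  if (length(bad))
    stopf("manifest %s row %d: unknown stage \"%s\"", path, bad[1], df$stage[bad[1]])
  out <- data.frame(
    image = resolve(df$image),
    stage = factor(stage_key, levels = STROKE_STAGES),
    mask = if ("mask" %in% names(df)) {
      m <- df$mask; m[m == ""] <- NA_character_; resolve(m)
    } else NA_character_,
    stringsAsFactors = FALSE
  )
  out$box <- if ("box" %in% names(df)) {
    lapply(df$box, function(s) if (is.na(s) || s == "") NULL else parse_box(s))
  } else {
    rep(list(NULL), nrow(out))
  }
  out
}

#' Write a sample manifest
#'
#' Inverse of [read_manifest()]; paths are written as given.
#'
#' @param records manifest data.frame (columns `image`, `stage`, optionally
#'   `mask` and `box`).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(records, path) {
  df <- data.frame(
    image = records$image,
    stage = as.character(records$stage),
    mask = if ("mask" %in% names(records)) ifelse(is.na(records$mask), "", records$mask) else "",
    box = if ("box" %in% names(records))
      vapply(records$box, function(b) if (is.null(b)) "" else format_box(b), "")
    else "",
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# reflect 0-based indices into [0, n-1] ("mirror without repeating the edge
# sample twice at the fold")
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(0L, length(i)))
  p <- 2L * (n - 1L)
  i <- ((i %% p) + p) %% p
  ifelse(i >= n, p - i, i)
}

# rotate about the image center by `angle` degrees (counter-clockwise),
# bilinear interpolation, reflective padding outside the frame
rotate_reflect <- function(img, angle) {
  m <- nrow(img); n <- ncol(img)
  th <- angle * pi / 180
  cy <- (m - 1) / 2; cx <- (n - 1) / 2
  yy <- matrix(seq_len(m) - 1, m, n) - cy
  xx <- matrix(seq_len(n) - 1, m, n, byrow = TRUE) - cx
  # inverse mapping: source coords of each target pixel
  sx <- cos(th) * xx + sin(th) * yy + cx
  sy <- -sin(th) * xx + cos(th) * yy + cy
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  gather <- function(yi, xi) {
    img[cbind(reflect_index(as.vector(yi), m) + 1L,
              reflect_index(as.vector(xi), n) + 1L)]
  }
  v <- (1 - fy) * ((1 - fx) * gather(y0, x0) + fx * gather(y0, x0 + 1)) +
    fy * ((1 - fx) * gather(y0 + 1, x0) + fx * gather(y0 + 1, x0 + 1))
  matrix(v, m, n)
}

#' Four-fold training augmentation
#'
#' Expands one image into the four variants used to quadruple a training
#' set: the original, a horizontal (left-right) flip, a rotation by an angle
#' drawn uniformly from \[-15, +15\] degrees with reflective padding, and a
#' random crop covering 85--100\% of the area resampled back to the original
#' size. Deterministic for a given `seed`.
#'
#' @param image grayscale intensity matrix.
#' @param seed integer seed driving the random rotation angle and crop.
#' @return list of 4 matrices, each the shape of `image`.
#' @export
augment <- function(image, seed) {
  check_gray(image)
  m <- nrow(image); n <- ncol(image)
  with_seed(seed, {
    angle <- stats::runif(1, -15, 15)
    area <- stats::runif(1, 0.85, 1)
    side <- sqrt(area)
    ch <- max(1L, as.integer(round(m * side)))
    cw <- max(1L, as.integer(round(n * side)))
    y0 <- if (m > ch) sample.int(m - ch + 1L, 1L) else 1L
    x0 <- if (n > cw) sample.int(n - cw + 1L, 1L) else 1L
    rot <- clip01(rotate_reflect(image, angle))
    crop <- clip01(resize_bilinear(image[y0:(y0 + ch - 1L), x0:(x0 + cw - 1L), drop = FALSE], m, n))
    list(original = image,
         flip = image[, n:1, drop = FALSE],
         rotate = rot,
         crop = crop)
  })
}
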