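# Dice-scored, box-guided lesion segmentation evaluation. Detection and
# foundation-model segmentation stay external: boxes come from the manifest
# (ground truth or an external detector's output) and any object honouring
# the segmenter contract can be evaluated. A classical Otsu-threshold
# reference segmenter makes the harness testable offline.

check_mask <- function(x, name = "mask") {
  if (!is.matrix(x) || !is.numeric(x)) stopf("`%s` must be a numeric matrix", name)
  if (!all(x %in% c(0, 1))) stopf("`%s` must be strictly binary (0/1)", name)
  invisible(x)
}

#' Dice similarity coefficient
#'
#' `DSC = 2 |A intersect B| / (|A| + |B|)`, the standard spatial-overlap
#' score between two binary masks: 1 is perfect overlap, 0 is none. When
#' both masks are empty the score is `both_empty` (default 1: agreement on
#' the absence of a lesion counts as correct; set 0 for strict
#' benchmarking).
#'
#' @param a,b binary (0/1) matrices of identical shape.
#' @param both_empty value returned when both masks are empty.
#' @return dice value in `[0, 1]`.
#' @export
dsc <- function(a, b, both_empty = 1.0) {
  check_mask(a, "a"); check_mask(b, "b")
  if (!identical(dim(a), dim(b))) stopf("masks must have identical shapes")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(both_empty)
  2 * sum(a * b) / (sa + sb)
}

#' Create a segmenter
#'
#' Wraps a `(image, box) -> binary mask` function in the segmenter contract
#' used by [evaluate_segmentation()]. The returned mask must be empty
#' outside the box.
#'
#' @param name identifier used in reports.
#' @param segment function of `(image, box)` returning a 0/1 matrix the
#'   shape of `image`.
#' @return a `segmenter` object.
#' @export
segmenter <- function(name, segment) {
  stopifnot(is.function(segment))
  structure(list(name = name, segment = segment), class = "segmenter")
}

#' Otsu box-guided reference segmenter
#'
#' Classical stand-in for a promptable foundation segmenter: the Otsu
#' threshold is computed from the intensities inside the box only (256
#' levels, so surrounding skull intensities cannot skew it), the side of
#' the threshold matching `polarity` is kept (`hypodense` = below, the
#' ischemic-CT appearance; `hyperdense` = above), and only the largest
#' 4-connected component is retained. Pixels outside the box are never
#' marked. A degenerate box (single intensity) yields an empty mask with a
#' warning.
#'
#' @param image intensity matrix.
#' @param box a [bounding_box()] lying within the image.
#' @param polarity `"hypodense"` or `"hyperdense"`.
#' @return binary matrix the shape of `image`.
#' @export
otsu_box_segment <- function(image, box, polarity = c("hypodense", "hyperdense")) {
  check_gray(image)
  polarity <- match.arg(polarity)
  m <- nrow(image); n <- ncol(image)
  if (box["x_max"] > n || box["y_max"] > m) stopf("box exceeds image bounds")
  rows <- (box["y_min"] + 1L):box["y_max"]
  cols <- (box["x_min"] + 1L):box["x_max"]
  roi <- image[rows, cols, drop = FALSE]
  mask <- matrix(0, m, n)
  if (max(roi) == min(roi)) {
    warning("degenerate box (single intensity); returning empty mask")
    return(mask)
  }
  thr <- EBImage::otsu(EBImage::Image(roi / 255), range = c(0, 1), levels = 256) * 255
  keep <- if (polarity == "hypodense") roi <= thr else roi > thr
  lab <- EBImage::bwlabel(EBImage::Image(keep * 1))
  lab <- EBImage::imageData(lab)
  if (max(lab) >= 1) {
    counts <- tabulate(lab[lab > 0], nbins = max(lab))
    keep <- lab == which.max(counts)
  }
  mask[rows, cols] <- keep * 1
  mask
}

#' Evaluate a segmenter over a dataset
#'
#' Runs `segmenter` on every record's image, prompted by the record's box,
#' and scores each prediction against the ground-truth mask with [dsc()].
#' When `enhance` is given the segmenter is additionally run on
#' SPEM-enhanced images, and both scores are reported side by side.
#'
#' @param records manifest data.frame; every row must have `mask` and `box`.
#' @param segmenter a [segmenter()]; its `segment` function receives
#'   `(image, box)`.
#' @param enhance optional [spem_config()] for the paired enhanced run.
#' @param both_empty passed to [dsc()].
#' @return a `dsc_result` list: `per_sample` (data.frame: image, stage,
#'   dice_raw[, dice_enhanced]) and `per_stage` (data.frame of stage
#'   means).
#' @export
evaluate_segmentation <- function(records, segmenter, enhance = NULL,
                                  both_empty = 1.0) {
  stopifnot(inherits(segmenter, "segmenter"))
  miss <- which(is.na(records$mask) |
                  vapply(records$box, is.null, TRUE))
  if (length(miss))
    stopf("record %d (%s) lacks a mask or box", miss[1], records$image[miss[1]])
  n <- nrow(records)
  dice_raw <- dice_enh <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    img <- load_image(records$image[i])
    truth <- load_image(records$mask[i])
    truth <- (truth > 0) * 1
    box <- records$box[[i]]
    dice_raw[i] <- dsc(segmenter$segment(img, box), truth, both_empty)
    if (!is.null(enhance)) {
      enh <- spem_enhance(img, enhance)$image
      dice_enh[i] <- dsc(segmenter$segment(enh, box), truth, both_empty)
    }
  }
  per_sample <- data.frame(image = records$image,
                           stage = as.character(records$stage),
                           dice_raw = dice_raw,
                           stringsAsFactors = FALSE)
  if (!is.null(enhance)) per_sample$dice_enhanced <- dice_enh
  agg <- stats::aggregate(dice_raw ~ stage, per_sample, mean)
  names(agg)[2] <- "dice_raw"
  if (!is.null(enhance)) {
    agg2 <- stats::aggregate(dice_enhanced ~ stage, per_sample, mean)
    agg <- merge(agg, agg2, by = "stage", sort = FALSE)
  }
  structure(list(per_sample = per_sample, per_stage = agg,
                 segmenter = segmenter$name),
            class = "dsc_result")
}

#' @export
print.dsc_result <- function(x, ...) {
  cat(sprintf("Segmentation evaluation (%s), %d samples\n",
              x$segmenter, nrow(x$per_sample)))
  print(x$per_stage, row.names = FALSE)
  invisible(x)
}
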