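# Seeded synthetic brain-CT phantom generator. Each phantom is a window-
# rendered-looking 8-bit slice: bright elliptical skull ring, noisy
# parenchyma interior, a dark ventricle pair, and (for non-normal stages) a
# hypodense elliptical lesion whose contrast and boundary sharpness depend
# on the stroke stage — hyper-acute lesions are faint and blurry, chronic
# lesions deep and well demarcated, reproducing the clinical difficulty
# ordering without claiming anatomical realism.

#' Phantom generator configuration
#'
#' Stage parameters give each stroke stage its CT conspicuity:
#' `lesion_delta` is the additive intensity offset of the lesion core
#' (negative = hypodense, the ischemic appearance) and `boundary_sigma` the
#' Gaussian blur of the lesion boundary in pixels. Defaults:
#' hyper-acute (-6, 4), acute (-15, 3), sub-acute (-25, 2), chronic
#' (-40, 1).
#'
#' @param size image side in pixels (square); 128 for desk-scale work, 640
#'   to mimic full-size inputs.
#' @param skull_intensity skull ring intensity.
#' @param skull_thickness ring thickness in pixels; default scales with
#'   `size`.
#' @param parenchyma_mean,parenchyma_noise_sd brain-tissue intensity mean
#'   and Gaussian noise SD.
#' @param ventricle_intensity intensity of the dark ventricle pair.
#' @param radius_range lesion semi-axis range in pixels; default scales
#'   with `size`.
#' @param stage_params named list over the four stroke stages; each element
#'   a list with `lesion_delta` and `boundary_sigma`.
#' @return a `phantom_config` list.
#' @export
phantom_config <- function(size = 128L, skull_intensity = 230,
                           skull_thickness = NULL, parenchyma_mean = 100,
                           parenchyma_noise_sd = 8, ventricle_intensity = 40,
                           radius_range = NULL,
                           stage_params = list(
                             hyper_acute = list(lesion_delta = -6, boundary_sigma = 4),
                             acute = list(lesion_delta = -15, boundary_sigma = 3),
                             sub_acute = list(lesion_delta = -25, boundary_sigma = 2),
                             chronic = list(lesion_delta = -40, boundary_sigma = 1))) {
  size <- as.integer(size)
  if (size < 32L) stopf("size must be >= 32")
  if (is.null(skull_thickness)) skull_thickness <- max(2L, round(size / 32))
  if (is.null(radius_range)) radius_range <- round(size * c(0.08, 0.15))
  need <- setdiff(STROKE_STAGES, "normal")
  if (!all(need %in% names(stage_params)))
    stopf("stage_params must cover %s", paste(need, collapse = ", "))
  structure(list(size = size, skull_intensity = skull_intensity,
                 skull_thickness = skull_thickness,
                 parenchyma_mean = parenchyma_mean,
                 parenchyma_noise_sd = parenchyma_noise_sd,
                 ventricle_intensity = ventricle_intensity,
                 radius_range = radius_range, stage_params = stage_params),
            class = "phantom_config")
}

# squared normalized elliptical distance grid: <= 1 inside the ellipse
ellipse_dist2 <- function(size, cx, cy, rx, ry) {
  x <- matrix(seq_len(size) - 1, size, size, byrow = TRUE)
  y <- matrix(seq_len(size) - 1, size, size)
  ((x - cx) / rx)^2 + ((y - cy) / ry)^2
}

#' Generate one phantom sample
#'
#' Deterministic given `seed`. The lesion is an ellipse with semi-axes drawn
#' from `cfg$radius_range` at a random interior position; its indicator
#' field is blurred by the stage's `boundary_sigma`, scaled by
#' `lesion_delta` and added to the noise-free base image before parenchymal
#' noise. The ground-truth mask is the half-peak contour of the pre-noise
#' lesion field, so it does not depend on the noise draw. If the lesion
#' cannot be placed inside the brain, the radius shrinks and placement is
#' retried (up to 10 attempts).
#'
#' @param stage one of [stroke_stages()].
#' @param cfg a [phantom_config()].
#' @param seed integer seed.
#' @return list with `image` (intensity matrix), `stage`, `mask` (binary
#'   matrix, all-zero for normal), `box` ([bounding_box()] or `NULL` for
#'   normal).
#' @export
generate_phantom <- function(stage, cfg = phantom_config(), seed = 1L) {
  stage <- match.arg(stage, STROKE_STAGES)
  s <- cfg$size
  ctr <- (s - 1) / 2
  brain_rx <- 0.40 * s; brain_ry <- 0.45 * s
  skull_rx <- brain_rx + cfg$skull_thickness
  skull_ry <- brain_ry + cfg$skull_thickness

  d_brain <- ellipse_dist2(s, ctr, ctr, brain_rx, brain_ry)
  d_skull <- ellipse_dist2(s, ctr, ctr, skull_rx, skull_ry)
  inside <- d_brain <= 1
  skull <- (d_skull <= 1) & !inside

  base <- matrix(20, s, s)                 # air/background
  base[skull] <- cfg$skull_intensity
  base[inside] <- cfg$parenchyma_mean
  # ventricle pair: two slim dark ellipses flanking the midline
  voff <- 0.10 * s
  vent <- matrix(FALSE, s, s)
  for (sgn in c(-1, 1)) {
    v <- ellipse_dist2(s, ctr + sgn * voff, ctr - 0.04 * s,
                       0.05 * s, 0.14 * s) <= 1
    vent <- vent | (v & inside)
  }
  base[vent] <- cfg$ventricle_intensity

  with_seed(seed, {
    mask <- matrix(0, s, s)
    box <- NULL
    img <- base
    if (stage != "normal") {
      pars <- cfg$stage_params[[stage]]
      rr <- cfg$radius_range
      placed <- FALSE
      # radius shrinks only when the lesion cannot geometrically fit; a
      # placement clash (ventricle overlap, leakage) resamples the position
      # at the same radius so realized sizes stay true to radius_range
      for (attempt in seq_len(10L)) {
        shrink <- 0.75^(attempt - 1)
        rx <- stats::runif(1, rr[1], rr[2]) * shrink
        ry <- stats::runif(1, rr[1], rr[2]) * shrink
        # the mask is the half-peak contour, which tracks the sharp ellipse
        # boundary; one sigma of slack keeps it inside the brain
        margin <- pars$boundary_sigma
        # admissible center region: lesion extent + blur must stay inside
        ax <- brain_rx - (rx + margin + cfg$skull_thickness)
        ay <- brain_ry - (ry + margin + cfg$skull_thickness)
        if (ax <= 0 || ay <= 0) next
        for (try in seq_len(20L)) {
          u <- stats::runif(1); th <- stats::runif(1, 0, 2 * pi)
          cx <- ctr + sqrt(u) * ax * cos(th)
          cy <- ctr + sqrt(u) * ay * sin(th)
          field <- 1 * (ellipse_dist2(s, cx, cy, rx, ry) <= 1)
          if (sum(field) < 4) next
          field <- gaussian_blur(field, pars$boundary_sigma)
          mask <- 1 * (field >= max(field) / 2)
          if (any(mask & !inside)) next   # blurred lesion leaked outside
          if (any(mask & vent)) next      # lesions are parenchymal: keep off ventricles
          img <- img + pars$lesion_delta * field
          placed <- TRUE
          break
        }
        if (placed) break
      }
      if (!placed) stopf("could not place a lesion after 10 attempts")
      ys <- which(rowSums(mask) > 0); xs <- which(colSums(mask) > 0)
      box <- bounding_box(min(xs) - 1L, min(ys) - 1L, max(xs), max(ys))
    }
    noise <- matrix(stats::rnorm(s * s, 0, cfg$parenchyma_noise_sd), s, s)
    img[inside] <- img[inside] + noise[inside]
    img <- clip01(img)
    list(image = img, stage = stage, mask = mask, box = box)
  })
}

#' Generate a phantom dataset on disk
#'
#' Writes `n_per_class` samples for each of the five stages as PNG images
#' (plus lesion-mask PNGs and bounding boxes for non-normal stages) and a
#' manifest CSV consumable by [read_manifest()]. File naming is
#' `stage_index.png` / `stage_index_mask.png`. Byte-identical across runs
#' with the same seed.
#'
#' @param n_per_class samples per stage.
#' @param cfg a [phantom_config()].
#' @param seed integer master seed; each sample derives its own child seed.
#' @param out_dir output directory (created if missing).
#' @return path to the written `manifest.csv`, invisibly.
#' @export
generate_dataset <- function(n_per_class, cfg = phantom_config(), seed = 1L,
                             out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  rows <- list()
  for (si in seq_along(STROKE_STAGES)) {
    stage <- STROKE_STAGES[si]
    for (i in seq_len(n_per_class)) {
      ph <- generate_phantom(stage, cfg, child_seed(seed, si * 100000L + i))
      img_name <- sprintf("%s_%03d.png", stage, i)
      save_image(ph$image, file.path(out_dir, img_name))
      mask_name <- ""
      if (stage != "normal") {
        mask_name <- sprintf("%s_%03d_mask.png", stage, i)
        png::writePNG(ph$mask, target = file.path(out_dir, mask_name))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        image = img_name, stage = stage, mask = mask_name,
        box = if (is.null(ph$box)) "" else format_box(ph$box),
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  manifest <- file.path(out_dir, "manifest.csv")
  utils::write.csv(df, manifest, row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

# in-memory dataset used by tests and the experiment harness when no file
# round-trip is needed; returns list(images, stages, masks, boxes)
generate_phantoms <- function(n_per_class, stages = STROKE_STAGES,
                              cfg = phantom_config(), seed = 1L) {
  images <- list(); stage_out <- character(0); masks <- list(); boxes <- list()
  for (si in seq_along(STROKE_STAGES)) {
    stage <- STROKE_STAGES[si]
    if (!(stage %in% stages)) next
    for (i in seq_len(n_per_class)) {
      ph <- generate_phantom(stage, cfg, child_seed(seed, si * 100000L + i))
      images[[length(images) + 1L]] <- ph$image
      masks[[length(masks) + 1L]] <- ph$mask
      boxes[[length(boxes) + 1L]] <- ph$box
      stage_out <- c(stage_out, stage)
    }
  }
  list(images = images, stages = factor(stage_out, levels = STROKE_STAGES),
       masks = masks, boxes = boxes)
}
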