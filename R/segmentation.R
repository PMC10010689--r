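#' Segmentation parameters
#'
#' Parameter set for the automatic blob-segmentation procedure. The outlier
#' removal radius/threshold, the blur sigma and the minimum object area follow
#' the published Fiji procedure; the background coefficient is the one free
#' parameter of the method (the multiplier applied to the mean background
#' level to obtain the binarisation threshold) and is always logged with the
#' results.
#'
#' @param outlier_radius_px disc radius (pixels) for bright-outlier removal.
#' @param outlier_threshold minimum excess over the local disc median for a
#'   pixel to be replaced (intensity units; the procedure is therefore not
#'   invariant to intensity rescaling).
#' @param gaussian_sigma_px Gaussian blur sigma, in pixels.
#' @param background_coefficient multiplier of the mean background intensity
#'   defining the binarisation threshold.
#' @param min_area_um2 objects with area strictly below this are discarded;
#'   equality survives.
#' @param connectivity 8 (default) or 4 connected components.
#' @param keep_border_objects keep objects touching the ROI border (default
#'   TRUE: density is the headline metric and exclusion would bias counts).
#' @return a `segmentation_params` list.
#' @export
segmentation_params <- function(outlier_radius_px = 30L,
                                outlier_threshold = 30,
                                gaussian_sigma_px = 1,
                                background_coefficient = 2.0,
                                min_area_um2 = 0.15,
                                connectivity = 8L,
                                keep_border_objects = TRUE) {
  stopifnot(outlier_radius_px >= 1, outlier_threshold >= 0,
            gaussian_sigma_px > 0, background_coefficient > 0,
            min_area_um2 > 0, connectivity %in% c(4L, 8L))
  structure(list(outlier_radius_px = as.integer(outlier_radius_px),
                 outlier_threshold = outlier_threshold,
                 gaussian_sigma_px = gaussian_sigma_px,
                 background_coefficient = background_coefficient,
                 min_area_um2 = min_area_um2,
                 connectivity = as.integer(connectivity),
                 keep_border_objects = isTRUE(keep_border_objects)),
            class = "segmentation_params")
}

#' Remove bright outliers by conditional disc-median filtering
#'
#' Replaces a pixel by the median of the disc of radius `radius_px` centred on
#' it when (and only when) the pixel exceeds that median by more than
#' `threshold`. Bright structures much smaller than the disc are flattened to
#' the local background level while everything else is left untouched, so the
#' output serves as the background image of the pipeline.
#'
#' @param img an `intensity_image`.
#' @param radius_px disc radius in pixels (>= 1, smaller than the image).
#' @param threshold replacement margin in intensity units (>= 0).
#' @return an `intensity_image` of identical geometry.
#' @export
remove_bright_outliers <- function(img, radius_px = 30L, threshold = 30) {
  stopifnot(inherits(img, "intensity_image"))
  if (radius_px < 1) stop("`radius_px` must be >= 1")
  if (threshold < 0) stop("`threshold` must be >= 0")
  if (radius_px >= nrow(img$values) && radius_px >= ncol(img$values)) {
    stop("`radius_px` exceeds the image extent")
  }
  out <- remove_outliers_disc_cpp(img$values, as.integer(radius_px), threshold)
  intensity_image(out, img$pixel_size_um, img$bit_depth)
}

#' Foreground image by clamped subtraction
#'
#' `max(raw - background, 0)` pixelwise: isolates the organelle signal from
#' the background image produced by [remove_bright_outliers()].
#'
#' @param raw,background congruent `intensity_image`s.
#' @return an `intensity_image`.
#' @export
foreground_image <- function(raw, background) {
  stopifnot(inherits(raw, "intensity_image"), inherits(background, "intensity_image"))
  check_congruent(raw$values, background$values)
  intensity_image(pmax(raw$values - background$values, 0),
                  raw$pixel_size_um, raw$bit_depth)
}

# Discrete Gaussian kernel, radius 3*sigma (at least 1), normalised to sum 1.
gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  x <- (-r):r
  w <- exp(-x^2 / (2 * sigma^2))
  w / sum(w)
}

# Reflective (mirror-at-edge) padding along both axes, then separable
# convolution by row and column passes.
convolve_separable_reflect <- function(m, w) {
  r <- (length(w) - 1L) %/% 2L
  reflect_idx <- function(n) {
    idx <- c(rev(seq_len(min(r, n))), seq_len(n), n + 1 - seq_len(min(r, n)))
    # if r >= n the reflection above is short; clamp by recycling edge
    if (length(idx) < n + 2 * r) {
      pre <- rep(1L, n + 2L * r)
      pre[(r + 1):(r + n)] <- seq_len(n)
      for (k in seq_len(r)) {
        pre[r + 1 - k] <- min(n, k + 1L)
        pre[r + n + k] <- max(1L, n - k)
      }
      idx <- pre
    }
    idx
  }
  # rows pass
  ridx <- reflect_idx(nrow(m))
  padded <- m[ridx, , drop = FALSE]
  out <- matrix(0, nrow(m), ncol(m))
  for (k in seq_along(w)) {
    out <- out + w[k] * padded[(k - 1) + seq_len(nrow(m)), , drop = FALSE]
  }
  # columns pass
  cidx <- reflect_idx(ncol(out))
  padded <- out[, cidx, drop = FALSE]
  res <- matrix(0, nrow(m), ncol(m))
  for (k in seq_along(w)) {
    res <- res + w[k] * padded[, (k - 1) + seq_len(ncol(m)), drop = FALSE]
  }
  res
}

#' Gaussian smoothing
#'
#' Linear separable Gaussian convolution with reflective boundary handling;
#' total intensity is conserved up to boundary effects.
#'
#' @param img an `intensity_image`.
#' @param sigma_px Gaussian sigma in pixels (> 0).
#' @return an `intensity_image`.
#' @export
gaussian_smooth <- function(img, sigma_px = 1) {
  stopifnot(inherits(img, "intensity_image"))
  if (sigma_px <= 0) stop("`sigma_px` must be > 0")
  w <- gaussian_kernel_1d(sigma_px)
  intensity_image(pmax(convolve_separable_reflect(img$values, w), 0),
                  img$pixel_size_um, img$bit_depth)
}

#' Binarisation threshold from the background level
#'
#' The segmentation threshold is the mean background intensity multiplied by a
#' constant coefficient; this normalises the segmentation across animals with
#' different expression levels. A zero background mean makes the
#' normalisation degenerate: a warning is raised and the result flagged.
#'
#' @param background_mean mean intensity of the background image (>= 0),
#'   conventionally computed over ROI pixels only.
#' @param coefficient positive multiplier.
#' @return threshold value with attribute `degenerate` (TRUE when the
#'   background mean was 0).
#' @export
compute_threshold <- function(background_mean, coefficient) {
  if (background_mean < 0) stop("`background_mean` must be >= 0")
  if (coefficient <= 0) stop("`coefficient` must be > 0")
  degenerate <- background_mean == 0
  if (degenerate) {
    warning("background mean is 0: threshold degenerates to 0")
  }
  structure(background_mean * coefficient, degenerate = degenerate)
}

#' Maximum-caliper (Feret's) diameter of a pixel set
#'
#' Longest axis of an object, computed as the maximum pairwise distance over
#' the convex hull of the pixel *corner* points (outline convention): a single
#' pixel of side s has Feret diameter s * sqrt(2), never 0.
#'
#' @param object_pixels two-column matrix of 1-based (row, col) pixel indices.
#' @param pixel_size_um pixel size in micrometres.
#' @return Feret's diameter in micrometres.
#' @export
feret_diameter <- function(object_pixels, pixel_size_um) {
  if (is.null(dim(object_pixels))) object_pixels <- matrix(object_pixels, ncol = 2)
  if (nrow(object_pixels) == 0) stop("empty pixel set")
  if (pixel_size_um <= 0) stop("`pixel_size_um` must be positive")
  r <- object_pixels[, 1]; c <- object_pixels[, 2]
  # 4 corners per pixel on the 0-based integer grid
  x <- c(c - 1, c, c - 1, c)
  y <- c(r - 1, r - 1, r, r)
  pts <- unique(cbind(x, y))
  hull <- pts[grDevices::chull(pts[, 1], pts[, 2]), , drop = FALSE]
  d2max <- 0
  n <- nrow(hull)
  for (i in seq_len(n)) {
    dx <- hull[, 1] - hull[i, 1]
    dy <- hull[, 2] - hull[i, 2]
    d2max <- max(d2max, max(dx * dx + dy * dy))
  }
  sqrt(d2max) * pixel_size_um
}

# Per-object morphometrics from a label image: area (pixel count x ps^2),
# Feret diameter, centroid of pixel centres in physical coordinates.
blob_table_from_labels <- function(label_image, pixel_size_um) {
  labs <- sort(unique(label_image[label_image > 0]))
  n <- length(labs)
  tab <- data.frame(label = integer(n), area_um2 = numeric(n),
                    feret_um = numeric(n), centroid_x_um = numeric(n),
                    centroid_y_um = numeric(n))
  ps <- pixel_size_um
  for (i in seq_len(n)) {
    px <- which(label_image == labs[i], arr.ind = TRUE)
    tab$label[i] <- labs[i]
    tab$area_um2[i] <- nrow(px) * ps^2
    tab$feret_um[i] <- feret_diameter(px, ps)
    tab$centroid_x_um[i] <- mean(px[, 2] - 0.5) * ps
    tab$centroid_y_um[i] <- mean(px[, 1] - 0.5) * ps
  }
  tab
}

#' Segment blobs by thresholding and connected components
#'
#' Pixels above `threshold` inside the ROI form the foreground mask;
#' components are labelled (8-connected by default) and those with area
#' strictly below `min_area_um2` are removed. Surviving labels are renumbered
#' consecutively in scan order.
#'
#' @param foreground_blurred the blurred foreground `intensity_image`.
#' @param threshold binarisation threshold (>= 0).
#' @param roi an `roi_mask` congruent with the image.
#' @param params a [segmentation_params()] object (area filter, connectivity,
#'   border policy).
#' @return list with `label_image` (integer matrix) and `blobs` (data frame:
#'   label, area_um2, feret_um, centroid_x_um, centroid_y_um).
#' @export
segment_blobs <- function(foreground_blurred, threshold, roi,
                          params = segmentation_params()) {
  stopifnot(inherits(foreground_blurred, "intensity_image"),
            inherits(roi, "roi_mask"))
  if (threshold < 0) stop("`threshold` must be >= 0")
  check_congruent(foreground_blurred$values, roi$mask, "image and ROI")
  ps <- foreground_blurred$pixel_size_um
  mask <- (foreground_blurred$values > threshold) & roi$mask
  lab <- if (params$connectivity == 8L) {
    label_components_cpp(mask)
  } else {
    label_components4(mask)
  }
  if (!params$keep_border_objects) {
    border <- border_labels(lab, roi$mask)
    lab[lab %in% border] <- 0L
  }
  # strict-< area filter; equality survives
  min_px <- params$min_area_um2 / ps^2
  counts <- tabulate(lab[lab > 0])
  drop <- which(counts < min_px - 1e-9)
  if (length(drop)) lab[lab %in% drop] <- 0L
  # consecutive relabel in first-encounter (column-major) order
  old <- unique(lab[lab > 0])
  old <- old[order(match(old, lab))]
  relab <- integer(max(lab, 1L))
  relab[old] <- seq_along(old)
  lab[lab > 0] <- relab[lab[lab > 0]]
  list(label_image = lab, blobs = blob_table_from_labels(lab, ps))
}

# 4-connected labelling fallback in plain R (small images / comparison).
label_components4 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (c0 in seq_len(nc)) for (r0 in seq_len(nr)) {
    if (!mask[r0, c0] || lab[r0, c0] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(r0, c0)); lab[r0, c0] <- nxt
    while (length(queue)) {
      p <- queue[[length(queue)]]; queue[[length(queue)]] <- NULL
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        rr <- p[1] + d[1]; cc <- p[2] + d[2]
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
            mask[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- nxt
          queue[[length(queue) + 1L]] <- c(rr, cc)
        }
      }
    }
  }
  lab
}

border_labels <- function(lab, roi) {
  inner <- roi
  inner[] <- FALSE
  nr <- nrow(roi); nc <- ncol(roi)
  inner[2:(nr - 1), 2:(nc - 1)] <-
    roi[1:(nr - 2), 2:(nc - 1)] & roi[3:nr, 2:(nc - 1)] &
    roi[2:(nr - 1), 1:(nc - 2)] & roi[2:(nr - 1), 3:nc]
  unique(lab[lab > 0 & !inner])
}

#' Summarise per-image morphometry
#'
#' Aggregates a blob table into the three per-image readouts: mean object
#' area, mean Feret's diameter and object density (count per square
#' micrometre of ROI). With zero objects the means are undefined: they are
#' returned as `NA` with `defined = FALSE`, never silently as NaN.
#'
#' @param blobs blob table from [segment_blobs()].
#' @param roi_area_um2 ROI area in square micrometres (> 0).
#' @return a `morpho_summary` list: `n_objects`, `mean_area_um2`,
#'   `mean_feret_um`, `density_per_um2`, `roi_area_um2`, `defined`.
#' @export
summarize_morphometry <- function(blobs, roi_area_um2) {
  if (roi_area_um2 <= 0) stop("`roi_area_um2` must be > 0")
  n <- nrow(blobs)
  structure(list(
    n_objects = n,
    mean_area_um2 = if (n > 0) mean(blobs$area_um2) else NA_real_,
    mean_feret_um = if (n > 0) mean(blobs$feret_um) else NA_real_,
    density_per_um2 = n / roi_area_um2,
    roi_area_um2 = roi_area_um2,
    defined = n > 0
  ), class = "morpho_summary")
}

#' @export
print.morpho_summary <- function(x, ...) {
  cat(sprintf(
    "<morpho_summary> n = %d over %.1f um2 ROI | density %.4f /um2 | mean area %s um2 | mean Feret %s um\n",
    x$n_objects, x$roi_area_um2, x$density_per_um2,
    if (x$defined) sprintf("%.3f", x$mean_area_um2) else "NA",
    if (x$defined) sprintf("%.3f", x$mean_feret_um) else "NA"))
  invisible(x)
}

#' Run the full segmentation pipeline on one image
#'
#' Composes the stages in order: bright-outlier removal (background image),
#' clamped subtraction (foreground image), Gaussian blur, background-mean x
#' coefficient thresholding, connected-component labelling with the minimum
#' area filter, and morphometric summary. The background mean is computed
#' over ROI pixels only. The resolved parameters, threshold and background
#' mean are returned with the results so every run is auditable.
#'
#' @param raw an `intensity_image`.
#' @param roi an `roi_mask`; defaults to the full image.
#' @param params a [segmentation_params()] object.
#' @param keep_intermediates also return the background, foreground and
#'   blurred images.
#' @return a `blob_pipeline_result` list: `label_image`, `blobs`, `summary`,
#'   `threshold`, `background_mean`, `params`, and optionally
#'   `intermediates`.
#' @export
run_pipeline <- function(raw, roi = NULL, params = segmentation_params(),
                         keep_intermediates = FALSE) {
  stopifnot(inherits(raw, "intensity_image"))
  if (is.null(roi)) roi <- full_roi(raw)
  check_congruent(raw$values, roi$mask, "image and ROI")
  background <- remove_bright_outliers(raw, params$outlier_radius_px,
                                       params$outlier_threshold)
  fg <- foreground_image(raw, background)
  blurred <- gaussian_smooth(fg, params$gaussian_sigma_px)
  bg_mean <- mean(background$values[roi$mask])
  thr <- compute_threshold(bg_mean, params$background_coefficient)
  seg <- segment_blobs(blurred, as.numeric(thr), roi, params)
  res <- list(label_image = seg$label_image, blobs = seg$blobs,
              summary = summarize_morphometry(seg$blobs, roi$area_um2),
              threshold = as.numeric(thr), background_mean = bg_mean,
              params = params)
  if (keep_intermediates) {
    res$intermediates <- list(background = background, foreground = fg,
                              blurred = blurred)
  }
  class(res) <- "blob_pipeline_result"
  res
}

#' @export
print.blob_pipeline_result <- function(x, ...) {
  cat(sprintf("<blob_pipeline_result> threshold %.3f (bg mean %.3f x coef %.2f)\n",
              x$threshold, x$background_mean, x$params$background_coefficient))
  print(x$summary)
  invisible(x)
}
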