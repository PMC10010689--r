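#' Construct an intensity image
#'
#' The elementary unit of the imaging pipeline: a 2D grid of non-negative
#' intensities together with the physical size of a pixel. Rows run along y
#' and columns along x; physical coordinates use 0-based pixel indices, so a
#' pixel at (row r, col c) has its centre at `((c - 0.5) * pixel_size_um,
#' (r - 0.5) * pixel_size_um)` and its corners on the integer grid.
#'
#' @param values numeric matrix of finite, non-negative intensities.
#' @param pixel_size_um physical edge length of one pixel, in micrometres.
#' @param bit_depth nominal acquisition bit depth (metadata only).
#' @return an object of class `intensity_image`.
#' @export
intensity_image <- function(values, pixel_size_um, bit_depth = 16L) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (!all(is.finite(values))) stop("image intensities must be finite")
  if (any(values < 0)) stop("image intensities must be non-negative")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0) {
    stop("`pixel_size_um` must be a single positive number")
  }
  structure(
    list(values = values, pixel_size_um = as.numeric(pixel_size_um),
         bit_depth = as.integer(bit_depth)),
    class = "intensity_image"
  )
}

#' @export
print.intensity_image <- function(x, ...) {
  cat(sprintf(
    "<intensity_image> %d x %d px, %.4g um/px (%.4g x %.4g um), range [%.3g, %.3g]\n",
    nrow(x$values), ncol(x$values), x$pixel_size_um,
    ncol(x$values) * x$pixel_size_um, nrow(x$values) * x$pixel_size_um,
    min(x$values), max(x$values)))
  invisible(x)
}

#' Region-of-interest mask
#'
#' Logical mask congruent with an image; analysis (background averaging,
#' thresholding, object counting, density) is restricted to `TRUE` pixels,
#' mirroring manually drawn ROIs on micrographs.
#'
#' @param mask logical matrix with at least one `TRUE` pixel.
#' @param pixel_size_um pixel size used to derive the ROI area.
#' @return an object of class `roi_mask` with an `area_um2` field.
#' @export
roi_mask <- function(mask, pixel_size_um) {
  if (!is.matrix(mask) || !is.logical(mask)) stop("`mask` must be a logical matrix")
  if (!any(mask)) stop("ROI mask must contain at least one TRUE pixel")
  if (pixel_size_um <= 0) stop("`pixel_size_um` must be positive")
  structure(
    list(mask = mask, pixel_size_um = as.numeric(pixel_size_um),
         area_um2 = sum(mask) * pixel_size_um^2),
    class = "roi_mask"
  )
}

#' Full-image ROI for an intensity image
#' @param img an `intensity_image`.
#' @return an `roi_mask` covering every pixel.
#' @export
full_roi <- function(img) {
  stopifnot(inherits(img, "intensity_image"))
  roi_mask(matrix(TRUE, nrow(img$values), ncol(img$values)), img$pixel_size_um)
}

check_congruent <- function(a, b, what = "images") {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("%s have mismatched shapes: %s vs %s", what,
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")))
  }
  invisible(TRUE)
}

#' Percent change from a reference value
#'
#' `100 * (to - from) / from`; the convention used throughout for reporting
#' relative increases (e.g. object density in fragmented vs baseline scenes,
#' or the width of cytoplasmic-facing vs cuticle-facing membrane-fold gaps).
#'
#' @param from reference value (non-zero).
#' @param to new value.
#' @return percent change, positive when `to > from`.
#' @export
percent_increase <- function(from, to) {
  if (any(from == 0)) stop("reference value must be non-zero")
  100 * (to - from) / from
}
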