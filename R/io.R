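#' Load a single-channel TIFF as an intensity image
#'
#' Reads 8- or 16-bit single-channel TIFFs. The pixel size is taken from the
#' `pixel_size_um` argument when given; otherwise from the file's resolution
#' tags (pixels per unit with an inch or cm resolution unit); if neither is
#' available the call errors, since every downstream quantity is physical.
#'
#' @param path path to a TIFF file.
#' @param pixel_size_um pixel size override, um (wins over file metadata).
#' @param channel for multi-channel files, which channel to extract; without
#'   it a multi-channel file is an error.
#' @return an `intensity_image` with integer sample values.
#' @export
load_image <- function(path, pixel_size_um = NULL, channel = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  magic <- readBin(path, "raw", n = 4L)
  tiff_le <- as.integer(magic) [1:4]
  is_tiff <- identical(tiff_le, c(0x49L, 0x49L, 0x2AL, 0x00L)) ||
    identical(tiff_le, c(0x4DL, 0x4DL, 0x00L, 0x2AL))
  if (!is_tiff) {
    stop(sprintf("unsupported format for '%s': only TIFF (8/16-bit) is accepted",
                 path))
  }
  v <- tiff::readTIFF(path, info = TRUE, as.is = TRUE)
  if (length(dim(v)) == 3L) {
    if (is.null(channel)) {
      stop(sprintf("'%s' has %d channels: pass `channel` to select one",
                   path, dim(v)[3]))
    }
    v <- v[, , channel]
  }
  if (is.null(pixel_size_um)) {
    xres <- attr(v, "x.resolution")
    unit <- attr(v, "resolution.unit")
    if (!is.null(xres) && is.finite(xres) && xres > 0 && !is.null(unit)) {
      um_per_unit <- switch(as.character(unit), inch = 25400, cm = 10000,
                            NA_real_)
      if (is.finite(um_per_unit)) pixel_size_um <- um_per_unit / xres
    }
    if (is.null(pixel_size_um)) {
      stop(sprintf("no pixel size: '%s' carries no usable resolution tags; pass `pixel_size_um`",
                   path))
    }
  }
  bits <- attr(v, "bits.per.sample")
  intensity_image(matrix(as.numeric(v), nrow(v), ncol(v)), pixel_size_um,
                  if (is.null(bits)) 16L else as.integer(bits))
}

#' Write an intensity image as a 16-bit TIFF
#'
#' Values are rounded to integers and stored as 16-bit samples; a JSON
#' sidecar (`<path>.json`) records the pixel size and value scale so a
#' round trip through [load_image()] is bit-exact on the integer values.
#'
#' @param img an `intensity_image` (values must fit in 0..65535).
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "intensity_image"))
  v <- round(img$values)
  if (max(v) > 65535) stop("intensity values exceed the 16-bit range")
  tiff::writeTIFF(v / 65535, path, bits.per.sample = 16L, compression = "none")
  jsonlite::write_json(list(pixel_size_um = img$pixel_size_um,
                            bit_depth = img$bit_depth,
                            value_scale = "raw integer counts"),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write / read a label image as a 16-bit TIFF
#' @param labels integer label matrix (0 = background, < 65536 labels).
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_label_image <- function(labels, path) {
  if (max(labels) > 65535) stop("too many labels for 16-bit storage")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' @rdname write_label_image
#' @export
read_label_image <- function(path) {
  v <- tiff::readTIFF(path, as.is = TRUE)
  matrix(as.integer(round(v)), nrow(v), ncol(v))
}

#' Read a force curve from a two-column text file
#'
#' Accepts CSV/TSV with columns `z_nm` (piezo height) and either `force_nN`
#' or `deflection_nm` (converted with the cantilever stiffness,
#' `F = k * d`).
#'
#' @param path file path.
#' @param k_n_per_m cantilever stiffness, needed when the file stores
#'   deflection.
#' @return a `force_curve` data frame.
#' @export
read_force_curve <- function(path, k_n_per_m = NULL) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep)
  if (!"z_nm" %in% names(df)) stop("force-curve file must have a `z_nm` column")
  if (!"force_nN" %in% names(df)) {
    if (!"deflection_nm" %in% names(df)) {
      stop("force-curve file needs `force_nN` or `deflection_nm`")
    }
    if (is.null(k_n_per_m)) {
      stop("`k_n_per_m` is required to convert deflection to force")
    }
    df$force_nN <- df$deflection_nm * k_n_per_m
  }
  as_force_curve(df[, c("z_nm", "force_nN")])
}

#' @rdname read_force_curve
#' @param curve a `force_curve` to write as CSV.
#' @export
write_force_curve <- function(curve, path) {
  utils::write.csv(data.frame(z_nm = curve$z_nm, force_nN = curve$force_nN),
                   path, row.names = FALSE)
  invisible(path)
}
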