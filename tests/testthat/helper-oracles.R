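# Independent brute-force oracles, deliberately naive and separate from the
# package's implementation paths.

# Conditional disc-median filter: loop over every pixel, gather the disc by
# explicit distance test, take stats::median, replace only on excess.
oracle_remove_outliers <- function(m, radius, threshold) {
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      vals <- c()
      for (dr in -radius:radius) {
        for (dc in -radius:radius) {
          if (dr^2 + dc^2 <= radius^2) {
            rr <- r + dr; cc <- c + dc
            if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc) {
              vals <- c(vals, m[rr, cc])
            }
          }
        }
      }
      med <- stats::median(vals)
      if (m[r, c] - med > threshold) out[r, c] <- med
    }
  }
  out
}

# Maximum pairwise distance over all 4 corner points of every pixel.
oracle_feret <- function(px, ps) {
  if (is.null(dim(px))) px <- matrix(px, ncol = 2)
  x <- c(px[, 2] - 1, px[, 2], px[, 2] - 1, px[, 2])
  y <- c(px[, 1] - 1, px[, 1] - 1, px[, 1], px[, 1])
  pts <- unique(cbind(x, y))
  d2 <- outer(pts[, 1], pts[, 1], "-")^2 + outer(pts[, 2], pts[, 2], "-")^2
  sqrt(max(d2)) * ps
}

# Recompute a ground-truth object table from a label image from first
# principles (area = pixel count x ps^2, Feret by all-pairs corners).
oracle_blob_table <- function(label_image, ps) {
  labs <- sort(unique(label_image[label_image > 0]))
  do.call(rbind, lapply(labs, function(id) {
    px <- which(label_image == id, arr.ind = TRUE)
    data.frame(label = id, area_um2 = nrow(px) * ps^2,
               feret_um = oracle_feret(px, ps))
  }))
}

with_seed_local <- function(seed, code) withr::with_seed(seed, code)

# A small, quick scene for unit tests (about 0.4 s per pipeline run).
small_scene_spec <- function(seed = 1L, n_objects = 12L, ...) {
  scene_spec(roi_width_um = 20, roi_height_um = 10, n_objects = n_objects,
             elongation_range = c(1, 3), seed = seed, ...)
}
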