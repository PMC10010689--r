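#' Object-based co-localisation of two label images
#'
#' For every object of channel A, its centroid (unweighted mean of pixel
#' indices, rounded to the nearest pixel) is tested for membership of a
#' labelled object of channel B, and symmetrically. The statistic is the
#' percentage of objects of one channel whose centroid lies in an object of
#' the other. Centroids falling outside any B pixel count as misses even if
#' they are inside B's convex hull (mask membership, not geometry); an
#' object's membership of its own channel is irrelevant.
#'
#' @param labels_A,labels_B congruent integer label matrices (0 =
#'   background).
#' @return a `coloc_result` list: `pct_A_in_B`, `pct_B_in_A` (NA and flagged
#'   when the corresponding channel has no objects), counts `n_A`, `n_B`,
#'   `n_A_hits`, `n_B_hits`, and `defined` flags per direction.
#' @export
centroid_in_mask_pct <- function(labels_A, labels_B) {
  check_congruent(labels_A, labels_B, "label images")
  dir_pct <- function(from, into) {
    labs <- sort(unique(from[from > 0]))
    if (length(labs) == 0) {
      return(list(pct = NA_real_, n = 0L, hits = 0L, defined = FALSE))
    }
    hits <- 0L
    for (id in labs) {
      px <- which(from == id, arr.ind = TRUE)
      r <- round(mean(px[, 1])); c <- round(mean(px[, 2]))
      r <- min(max(r, 1L), nrow(into)); c <- min(max(c, 1L), ncol(into))
      if (into[r, c] > 0) hits <- hits + 1L
    }
    list(pct = 100 * hits / length(labs), n = length(labs),
         hits = hits, defined = TRUE)
  }
  ab <- dir_pct(labels_A, labels_B)
  ba <- dir_pct(labels_B, labels_A)
  structure(list(pct_A_in_B = ab$pct, pct_B_in_A = ba$pct,
                 n_A = ab$n, n_B = ba$n,
                 n_A_hits = ab$hits, n_B_hits = ba$hits,
                 defined = c(A_in_B = ab$defined, B_in_A = ba$defined)),
            class = "coloc_result")
}

#' Study-level co-localisation summary
#'
#' Unweighted mean and sd of the per-image percentages, per direction, with
#' each image conventionally representing one animal. Images whose
#' percentage is undefined for a direction (zero objects) are excluded from
#' that direction's mean.
#'
#' @param results non-empty list of per-image `coloc_result`s.
#' @return a `coloc_summary` list with per-direction `mean`, `sd`, `n_images`
#'   and the per-image values.
#' @export
coloc_summary <- function(results) {
  if (length(results) == 0) stop("no per-image results supplied")
  stopifnot(all(vapply(results, inherits, logical(1), "coloc_result")))
  ab <- vapply(results, function(x) x$pct_A_in_B, numeric(1))
  ba <- vapply(results, function(x) x$pct_B_in_A, numeric(1))
  summ <- function(v) {
    v <- v[!is.na(v)]
    list(mean = if (length(v)) mean(v) else NA_real_,
         sd = if (length(v) > 1) stats::sd(v) else NA_real_,
         n_images = length(v))
  }
  structure(list(A_in_B = summ(ab), B_in_A = summ(ba),
                 per_image = data.frame(pct_A_in_B = ab, pct_B_in_A = ba)),
            class = "coloc_summary")
}

#' @export
print.coloc_result <- function(x, ...) {
  fmt <- function(p, n, h, ok) {
    if (ok) sprintf("%.1f%% (%d/%d)", p, h, n) else sprintf("undefined (0 objects)")
  }
  cat("<coloc_result> A in B:", fmt(x$pct_A_in_B, x$n_A, x$n_A_hits, x$defined["A_in_B"]),
      "| B in A:", fmt(x$pct_B_in_A, x$n_B, x$n_B_hits, x$defined["B_in_A"]), "\n")
  invisible(x)
}
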