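# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Specification of a synthetic reticulated scene
#'
#' Describes a wild-type-like scene: irregular bright objects (rotated
#' ellipses of random area, elongation up to ~6 and orientation, with no
#' preferred direction) scattered without overlap over an autofluorescent
#' background, plus additive Gaussian noise.
#' Defaults describe the study baseline: 40 objects of 0.3-1.5 um^2 in a
#' 40 x 25 um (1000 um^2) field at 0.05 um/px (Airyscan-like oversampling),
#' with foreground/background mean intensities (150/30) and noise (sd 6)
#' chosen so the default segmentation parameters place the half-maximum
#' contour of a blurred object at its true boundary (background mean 30 x
#' coefficient 2 = 60 = half the 120 foreground amplitude). Rendered
#' intensities are integer counts, as a camera would deliver.
#'
#' @param roi_width_um,roi_height_um physical field size, um.
#' @param pixel_size_um pixel edge, um (> 0).
#' @param n_objects number of planted objects (>= 0).
#' @param area_range_um2 (low, high) of the uniform per-object area draw.
#' @param elongation_range (1, max) aspect-ratio range of the ellipses.
#' @param intensity_fg,intensity_bg mean object / background intensities.
#' @param noise_sd additive Gaussian noise sd (intensities clipped at 0).
#' @param min_separation_um minimum clearance between object envelopes.
#' @param seed RNG seed; identical specs generate bit-identical scenes.
#' @return a `scene_spec` list.
#' @export
scene_spec <- function(roi_width_um = 40, roi_height_um = 25,
                       pixel_size_um = 0.05, n_objects = 40,
                       area_range_um2 = c(0.3, 1.5),
                       elongation_range = c(1, 6),
                       intensity_fg = 150, intensity_bg = 30,
                       noise_sd = 6, min_separation_um = 1,
                       seed = 1L) {
  stopifnot(roi_width_um > 0, roi_height_um > 0, pixel_size_um > 0,
            n_objects >= 0, length(area_range_um2) == 2,
            area_range_um2[1] > 0, area_range_um2[2] >= area_range_um2[1],
            length(elongation_range) == 2, elongation_range[1] >= 1,
            elongation_range[2] >= elongation_range[1],
            intensity_fg > intensity_bg, intensity_bg >= 0,
            noise_sd >= 0, min_separation_um >= 0)
  structure(list(roi_width_um = roi_width_um, roi_height_um = roi_height_um,
                 pixel_size_um = pixel_size_um, n_objects = as.integer(n_objects),
                 area_range_um2 = as.numeric(area_range_um2),
                 elongation_range = as.numeric(elongation_range),
                 intensity_fg = intensity_fg, intensity_bg = intensity_bg,
                 noise_sd = noise_sd, min_separation_um = min_separation_um,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

scene_dims <- function(spec) {
  c(nr = max(1L, as.integer(round(spec$roi_height_um / spec$pixel_size_um))),
    nc = max(1L, as.integer(round(spec$roi_width_um / spec$pixel_size_um))))
}

# Rasterise a rotated ellipse: pixels whose centre lies inside. Centre
# (cx, cy) and semi-axes in um; theta in radians.
rasterize_ellipse <- function(cx, cy, a, b, theta, nr, nc, ps) {
  ct <- cos(theta); st <- sin(theta)
  c_lo <- max(1L, floor((cx - a) / ps)); c_hi <- min(nc, ceiling((cx + a) / ps) + 1L)
  r_lo <- max(1L, floor((cy - a) / ps)); r_hi <- min(nr, ceiling((cy + a) / ps) + 1L)
  if (c_lo > c_hi || r_lo > r_hi) return(NULL)
  cols <- c_lo:c_hi; rows <- r_lo:r_hi
  px <- (cols - 0.5) * ps; py <- (rows - 0.5) * ps
  X <- matrix(px, length(rows), length(cols), byrow = TRUE) - cx
  Y <- matrix(py, length(rows), length(cols)) - cy
  U <- X * ct + Y * st
  V <- -X * st + Y * ct
  inside <- (U / a)^2 + (V / b)^2 <= 1
  idx <- which(inside, arr.ind = TRUE)
  if (nrow(idx) == 0) return(NULL)
  cbind(row = rows[idx[, 1]], col = cols[idx[, 2]])
}

render_scene_image <- function(label_image, spec, noise_seed = spec$seed) {
  vals <- matrix(spec$intensity_bg, nrow(label_image), ncol(label_image))
  vals[label_image > 0] <- spec$intensity_fg
  if (spec$noise_sd > 0) {
    noise <- with_seed(noise_seed + 7777L,
                       matrix(stats::rnorm(length(vals), 0, spec$noise_sd),
                              nrow(vals), ncol(vals)))
    vals <- vals + noise
  }
  intensity_image(round(pmax(vals, 0)), spec$pixel_size_um)
}

ground_truth_from_labels <- function(label_image, spec) {
  objects <- blob_table_from_labels(label_image, spec$pixel_size_um)
  roi_area <- spec$roi_width_um * spec$roi_height_um
  structure(list(label_image = label_image, objects = objects,
                 n_objects = nrow(objects),
                 density_per_um2 = nrow(objects) / roi_area,
                 roi_area_um2 = roi_area, spec = spec),
            class = "scene_ground_truth")
}

#' Generate a reticulated wild-type-like scene
#'
#' Places `n_objects` rotated ellipses of random area/elongation/orientation
#' without overlap (centre distance at least the sum of circumscribed radii
#' plus `min_separation_um`), rasterises them onto the pixel grid, and
#' returns the noisy intensity image together with the planted ground truth.
#' Recorded per-object areas are the rasterised areas (pixel count x
#' pixel_size^2) and Feret diameters use the same pixel-corner convention as
#' the measurement pipeline, so ground truth is exactly recomputable from the
#' label image.
#'
#' @param spec a [scene_spec()].
#' @param max_tries placement retries per object before giving up.
#' @return list with `image` (`intensity_image`) and `ground_truth`
#'   (`scene_ground_truth`: label image, per-object table, density, spec).
#' @export
generate_reticulated_image <- function(spec, max_tries = 2000L) {
  stopifnot(inherits(spec, "scene_spec"))
  d <- scene_dims(spec)
  ps <- spec$pixel_size_um
  with_seed(spec$seed, {
    lab <- matrix(0L, d["nr"], d["nc"])
    if (spec$n_objects > 0) {
      areas <- stats::runif(spec$n_objects, spec$area_range_um2[1], spec$area_range_um2[2])
      elong <- stats::runif(spec$n_objects, spec$elongation_range[1], spec$elongation_range[2])
      theta <- stats::runif(spec$n_objects, 0, pi)
      a <- sqrt(areas * elong / pi)  # semi-major, um
      b <- sqrt(areas / (elong * pi))
      cx <- numeric(spec$n_objects); cy <- numeric(spec$n_objects)
      for (i in seq_len(spec$n_objects)) {
        placed <- FALSE
        for (t in seq_len(max_tries)) {
          x <- stats::runif(1, a[i] + ps, spec$roi_width_um - a[i] - ps)
          y <- stats::runif(1, a[i] + ps, spec$roi_height_um - a[i] - ps)
          if (i == 1L ||
              all(sqrt((x - cx[seq_len(i - 1)])^2 + (y - cy[seq_len(i - 1)])^2) >=
                  a[i] + a[seq_len(i - 1)] + spec$min_separation_um)) {
            cx[i] <- x; cy[i] <- y; placed <- TRUE
            break
          }
        }
        if (!placed) {
          stop(sprintf(
            "could not place %d objects in a %.0f x %.0f um field (failed at object %d)",
            spec$n_objects, spec$roi_width_um, spec$roi_height_um, i))
        }
        px <- rasterize_ellipse(cx[i], cy[i], a[i], b[i], theta[i],
                                d["nr"], d["nc"], ps)
        if (is.null(px)) stop(sprintf("object %d rasterised to zero pixels", i))
        lab[px] <- i
      }
    }
    list(image = render_scene_image(lab, spec, spec$seed),
         ground_truth = ground_truth_from_labels(lab, spec))
  })
}

#' Fragment every planted object into k pieces
#'
#' Synthetic surrogate for the fragmented mutant phenotype: each planted
#' object is cut into `k_fragments` slabs perpendicular to its principal
#' axis, taking approximately equal pixel counts per piece and erasing every
#' pixel within `gap_um` (along the axis) of a piece boundary, so
#' consecutive pieces stay separated by at least `gap_um`. Pieces shrink in
#' area and Feret diameter while the object count (and hence density)
#' multiplies by `k_fragments`. Pieces that would come out empty make the
#' split infeasible and raise an error naming the object; a minimum piece
#' area is enforced only when `min_piece_area_um2` is supplied, since the
#' smallest plantable objects cannot yield k pieces above the downstream
#' area filter.
#'
#' @param gt a `scene_ground_truth` from [generate_reticulated_image()].
#' @param k_fragments integer >= 1; 1 returns the scene unchanged.
#' @param gap_um erased strip width, um; must exceed one pixel diagonal so
#'   pieces are not 8-connected across the cut.
#' @param seed RNG seed used for the re-rendered image noise.
#' @param min_piece_area_um2 optional hard floor on piece area; infeasible
#'   objects raise an error rather than being silently dropped.
#' @return list with `image` and `ground_truth` for the fragmented scene.
#' @export
fragment_scene <- function(gt, k_fragments, gap_um = 0.15, seed = gt$spec$seed + 1L,
                           min_piece_area_um2 = NULL) {
  stopifnot(inherits(gt, "scene_ground_truth"), k_fragments >= 1)
  k <- as.integer(k_fragments)
  spec <- gt$spec
  ps <- spec$pixel_size_um
  if (k == 1L) {
    return(list(image = render_scene_image(gt$label_image, spec, seed),
                ground_truth = gt))
  }
  if (gap_um <= ps * sqrt(2)) {
    stop("`gap_um` must exceed one pixel diagonal to separate the pieces")
  }
  lab_old <- gt$label_image
  lab_new <- matrix(0L, nrow(lab_old), ncol(lab_old))
  next_label <- 0L
  for (id in gt$objects$label) {
    px <- which(lab_old == id, arr.ind = TRUE)
    xy <- cbind((px[, 2] - 0.5) * ps, (px[, 1] - 0.5) * ps)
    ctr <- colMeans(xy)
    xyc <- sweep(xy, 2, ctr)
    # principal axis of the pixel cloud
    ev <- eigen(stats::cov(xyc), symmetric = TRUE)$vectors[, 1]
    t_coord <- drop(xyc %*% ev)
    n_px <- length(t_coord)
    # equal-extent slabs along the axis with erased bands of width `gap_um`
    # between them; pieces of a convex object stay connected
    t_lo <- min(t_coord); t_hi <- max(t_coord)
    extent <- (t_hi - t_lo - (k - 1) * gap_um) / k
    if (extent <= 0) {
      stop(sprintf("object %d (area %.2f um2) is too small to split into %d pieces with a %.2f um gap",
                   id, n_px * ps^2, k, gap_um))
    }
    piece_of <- integer(n_px)  # 0 = erased
    for (j in seq_len(k)) {
      s <- t_lo + (j - 1) * (extent + gap_um)
      piece_of[t_coord >= s - 1e-9 & t_coord <= s + extent + 1e-9] <- j
    }
    counts <- tabulate(piece_of[piece_of > 0], nbins = k)
    if (any(counts == 0)) {
      stop(sprintf("object %d (area %.2f um2) is too small to split into %d pieces with a %.2f um gap",
                   id, n_px * ps^2, k, gap_um))
    }
    if (!is.null(min_piece_area_um2) &&
        any(counts * ps^2 < min_piece_area_um2 - 1e-9)) {
      stop(sprintf("object %d yields a piece below %.3f um2 when split into %d",
                   id, min_piece_area_um2, k))
    }
    for (j in seq_len(k)) {
      next_label <- next_label + 1L
      lab_new[px[piece_of == j, , drop = FALSE]] <- next_label
    }
  }
  list(image = render_scene_image(lab_new, spec, seed),
       ground_truth = ground_truth_from_labels(lab_new, spec))
}

#' Generate a paired-channel co-localisation scene
#'
#' Builds two label images A and B with a planted containment fraction:
#' `round(planted_fraction * n_a)` A objects are small discs centred on
#' distinct B objects (centroid decisively inside), the remaining A objects
#' are placed with clearance from every B object (centroid decisively
#' outside), so the expected percentage of A centroids inside B equals
#' `100 * round(planted_fraction * n_a) / n_a` exactly by construction.
#'
#' @param n_a,n_b object counts per channel (`n_b` at least the number of
#'   planted hits).
#' @param planted_fraction fraction of A objects planted inside B, in [0, 1].
#' @param spec a [scene_spec()] providing geometry (field size, pixel size).
#' @param seed RNG seed.
#' @return list with `labels_A`, `labels_B` (integer matrices),
#'   `expected_pct_A_in_B`, `n_hits` and `pixel_size_um`.
#' @export
generate_coloc_pair <- function(n_a, n_b, planted_fraction,
                                spec = scene_spec(), seed = 1L) {
  if (planted_fraction < 0 || planted_fraction > 1) {
    stop("`planted_fraction` must be in [0, 1]")
  }
  stopifnot(n_a >= 1, n_b >= 1)
  n_hits <- as.integer(round(planted_fraction * n_a))
  if (n_hits > n_b) stop("not enough B objects to host the planted hits")
  d <- scene_dims(spec)
  ps <- spec$pixel_size_um
  r_b <- sqrt(mean(spec$area_range_um2) / pi)   # B disc radius, um
  r_a <- max(2.5 * ps, r_b / 2)                 # A discs smaller, >= 2.5 px
  with_seed(seed, {
    # place B discs without overlap
    cxB <- numeric(n_b); cyB <- numeric(n_b)
    for (i in seq_len(n_b)) {
      for (t in seq_len(4000L)) {
        x <- stats::runif(1, r_b + ps, spec$roi_width_um - r_b - ps)
        y <- stats::runif(1, r_b + ps, spec$roi_height_um - r_b - ps)
        if (i == 1L || all(sqrt((x - cxB[seq_len(i - 1)])^2 +
                                (y - cyB[seq_len(i - 1)])^2) >= 2 * r_b + 2 * r_a + 3 * ps)) {
          cxB[i] <- x; cyB[i] <- y
          break
        }
        if (t == 4000L) stop(sprintf("could not place %d B objects in the field", n_b))
      }
    }
    labB <- matrix(0L, d["nr"], d["nc"])
    for (i in seq_len(n_b)) {
      labB[rasterize_ellipse(cxB[i], cyB[i], r_b, r_b, 0, d["nr"], d["nc"], ps)] <- i
    }
    # A hits: centred on the first n_hits B objects
    cxA <- numeric(n_a); cyA <- numeric(n_a)
    if (n_hits > 0) {
      cxA[seq_len(n_hits)] <- cxB[seq_len(n_hits)]
      cyA[seq_len(n_hits)] <- cyB[seq_len(n_hits)]
    }
    # A misses: clear of every B disc and of other A objects
    if (n_a > n_hits) {
      for (i in (n_hits + 1L):n_a) {
        placed <- FALSE
        for (t in seq_len(4000L)) {
          x <- stats::runif(1, r_a + ps, spec$roi_width_um - r_a - ps)
          y <- stats::runif(1, r_a + ps, spec$roi_height_um - r_a - ps)
          clear_b <- all(sqrt((x - cxB)^2 + (y - cyB)^2) >= r_b + r_a + 3 * ps)
          clear_a <- i == 1L || all(sqrt((x - cxA[seq_len(i - 1)])^2 +
                                         (y - cyA[seq_len(i - 1)])^2) >= 2 * r_a + 2 * ps)
          if (clear_b && clear_a) {
            cxA[i] <- x; cyA[i] <- y; placed <- TRUE
            break
          }
        }
        if (!placed) stop(sprintf("could not place %d A objects clear of B", n_a))
      }
    }
    labA <- matrix(0L, d["nr"], d["nc"])
    for (i in seq_len(n_a)) {
      labA[rasterize_ellipse(cxA[i], cyA[i], r_a, r_a, 0, d["nr"], d["nc"], ps)] <- i
    }
    list(labels_A = labA, labels_B = labB,
         expected_pct_A_in_B = 100 * n_hits / n_a,
         n_hits = n_hits, pixel_size_um = ps)
  })
}
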