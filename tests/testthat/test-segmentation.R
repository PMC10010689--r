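make_img <- function(m, ps = 0.1) intensity_image(m, ps)

test_that("remove_bright_outliers matches the brute-force disc median oracle", {
  set.seed(42)
  # float-valued image (direct path)
  m <- matrix(runif(20 * 16, 0, 50), 20, 16)
  m[5, 5] <- 500; m[12, 9] <- 300
  got <- remove_bright_outliers(make_img(m), radius_px = 3, threshold = 30)
  expect_equal(got$values, oracle_remove_outliers(m, 3, 30))
  # integer-valued image (sliding-histogram path)
  mi <- matrix(sample(0:60, 24 * 18, replace = TRUE), 24, 18)
  mi[3, 11] <- 4000
  got_i <- remove_bright_outliers(make_img(mi), radius_px = 4, threshold = 25)
  expect_equal(got_i$values, oracle_remove_outliers(mi, 4, 25))
})

test_that("outlier removal replaces conditionally, by the stated margin", {
  base <- matrix(10, 15, 15)
  expect_equal(remove_bright_outliers(make_img(base), 2, 30)$values, base)
  spike <- base; spike[8, 8] <- 100
  out <- remove_bright_outliers(make_img(spike), 2, 30)
  expect_equal(out$values[8, 8], 10)
  expect_equal(out$values[-8, ], spike[-8, ])
  weak <- base; weak[8, 8] <- 35  # deviation 25 <= 30: untouched
  expect_equal(remove_bright_outliers(make_img(weak), 2, 30)$values, weak)
  expect_error(remove_bright_outliers(make_img(base), 40, 30), "extent")
})

test_that("foreground subtraction clamps at zero and checks shapes", {
  raw <- make_img(matrix(c(10, 20, 5, 40), 2, 2))
  bg <- make_img(matrix(c(10, 25, 2, 15), 2, 2))
  fg <- foreground_image(raw, bg)
  expect_equal(fg$values, matrix(c(0, 0, 3, 25), 2, 2))
  expect_error(foreground_image(raw, make_img(matrix(0, 3, 2))), "mismatch")
})

test_that("gaussian smoothing is normalised, conservative and identity on constants", {
  const <- make_img(matrix(7, 12, 12))
  expect_equal(gaussian_smooth(const, 1)$values, const$values, tolerance = 1e-12)
  imp <- matrix(0, 21, 21); imp[11, 11] <- 1
  sm <- gaussian_smooth(make_img(imp), 1)
  # centre weight of the discrete normalised kernel, radius 3 sigma
  w <- exp(-(-3:3)^2 / 2); w <- w / sum(w)
  expect_equal(sm$values[11, 11], w[4]^2, tolerance = 1e-12)
  expect_equal(sm$values[11, 11], 0.1592, tolerance = 1e-3)
  expect_equal(sum(sm$values), 1, tolerance = 1e-6)  # interior impulse
})

test_that("threshold is background mean times coefficient, with degenerate flag", {
  expect_equal(as.numeric(compute_threshold(100, 2)), 200)
  expect_equal(as.numeric(compute_threshold(12.5, 1.6)), 20)
  expect_warning(thr <- compute_threshold(0, 2), "degenerate")
  expect_equal(as.numeric(thr), 0)
  expect_true(attr(thr, "degenerate"))
  expect_error(compute_threshold(-1, 2))
  expect_error(compute_threshold(10, 0))
})

test_that("area filter keeps equality and removes strictly smaller objects", {
  # squares of 0.10, 0.15, 0.20 um^2 at 0.1 um/px: 10, 15 and 20 pixels
  m <- matrix(0, 30, 30)
  m[2:6, 2:3] <- 100        # 10 px = 0.10
  m[10:14, 2:4] <- 100      # 15 px = 0.15
  m[20:24, 2:5] <- 100      # 20 px = 0.20
  img <- make_img(m, ps = 0.1)
  seg <- segment_blobs(img, threshold = 50, roi = full_roi(img),
                       params = segmentation_params(min_area_um2 = 0.15))
  expect_equal(nrow(seg$blobs), 2)
  expect_equal(sort(seg$blobs$area_um2), c(0.15, 0.20))
  # all-background image
  empty <- segment_blobs(make_img(matrix(0, 10, 10)), 50,
                         full_roi(make_img(matrix(0, 10, 10))))
  expect_equal(nrow(empty$blobs), 0)
})

test_that("raising the area filter or the threshold never adds objects", {
  sc <- generate_reticulated_image(small_scene_spec(seed = 4L))
  res <- run_pipeline(sc$image, keep_intermediates = TRUE)
  blurred <- res$intermediates$blurred
  roi <- full_roi(sc$image)
  n_prev <- Inf
  for (amin in c(0.05, 0.15, 0.4, 1.0)) {
    n <- nrow(segment_blobs(blurred, res$threshold, roi,
                            segmentation_params(min_area_um2 = amin))$blobs)
    expect_lte(n, n_prev)
    n_prev <- n
  }
  fg_prev <- Inf
  for (coef in c(1.5, 2, 3, 4)) {
    thr <- compute_threshold(res$background_mean, coef)
    fg <- sum(blurred$values > as.numeric(thr))
    expect_lte(fg, fg_prev)
    fg_prev <- fg
  }
})

test_that("segmentation respects the ROI mask", {
  m <- matrix(0, 20, 20)
  m[3:6, 3:6] <- 100   # inside ROI
  m[14:17, 14:17] <- 100  # outside ROI
  img <- make_img(m, ps = 0.1)
  mask <- matrix(FALSE, 20, 20); mask[1:10, 1:10] <- TRUE
  roi <- roi_mask(mask, 0.1)
  seg <- segment_blobs(img, 50, roi, segmentation_params(min_area_um2 = 0.05))
  expect_equal(nrow(seg$blobs), 1)
  expect_error(roi_mask(matrix(FALSE, 2, 2), 0.1), "TRUE pixel")
})

test_that("morphometry summary computes means and density, flagging empties", {
  tb <- data.frame(label = 1:2, area_um2 = c(0.2, 0.4), feret_um = c(0.6, 1.0),
                   centroid_x_um = c(1, 2), centroid_y_um = c(1, 2))
  s <- summarize_morphometry(tb, 400)
  expect_equal(s$mean_area_um2, 0.3)
  expect_equal(s$density_per_um2, 2 / 400)
  s12 <- summarize_morphometry(tb[rep(1, 12), ], 400)
  expect_equal(s12$density_per_um2, 0.03)
  s0 <- summarize_morphometry(tb[0, ], 400)
  expect_equal(s0$n_objects, 0)
  expect_equal(s0$density_per_um2, 0)
  expect_false(s0$defined)
  expect_true(is.na(s0$mean_area_um2))
  expect_error(summarize_morphometry(tb, 0))
})

test_that("a noise-only image yields zero objects at the default coefficient", {
  sp <- scene_spec(n_objects = 0, roi_width_um = 15, roi_height_um = 15,
                   seed = 9L)
  sc <- generate_reticulated_image(sp)
  res <- run_pipeline(sc$image)
  expect_equal(res$summary$n_objects, 0)
  expect_false(res$summary$defined)
})
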