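test_that("identity and disjoint channels give 100% and 0%", {
  gt <- generate_reticulated_image(small_scene_spec(seed = 31L))$ground_truth
  ident <- centroid_in_mask_pct(gt$label_image, gt$label_image)
  expect_equal(ident$pct_A_in_B, 100)
  expect_equal(ident$pct_B_in_A, 100)
  # shift channel B far away: disjoint masks
  shifted <- matrix(0L, nrow(gt$label_image), ncol(gt$label_image))
  half <- ncol(shifted) %/% 2
  left <- gt$label_image[, 1:half]
  left_only <- matrix(0L, nrow(shifted), ncol(shifted))
  left_only[, 1:half] <- left
  right_only <- matrix(0L, nrow(shifted), ncol(shifted))
  right_only[, (half + 1):(2 * half)] <- left
  dj <- centroid_in_mask_pct(left_only, right_only)
  expect_equal(dj$pct_A_in_B, 0)
  expect_equal(dj$pct_B_in_A, 0)
  expect_error(centroid_in_mask_pct(left_only, matrix(0L, 2, 2)), "mismatch")
})

test_that("planted containment fractions are recovered exactly per image", {
  for (f in c(0, 0.25, 1)) {
    pair <- generate_coloc_pair(8, 10, f, seed = 41L + round(100 * f))
    res <- centroid_in_mask_pct(pair$labels_A, pair$labels_B)
    expect_equal(res$pct_A_in_B, pair$expected_pct_A_in_B)
    expect_equal(res$pct_A_in_B, 100 * f)
    expect_true(res$pct_B_in_A >= 0 && res$pct_B_in_A <= 100)
  }
})

test_that("zero-object channels are flagged undefined, not 0 or NaN", {
  lab <- matrix(0L, 10, 10); lab[3:5, 3:5] <- 1L
  none <- matrix(0L, 10, 10)
  res <- centroid_in_mask_pct(lab, none)
  expect_false(res$defined["B_in_A"])
  expect_true(is.na(res$pct_B_in_A))
  expect_true(res$defined["A_in_B"])
  expect_equal(res$pct_A_in_B, 0)  # defined, just no hits
})

test_that("study-level summary averages per-image percentages unweighted", {
  mk <- function(p) structure(list(pct_A_in_B = p, pct_B_in_A = NA_real_,
                                   n_A = 4L, n_B = 0L, n_A_hits = 0L,
                                   n_B_hits = 0L,
                                   defined = c(A_in_B = TRUE, B_in_A = FALSE)),
                              class = "coloc_result")
  s <- coloc_summary(list(mk(0), mk(50), mk(100)))
  expect_equal(s$A_in_B$mean, 50)
  expect_equal(s$A_in_B$n_images, 3)
  expect_true(is.na(s$B_in_A$mean))
  one <- coloc_summary(list(mk(40)))
  expect_equal(one$A_in_B$mean, 40)
  expect_error(coloc_summary(list()), "no per-image")
})

test_that("a planted study recovers its fraction across images", {
  res <- lapply(1:10, function(i) {
    pair <- generate_coloc_pair(10, 12, 0.3, seed = 500L + i)
    centroid_in_mask_pct(pair$labels_A, pair$labels_B)
  })
  s <- coloc_summary(res)
  # construction is exact per image, so the mean is exact
  expect_equal(s$A_in_B$mean, 30)
  expect_equal(s$A_in_B$sd, 0)
})
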