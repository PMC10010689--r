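test_that("empty and trivial scenes behave as specified", {
  sp <- scene_spec(n_objects = 0, noise_sd = 0, roi_width_um = 10,
                   roi_height_um = 10)
  sc <- generate_reticulated_image(sp)
  expect_true(all(sc$image$values == sp$intensity_bg))
  expect_equal(sc$ground_truth$n_objects, 0)
  expect_equal(sc$ground_truth$density_per_um2, 0)

  sp2 <- scene_spec(n_objects = 40)
  sc2 <- generate_reticulated_image(sp2)
  expect_equal(sc2$ground_truth$density_per_um2, 40 / 1000)
})

test_that("scene generation is deterministic given the seed", {
  sp <- small_scene_spec(seed = 11L)
  a <- generate_reticulated_image(sp)
  b <- generate_reticulated_image(sp)
  expect_identical(a$image$values, b$image$values)
  expect_identical(a$ground_truth$label_image, b$ground_truth$label_image)
  expect_identical(a$ground_truth$objects, b$ground_truth$objects)

  c2 <- generate_reticulated_image(small_scene_spec(seed = 12L))
  expect_false(identical(a$image$values, c2$image$values))
})

test_that("planted areas respect the requested range up to one pixel ring", {
  sp <- scene_spec(seed = 1L, n_objects = 25, area_range_um2 = c(0.3, 1.5),
                   roi_width_um = 30, roi_height_um = 30)
  gt <- generate_reticulated_image(sp)$ground_truth
  expect_equal(nrow(gt$objects), 25)
  ps <- sp$pixel_size_um
  # rasterization tolerance: one ring of boundary pixels around the outline
  ring <- gt$objects$feret_um * pi * ps
  expect_true(all(gt$objects$area_um2 >= 0.3 - ring))
  expect_true(all(gt$objects$area_um2 <= 1.5 + ring))
})

test_that("ground truth is self-consistent with its label image", {
  for (seed in c(3L, 17L)) {
    gt <- generate_reticulated_image(small_scene_spec(seed = seed))$ground_truth
    oracle <- oracle_blob_table(gt$label_image, gt$spec$pixel_size_um)
    expect_equal(gt$objects$label, oracle$label)
    expect_equal(gt$objects$area_um2, oracle$area_um2)
    expect_equal(gt$objects$feret_um, oracle$feret_um)
    expect_equal(gt$density_per_um2, nrow(oracle) / gt$roi_area_um2)
    # labels are consecutive positive integers
    expect_identical(sort(unique(as.vector(gt$label_image[gt$label_image > 0]))),
                     seq_len(gt$n_objects))
  }
})

test_that("fragment_scene with k = 1 is the identity on the ground truth", {
  gt <- generate_reticulated_image(small_scene_spec(seed = 2L))$ground_truth
  fr <- fragment_scene(gt, 1)
  expect_identical(fr$ground_truth$label_image, gt$label_image)
  expect_identical(fr$ground_truth$objects, gt$objects)
})

test_that("fragment_scene multiplies the count and shrinks the pieces", {
  gt <- generate_reticulated_image(scene_spec(seed = 5L))$ground_truth
  fr <- fragment_scene(gt, 3)$ground_truth
  expect_equal(fr$n_objects, 3 * gt$n_objects)
  expect_equal(fr$density_per_um2, 3 * gt$density_per_um2)
  # recompute from label pixels via the independent oracle
  oracle <- oracle_blob_table(fr$label_image, fr$spec$pixel_size_um)
  expect_equal(fr$objects$area_um2, oracle$area_um2)
  expect_lt(mean(fr$objects$area_um2), mean(gt$objects$area_um2))
  expect_lt(mean(fr$objects$feret_um), mean(gt$objects$feret_um))
  # pieces of one parent never touch: every label is 8-disconnected from
  # every other (gap erasure), so relabelling the mask reproduces the count
  relab <- meisoquant:::label_components_cpp(fr$label_image > 0)
  expect_equal(max(relab), fr$n_objects)
})

test_that("fragmentation conserves foreground area up to the erased gaps", {
  gt <- generate_reticulated_image(small_scene_spec(seed = 7L))$ground_truth
  gap <- 0.15
  fr <- fragment_scene(gt, 2, gap_um = gap)$ground_truth
  before <- sum(gt$objects$area_um2)
  after <- sum(fr$objects$area_um2)
  expect_lte(after, before)
  # erased area bounded by one gap band per cut, each at most gap x extent
  ps <- gt$spec$pixel_size_um
  bound <- sum((gap + 2 * ps) * (gt$objects$feret_um + 2 * ps))
  expect_lte(before - after, bound)
})

test_that("infeasible splits raise errors naming the object", {
  gt <- generate_reticulated_image(small_scene_spec(seed = 2L))$ground_truth
  expect_error(fragment_scene(gt, 50), "too small to split")
  expect_error(fragment_scene(gt, 3, min_piece_area_um2 = 0.4),
               "piece below")
  expect_error(fragment_scene(gt, 2, gap_um = 0.01), "pixel diagonal")
})

test_that("coloc pair generation plants the containment fraction exactly", {
  expect_error(generate_coloc_pair(8, 10, 1.2), "planted_fraction")
  pair <- generate_coloc_pair(8, 10, 0.25, seed = 3L)
  expect_equal(pair$expected_pct_A_in_B, 25)
  expect_equal(pair$n_hits, 2L)
  expect_equal(max(pair$labels_A), 8)
  expect_equal(max(pair$labels_B), 10)
})
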