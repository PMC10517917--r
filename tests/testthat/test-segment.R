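test_that("contrast matching inverts affine distortions", {
  ref <- generate_phantom(small_spec(n_tubules = 1, noise_sigma = 0.03,
                                     seed = 1))$volume
  expect_equal(match_contrast(ref, ref)$data, ref$data, tolerance = 1e-12)
  distorted <- voxel_volume(2 * ref$data + 5, ref$voxel_size_nm)
  recovered <- match_contrast(distorted, ref)
  expect_equal(recovered$data, ref$data, tolerance = 1e-8)
  once <- match_contrast(distorted, ref)
  twice <- match_contrast(once, ref)
  expect_equal(twice$data, once$data, tolerance = 1e-12)
})

test_that("contrast matching preserves intensity rank order", {
  set.seed(31)
  a <- voxel_volume(array(rnorm(8^3), dim = c(8, 8, 8)))
  b <- voxel_volume(array(rexp(8^3), dim = c(8, 8, 8)))
  m <- match_contrast(a, b)
  expect_identical(order(m$data), order(a$data))
  const <- voxel_volume(array(1, dim = c(4, 4, 4)))
  expect_error(match_contrast(const, b), "constant")
})

test_that("median filtering removes impulses and fixes constants", {
  v <- voxel_volume(array(0.5, dim = c(12, 12, 12)))
  expect_identical(median_filter_volume(v, 0)$data, v$data)
  expect_equal(median_filter_volume(v, 2)$data, v$data)
  spiked <- v
  spiked$data[6, 6, 6] <- 10
  cleaned <- median_filter_volume(spiked, 1)
  expect_equal(cleaned$data, v$data)
})

test_that("mid-gap manual thresholds recover the phantom truth exactly", {
  spec <- small_spec(n_tubules = 2, silver_fill_fraction = 0.03,
                     silver_decay_length_um = 4, n_cracks = 1, seed = 6)
  ph <- generate_phantom(spec)
  ph <- add_cracks(ph$volume, ph$truth, spec)
  seg <- threshold_segment(ph$volume, segmentation_params(
    median_radius_voxels = 0, threshold_lumen_dentin = 0.25,
    threshold_dentin_silver = 0.75))
  d <- class_dice(ph$truth$labels$labels, seg$labels)
  expect_equal(unname(d), rep(1, length(d)))
})

test_that("no voxel above the silver threshold means zero silver", {
  ph <- generate_phantom(small_spec(n_tubules = 1))
  seg <- threshold_segment(ph$volume, segmentation_params(
    median_radius_voxels = 0, threshold_lumen_dentin = 0.25,
    threshold_dentin_silver = 2))
  expect_identical(label_counts(seg)[["silver"]], 0L)
})

test_that("auto thresholds segment a noisy phantom with Dice >= 0.9", {
  for (seed in 1:5) {
    spec <- phantom_spec(shape_voxels = c(96, 96, 160), n_tubules = 2,
                         silver_fill_fraction = 0.05,
                         silver_decay_length_um = 6,
                         noise_sigma = 0.05, seed = seed)
    ph <- generate_phantom(spec)
    seg <- threshold_segment(ph$volume,
                             segmentation_params(median_radius_voxels = 1))
    th <- seg$provenance$thresholds
    expect_true(th[1] > 0.05 && th[1] < 0.5)
    expect_true(th[2] > 0.5 && th[2] < 1)
    d <- class_dice(ph$truth$labels$labels, seg$labels)
    expect_true(all(d >= 0.9))
  }
})

test_that("auto thresholding a two-mode volume falls back with a warning", {
  set.seed(12)
  arr <- array(sample(c(0, 1), 6^3, replace = TRUE), dim = c(6, 6, 6))
  expect_warning(tubulometry:::auto_thresholds(as.vector(arr)),
                 "2-class")
})

test_that("raising the silver threshold never increases the silver count", {
  ph <- generate_phantom(small_spec(n_tubules = 2,
                                    silver_fill_fraction = 0.05,
                                    silver_decay_length_um = 5,
                                    noise_sigma = 0.05, seed = 13))
  counts <- sapply(seq(0.6, 1.1, by = 0.1), function(t2) {
    seg <- threshold_segment(ph$volume, segmentation_params(
      median_radius_voxels = 0, threshold_lumen_dentin = 0.25,
      threshold_dentin_silver = t2))
    label_counts(seg)[["silver"]]
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("small silver specks can be suppressed by component size", {
  spec <- small_spec(n_tubules = 1, noise_sigma = 0.12, seed = 17)
  ph <- generate_phantom(spec)
  loose <- threshold_segment(ph$volume, segmentation_params(
    median_radius_voxels = 0, threshold_lumen_dentin = 0.25,
    threshold_dentin_silver = 0.9))
  pruned <- threshold_segment(ph$volume, segmentation_params(
    median_radius_voxels = 0, threshold_lumen_dentin = 0.25,
    threshold_dentin_silver = 0.9, min_silver_component_voxels = 10))
  expect_lte(label_counts(pruned)[["silver"]],
             label_counts(loose)[["silver"]])
  expect_identical(label_counts(pruned)[["silver"]], 0L)
})

test_that("inverted manual thresholds are rejected", {
  expect_error(segmentation_params(threshold_lumen_dentin = 0.8,
                                   threshold_dentin_silver = 0.2), "<")
})

test_that("cropping preserves counts and partitions add up", {
  spec <- small_spec(n_tubules = 2, silver_fill_fraction = 0.03, seed = 19)
  ph <- generate_phantom(spec)
  lab <- ph$truth$labels
  d <- dim(lab)
  full <- crop_interior(lab, c(0, d[1], 0, d[2], 0, d[3]))
  expect_identical(full$labels, lab$labels)
  half <- d[3] %/% 2
  lower <- crop_interior(lab, c(0, d[1], 0, d[2], 0, half))
  upper <- crop_interior(lab, c(0, d[1], 0, d[2], half, d[3]))
  expect_identical(label_counts(lower) + label_counts(upper),
                   label_counts(lab))
  # a box excluding all silver has zero silver
  codes <- material_codes()
  zs <- which(apply(lab$labels == codes[["silver"]], 3, any))
  expect_gt(length(zs), 0)
  below <- crop_interior(lab, c(0, d[1], 0, d[2], 0, min(zs) - 1))
  expect_identical(label_counts(below)[["silver"]], 0L)
  expect_error(crop_interior(lab, c(0, d[1], 0, d[2], 5, 5)), "non-empty")
  expect_error(crop_interior(lab, c(0, d[1] + 1, 0, d[2], 0, d[3])),
               "bounds")
})

test_that("planar horizontal air gaps are relabeled as cracks", {
  spec <- small_spec(n_tubules = 1, n_cracks = 1,
                     crack_thickness_voxels = 2, seed = 23)
  ph <- generate_phantom(spec)
  ph <- add_cracks(ph$volume, ph$truth, spec)
  seg <- threshold_segment(ph$volume, segmentation_params(
    median_radius_voxels = 0, threshold_lumen_dentin = 0.25,
    threshold_dentin_silver = 0.75))
  expect_identical(label_counts(seg)[["crack"]], 0L)
  fixed <- relabel_cracks(seg, max_thickness_voxels = 4)
  codes <- material_codes()
  truth_crack <- ph$truth$labels$labels == codes[["crack"]]
  got_crack <- fixed$labels == codes[["crack"]]
  # every true crack voxel is excluded ...
  expect_true(all(got_crack[truth_crack]))
  # ... and anything else excluded lies within the crack slab slices
  # (tubule cross-sections passing through the slab, by design)
  crack_slices <- apply(truth_crack, 3, any)
  expect_true(all(apply(got_crack, 3, any) == crack_slices))
  # tubule lumen outside the slab is untouched
  outside <- which(!crack_slices)
  expect_identical(fixed$labels[, , outside], seg$labels[, , outside])
})
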