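test_that("slice fractions count silver pixels over slice pixels", {
  codes <- material_codes()
  lab <- array(codes[["dentin"]], dim = c(300, 300, 2))
  idx <- cbind(sample(300, 9), sample(300, 9), 2)
  lab[idx] <- codes[["silver"]]
  fr <- slice_volume_fraction(label_volume(lab, 128))
  expect_equal(fr, c(0, 1e-4))
})

test_that("slice fractions agree exactly with phantom truth counts", {
  spec <- cylinder_spec(n_tubules = 2, silver_fill_fraction = 0.03,
                        silver_decay_length_um = 5, seed = 61)
  ph <- generate_phantom(spec)
  lab <- ph$truth$labels
  d <- dim(lab)
  codes <- material_codes()
  truth_counts <- sapply(seq_len(d[3]), function(k)
    sum(lab$labels[, , k] == codes[["silver"]]))
  fr <- slice_volume_fraction(lab)
  expect_identical(as.integer(round(fr * d[1] * d[2])),
                   as.integer(truth_counts))
  # counting conservation: fractions recombine to the exact voxel count
  prof <- occlusion_profile(lab)
  expect_identical(prof$slice_silver_counts, as.integer(truth_counts))
  expect_equal(sum(prof$slice_fractions * prof$slice_pixels),
               as.numeric(prof$silver_voxel_count), tolerance = 1e-12)
  expect_identical(prof$silver_voxel_count,
                   ph$truth$silver_voxel_count)
})

test_that("silver percentage reproduces the worked examples", {
  expect_equal(format_percent(silver_percentage(4.8, 761)), "0.63%")
  expect_equal(format_percent(silver_percentage(6.9, 410)), "1.68%")
  expect_equal(format_percent(silver_percentage(0, 761)), "0.00%")
  expect_error(silver_percentage(1, 0), "undefined")
})

test_that("penetration depth handles degenerate concentrations", {
  codes <- material_codes()
  lab <- array(codes[["dentin"]], dim = c(10, 10, 30))
  lab[5, 5, 30] <- codes[["silver"]]
  prof <- occlusion_profile(label_volume(lab, 128))
  dq <- penetration_depth(prof, c(0.1, 0.5, 1))
  expect_equal(dq$depth_um, rep(0.128, 3))
  empty <- array(codes[["dentin"]], dim = c(6, 6, 6))
  eprof <- occlusion_profile(label_volume(empty, 128))
  expect_error(penetration_depth(eprof), "no silver")
  expect_error(penetration_depth(prof, 0), "quantiles")
})

test_that("uniform silver over the top N slices has median depth N/2", {
  codes <- material_codes()
  N <- 10
  lab <- array(codes[["dentin"]], dim = c(12, 12, 40))
  for (k in seq(40 - N + 1, 40)) lab[6, 6, k] <- codes[["silver"]]
  prof <- occlusion_profile(label_volume(lab, 128))
  dq <- penetration_depth(prof, 0.5)
  expect_equal(dq$n_slices, ceiling(N / 2))
  expect_equal(dq$depth_um, ceiling(N / 2) * 0.128)
})

test_that("exponential-decay phantoms recover the decay length", {
  L <- 3
  depths <- sapply(1:5, function(seed) {
    spec <- phantom_spec(shape_voxels = c(96, 96, 200), n_tubules = 4,
                         cone_tip_radius_um = 5.2, cone_base_radius_um = 5.8,
                         cone_height_um = 25,
                         tubule_diameter_range_um = c(2.9, 3.5),
                         tubule_tilt_max_deg = 1,
                         silver_particle_radius_range_um = c(0.2, 0.35),
                         silver_fill_fraction = 0.015,
                         silver_decay_length_um = L, seed = seed)
    ph <- generate_phantom(spec)
    penetration_depth(occlusion_profile(ph$truth$labels), 0.63)$depth_um
  })
  expect_lt(abs(mean(depths) - L) / L, 0.2)
})

test_that("depth quantiles are monotone in q", {
  spec <- cylinder_spec(n_tubules = 2, silver_fill_fraction = 0.02,
                        silver_decay_length_um = 4, seed = 67)
  ph <- generate_phantom(spec)
  dq <- penetration_depth(occlusion_profile(ph$truth$labels),
                          seq(0.1, 1, by = 0.1))
  expect_true(all(diff(dq$depth_um) >= 0))
})

test_that("silver percent is invariant under enclosing crops", {
  spec <- cylinder_spec(shape = c(64, 64, 120), n_tubules = 1,
                        silver_fill_fraction = 0.03,
                        silver_decay_length_um = 5, seed = 71)
  ph <- generate_phantom(spec)
  lab <- ph$truth$labels
  full <- occlusion_profile(lab)
  codes <- material_codes()
  keep <- lab$labels == codes[["lumen"]] | lab$labels == codes[["silver"]]
  idx <- which(keep, arr.ind = TRUE)
  box <- c(min(idx[, 1]) - 1, max(idx[, 1]), min(idx[, 2]) - 1,
           max(idx[, 2]), min(idx[, 3]) - 1, max(idx[, 3]))
  cropped <- occlusion_profile(crop_interior(lab, box))
  expect_equal(cropped$silver_percent, full$silver_percent)
})

test_that("profiles of two decay lengths order as expected", {
  mk <- function(L, seed) {
    spec <- cylinder_spec(n_tubules = 2, silver_fill_fraction = 0.02,
                          silver_particle_radius_range_um = c(0.2, 0.4),
                          silver_decay_length_um = L, seed = seed)
    occlusion_profile(generate_phantom(spec)$truth$labels)
  }
  shallow <- mk(2, 81)
  deep <- mk(10, 81)
  cmp <- compare_profiles(shallow, deep, quantiles = 0.5)
  expect_false(any(cmp$undefined_depth))
  expect_lt(cmp$depth$depth_a_um, cmp$depth$depth_b_um)
  # self-comparison has zero differences
  self <- compare_profiles(shallow, shallow)
  expect_true(all(self$depth$difference_um == 0))
  expect_equal(unname(diff(self$silver_percent)), 0)
})

test_that("comparing against an empty-silver profile flags it", {
  codes <- material_codes()
  lab <- array(codes[["dentin"]], dim = c(10, 10, 10))
  empty <- occlusion_profile(label_volume(lab, 128))
  lab[5, 5, 9] <- codes[["silver"]]
  some <- occlusion_profile(label_volume(lab, 128))
  cmp <- compare_profiles(some, empty)
  expect_identical(unname(cmp$undefined_depth), c(FALSE, TRUE))
  expect_true(all(is.na(cmp$depth$depth_b_um)))
  other <- occlusion_profile(label_volume(lab, 64))
  expect_error(compare_profiles(some, other), "voxel")
})

test_that("segmentation recovers the phantom silver percentage", {
  # noiseless, mid-gap manual thresholds: exact recovery
  spec <- cylinder_spec(shape = c(72, 72, 140), n_tubules = 2,
                        silver_fill_fraction = 0.04,
                        silver_decay_length_um = 6, seed = 91)
  ph <- generate_phantom(spec)
  seg <- threshold_segment(ph$volume, segmentation_params(
    median_radius_voxels = 0, threshold_lumen_dentin = 0.25,
    threshold_dentin_silver = 0.75))
  truth_pct <- 100 * ph$truth$silver_voxel_count /
    ph$truth$tubule_voxel_count
  est <- occlusion_profile(seg)$silver_percent
  expect_lt(abs(est - truth_pct) / truth_pct, 0.01)
  # noisy, auto thresholds: within 15% relative over 5 seeds
  rel <- sapply(1:5, function(seed) {
    spec <- cylinder_spec(shape = c(72, 72, 140), n_tubules = 2,
                          silver_fill_fraction = 0.04,
                          silver_decay_length_um = 6,
                          noise_sigma = 0.05, seed = 90 + seed)
    ph <- generate_phantom(spec)
    seg <- threshold_segment(ph$volume,
                             segmentation_params(median_radius_voxels = 1))
    truth_pct <- 100 * ph$truth$silver_voxel_count /
      ph$truth$tubule_voxel_count
    abs(occlusion_profile(seg)$silver_percent - truth_pct) / truth_pct
  })
  expect_true(all(rel < 0.15))
})
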