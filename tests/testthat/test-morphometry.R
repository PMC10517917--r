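test_that("non-touching phantom tubules map to one component each", {
  spec <- phantom_spec(shape_voxels = c(128, 128, 96), n_tubules = 5,
                       tubule_diameter_range_um = c(2.9, 3.2),
                       cone_tip_radius_um = 7, cone_base_radius_um = 7.5,
                       cone_height_um = 11.5,
                       silver_fill_fraction = 0.02,
                       silver_decay_length_um = 50, seed = 41)
  ph <- generate_phantom(spec)
  expect_identical(nrow(ph$truth$tubule_registry), 5L)
  m <- label_tubules(ph$truth$labels)
  expect_identical(nrow(m$stats), 5L)
  # partition property: per-tubule counts add up to the tubule-region total
  counts <- label_counts(ph$truth$labels)
  expect_identical(sum(m$stats$voxel_count),
                   unname(counts[["lumen"]] + counts[["silver"]]))
  expect_equal(m$stats$volume_um3,
               m$stats$voxel_count * voxel_volume_um3(ph$truth$labels))
})

test_that("an empty label volume yields an empty tubule list", {
  lab <- label_volume(array(material_codes()[["dentin"]],
                            dim = c(8, 8, 8)), 128)
  m <- label_tubules(lab)
  expect_identical(nrow(m$stats), 0L)
  expect_true(all(m$components == 0))
})

test_that("tubules merged by a silver bridge form one component", {
  codes <- material_codes()
  lab <- array(codes[["dentin"]], dim = c(24, 24, 20))
  lab[8, 8, ] <- codes[["lumen"]]
  lab[16, 16, ] <- codes[["lumen"]]
  two <- label_tubules(label_volume(lab, 128))
  expect_identical(nrow(two$stats), 2L)
  lab[9:15, 9:15, 10] <- codes[["silver"]]  # diagonal silver bridge
  one <- label_tubules(label_volume(lab, 128))
  expect_identical(nrow(one$stats), 1L)
})

test_that("crack voxels are excluded from the tubule region", {
  codes <- material_codes()
  lab <- array(codes[["dentin"]], dim = c(20, 20, 20))
  lab[5:15, 5:15, 10] <- codes[["crack"]]
  lab[10, 10, ] <- codes[["lumen"]]
  m <- label_tubules(label_volume(lab, 128))
  expect_identical(nrow(m$stats), 1L)
  expect_identical(sum(m$stats$voxel_count), 20L)
})

test_that("inscribed-sphere diameter recovers digitized cylinders", {
  lab <- cylinder_labels(n = 48, nz = 40, diameter_vox = 30)
  mask <- lab == material_codes()[["lumen"]]
  d_um <- estimate_diameter(mask, voxel_size_nm = 128)
  expect_lt(abs(d_um / 0.128 - 30), 2)
  # single-voxel component has a one-voxel diameter
  single <- array(FALSE, dim = c(9, 9, 9))
  single[5, 5, 5] <- TRUE
  expect_equal(estimate_diameter(single, 128), 0.128)
  expect_error(estimate_diameter(array(FALSE, dim = c(4, 4, 4))), "empty")
})

test_that("diameter is invariant under translation and axis permutation", {
  mk <- function(center) {
    arr <- array(FALSE, dim = c(40, 40, 30))
    r2 <- outer((seq_len(40) - center[1])^2, (seq_len(40) - center[2])^2,
                "+")
    for (k in 5:25) arr[, , k] <- r2 <= 8^2
    arr
  }
  d1 <- estimate_diameter(mk(c(20, 20)), 128)
  d2 <- estimate_diameter(mk(c(14, 26)), 128)
  expect_equal(d1, d2)
  arr <- mk(c(20, 20))
  expect_equal(estimate_diameter(aperm(arr, c(3, 1, 2)), 128), d1)
  expect_equal(estimate_diameter(aperm(arr, c(2, 3, 1)), 128), d1)
})

test_that("phantom tubule diameters are recovered within two voxels", {
  spec <- cylinder_spec(shape = c(72, 72, 160), n_tubules = 1,
                        tubule_diameter_range_um = c(4.5, 4.5),
                        tubule_tilt_max_deg = 0, seed = 43)
  ph <- generate_phantom(spec)
  m <- label_tubules(ph$truth$labels)
  expect_lt(abs(m$stats$max_diameter_um - 4.5), 0.26)
})

test_that("orientation recovers the axis of straight cylinders", {
  lab <- cylinder_labels(n = 40, nz = 60, diameter_vox = 16)
  ori <- estimate_orientation(lab == material_codes()[["lumen"]])
  expect_false(ori$degenerate)
  expect_lt(ori$tilt_deg, 1)
  expect_equal(sqrt(sum(ori$vector^2)), 1)
  expect_gte(ori$vector[3], 0)
})

test_that("a tilted phantom tubule's tilt is recovered within 3 degrees", {
  spec <- cylinder_spec(shape = c(96, 96, 160), n_tubules = 1,
                        tubule_diameter_range_um = c(3.5, 3.5),
                        tubule_tilt_max_deg = 10, seed = 47)
  ph <- generate_phantom(spec)
  reg <- ph$truth$tubule_registry
  true_tilt <- acos(reg$uz) * 180 / pi
  m <- label_tubules(ph$truth$labels)
  expect_lt(abs(m$stats$tilt_deg - true_tilt), 3)
})

test_that("an isotropic sphere is flagged as orientation-degenerate", {
  arr <- array(FALSE, dim = c(21, 21, 21))
  r2 <- outer(outer((1:21 - 11)^2, (1:21 - 11)^2, "+"), (1:21 - 11)^2, "+")
  arr[r2 <= 8^2] <- TRUE
  ori <- estimate_orientation(arr)
  expect_true(ori$degenerate)
  single <- estimate_orientation(matrix(c(3, 3, 3), ncol = 3))
  expect_true(single$degenerate)
  expect_equal(single$vector, c(0, 0, 1))
})

test_that("diameters and tilts are recovered across many random tubules", {
  dia_err <- c()
  tilt_err <- c()
  for (seed in 1:3) {
    spec <- phantom_spec(shape_voxels = c(160, 160, 96), n_tubules = 4,
                         tubule_diameter_range_um = c(2.9, 4.5),
                         tubule_tilt_max_deg = 8,
                         cone_tip_radius_um = 9, cone_base_radius_um = 9.6,
                         cone_height_um = 11.5,
                         silver_fill_fraction = 0, seed = 50 + seed)
    ph <- generate_phantom(spec)
    reg <- ph$truth$tubule_registry
    m <- label_tubules(ph$truth$labels)
    expect_identical(nrow(m$stats), nrow(reg))
    vs <- voxel_size_um(ph$truth$labels)
    # match estimated components to registry tubules by lateral centroid
    for (i in seq_len(nrow(m$stats))) {
      cx <- m$stats$centroid_x[i] * vs
      cy <- m$stats$centroid_y[i] * vs
      j <- which.min((reg$ax - cx)^2 + (reg$ay - cy)^2)
      dia_err <- c(dia_err, abs(m$stats$max_diameter_um[i] -
                                  reg$diameter_um[j]))
      tilt_err <- c(tilt_err, abs(m$stats$tilt_deg[i] -
                                    acos(reg$uz[j]) * 180 / pi))
    }
  }
  expect_gte(length(dia_err), 10)
  expect_lte(mean(dia_err), 0.26)
  expect_lte(mean(tilt_err), 3)
})
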