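# Shared fixture builders. All phantoms are generated in code at test time.

# Desk-scale conical specimen.
small_spec <- function(...) {
  defaults <- list(shape_voxels = c(64, 64, 96), n_tubules = 1,
                   tubule_diameter_range_um = c(2.9, 3.3),
                   silver_fill_fraction = 0, seed = 1L)
  do.call(phantom_spec, utils::modifyList(defaults, list(...)))
}

# Near-cylindrical specimen whose tubules span the full height; used where a
# closed-form depth/volume oracle assumes full-height tubules.
cylinder_spec <- function(shape = c(72, 72, 200), ...) {
  vs <- 0.128
  defaults <- list(shape_voxels = shape, n_tubules = 2,
                   cone_tip_radius_um = 0.46 * min(shape[1:2]) * vs - 0.3,
                   cone_base_radius_um = 0.46 * min(shape[1:2]) * vs,
                   cone_height_um = 0.95 * shape[3] * vs,
                   tubule_diameter_range_um = c(2.9, 3.5),
                   tubule_tilt_max_deg = 2)
  do.call(phantom_spec, utils::modifyList(defaults, list(...)))
}

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# Per-class Dice between a truth label array and a segmentation, with truth
# cracks counted as lumen (cracks are air and threshold as lumen).
class_dice <- function(truth, seg) {
  codes <- material_codes()
  tr <- truth
  tr[tr == codes[["crack"]]] <- codes[["lumen"]]
  out <- c()
  for (cl in c("exterior", "dentin", "lumen", "silver")) {
    a <- tr == codes[[cl]]
    b <- seg == codes[[cl]]
    if (any(a) || any(b)) out[cl] <- dice(a, b)
  }
  out
}

# A solid digitized cylinder along z inside a dentin block, as a label array.
cylinder_labels <- function(n = 48, nz = 60, diameter_vox = 30,
                            center = c(n / 2, n / 2)) {
  codes <- material_codes()
  lab <- array(codes[["dentin"]], dim = c(n, n, nz))
  r2 <- outer((seq_len(n) - center[1])^2, (seq_len(n) - center[2])^2, "+")
  inside <- r2 <= (diameter_vox / 2)^2
  for (k in seq_len(nz)) {
    sl <- lab[, , k]
    sl[inside] <- codes[["lumen"]]
    lab[, , k] <- sl
  }
  lab
}

label_components <- function(mask) {
  array(tubulometry:::cpp_label3d(as.vector(mask), dim(mask), 26L),
        dim = dim(mask))
}
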