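# Synthetic conical dentin phantom with known ground truth.
#
# The phantom emulates a laser-machined conical dentin specimen pierced by
# near-vertical cylindrical tubules, with silver agglomerates deposited
# inside the tubules at a density that decays exponentially with depth below
# the top (application) surface. The top surface is the slice with the
# largest z index.

# Run code with a private RNG stream, restoring the caller's state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Phantom specification
#'
#' Parameters of the synthetic conical dentin specimen. Geometry defaults are
#' scaled versions of the reference specimen (a cone of ~300 um height with a
#' tip of ~50 um diameter): the cone is scaled uniformly so that it fills
#' ~92% of the grid. Tubule diameters default to the 2.9-4.5 um range
#' observed in dentin at this resolution.
#'
#' @param shape_voxels Integer vector (nx, ny, nz), the grid size.
#' @param voxel_size_nm Isotropic voxel size in nm (default 128, the
#'   reference instrument resolution at camera binning 2).
#' @param cone_tip_radius_um,cone_base_radius_um,cone_height_um Cone
#'   geometry in um; `NULL` means scale the reference cone (tip radius 25,
#'   base radius 75, height 300 um) to the grid.
#' @param n_tubules Number of tubules to place (non-negative).
#' @param tubule_diameter_range_um Length-2 numeric, min/max tubule diameter.
#' @param tubule_tilt_max_deg Maximum deviation of a tubule axis from the
#'   specimen z-axis, degrees.
#' @param silver_fill_fraction Target fraction of tubule bore volume occupied
#'   by silver, in `[0, 1)`.
#' @param silver_decay_length_um E-folding depth of the silver placement
#'   probability below the top surface.
#' @param silver_particle_radius_range_um Length-2 numeric, min/max silver
#'   particle radius in um.
#' @param n_cracks Number of horizontal crack artifacts for [add_cracks()].
#' @param crack_thickness_voxels Crack slab thickness in voxels.
#' @param attenuation Named numeric vector with entries `exterior`, `lumen`,
#'   `dentin`, `silver` (arbitrary units). Must satisfy
#'   lumen < dentin < silver strictly; only the ordering matters downstream.
#' @param noise_sigma Standard deviation of additive Gaussian noise.
#' @param seed Integer seed; generation is a pure function of the spec.
#' @return A `phantom_spec` object.
#' @export
#' @examples
#' spec <- phantom_spec(shape_voxels = c(64, 64, 96), n_tubules = 2)
#' spec$cone_height_um
phantom_spec <- function(shape_voxels = c(128, 128, 256),
                         voxel_size_nm = 128,
                         cone_tip_radius_um = NULL,
                         cone_base_radius_um = NULL,
                         cone_height_um = NULL,
                         n_tubules = 4,
                         tubule_diameter_range_um = c(2.9, 4.5),
                         tubule_tilt_max_deg = 5,
                         silver_fill_fraction = 0.02,
                         silver_decay_length_um = 5,
                         silver_particle_radius_range_um = c(0.3, 0.8),
                         n_cracks = 0,
                         crack_thickness_voxels = 2,
                         attenuation = c(exterior = 0, lumen = 0.05,
                                         dentin = 0.5, silver = 1.0),
                         noise_sigma = 0,
                         seed = 1L) {
  shape_voxels <- as.integer(shape_voxels)
  vs <- voxel_size_nm / 1000
  # Reference cone: height 300 um, tip radius 25 um, base radius 75 um.
  s <- min(0.92 * shape_voxels[3] * vs / 300,
           0.46 * min(shape_voxels[1:2]) * vs / 75)
  if (is.null(cone_height_um)) cone_height_um <- 300 * s
  if (is.null(cone_tip_radius_um)) cone_tip_radius_um <- 25 * s
  if (is.null(cone_base_radius_um)) cone_base_radius_um <- 75 * s
  spec <- structure(list(
    shape_voxels = shape_voxels,
    voxel_size_nm = as.numeric(voxel_size_nm),
    cone_tip_radius_um = cone_tip_radius_um,
    cone_base_radius_um = cone_base_radius_um,
    cone_height_um = cone_height_um,
    n_tubules = as.integer(n_tubules),
    tubule_diameter_range_um = as.numeric(tubule_diameter_range_um),
    tubule_tilt_max_deg = tubule_tilt_max_deg,
    silver_fill_fraction = silver_fill_fraction,
    silver_decay_length_um = silver_decay_length_um,
    silver_particle_radius_range_um =
      as.numeric(silver_particle_radius_range_um),
    n_cracks = as.integer(n_cracks),
    crack_thickness_voxels = as.integer(crack_thickness_voxels),
    attenuation = attenuation,
    noise_sigma = noise_sigma,
    seed = as.integer(seed)
  ), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

#' Validate a phantom specification
#' @param spec A `phantom_spec`.
#' @return Invisibly `TRUE`; stops with an informative error otherwise.
#' @export
validate_phantom_spec <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  sv <- spec$shape_voxels
  if (length(sv) != 3 || any(sv < 1)) stop("shape_voxels must be 3 positive integers")
  if (spec$voxel_size_nm <= 0) stop("voxel_size_nm must be positive")
  vs <- spec$voxel_size_nm / 1000
  r <- spec$tubule_diameter_range_um
  if (length(r) != 2 || r[1] > r[2]) {
    stop("tubule_diameter_range_um must be (low, high) with low <= high")
  }
  if (spec$n_tubules > 0 && r[1] <= 2 * vs) {
    stop("tubule diameters must exceed 2 voxel sizes to be resolvable")
  }
  att <- spec$attenuation
  need <- c("exterior", "lumen", "dentin", "silver")
  if (!all(need %in% names(att))) {
    stop("attenuation must name exterior, lumen, dentin, silver")
  }
  if (!(att[["lumen"]] < att[["dentin"]] && att[["dentin"]] < att[["silver"]])) {
    stop("attenuation ordering must be strict: lumen < dentin < silver")
  }
  if (spec$silver_fill_fraction < 0 || spec$silver_fill_fraction >= 1) {
    stop("silver_fill_fraction must be in [0, 1)")
  }
  if (spec$noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (any(c(spec$cone_tip_radius_um, spec$cone_base_radius_um,
            spec$cone_height_um) <= 0)) {
    stop("cone dimensions must be positive")
  }
  # geometry must fit the grid
  if (spec$cone_height_um > sv[3] * vs) {
    stop("geometry error: cone height ", spec$cone_height_um,
         " um exceeds grid height ", sv[3] * vs, " um")
  }
  if (2 * max(spec$cone_base_radius_um, spec$cone_tip_radius_um) >
      min(sv[1:2]) * vs) {
    stop("geometry error: cone radius exceeds the lateral grid extent")
  }
  invisible(TRUE)
}

# Cone geometry helper: axis center (um), z of base/top (um), and the radius
# at height z. The cone top sits 1% of the grid height below the top face.
cone_geometry <- function(spec) {
  sv <- spec$shape_voxels
  vs <- spec$voxel_size_nm / 1000
  z_top <- min(sv[3] * vs * 0.99, sv[3] * vs)
  z_top <- max(z_top, spec$cone_height_um)
  list(
    cx = sv[1] * vs / 2, cy = sv[2] * vs / 2,
    z_top = z_top, z_base = z_top - spec$cone_height_um,
    radius_at = function(z) {
      h <- (z - (z_top - spec$cone_height_um)) / spec$cone_height_um
      spec$cone_base_radius_um +
        h * (spec$cone_tip_radius_um - spec$cone_base_radius_um)
    }
  )
}

#' Generate a synthetic dentin phantom
#'
#' Builds a conical dentin specimen pierced by near-vertical cylindrical
#' tubules, deposits spherical silver particles inside the tubules with
#' per-particle acceptance probability `exp(-depth / silver_decay_length_um)`
#' (depth measured from the top surface), and returns the grayscale volume
#' (material attenuations plus optional Gaussian noise) together with the
#' ground truth. Identical specs (including seed) give bit-identical output.
#'
#' Tubules are clipped to the cone interior with a ~2 voxel dentin rim so
#' that every tubule cross-section is enclosed by dentin in its slice.
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `volume` (a [voxel_volume()]) and `truth`
#'   (a `phantom_truth`: `labels` ([label_volume()]), `tubule_registry`
#'   data frame, `tubule_id_map` integer array, `silver_voxel_count`,
#'   `tubule_voxel_count`, `warnings` character vector).
#' @export
#' @examples
#' ph <- generate_phantom(phantom_spec(shape_voxels = c(48, 48, 64),
#'                                     n_tubules = 1, seed = 7))
#' ph$truth$tubule_voxel_count
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  with_seed(spec$seed, generate_phantom_impl(spec))
}

generate_phantom_impl <- function(spec) {
  sv <- spec$shape_voxels
  nx <- sv[1]; ny <- sv[2]; nz <- sv[3]
  vs <- spec$voxel_size_nm / 1000
  geo <- cone_geometry(spec)
  codes <- material_codes()
  warnings <- character()

  xs <- (seq_len(nx) - 0.5) * vs
  ys <- (seq_len(ny) - 0.5) * vs
  zs <- (seq_len(nz) - 0.5) * vs

  # cone support: radial distance <= radius(z) within [z_base, z_top]
  r2_lat <- outer((xs - geo$cx)^2, (ys - geo$cy)^2, "+")  # nx x ny
  labels <- array(codes[["exterior"]], dim = sv)
  rad_z <- ifelse(zs >= geo$z_base & zs <= geo$z_top, geo$radius_at(zs), -1)
  for (k in seq_len(nz)) {
    if (rad_z[k] > 0) {
      sl <- labels[, , k]
      sl[r2_lat <= rad_z[k]^2] <- codes[["dentin"]]
      labels[, , k] <- sl
    }
  }

  # -- tubules: straight cylinders, small random tilt, clipped to the cone
  # eroded radially by 2 voxels so a dentin rim always remains.
  id_map <- array(0L, dim = sv)
  registry <- data.frame(id = integer(), ax = numeric(), ay = numeric(),
                         az = numeric(), ux = numeric(), uy = numeric(),
                         uz = numeric(), diameter_um = numeric(),
                         voxel_count = integer(), zmin_um = numeric(),
                         zmax_um = numeric())
  erode <- 2 * vs
  z_mid <- (geo$z_base + geo$z_top) / 2
  if (spec$n_tubules > 0) {
    anchors <- matrix(numeric(0), ncol = 2)
    diams <- numeric(0)
    placed <- 0L
    for (t in seq_len(spec$n_tubules)) {
      d <- runif(1, spec$tubule_diameter_range_um[1],
                 spec$tubule_diameter_range_um[2])
      ok <- FALSE
      for (attempt in 1:200) {
        rmax <- geo$radius_at(z_mid) - erode - d / 2
        if (rmax <= 0) { a <- c(geo$cx, geo$cy) } else {
          rr <- rmax * sqrt(runif(1)); th <- runif(1, 0, 2 * pi)
          a <- c(geo$cx + rr * cos(th), geo$cy + rr * sin(th))
        }
        if (nrow(anchors) == 0) { ok <- TRUE; break }
        sep <- sqrt((anchors[, 1] - a[1])^2 + (anchors[, 2] - a[2])^2)
        # margin includes the worst-case lateral drift of tilted axes over
        # the specimen height, so tubules cannot merge
        drift <- spec$cone_height_um *
          tan(spec$tubule_tilt_max_deg * pi / 180)
        if (all(sep >= (diams + d) / 2 + 3 * vs + drift)) { ok <- TRUE; break }
      }
      if (!ok) {
        warnings <- c(warnings, sprintf(
          "tubule %d could not be placed without overlap; skipped", t))
        next
      }
      placed <- placed + 1L
      anchors <- rbind(anchors, a)
      diams <- c(diams, d)
      tilt <- runif(1, 0, spec$tubule_tilt_max_deg) * pi / 180
      az_ang <- runif(1, 0, 2 * pi)
      u <- c(sin(tilt) * cos(az_ang), sin(tilt) * sin(az_ang), cos(tilt))
      anchor <- c(a[1], a[2], z_mid)
      res <- rasterize_tubule(labels, id_map, placed, anchor, u, d / 2,
                              xs, ys, zs, geo, erode, codes)
      labels <- res$labels; id_map <- res$id_map
      if (res$count == 0) {
        warnings <- c(warnings, sprintf("tubule %d has zero voxels", placed))
      }
      registry <- rbind(registry, data.frame(
        id = placed, ax = anchor[1], ay = anchor[2], az = anchor[3],
        ux = u[1], uy = u[2], uz = u[3], diameter_um = d,
        voxel_count = res$count, zmin_um = res$zmin, zmax_um = res$zmax))
    }
  }
  tubule_voxel_count <- sum(registry$voxel_count)

  # -- silver: spheres inside tubule lumens, exponential depth decay
  silver_count <- 0L
  target <- round(spec$silver_fill_fraction * tubule_voxel_count)
  if (target > 0 && tubule_voxel_count > 0) {
    L <- spec$silver_decay_length_um
    pr <- spec$silver_particle_radius_range_um
    max_attempts <- 20000L
    attempts <- 0L
    probs <- registry$voxel_count / sum(registry$voxel_count)
    while (silver_count < target && attempts < max_attempts) {
      attempts <- attempts + 1L
      k <- sample.int(nrow(registry), 1, prob = probs)
      row <- registry[k, ]
      z_c <- runif(1, row$zmin_um, row$zmax_um)
      depth <- geo$z_top - z_c
      if (runif(1) > exp(-depth / L)) next
      r_part <- runif(1, pr[1], pr[2])
      # axis point at that height plus a radial offset inside the bore
      u <- c(row$ux, row$uy, row$uz)
      axis_pt <- c(row$ax, row$ay, row$az) + u * ((z_c - row$az) / u[3])
      slack <- row$diameter_um / 2 - r_part
      if (slack > 0) {
        b1 <- c(-u[3], 0, u[1]); b1 <- b1 / sqrt(sum(b1^2))
        b2 <- c(u[2] * b1[3] - u[3] * b1[2],
                u[3] * b1[1] - u[1] * b1[3],
                u[1] * b1[2] - u[2] * b1[1])
        rr <- slack * sqrt(runif(1)); th <- runif(1, 0, 2 * pi)
        axis_pt <- axis_pt + rr * (cos(th) * b1 + sin(th) * b2)
      }
      res <- rasterize_sphere(labels, axis_pt, r_part, xs, ys, zs, codes)
      labels <- res$labels
      silver_count <- silver_count + res$count
    }
    if (silver_count < target) {
      warnings <- c(warnings, sprintf(
        paste0("silver_fill_fraction %.3g unreachable: placed %d of %d ",
               "target voxels in %d attempts"),
        spec$silver_fill_fraction, silver_count, target, attempts))
    }
  }

  gray <- attenuation_image(labels, spec$attenuation)
  if (spec$noise_sigma > 0) {
    gray <- gray + array(rnorm(length(gray), 0, spec$noise_sigma), dim = sv)
  }

  truth <- structure(list(
    labels = label_volume(labels, spec$voxel_size_nm,
                          provenance = list(source = "phantom",
                                            seed = spec$seed)),
    tubule_registry = registry,
    tubule_id_map = id_map,
    silver_voxel_count = as.integer(silver_count),
    tubule_voxel_count = as.integer(tubule_voxel_count),
    warnings = warnings
  ), class = "phantom_truth")
  list(volume = voxel_volume(gray, spec$voxel_size_nm), truth = truth)
}

# Map labels to attenuation values (crack voxels take the lumen value: a
# crack is an air-filled gap).
attenuation_image <- function(labels, attenuation) {
  codes <- material_codes()
  lut <- numeric(max(codes) + 1L)
  lut[codes[["exterior"]] + 1L] <- attenuation[["exterior"]]
  lut[codes[["dentin"]] + 1L] <- attenuation[["dentin"]]
  lut[codes[["lumen"]] + 1L] <- attenuation[["lumen"]]
  lut[codes[["silver"]] + 1L] <- attenuation[["silver"]]
  lut[codes[["crack"]] + 1L] <- attenuation[["lumen"]]
  array(lut[labels + 1L], dim = dim(labels))
}

# Carve one cylindrical tubule into `labels` (dentin -> lumen) within the
# radially eroded cone. Works on a bounding box for speed.
rasterize_tubule <- function(labels, id_map, id, anchor, u, radius,
                             xs, ys, zs, geo, erode, codes) {
  vs <- xs[2] - xs[1]
  nz <- length(zs)
  # lateral reach: radius + axial excursion over the full height
  span <- radius + abs(zs[nz] - zs[1]) * sqrt(1 - u[3]^2) / u[3] + 2 * vs
  ix <- which(xs >= anchor[1] - span & xs <= anchor[1] + span)
  iy <- which(ys >= anchor[2] - span & ys <= anchor[2] + span)
  iz <- which(zs >= geo$z_base & zs <= geo$z_top)
  if (!length(ix) || !length(iy) || !length(iz)) {
    return(list(labels = labels, id_map = id_map, count = 0L,
                zmin = anchor[3], zmax = anchor[3]))
  }
  px <- xs[ix] - anchor[1]; py <- ys[iy] - anchor[2]; pz <- zs[iz] - anchor[3]
  nxb <- length(ix); nyb <- length(iy); nzb <- length(iz)
  PX <- array(px, dim = c(nxb, nyb, nzb))
  PY <- array(rep(py, each = nxb), dim = c(nxb, nyb, nzb))
  PZ <- array(rep(pz, each = nxb * nyb), dim = c(nxb, nyb, nzb))
  tt <- PX * u[1] + PY * u[2] + PZ * u[3]
  d2 <- PX^2 + PY^2 + PZ^2 - tt^2
  # eroded cone test
  cone_r <- pmax(geo$radius_at(zs[iz]) - erode, 0)
  CR <- array(rep(cone_r, each = nxb * nyb), dim = c(nxb, nyb, nzb))
  RX <- array(xs[ix] - geo$cx, dim = c(nxb, nyb, nzb))
  RY <- array(rep(ys[iy] - geo$cy, each = nxb), dim = c(nxb, nyb, nzb))
  inside <- d2 <= radius^2 & (RX^2 + RY^2) <= CR^2 &
    labels[ix, iy, iz, drop = FALSE] == codes[["dentin"]]
  cnt <- sum(inside)
  zmin <- anchor[3]; zmax <- anchor[3]
  if (cnt > 0) {
    sub <- labels[ix, iy, iz, drop = FALSE]
    sub[inside] <- codes[["lumen"]]
    labels[ix, iy, iz] <- sub
    subid <- id_map[ix, iy, iz, drop = FALSE]
    subid[inside] <- as.integer(id)
    id_map[ix, iy, iz] <- subid
    kz <- which(apply(inside, 3, any))
    zmin <- zs[iz[min(kz)]]; zmax <- zs[iz[max(kz)]]
  }
  list(labels = labels, id_map = id_map, count = as.integer(cnt),
       zmin = zmin, zmax = zmax)
}

# Convert lumen voxels inside a sphere to silver; returns converted count.
rasterize_sphere <- function(labels, center, radius, xs, ys, zs, codes) {
  ix <- which(xs >= center[1] - radius & xs <= center[1] + radius)
  iy <- which(ys >= center[2] - radius & ys <= center[2] + radius)
  iz <- which(zs >= center[3] - radius & zs <= center[3] + radius)
  if (!length(ix) || !length(iy) || !length(iz)) {
    return(list(labels = labels, count = 0L))
  }
  nxb <- length(ix); nyb <- length(iy); nzb <- length(iz)
  PX <- array(xs[ix] - center[1], dim = c(nxb, nyb, nzb))
  PY <- array(rep(ys[iy] - center[2], each = nxb), dim = c(nxb, nyb, nzb))
  PZ <- array(rep(zs[iz] - center[3], each = nxb * nyb),
              dim = c(nxb, nyb, nzb))
  sub <- labels[ix, iy, iz, drop = FALSE]
  inside <- (PX^2 + PY^2 + PZ^2) <= radius^2 & sub == codes[["lumen"]]
  cnt <- sum(inside)
  if (cnt > 0) {
    sub[inside] <- codes[["silver"]]
    labels[ix, iy, iz] <- sub
  }
  list(labels = labels, count = as.integer(cnt))
}

#' Insert horizontal crack artifacts
#'
#' Adds `spec$n_cracks` thin near-horizontal air-filled slabs through the
#' dentin, emulating the cracks introduced by specimen preparation. Cracks
#' are internal delaminations: they stop ~2 voxels short of the cone
#' surface, leaving a connecting dentin rim (a fully severed specimen could
#' not hold together). Crack voxels replace dentin only (tubule lumen and
#' silver are untouched), are labeled with the distinct `crack` class in the
#' truth, and take the lumen attenuation in the grayscale volume.
#'
#' @param volume The phantom [voxel_volume()].
#' @param truth The matching `phantom_truth`.
#' @param spec The [phantom_spec()] used to generate the phantom.
#' @param z_slices Optional integer vector of bottom slice indices for the
#'   cracks (1-based); by default positions are drawn reproducibly from the
#'   middle of the cone.
#' @return A list `(volume, truth)` with cracks inserted.
#' @export
add_cracks <- function(volume, truth, spec, z_slices = NULL) {
  stopifnot(inherits(volume, "voxel_volume"), inherits(truth, "phantom_truth"))
  n <- spec$n_cracks
  if (!is.null(z_slices)) n <- length(z_slices)
  if (n == 0) return(list(volume = volume, truth = truth))
  vs <- spec$voxel_size_nm / 1000
  thick <- spec$crack_thickness_voxels
  if (thick * vs >= spec$cone_height_um) {
    stop("crack thickness (", thick, " voxels) must be smaller than the ",
         "specimen height")
  }
  geo <- cone_geometry(spec)
  nz <- dim(volume)[3]
  codes <- material_codes()
  if (is.null(z_slices)) {
    k_lo <- max(1L, ceiling(geo$z_base / vs) + floor(0.2 * spec$cone_height_um / vs))
    k_hi <- min(nz - thick + 1L,
                floor(geo$z_top / vs) - floor(0.2 * spec$cone_height_um / vs))
    z_slices <- with_seed((spec$seed + 77777L) %% 2147483647L,
                          sample(seq(k_lo, k_hi), n, replace = FALSE))
  }
  gray <- volume$data
  labels <- truth$labels$labels
  lum_att <- spec$attenuation[["lumen"]]
  sv <- dim(volume)
  xs <- (seq_len(sv[1]) - 0.5) * vs
  ys <- (seq_len(sv[2]) - 0.5) * vs
  r2_lat <- outer((xs - geo$cx)^2, (ys - geo$cy)^2, "+")
  for (k0 in z_slices) {
    ks <- seq(k0, min(k0 + thick - 1L, nz))
    sub <- labels[, , ks, drop = FALSE]
    # delaminate inside the cone only, keeping a ~2 voxel dentin rim
    rim <- vapply(ks, function(k) {
      z <- (k - 0.5) * vs
      if (z < geo$z_base || z > geo$z_top) return(-1)
      max(geo$radius_at(z) - 2 * vs, 0)
    }, numeric(1))
    inner <- array(FALSE, dim = dim(sub))
    for (i in seq_along(ks)) {
      if (rim[i] > 0) inner[, , i] <- r2_lat <= rim[i]^2
    }
    hit <- sub == codes[["dentin"]] & inner
    if (!any(hit)) next
    sub[hit] <- codes[["crack"]]
    labels[, , ks] <- sub
    g <- gray[, , ks, drop = FALSE]
    vals <- rep(lum_att, sum(hit))
    if (spec$noise_sigma > 0) {
      vals <- vals + with_seed((spec$seed + 88888L + k0) %% 2147483647L,
                               rnorm(sum(hit), 0, spec$noise_sigma))
    }
    g[hit] <- vals
    gray[, , ks] <- g
  }
  truth$labels <- label_volume(labels, spec$voxel_size_nm,
                               provenance = truth$labels$provenance)
  list(volume = voxel_volume(gray, spec$voxel_size_nm), truth = truth)
}
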