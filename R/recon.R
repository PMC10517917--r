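# Idealized parallel-beam absorption imaging and filtered back-projection.
#
# The real instrument is a full-field zone-plate X-ray microscope; here the
# acquisition is modeled as monochromatic parallel-beam absorption: each
# z-slice is projected independently at equally spaced angles over [0, 180).
# Line integrals are expressed in attenuation x voxel-length units so that
# reconstruction recovers the per-voxel attenuation directly.

#' Parallel-beam sinogram set
#'
#' @param data Numeric array `n_angles x detector_width x nz` of line
#'   integrals.
#' @param angles_deg Strictly increasing projection angles in `[0, 180)`.
#' @param voxel_size_nm Isotropic voxel size of the projected volume.
#' @param orig_shape Integer (nx, ny, nz) of the source volume, used to size
#'   the reconstruction grid.
#' @param source_energy_keV Beam energy metadata (default 5.4, a chromium
#'   source).
#' @return A `sinogram_set` object.
#' @export
sinogram_set <- function(data, angles_deg, voxel_size_nm, orig_shape,
                         source_energy_keV = 5.4) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (length(angles_deg) != dim(data)[1]) {
    stop("n_angles must equal length(angles_deg)")
  }
  if (is.unsorted(angles_deg, strictly = TRUE) ||
      any(angles_deg < 0 | angles_deg >= 180)) {
    stop("angles_deg must be strictly increasing within [0, 180)")
  }
  if (!all(is.finite(data))) stop("sinogram contains non-finite values")
  structure(list(data = data, angles_deg = as.numeric(angles_deg),
                 voxel_size_nm = as.numeric(voxel_size_nm),
                 orig_shape = as.integer(orig_shape),
                 source_energy_keV = source_energy_keV),
            class = "sinogram_set")
}

#' @export
print.sinogram_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<sinogram_set> %d angles x %d detector bins x %d slices @ %g nm\n",
              d[1], d[2], d[3], x$voxel_size_nm))
  invisible(x)
}

#' Simulate parallel-beam projections
#'
#' Computes, for each z-slice independently, parallel-beam line integrals at
#' `n_angles` equally spaced angles over `[0, 180)` degrees. The default
#' matches the reference acquisition protocol (901 projections over 180
#' degrees). Rays are sampled at unit voxel steps with bilinear
#' interpolation, so for each slice and angle the projection sums to the
#' slice attenuation sum up to interpolation error.
#'
#' @param volume A [voxel_volume()].
#' @param n_angles Number of projection angles (>= 1, default 901).
#' @return A [sinogram_set()].
#' @export
#' @examples
#' v <- voxel_volume(array(0, dim = c(16, 16, 2)))
#' s <- forward_project(v, n_angles = 10)
#' all(s$data == 0)
forward_project <- function(volume, n_angles = 901) {
  stopifnot(inherits(volume, "voxel_volume"))
  n_angles <- as.integer(n_angles)
  if (n_angles < 1) stop("n_angles must be >= 1")
  if (!all(is.finite(volume$data))) stop("volume contains non-finite voxels")
  d <- dim(volume)
  dw <- 2L * as.integer(floor(sqrt(d[1]^2 + d[2]^2) / 2)) + 1L
  angles_deg <- seq(0, 180, length.out = n_angles + 1L)[seq_len(n_angles)]
  angles_rad <- angles_deg * pi / 180
  sino <- array(0, dim = c(n_angles, dw, d[3]))
  for (k in seq_len(d[3])) {
    sino[, , k] <- cpp_radon_slice(volume$data[, , k], angles_rad, dw)
  }
  sinogram_set(sino, angles_deg, volume$voxel_size_nm, d)
}

# Ramp filter built from its spatial-domain kernel (avoids the DC bias of a
# naively sampled |f|), optionally windowed.
fbp_filter <- function(npad, filter_name) {
  n <- npad
  h <- numeric(n)
  h[1] <- 0.25
  k <- seq_len(n / 2)
  odd <- k[k %% 2 == 1]
  h[1 + odd] <- -1 / (pi^2 * odd^2)
  h[n + 1 - odd] <- -1 / (pi^2 * odd^2)
  ramp <- 2 * Re(stats::fft(h))
  f <- c(seq(0, n / 2), seq(n / 2 - 1, 1)) / (n / 2)  # |freq| / Nyquist
  win <- switch(filter_name,
    "ramp" = rep(1, n),
    "shepp-logan" = { w <- rep(1, n); nz <- f > 0
                      w[nz] <- sin(pi * f[nz] / 2) / (pi * f[nz] / 2); w },
    "hann" = (1 + cos(pi * f)) / 2,
    stop("unknown filter '", filter_name,
         "'; available: ramp, shepp-logan, hann")
  )
  ramp * win
}

#' Filtered back-projection reconstruction
#'
#' Slice-wise filtered back-projection: each projection is frequency-filtered
#' (ramp, optionally windowed) and smeared back across the slice at its
#' acquisition angle with linear interpolation. The rotation center is the
#' grid center. The output grid matches the shape of the projected volume.
#'
#' @param sino A [sinogram_set()].
#' @param filter_name One of `"ramp"`, `"shepp-logan"`, `"hann"`.
#' @return A [voxel_volume()] of reconstructed attenuation values.
#' @export
fbp_reconstruct <- function(sino, filter_name = c("ramp", "shepp-logan",
                                                  "hann")) {
  stopifnot(inherits(sino, "sinogram_set"))
  filter_name <- match.arg(filter_name)
  d <- dim(sino$data)
  na <- d[1]; dw <- d[2]; nz <- d[3]
  if (na == 0) stop("sinogram has zero angles")
  shape <- sino$orig_shape
  angles_rad <- sino$angles_deg * pi / 180
  npad <- 2^ceiling(log2(2 * dw))
  filt <- fbp_filter(npad, filter_name)
  out <- array(0, dim = shape)
  for (k in seq_len(nz)) {
    proj <- sino$data[, , k, drop = TRUE]
    if (na == 1) proj <- matrix(proj, nrow = 1)
    padded <- matrix(0, na, npad)
    padded[, seq_len(dw)] <- proj
    ft <- t(apply(padded, 1, function(row) {
      Re(stats::fft(stats::fft(row) * filt, inverse = TRUE)) / npad
    }))
    fproj <- ft[, seq_len(dw), drop = FALSE]
    bp <- cpp_backproject_slice(fproj, angles_rad, shape[1], shape[2])
    out[, , k] <- bp * pi / (2 * na)
  }
  voxel_volume(out, sino$voxel_size_nm)
}
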