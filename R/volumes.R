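# Core containers: grayscale voxel volumes and material label volumes.
# All volumes are 3D arrays indexed (x, y, z); z is the specimen axis and the
# slice with the LARGEST z index is the treatment-application (top) surface.

#' Material label codes
#'
#' Integer codes used in [label_volume()] arrays: exterior (outside the
#' specimen), dentin matrix, tubule lumen (air), silver deposit, and crack
#' (preparation artifact).
#'
#' @return Named integer vector mapping material name to code.
#' @export
#' @examples
#' material_codes()
material_codes <- function() {
  c(exterior = 0L, dentin = 1L, lumen = 2L, silver = 3L, crack = 4L)
}

#' Grayscale voxel volume
#'
#' A 3D scalar attenuation grid with isotropic voxel spacing, either
#' reconstructed from projections or produced by [generate_phantom()].
#'
#' @param data Numeric 3D array (x, y, z); all values must be finite.
#' @param voxel_size_nm Isotropic voxel edge length in nanometres (the
#'   reference instrument acquires at 128 nm).
#' @return A `voxel_volume` object.
#' @export
voxel_volume <- function(data, voxel_size_nm = 128) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (!all(is.finite(data))) stop("voxel volume contains non-finite values")
  if (!is.numeric(voxel_size_nm) || length(voxel_size_nm) != 1 ||
      voxel_size_nm <= 0) {
    stop("voxel_size_nm must be a single positive number")
  }
  structure(list(data = data, voxel_size_nm = as.numeric(voxel_size_nm)),
            class = "voxel_volume")
}

#' Material label volume
#'
#' @param labels Integer 3D array of material codes (see [material_codes()]).
#' @param voxel_size_nm Isotropic voxel edge length in nanometres.
#' @param provenance Optional list recording how the labels were produced
#'   (segmentation parameters, source volume id, chosen thresholds).
#' @return A `label_volume` object.
#' @export
label_volume <- function(labels, voxel_size_nm = 128, provenance = list()) {
  stopifnot(is.array(labels), length(dim(labels)) == 3)
  storage.mode(labels) <- "integer"
  known <- material_codes()
  bad <- setdiff(unique(as.vector(labels)), unname(known))
  if (length(bad) > 0) {
    stop("unknown label codes: ", paste(bad, collapse = ", "))
  }
  structure(list(labels = labels, voxel_size_nm = as.numeric(voxel_size_nm),
                 provenance = provenance),
            class = "label_volume")
}

#' @export
dim.voxel_volume <- function(x) dim(x$data)

#' @export
dim.label_volume <- function(x) dim(x$labels)

#' Voxel edge length in micrometres
#' @param x A `voxel_volume` or `label_volume`.
#' @return Scalar voxel size in um.
#' @export
voxel_size_um <- function(x) x$voxel_size_nm / 1000

#' Volume of one voxel in cubic micrometres
#' @param x A `voxel_volume` or `label_volume`.
#' @return Scalar voxel volume in um^3.
#' @export
voxel_volume_um3 <- function(x) (x$voxel_size_nm / 1000)^3

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<voxel_volume> %d x %d x %d voxels @ %g nm (%.1f x %.1f x %.1f um)\n",
              d[1], d[2], d[3], x$voxel_size_nm,
              d[1] * voxel_size_um(x), d[2] * voxel_size_um(x),
              d[3] * voxel_size_um(x)))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<label_volume> %d x %d x %d voxels @ %g nm\n",
              d[1], d[2], d[3], x$voxel_size_nm))
  counts <- label_counts(x)
  for (nm in names(counts)) {
    if (counts[[nm]] > 0) cat(sprintf("  %-9s %d\n", nm, counts[[nm]]))
  }
  invisible(x)
}

#' Count voxels per material class
#' @param labels A `label_volume`.
#' @return Named integer vector, one entry per material in
#'   [material_codes()].
#' @export
label_counts <- function(labels) {
  stopifnot(inherits(labels, "label_volume"))
  codes <- material_codes()
  tab <- tabulate(as.vector(labels$labels) + 1L, nbins = max(codes) + 1L)
  stats::setNames(tab[codes + 1L], names(codes))
}

check_same_geometry <- function(a, b) {
  if (!isTRUE(all.equal(a$voxel_size_nm, b$voxel_size_nm))) {
    stop("voxel sizes differ (", a$voxel_size_nm, " vs ", b$voxel_size_nm,
         " nm)")
  }
  if (!identical(dim(a), dim(b))) stop("volume shapes differ")
  invisible(TRUE)
}
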