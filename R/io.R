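# Volume I/O. Two interchange formats, both with a JSON sidecar carrying the
# voxel size and axis convention (quantification in um is meaningless
# without them):
#   - TIFF stacks (one page per z-slice): 32-bit float for grayscale
#     (intensities affinely packed into [0, 1]; offset/scale recorded in the
#     sidecar), 8-bit for labels with a label legend. The microscopy-world
#     format; grayscale round trips at float32 precision.
#   - Raw little-endian float64 + sidecar: bit-exact round trips.

sidecar_path <- function(path) paste0(path, ".json")

write_sidecar <- function(path, meta) {
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}

read_sidecar <- function(path, required = character()) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) {
    stop("missing sidecar '", sp, "'; cannot interpret the volume ",
         "(required fields: ", paste(c("voxel_size_nm", required),
                                     collapse = ", "), ")")
  }
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  for (f in c("voxel_size_nm", required)) {
    if (is.null(meta[[f]])) {
      stop("sidecar '", sp, "' is missing required field '", f, "'")
    }
  }
  if (!is.null(meta$voxel_size_um) || isTRUE(meta$anisotropic)) {
    stop("anisotropic voxel spacing is not supported")
  }
  meta
}

#' Write a grayscale volume
#'
#' @param volume A [voxel_volume()].
#' @param path Output file path. A JSON sidecar `<path>.json` is written
#'   alongside.
#' @param format `"tiff"` (32-bit float pages, intensities affinely packed
#'   into `[0, 1]`) or `"raw"` (little-endian float64, bit-exact).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, format = c("tiff", "raw")) {
  stopifnot(inherits(volume, "voxel_volume"))
  format <- match.arg(format)
  d <- dim(volume)
  meta <- list(kind = "voxel_volume", format = format, shape = d,
               voxel_size_nm = volume$voxel_size_nm,
               axis_convention = "z is the specimen axis; the top (largest z) slice is the application surface")
  if (format == "raw") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.vector(volume$data), con, size = 8, endian = "little")
  } else {
    lo <- min(volume$data); hi <- max(volume$data)
    scale <- if (hi > lo) hi - lo else 1
    meta$intensity_offset <- lo
    meta$intensity_scale <- scale
    packed <- (volume$data - lo) / scale
    pages <- lapply(seq_len(d[3]), function(k) packed[, , k])
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  }
  write_sidecar(path, meta)
  invisible(path)
}

#' Read a grayscale volume
#'
#' @param path Path previously written by [write_volume()]; the JSON sidecar
#'   must be present.
#' @return A [voxel_volume()].
#' @export
read_volume <- function(path) {
  meta <- read_sidecar(path, required = c("shape", "format"))
  d <- as.integer(meta$shape)
  if (identical(meta$format, "raw")) {
    con <- file(path, "rb")
    on.exit(close(con))
    v <- readBin(con, "double", n = prod(d), size = 8, endian = "little")
    arr <- array(v, dim = d)
  } else {
    pages <- tiff::readTIFF(path, all = TRUE)
    arr <- array(0, dim = d)
    for (k in seq_len(d[3])) arr[, , k] <- pages[[k]]
    arr <- arr * meta$intensity_scale + meta$intensity_offset
  }
  voxel_volume(arr, meta$voxel_size_nm)
}

#' Write a label volume as an 8-bit TIFF stack
#'
#' The label legend (material name to code) is recorded in the sidecar and
#' validated on read.
#'
#' @param labels A [label_volume()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  stopifnot(inherits(labels, "label_volume"))
  d <- dim(labels)
  pages <- lapply(seq_len(d[3]), function(k) labels$labels[, , k] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  write_sidecar(path, list(kind = "label_volume", format = "tiff",
                           shape = d,
                           voxel_size_nm = labels$voxel_size_nm,
                           legend = as.list(material_codes()),
                           provenance = labels$provenance))
  invisible(path)
}

#' Read a label volume written by [write_labels()]
#' @param path Path to the 8-bit TIFF stack.
#' @return A [label_volume()].
#' @export
read_labels <- function(path) {
  meta <- read_sidecar(path, required = c("shape", "legend"))
  legend <- unlist(meta$legend)
  known <- material_codes()
  extra <- setdiff(names(legend), names(known))
  if (length(extra) > 0) {
    stop("label legend names unknown materials: ",
         paste(extra, collapse = ", "))
  }
  if (!all(legend[names(legend)] == known[names(legend)])) {
    stop("label legend codes disagree with the material enum")
  }
  d <- as.integer(meta$shape)
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0L, dim = d)
  for (k in seq_len(d[3])) arr[, , k] <- as.integer(round(pages[[k]] * 255))
  bad <- setdiff(unique(as.vector(arr)), unname(legend))
  if (length(bad) > 0) {
    stop("label stack contains codes missing from the legend: ",
         paste(bad, collapse = ", "))
  }
  label_volume(arr, meta$voxel_size_nm,
               provenance = if (is.null(meta$provenance)) list() else
                 meta$provenance)
}

#' Write / read a sinogram set (raw float64 + sidecar with angle metadata)
#' @param sino A [sinogram_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sinogram <- function(sino, path) {
  stopifnot(inherits(sino, "sinogram_set"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(sino$data), con, size = 8, endian = "little")
  write_sidecar(path, list(kind = "sinogram_set", format = "raw",
                           shape = dim(sino$data),
                           angles_deg = sino$angles_deg,
                           voxel_size_nm = sino$voxel_size_nm,
                           orig_shape = sino$orig_shape,
                           source_energy_keV = sino$source_energy_keV))
  invisible(path)
}

#' @rdname write_sinogram
#' @export
read_sinogram <- function(path) {
  meta <- read_sidecar(path, required = c("shape", "angles_deg",
                                          "orig_shape"))
  d <- as.integer(meta$shape)
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, "double", n = prod(d), size = 8, endian = "little")
  sinogram_set(array(v, dim = d), meta$angles_deg, meta$voxel_size_nm,
               meta$orig_shape,
               source_energy_keV = meta$source_energy_keV)
}
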