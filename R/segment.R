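# Three-class threshold segmentation of grayscale volumes into
# exterior / dentin / tubule lumen / silver, reproducing the processing
# chain used for the reference datasets: contrast matching between
# specimens, median filtering, threshold segmentation, and cropping to an
# interior region of interest.

#' Segmentation parameters
#'
#' @param median_radius_voxels Radius of the cubic median filter window
#'   (side `2r + 1`); 0 disables filtering.
#' @param threshold_lumen_dentin Lower threshold separating tubule lumen
#'   from dentin, or `"auto"`.
#' @param threshold_dentin_silver Upper threshold separating dentin from
#'   silver, or `"auto"`.
#' @param crop_box Optional integer vector `(x0, x1, y0, y1, z0, z1)` of
#'   0-based half-open voxel ranges to crop after segmentation.
#' @param min_silver_component_voxels Silver components smaller than this
#'   are relabeled dentin (0 keeps everything).
#' @param reference_volume_id Optional identifier of the contrast-matching
#'   reference, recorded in provenance.
#' @return A `segmentation_params` object.
#' @export
segmentation_params <- function(median_radius_voxels = 1,
                                threshold_lumen_dentin = "auto",
                                threshold_dentin_silver = "auto",
                                crop_box = NULL,
                                min_silver_component_voxels = 0,
                                reference_volume_id = NULL) {
  if (median_radius_voxels < 0) stop("median_radius_voxels must be >= 0")
  num1 <- is.numeric(threshold_lumen_dentin)
  num2 <- is.numeric(threshold_dentin_silver)
  if (num1 != num2) stop("thresholds must both be numeric or both 'auto'")
  if (num1 && threshold_lumen_dentin >= threshold_dentin_silver) {
    stop("threshold_lumen_dentin must be < threshold_dentin_silver")
  }
  if (!num1 && !identical(threshold_lumen_dentin, "auto")) {
    stop("thresholds must be numeric or 'auto'")
  }
  if (!is.null(crop_box) && length(crop_box) != 6) {
    stop("crop_box must be (x0, x1, y0, y1, z0, z1)")
  }
  structure(list(median_radius_voxels = as.integer(median_radius_voxels),
                 threshold_lumen_dentin = threshold_lumen_dentin,
                 threshold_dentin_silver = threshold_dentin_silver,
                 crop_box = crop_box,
                 min_silver_component_voxels =
                   as.integer(min_silver_component_voxels),
                 reference_volume_id = reference_volume_id),
            class = "segmentation_params")
}

#' Match the contrast of one volume to a reference
#'
#' Applies the affine intensity map that sends the target's robust (p1, p99)
#' percentiles onto the reference's, so that the silver signal is comparable
#' between datasets before thresholding. Rank order of intensities is
#' preserved.
#'
#' @param target,reference [voxel_volume()] objects; both must be
#'   non-constant.
#' @param probs Length-2 percentile pair used as anchors (default
#'   `c(0.01, 0.99)`).
#' @return The rescaled target volume.
#' @export
match_contrast <- function(target, reference, probs = c(0.01, 0.99)) {
  stopifnot(inherits(target, "voxel_volume"),
            inherits(reference, "voxel_volume"))
  qt <- stats::quantile(target$data, probs, names = FALSE)
  qr <- stats::quantile(reference$data, probs, names = FALSE)
  if (diff(qt) == 0 || diff(qr) == 0) {
    stop("contrast matching undefined for (near-)constant volumes")
  }
  a <- diff(qr) / diff(qt)
  b <- qr[1] - a * qt[1]
  voxel_volume(a * target$data + b, target$voxel_size_nm)
}

#' Median-filter a volume
#'
#' 3D median filter with a cubic window of side `2 * radius + 1`; edges are
#' handled by reflection. Radius 0 is the identity.
#'
#' @param volume A [voxel_volume()].
#' @param radius Non-negative integer window radius.
#' @return The filtered volume.
#' @export
median_filter_volume <- function(volume, radius = 1) {
  stopifnot(inherits(volume, "voxel_volume"))
  radius <- as.integer(radius)
  if (radius < 0) stop("radius must be >= 0")
  if (radius == 0) return(volume)
  out <- cpp_median3d(as.vector(volume$data), dim(volume), radius)
  voxel_volume(array(out, dim = dim(volume)), volume$voxel_size_nm)
}

# Three-class threshold selection by maximizing between-class variance over
# a binned histogram (multi-level Otsu). Returns c(t1, t2) or, when fewer
# than three populated classes can be separated, falls back to a two-class
# split (t2 = Inf) with a warning.
auto_thresholds <- function(values, nbins = 256) {
  rng <- range(values)
  if (diff(rng) == 0) stop("cannot auto-threshold a constant volume")
  edges <- seq(rng[1], rng[2], length.out = nbins + 1)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  h <- tabulate(pmin(pmax(findInterval(values, edges,
                                       rightmost.closed = TRUE), 1L),
                     nbins), nbins)
  p <- h / sum(h)
  cw <- cumsum(p)
  cmu <- cumsum(p * mids)
  total_mu <- cmu[nbins]
  # class boundaries i < j: classes [1..i], (i..j], (j..nbins]
  W1 <- matrix(cw, nbins, nbins)
  M1 <- matrix(cmu, nbins, nbins)
  W2 <- outer(cw, cw, function(a, b) b - a)   # W2[i, j] = cw[j] - cw[i]
  M2 <- outer(cmu, cmu, function(a, b) b - a)
  W3 <- 1 - matrix(cw, nbins, nbins, byrow = TRUE)
  M3 <- total_mu - matrix(cmu, nbins, nbins, byrow = TRUE)
  valid <- upper.tri(W2) & W1 > 0 & W2 > 0 & W3 > 0
  bcv <- matrix(-Inf, nbins, nbins)
  bcv[valid] <- M1[valid]^2 / W1[valid] + M2[valid]^2 / W2[valid] +
    M3[valid]^2 / W3[valid]
  if (!any(is.finite(bcv))) {
    warning("fewer than 3 distinguishable intensity modes; ",
            "falling back to a 2-class split")
    ok <- cw > 0 & cw < 1
    bcv2 <- ifelse(ok, cmu^2 / cw + (total_mu - cmu)^2 / (1 - cw), -Inf)
    i <- which.max(bcv2)
    return(c(edges[i + 1], Inf))
  }
  ij <- arrayInd(which.max(bcv), dim(bcv))
  c(edges[ij[1] + 1], edges[ij[2] + 1])
}

#' Threshold-segment a grayscale volume
#'
#' Classifies voxels into exterior, dentin, tubule lumen and silver using two
#' intensity thresholds: below the lower threshold is air (lumen or
#' exterior), between the thresholds is dentin, above the upper threshold is
#' silver. Thresholds may be given explicitly (reproducing an interactively
#' chosen segmentation) or chosen automatically by three-class between-class
#' variance maximization over the intensity histogram.
#'
#' The specimen support is the largest 26-connected component of the
#' above-lower-threshold material after filling, slice by slice, any
#' enclosed air regions (tubule cross-sections). Voxels outside the support
#' are labeled exterior; air voxels inside it are lumen. Silver components
#' smaller than `min_silver_component_voxels` are relabeled dentin.
#'
#' @param volume A [voxel_volume()] (already median-filtered if desired, or
#'   use `apply_median = TRUE` to filter here).
#' @param params A [segmentation_params()].
#' @param apply_median If `TRUE`, apply the median filter from `params`
#'   before thresholding (default `TRUE`).
#' @return A [label_volume()]; the chosen thresholds are recorded in its
#'   `provenance$thresholds`.
#' @export
threshold_segment <- function(volume, params = segmentation_params(),
                              apply_median = TRUE) {
  stopifnot(inherits(volume, "voxel_volume"),
            inherits(params, "segmentation_params"))
  if (!all(is.finite(volume$data))) stop("volume contains non-finite voxels")
  if (apply_median && params$median_radius_voxels > 0) {
    volume <- median_filter_volume(volume, params$median_radius_voxels)
  }
  if (is.numeric(params$threshold_lumen_dentin)) {
    th <- c(params$threshold_lumen_dentin, params$threshold_dentin_silver)
  } else {
    th <- auto_thresholds(as.vector(volume$data))
  }
  codes <- material_codes()
  d <- dim(volume)
  g <- volume$data
  solid <- g >= th[1]
  filled <- array(cpp_fill_slices(as.vector(solid), d), dim = d)
  # bridge air-filled slabs (cracks) along z: the specimen is convex in z,
  # so each (x, y) column is solid between its first and last filled slice
  m <- matrix(filled, nrow = d[1] * d[2], ncol = d[3])
  fwd <- t(apply(m, 1, cummax)) > 0
  bwd <- t(apply(m[, rev(seq_len(d[3])), drop = FALSE], 1, cummax))
  bwd <- bwd[, rev(seq_len(d[3])), drop = FALSE] > 0
  filled <- array(fwd & bwd, dim = d)
  comp <- array(cpp_label3d(as.vector(filled), d, 26L), dim = d)
  support <- array(FALSE, dim = d)
  if (max(comp) > 0) {
    sizes <- tabulate(comp[comp > 0], nbins = max(comp))
    support <- comp == which.max(sizes)
  }
  labels <- array(codes[["exterior"]], dim = d)
  labels[support & !solid] <- codes[["lumen"]]
  labels[support & solid & g <= th[2]] <- codes[["dentin"]]
  labels[support & g > th[2]] <- codes[["silver"]]
  if (params$min_silver_component_voxels > 0) {
    sm <- labels == codes[["silver"]]
    if (any(sm)) {
      sc <- array(cpp_label3d(as.vector(sm), d, 26L), dim = d)
      sizes <- tabulate(sc[sc > 0], nbins = max(sc))
      small <- which(sizes < params$min_silver_component_voxels)
      labels[sc %in% small] <- codes[["dentin"]]
    }
  }
  out <- label_volume(labels, volume$voxel_size_nm,
                      provenance = list(params = unclass(params),
                                        thresholds = th))
  if (!is.null(params$crop_box)) out <- crop_interior(out, params$crop_box)
  out
}

#' Crop to an interior region of interest
#'
#' Extracts the sub-volume given by 0-based half-open voxel ranges
#' `(x0, x1, y0, y1, z0, z1)`, as used to remove specimen borders and empty
#' areas before quantification. Class counts over the crop equal the counts
#' of the original restricted to the box.
#'
#' @param x A [label_volume()] or [voxel_volume()].
#' @param box Integer vector `(x0, x1, y0, y1, z0, z1)`, 0-based half-open.
#' @return The cropped object, with voxel size and provenance preserved.
#' @export
crop_interior <- function(x, box) {
  UseMethod("crop_interior")
}

check_box <- function(box, d) {
  box <- as.integer(box)
  if (length(box) != 6) stop("crop_box must have 6 entries")
  lo <- box[c(1, 3, 5)]; hi <- box[c(2, 4, 6)]
  if (any(lo < 0) || any(hi > d)) stop("crop_box out of volume bounds")
  if (any(hi <= lo)) stop("crop_box ranges must be non-empty")
  box
}

#' @export
crop_interior.label_volume <- function(x, box) {
  box <- check_box(box, dim(x))
  sub <- x$labels[(box[1] + 1):box[2], (box[3] + 1):box[4],
                  (box[5] + 1):box[6], drop = FALSE]
  prov <- x$provenance
  prov$crop_box <- box
  label_volume(sub, x$voxel_size_nm, provenance = prov)
}

#' @export
crop_interior.voxel_volume <- function(x, box) {
  box <- check_box(box, dim(x))
  sub <- x$data[(box[1] + 1):box[2], (box[3] + 1):box[4],
                (box[5] + 1):box[6], drop = FALSE]
  voxel_volume(sub, x$voxel_size_nm)
}

#' Relabel planar horizontal air gaps as cracks
#'
#' Preparation cracks are thin, near-horizontal air-filled gaps that
#' threshold into the lumen class; because a crack plane crosses the
#' tubules, a crack is usually 26-connected to tubule lumen and cannot be
#' isolated as its own component. This filter instead detects crack
#' *slices*: z-slices where the air fraction of the specimen support jumps
#' far above what tubule cross-sections produce, in runs of at most
#' `max_thickness_voxels` slices. Lumen voxels in detected slices are
#' relabeled `crack` so they can be excluded from tubule morphometry and
#' occlusion denominators.
#'
#' @param labels A [label_volume()].
#' @param max_thickness_voxels Maximum thickness (slices) of a crack slab.
#' @param min_lumen_fraction Minimum air fraction of the specimen support a
#'   slice must reach to be a crack candidate; tubules alone occupy a few
#'   percent, a crack fills nearly the whole cross-section (default 0.5).
#' @return The label volume with crack slices relabeled `crack`.
#' @export
relabel_cracks <- function(labels, max_thickness_voxels = 4,
                           min_lumen_fraction = 0.5) {
  stopifnot(inherits(labels, "label_volume"))
  codes <- material_codes()
  d <- dim(labels)
  m <- matrix(labels$labels, nrow = d[1] * d[2], ncol = d[3])
  lumen <- colSums(m == codes[["lumen"]])
  support <- colSums(m != codes[["exterior"]])
  frac <- ifelse(support > 0, lumen / support, 0)
  cand <- frac >= min_lumen_fraction
  if (!any(cand)) return(labels)
  runs <- rle(cand)
  ends <- cumsum(runs$lengths)
  lab <- labels$labels
  for (r in which(runs$values & runs$lengths <= max_thickness_voxels)) {
    ks <- seq(ends[r] - runs$lengths[r] + 1, ends[r])
    sub <- lab[, , ks, drop = FALSE]
    sub[sub == codes[["lumen"]]] <- codes[["crack"]]
    lab[, , ks] <- sub
  }
  label_volume(lab, labels$voxel_size_nm, provenance = labels$provenance)
}
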