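# Occlusion statistics: per-slice silver volume-fraction depth profile,
# silver-to-tubule volume percentage, and penetration-depth quantiles.

#' Per-slice silver volume fractions
#'
#' For every xy-slice, the ratio of silver-labeled voxels to a denominator:
#' either all pixels in the slice (`"slice"`, the convention of the
#' reference depth profiles) or only specimen (non-exterior) pixels
#' (`"support"`, which removes the depth dependence introduced by the cone
#' taper). Fractions are ordered bottom (slice index 0) to top.
#'
#' @param labels A [label_volume()].
#' @param denominator `"slice"` or `"support"`.
#' @return Numeric vector of per-slice fractions in `[0, 1]`.
#' @export
#' @examples
#' lab <- array(material_codes()[["dentin"]], dim = c(4, 4, 2))
#' lab[1, 1, 2] <- material_codes()[["silver"]]
#' slice_volume_fraction(label_volume(lab, 128))
slice_volume_fraction <- function(labels,
                                  denominator = c("slice", "support")) {
  stopifnot(inherits(labels, "label_volume"))
  denominator <- match.arg(denominator)
  codes <- material_codes()
  d <- dim(labels)
  m <- matrix(labels$labels, nrow = d[1] * d[2], ncol = d[3])
  silver <- colSums(m == codes[["silver"]])
  if (denominator == "slice") {
    denom <- rep(d[1] * d[2], d[3])
  } else {
    denom <- colSums(m != codes[["exterior"]])
  }
  frac <- ifelse(denom > 0, silver / denom, 0)
  as.numeric(frac)
}

#' Silver percentage relative to tubule volume
#'
#' The ratio of the volume occupied by silver to the volume occupied by the
#' tubules, times 100. Values are conventionally reported to two decimals;
#' use [format_percent()] for printing.
#'
#' @param silver_volume_um3 Silver volume (um^3, >= 0).
#' @param tubule_volume_um3 Tubule volume (um^3, > 0).
#' @return The percentage as a plain number.
#' @export
#' @examples
#' format_percent(silver_percentage(4.8, 761))  # "0.63%"
#' format_percent(silver_percentage(6.9, 410))  # "1.68%"
silver_percentage <- function(silver_volume_um3, tubule_volume_um3) {
  if (!is.numeric(tubule_volume_um3) || tubule_volume_um3 <= 0) {
    stop("silver percentage is undefined for zero tubule volume")
  }
  if (silver_volume_um3 < 0) stop("silver volume must be >= 0")
  100 * silver_volume_um3 / tubule_volume_um3
}

#' Format a percentage to the conventional two decimals
#' @param x Numeric percentage value(s).
#' @return Character, e.g. `"0.63%"`.
#' @export
format_percent <- function(x) sprintf("%.2f%%", x)

#' Occlusion profile of a labeled volume
#'
#' Bundles the quantitative occlusion outputs: per-slice silver volume
#' fractions (both normalizations), silver and tubule voxel counts and
#' volumes, the silver percentage, and penetration-depth quantiles measured
#' from the top (application) surface.
#'
#' The tubule volume denominator counts lumen plus silver voxels (the full
#' anatomical bore); the air-only alternative is reported alongside as
#' `silver_percent_of_lumen`.
#'
#' @param labels A [label_volume()].
#' @param quantiles Quantiles at which to report penetration depth.
#' @return An `occlusion_profile` object.
#' @export
occlusion_profile <- function(labels,
                              quantiles = c(0.25, 0.5, 0.63, 0.75, 0.9)) {
  stopifnot(inherits(labels, "label_volume"))
  codes <- material_codes()
  d <- dim(labels)
  vs <- voxel_size_um(labels)
  m <- matrix(labels$labels, nrow = d[1] * d[2], ncol = d[3])
  silver_by_slice <- colSums(m == codes[["silver"]])
  support_by_slice <- colSums(m != codes[["exterior"]])
  counts <- label_counts(labels)
  silver_n <- counts[["silver"]]
  tubule_n <- counts[["lumen"]] + counts[["silver"]]
  prof <- structure(list(
    slice_fractions = silver_by_slice / (d[1] * d[2]),
    slice_fractions_support = ifelse(support_by_slice > 0,
                                     silver_by_slice / support_by_slice, 0),
    slice_silver_counts = as.integer(silver_by_slice),
    slice_pixels = as.integer(rep(d[1] * d[2], d[3])),
    slice_support_pixels = as.integer(support_by_slice),
    voxel_size_nm = labels$voxel_size_nm,
    silver_voxel_count = silver_n,
    tubule_voxel_count = tubule_n,
    lumen_voxel_count = counts[["lumen"]],
    silver_volume_um3 = silver_n * vs^3,
    tubule_volume_um3 = tubule_n * vs^3,
    silver_percent = if (tubule_n > 0) 100 * silver_n / tubule_n else
      NA_real_,
    silver_percent_of_lumen = if (counts[["lumen"]] > 0)
      100 * silver_n / counts[["lumen"]] else NA_real_,
    depth_quantiles = NULL
  ), class = "occlusion_profile")
  if (silver_n > 0) {
    prof$depth_quantiles <- penetration_depth(prof, quantiles)
  }
  prof
}

#' @export
print.occlusion_profile <- function(x, ...) {
  cat(sprintf("<occlusion_profile> %d slices @ %g nm\n",
              length(x$slice_fractions), x$voxel_size_nm))
  cat(sprintf("  tubule volume: %.1f um^3 (%d voxels)\n",
              x$tubule_volume_um3, x$tubule_voxel_count))
  cat(sprintf("  silver volume: %.2f um^3 (%d voxels)\n",
              x$silver_volume_um3, x$silver_voxel_count))
  if (!is.na(x$silver_percent)) {
    cat(sprintf("  silver / tubule volume: %s\n",
                format_percent(x$silver_percent)))
  }
  if (!is.null(x$depth_quantiles)) {
    q <- x$depth_quantiles
    cat("  penetration depth (um): ",
        paste(sprintf("q%0.2f=%.2f", q$q, q$depth_um), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Penetration depth quantiles
#'
#' For each quantile `q`, the smallest depth below the top surface (the
#' topmost specimen-containing slice) whose cumulative share of all silver
#' voxels reaches `q`. Depth is a whole number of slices converted to um by
#' the voxel size.
#'
#' @param profile An [occlusion_profile()].
#' @param quantiles Numeric vector of quantiles in `(0, 1]`.
#' @return Data frame with columns `q`, `n_slices`, `depth_um`.
#' @export
penetration_depth <- function(profile,
                              quantiles = c(0.25, 0.5, 0.63, 0.75, 0.9)) {
  stopifnot(inherits(profile, "occlusion_profile"))
  if (any(quantiles <= 0 | quantiles > 1)) {
    stop("quantiles must lie in (0, 1]")
  }
  total <- sum(profile$slice_silver_counts)
  if (total == 0) {
    stop("penetration depth is undefined: the profile contains no silver")
  }
  vs <- profile$voxel_size_nm / 1000
  nz <- length(profile$slice_silver_counts)
  top <- max(which(profile$slice_support_pixels > 0))
  # cumulative silver from the top surface downward
  counts_topdown <- profile$slice_silver_counts[seq(top, 1)]
  cum <- cumsum(counts_topdown) / total
  n_slices <- vapply(quantiles, function(q) which(cum >= q - 1e-12)[1],
                     numeric(1))
  data.frame(q = quantiles, n_slices = n_slices, depth_um = n_slices * vs)
}

#' Compare two occlusion profiles
#'
#' Emits paired penetration-depth quantiles, total silver percentages, and a
#' per-slice fraction table aligned at the top surface, for side-by-side
#' plotting of two specimens (e.g. two formulations). No statistical test is
#' performed.
#'
#' @param profile_a,profile_b [occlusion_profile()] objects with equal voxel
#'   size.
#' @param quantiles Quantiles for the paired depth table.
#' @return A list with `depth` (data frame: q, depth_a_um, depth_b_um,
#'   difference), `silver_percent` (named vector, `NA` where undefined),
#'   `undefined_depth` (logical pair flagging empty-silver profiles), and
#'   `slices` (data frame of aligned per-slice fractions, depth 0 = top
#'   surface).
#' @export
compare_profiles <- function(profile_a, profile_b,
                             quantiles = c(0.25, 0.5, 0.63, 0.75, 0.9)) {
  stopifnot(inherits(profile_a, "occlusion_profile"),
            inherits(profile_b, "occlusion_profile"))
  if (!isTRUE(all.equal(profile_a$voxel_size_nm, profile_b$voxel_size_nm))) {
    stop("profiles have different voxel sizes and cannot be compared")
  }
  vs <- profile_a$voxel_size_nm / 1000
  und <- c(a = profile_a$silver_voxel_count == 0,
           b = profile_b$silver_voxel_count == 0)
  da <- if (!und["a"]) penetration_depth(profile_a, quantiles)$depth_um else
    rep(NA_real_, length(quantiles))
  db <- if (!und["b"]) penetration_depth(profile_b, quantiles)$depth_um else
    rep(NA_real_, length(quantiles))
  top_a <- max(which(profile_a$slice_support_pixels > 0))
  top_b <- max(which(profile_b$slice_support_pixels > 0))
  n <- max(top_a, top_b)
  below_a <- rev(profile_a$slice_fractions[seq_len(top_a)])
  below_b <- rev(profile_b$slice_fractions[seq_len(top_b)])
  slices <- data.frame(
    depth_um = (seq_len(n) - 1) * vs,
    fraction_a = c(below_a, rep(NA_real_, n - top_a)),
    fraction_b = c(below_b, rep(NA_real_, n - top_b)))
  list(
    depth = data.frame(q = quantiles, depth_a_um = da, depth_b_um = db,
                       difference_um = da - db),
    silver_percent = c(a = profile_a$silver_percent,
                       b = profile_b$silver_percent),
    undefined_depth = und,
    slices = slices
  )
}

#' Plot an occlusion depth profile
#'
#' Per-slice silver volume fraction against slice index, bottom of the
#' specimen (slice 0) on the left, reproducing the conventional layout of
#' penetration-depth plots.
#'
#' @param x An [occlusion_profile()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot.occlusion_profile <- function(x, ...) {
  graphics::plot(seq_along(x$slice_fractions) - 1, x$slice_fractions,
                 type = "l", xlab = "slice (0 = bottom)",
                 ylab = "silver volume fraction", ...)
  invisible(x)
}

#' Per-slice profile table
#'
#' @param profile An [occlusion_profile()].
#' @return Data frame with `slice_index` (0 = bottom), `depth_um` (below the
#'   top surface; negative above it), and both fraction normalizations.
#' @export
profile_table <- function(profile) {
  stopifnot(inherits(profile, "occlusion_profile"))
  vs <- profile$voxel_size_nm / 1000
  nz <- length(profile$slice_fractions)
  top <- if (any(profile$slice_support_pixels > 0))
    max(which(profile$slice_support_pixels > 0)) else nz
  data.frame(
    slice_index = seq_len(nz) - 1,
    depth_um = (top - seq_len(nz)) * vs,
    silver_fraction = profile$slice_fractions,
    silver_fraction_support = profile$slice_fractions_support)
}
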