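---
title: "Quantifying dentinal tubule occlusion from nano-CT volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dentinal tubule occlusion from nano-CT volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Silver diammine fluoride (SDF) treats dentin hypersensitivity and arrests
caries by precipitating silver inside dentinal tubules — the micron-scale
channels that run through dentin and transmit pain stimuli when open. How
deep the silver penetrates, and how much of the tubule network it occludes,
are the quantities a formulation is judged by. Full-field X-ray
nano-computed tomography resolves both: at ~128 nm isotropic voxels a
conical dentin specimen (~300 µm tall, tip ~50 µm) shows its tubules as
dark channels, the silver agglomerates as bright spots inside them.

`tubulometry` implements the quantification chain for such volumes:

1. **phantom** — a synthetic conical dentin specimen with known ground
   truth, so every downstream stage is testable without instrument data;
2. **recon** (optional) — idealized parallel-beam projection over 180° and
   filtered back-projection;
3. **segment** — contrast matching, 3D median filtering, three-class
   threshold segmentation, interior cropping;
4. **morphometry** — per-tubule volume, bore diameter, orientation;
5. **occlusion** — per-slice silver volume-fraction depth profiles, the
   silver-to-tubule volume percentage, penetration-depth quantiles.

Throughout, `z` is the specimen axis, and the slice with the *largest* z
index is the treatment-application (top) surface. Depth profiles are
indexed from the bottom (slice 0) upward; penetration depth is measured
downward from the topmost specimen-containing slice.

## The synthetic phantom

No public dataset accompanies the imaging protocol this package targets, so
the generator is a first-class, tested component, not a fixture. It
emulates:

* a **cone** of dentin (uniform attenuation), by default a uniformly scaled
  version of the reference specimen (height 300 µm, tip radius 25 µm, base
  radius 75 µm) sized to fill ~92% of the grid;
* **tubules**: straight cylinders with diameters drawn uniformly from
  2.9–4.5 µm (the range observed at this resolution) and axes tilted at
  most a few degrees from vertical. Tubules are clipped to the cone eroded
  radially by ~2 voxels, so every cross-section keeps an enclosing dentin
  rim, and the placement rule separates axes by the sum of radii plus the
  worst-case lateral drift of tilted axes over the specimen height —
  tubules never merge. Tubules that cannot be placed are skipped and
  recorded in the truth's warnings;
* **silver**: homogeneous spheres placed only inside tubule lumens. A
  candidate particle at depth $d$ below the top surface is accepted with
  probability $e^{-d/L}$, where $L$ is `silver_decay_length_um`. The
  exponential is a modeling choice — the reference work reports an
  empirical decay but no generative law — and is exposed as a parameter.
  Deposition stops when the target fill fraction of the tubule volume is
  reached; an unreachable target is reported in the truth metadata rather
  than silently truncated;
* **cracks**: thin horizontal air-filled slabs from specimen preparation,
  modeled as internal delaminations that stop ~2 voxels short of the cone
  surface (a fully severed specimen could not hold together). Crack voxels
  carry a distinct label so quantification tests can verify their
  exclusion;
* **noise**: additive Gaussian noise on the attenuation values. The
  instrument's raw noise is photon-limited, but noise in a reconstructed
  volume is approximately Gaussian; the level is user-set
  (`noise_sigma = 0.05` against a lumen–dentin–silver attenuation spacing
  of 0.05/0.5/1.0 is the "noisy" condition used in the tests).

Default attenuations are exterior 0, lumen 0.05, dentin 0.5, silver 1.0
(arbitrary units); only their strict ordering matters downstream.
Generation is a pure function of the spec including its seed: identical
specs give bit-identical volumes.

What the phantom does **not** emulate: peritubular/intertubular dentin
contrast, mineral-density gradients, tubule curvature and branching,
Zernike phase-contrast fringes, partial-volume blur at material boundaries,
and correlated reconstruction artifacts (rings, streaks). Consequently the
segmentation results on phantoms — especially the exact recovery at zero
noise — bound what thresholding can do on ideal data; they do not promise
the same Dice on instrument data, where boundary blur and artifacts
dominate the error budget.

## Projection and reconstruction

The real instrument is a zone-plate microscope; the package models
idealized monochromatic parallel-beam absorption, which is the geometry the
named reconstruction algorithm (filtered back-projection) assumes. Each
z-slice is projected independently at `n_angles` equally spaced angles over
[0°, 180°) — 901 by default, matching the reference acquisition. Rays are
sampled at unit voxel steps with bilinear interpolation, so line integrals
are in attenuation × voxel-length units and each projection sums to the
slice mass up to interpolation error.

FBP filters each projection in the frequency domain and smears it back with
linear interpolation about the grid center. The ramp filter is built from
its spatial-domain kernel (Kak–Slaney construction) rather than a sampled
$|f|$, which removes the DC bias that otherwise offsets reconstructed
attenuation; `shepp-logan` and `hann` windows are available for noisy
data. Projections are zero-padded to the next power of two ≥ twice the
detector width. On a 96² disk slice the projections match the analytic
chord-length transform within ~1.7% RMS and a 901-angle round trip
recovers the interior attenuation to well under 1%.

This stage is optional: segmentation consumes either a reconstructed volume
or the phantom grayscale directly.

## Segmentation

The processing chain mirrors the reference workflow: optional contrast
matching of one dataset onto another (an affine map of the robust p1/p99
percentiles, chosen over min/max to resist hot pixels), a cubic-window 3D
median filter (radius 1 by default; the reference work does not state its
kernel), then two thresholds: below the lower one is air, between is
dentin, above the upper is silver.

Thresholds may be given numerically — reproducing an interactively chosen
segmentation — or selected automatically by three-class between-class
variance maximization over a 256-bin histogram (multi-level Otsu). When no
valid three-class split exists the method falls back to a two-class split
with a warning. Chosen thresholds are always recorded in the label volume's
provenance and in the pipeline manifest.

Air must then be split into tubule lumen and exterior. The specimen support
is built by filling, slice by slice, any air region not connected to the
slice border (tubule cross-sections are enclosed by the dentin rim), then
closing each (x, y) column between its first and last solid slice — the
specimen is convex along z, and this bridges air-filled crack slabs — and
finally keeping the largest 26-connected component, which discards
bright noise specks floating in air. Air inside the support is lumen;
everything outside is exterior. Optionally, silver components smaller than
`min_silver_component_voxels` are relabeled dentin (noise suppression).

Cracks threshold as lumen. The optional `relabel_cracks()` filter detects
crack *slices* — z-slices whose air fraction of the support jumps far above
what tubule cross-sections produce (default ≥ 50%), in runs of a few
slices — and relabels their lumen as crack. Within a detected slab this
also excludes the tubule segments passing through it: a deliberate,
conservative choice, since inside the slab the two are not separable by
intensity. How the reference analysis excluded cracks from its tubule
volumes is not stated; this filter is therefore off by default and explicit
when used.

## Morphometry

The tubule region is lumen plus silver — a tubule's anatomical bore does
not shrink because material entered it — excluding crack voxels. Components
use 26-connectivity (thin tilted cylinders fragment under 6-connectivity);
components smaller than 3 voxels in every direction, or containing no lumen
at all, are discarded as noise. Two tubules bridged by a shared silver
deposit merge into one component; this is documented behavior, and the
generator's separation rule prevents it in synthetic data.

**Diameter.** The "largest diameter" of a tubule is taken as the largest
inscribed-sphere diameter: with `edt` the Euclidean distance from a tubule
voxel to the nearest background voxel, the estimate is
`(2 * max(edt) - 1)` voxel widths, so an isolated voxel has diameter one
voxel. For digitized cylinders this recovers the true diameter within about
2 voxel sizes (0.26 µm at 128 nm); the worst-case axis alignment (axis
exactly between voxel centers) can add roughly half a voxel more, while the
average over random alignments — what the parameter-recovery tests measure
— is well inside the bound. An in-slice maximum-Feret alternative is
available (`diameter_method = "feret"`) but the inscribed sphere is the
default because it is robust to tilt.

**Orientation.** The principal axis of the component's voxel-coordinate
covariance, sign-normalized to non-negative z; tilt is
`acos(|v_z|)` in degrees. Components without a dominant axis
(largest-to-second eigenvalue ratio < 1.5, e.g. an isolated sphere) are
flagged degenerate rather than rejected.

## Occlusion statistics

`slice_volume_fraction()` computes, per xy-slice, silver pixels over *all*
pixels in the slice — the convention of the reference depth profiles. Since
the conical taper makes that denominator depth-dependent, a
support-normalized variant (silver over specimen pixels) is always computed
alongside; both appear in the profile CSV.

The silver percentage is `100 × silver volume / tubule volume`, reported to
two decimals. The denominator includes silver-occupied voxels (the full
bore); the air-only alternative is reported as well — with realistic
numbers the difference is below rounding. Penetration depth at quantile
`q` is the smallest number of slices below the top surface containing a
fraction `q` of all silver, converted to µm. For an exponential deposition
profile the 63% quantile estimates the decay length (the exponential CDF
reaches 1 − e⁻¹ ≈ 0.632 at one decay length).

Two caveats the tests quantify: the depth estimate of the *generated* decay
length is biased upward by a fraction of a micron — particles have finite
radius, depth is quantized to whole slices, and near-surface lumen
saturates when the local fill is high — so the closed-form check is run in
a dilute regime (fill ≈ 1.5%, particle radius ≈ 0.2–0.35 µm) where these
effects stay within the 20% oracle band. And `compare_profiles()`
deliberately performs no hypothesis test: with one specimen per
formulation there is no basis for one.

## Numerical and scale choices

* Desk-scale grids (≈ 96×96×160 to 160×160×96 voxels) keep the full test
  suite around a minute and the acceptance script under a minute; the same
  code runs full-size volumes, only slower. These sizes are stated here as
  the package's chosen test conditions.
* The distance transform, connected components, median filter, projection
  and back-projection kernels are compiled (Rcpp); everything else is
  vectorized R.
* Determinism: a single config seed fans out to the generator and to crack
  placement; reruns of `run_pipeline()` with an identical config produce
  byte-identical CSV/JSON outputs. The run manifest records the config, its
  MD5, the chosen thresholds and the package version, and contains no
  timestamps (those go to `run.log`).
* Degenerate inputs fail loudly: constant volumes cannot be
  contrast-matched or auto-thresholded (explicit errors), a zero-silver
  profile has no penetration depth (explicit error), zero tubule volume has
  no silver percentage (explicit error), and volumes without a voxel-size
  sidecar are refused — µm-scale quantification without a voxel size is
  meaningless.

## Known limitations

* Straight-cylinder tubules and spherical silver particles are geometric
  idealizations; branching networks and wall-adherent silver films are out
  of scope.
* The segmentation support construction assumes a specimen convex along z
  (true for cones); strongly re-entrant specimens would need a different
  exterior model.
* The crack filter removes whole crack slabs including tubule segments
  inside them (conservative for occlusion denominators).
* The recon stage models neither phase contrast, beam hardening, ring
  artifacts nor misalignment; it is a testbed for the reconstruction
  algorithm, not an instrument simulator.
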