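# tubulometry

Quantification of dentinal tubule occlusion from X-ray nano-computed
tomography, for researchers evaluating desensitizing/caries-arresting
agents such as silver diammine fluoride (SDF). Open dentinal tubules —
micron-scale channels through dentin — transmit pain stimuli; SDF works by
precipitating silver inside them. Given a reconstructed nano-CT volume of a
conical dentin specimen (~128 nm isotropic voxels), or a synthetic phantom
with known ground truth, the package segments dentin / tubule lumen /
silver, measures each tubule, and quantifies how much silver entered the
tubule network and how deep it penetrated.

## What it computes

For a label volume with silver voxel count $n_{Ag}$ and tubule (lumen +
silver) voxel count $n_{tub}$, with voxel volume $v^3$:

* **per-slice silver volume fraction** — for each xy-slice $k$ (bottom =
  slice 0), $f_k = n_{Ag,k} / n_{pix}$, the depth profile of silver;
  a support-normalized variant divides by specimen pixels instead;
* **silver percentage** — $100 \cdot n_{Ag} v^3 / (n_{tub} v^3)$, the
  volume of silver relative to the volume of the tubules, reported to two
  decimals;
* **penetration depth** — for quantile $q$, the smallest depth below the
  application (top) surface containing a fraction $q$ of all silver; for
  exponential deposition, depth(0.63) estimates the decay length;
* **per-tubule morphometry** — volume, largest inscribed-sphere bore
  diameter, and orientation (principal axis + tilt from the specimen
  axis) of each 26-connected tubule component.

Supporting stages: a synthetic conical dentin phantom generator with
ground-truth registry (tubule diameters 2.9–4.5 µm, exponential-depth
silver, preparation cracks, Gaussian noise), an optional parallel-beam
projection (901 angles over 180°) + filtered back-projection stage, and
contrast matching / 3D median filtering / three-class (multi-level Otsu)
threshold segmentation. See the vignette
(`vignettes/tubule-occlusion-quantification.Rmd`) for the models and their
assumptions.

## Worked example

```r
library(tubulometry)

spec <- phantom_spec(shape_voxels = c(96, 96, 160), n_tubules = 2,
                     cone_tip_radius_um = 5.6, cone_base_radius_um = 6,
                     cone_height_um = 19, tubule_tilt_max_deg = 1,
                     tubule_diameter_range_um = c(2.9, 3.5),
                     silver_fill_fraction = 0.05, silver_decay_length_um = 4,
                     noise_sigma = 0.05, seed = 1)
ph <- generate_phantom(spec)

labels <- threshold_segment(ph$volume,
                            segmentation_params(median_radius_voxels = 1))
round(labels$provenance$thresholds, 3)
#> [1] 0.219 0.649

morpho <- label_tubules(labels)
morpho$stats[, c("tubule_id", "volume_um3", "max_diameter_um", "tilt_deg")]
#>   tubule_id volume_um3 max_diameter_um tilt_deg
#> 1         1        139            2.94    0.915
#> 2         2        174            3.21    0.229

occlusion_profile(labels)
#> <occlusion_profile> 160 slices @ 128 nm
#>   tubule volume: 313.2 um^3 (149324 voxels)
#>   silver volume: 14.49 um^3 (6908 voxels)
#>   silver / tubule volume: 4.63%
#>   penetration depth (um): q0.25=1.41, q0.50=2.94, q0.63=3.84, q0.75=4.74, q0.90=6.40
```

The automatic thresholds landed in the lumen–dentin and dentin–silver
intensity gaps. Both tubules are recovered with diameters inside the
generated 2.9–3.5 µm range and near-vertical orientations. The estimated
silver percentage (4.63%) is within 10% relative of the generator's ground
truth (5.05% of the tubule bore filled), and depth(0.63) = 3.84 µm
estimates the generated 4 µm decay length.

Given measured volumes directly:

```r
format_percent(silver_percentage(4.8, 761))   # silver / tubule volumes in um^3
#> [1] "0.63%"
format_percent(silver_percentage(6.9, 410))
#> [1] "1.68%"
```

An end-to-end run (`run_pipeline(pipeline_config(...))`) writes the
phantom, labels, `tubules.csv`, `profile.csv`, a summary JSON and a
manifest; reruns with the same config are byte-identical. A command-line
wrapper with `generate / project / reconstruct / segment / morpho /
occlude / run / compare` subcommands is installed at
`inst/scripts/tubulometry-cli.R`.

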