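# eosiquant

Quantification of lipid bodies (LBs) in eosinophils and EoL-1 cells from
three imaging modalities: CARS microscopy, two-channel fluorescence
(Hoechst/BODIPY), and Raman hyperspectral imaging.

Eosinophils respond to proinflammatory stimulation (butyric acid, TNF-α,
IL-1β, LPS) by accumulating neutral-lipid cytoplasmic inclusions. This
package implements the quantification pipeline that turns raw images into
per-cell LB counts, morphology profiles and lipid-unsaturation estimates:

* **CARS spot calling** (`detect_lipid_bodies()`): rolling-ball background
  subtraction (radius 3 px) → Laplacian of Gaussian (σ = 1) → FFT bandpass
  (2–20 px) → inversion + 8-bit conversion → global threshold (Rényi
  entropy, or 1.4× image mean) → particle filtering (circularity ≥ 0.5,
  area in [(2 px)²π/4, (20 px)²π/4]).
* **Cell segmentation** (`train_pixel_classifier()`, `clean_mask()`,
  `assign_spots_to_cells()`): random-forest pixel classification of
  CARS/TPEF RGB composites over a multi-scale filter bank, hole filling
  (< 500 px), watershed splitting, area/edge exclusion (≥ 2500 px, no edge
  contact), replayable manual edits, and centroid-based spot-to-cell
  assignment.
* **Fluorescence** (`find_nuclei()`, `find_spots()`,
  `lbs_per_cell_ratio()`, `morphology_profile()`,
  `mann_whitney_compare()`): nucleus segmentation (area > 5 µm²), BODIPY
  spot detection (area > 2 µm²), per-image LBs/cell with between-image
  SEM, multi-parametric morphology normalized to a reference group, and
  exact Mann–Whitney tests.
* **Raman** (`remove_cosmic_rays()`, `baseline_correct()`,
  `kmeans_segment()`, `unsaturation_ratio()`,
  `fit_unsaturation_calibration()`, `pca_cytoplasm()`, `anova_groups()`):
  cosmic-ray removal (filter size 3, dynamic factor 8), degree-3
  polynomial baseline, band-integration maps, k-means class extraction
  (cytoplasm / LB / nucleus / background), the 1660/1440 cm⁻¹
  unsaturation ratio calibrated against fatty acids of known C=C count,
  cytoplasm PCA (600–1800 cm⁻¹) and group ANOVA.
* **Count statistics** (`percent_rank()`, `count_histogram()`,
  `zero_fraction()`): percentile summaries suited to the heavily tied,
  zero-inflated per-cell count distributions.
* **Synthetic data** (`make_cars_tpef_scene()`,
  `make_fluorescence_scene()`, `make_raman_cube()`,
  `reference_fatty_acid_spectra()`): all three modalities with exact,
  seed-reproducible ground truth, used to validate every stage by
  parameter recovery.

The unsaturation readout rests on the linear relation between the
1660/1440 cm⁻¹ integrated-intensity ratio and the number of C=C bonds:
fit on oleic (18:1), linoleic (18:2) and α-linolenic (18:3) references,
a measured ratio inverts to an average C=C count per acyl chain.

## Worked example

Generate a synthetic CARS/TPEF frame, detect LBs, segment cells and count
per cell:

```r
library(eosiquant)

scene <- make_cars_tpef_scene(9, count_law_poisson(2), seed = 4,
                              frame = c(384, 384))
spots <- detect_lipid_bodies(scene$cars, cars_config("renyi"))
spots
#> <spot_set> 20 spots retained, 6 excluded (gates: area [3.14, 314] px^2, circ >= 0.5)

cells <- clean_mask(scene$ground_truth$cell_labels > 0)
counts <- assign_spots_to_cells(cells, spots)
counts
#> <per_cell_counts> group custom: 9 cells, mean 2.22 LBs/cell, 0 orphan spots

percent_rank(counts$counts$lb_count)
#> <percent_rank_summary> n = 9, median 2, mean 2.22, 25-75% [1, 3], 5-95% [0, 5]
```

The scene's ground truth holds 20 lipid bodies across 9 cells (mean 2.22
LBs/cell); the detection chain recovers all of them (the 6 excluded
candidates are sub-area noise specks removed by the particle gates), and
the per-cell tallies match the generator's records exactly. The percent-rank summary is
the per-cell dispersion report used for stimulation-group comparisons.

For the Raman side:

```r
refs <- reference_fatty_acid_spectra(1:3)
cal <- fit_unsaturation_calibration(refs)
cal
#> <unsaturation_calibration> ratio = -9.294e-15 + 0.3664 * C=C (R^2 = 1.000000, 3 refs)
wn <- attr(refs, "wavenumber_axis")
mix <- 0.5 * refs[["1"]] + 0.5 * refs[["2"]]   # equal oleic/linoleic mixture
estimate_double_bonds(cal, unsaturation_ratio(mix, wn))
#> [1] 1.5
```

The calibration is exactly linear through zero and inverts an equal
oleic/linoleic mixture to 1.5 C=C bonds, the value reported for
unstimulated control cells.

## Layout

```
R/                  implementation (one file per pipeline stage group)
tests/testthat/     unit, property and recovery tests with brute-force oracles
scripts/acceptance.R   parameter-recovery driver
vignettes/          methods vignette: models, parameters, design choices
```
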