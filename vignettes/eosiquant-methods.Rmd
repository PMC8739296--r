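---
title: "Quantifying lipid bodies in eosinophils: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying lipid bodies in eosinophils: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eosiquant)
```

## The problem

Eosinophils respond to inflammatory stimulation by accumulating lipid
bodies (LBs) — neutral-lipid cytoplasmic inclusions — and the number,
morphology and lipid composition of these LBs are read out with three
complementary microscopies: label-free CARS imaging tuned to the
2850 cm^-1 CH~2~ stretch (per-cell LB counts), two-channel fluorescence
with Hoechst (nuclei) and BODIPY 493/503 (LBs) staining (population-level
LBs/cell and morphology), and spontaneous Raman hyperspectral imaging
(chemical class maps and lipid unsaturation). `eosiquant` implements the
quantification pipeline for all three modalities, together with a
synthetic-data module that generates each modality with exact ground
truth, so every stage is validated by parameter recovery rather than by
eyeballing.

## CARS spot calling

`detect_lipid_bodies()` applies a fixed operator chain, in this order:

1. **Rolling-ball background subtraction**, ball radius 3 px, realized as
   grayscale opening with a ball-shaped structuring element (height
   profile $\sqrt{r^2 - d^2}$). Exactness was preferred over the
   shrink/enlarge speed tricks of common implementations: a constant
   image maps to exactly zero, and the test suite checks the operator
   against a brute-force erosion/dilation oracle.
2. **Laplacian of Gaussian**, smoothing scale $\sigma = 1$ px, realized
   as separable Gaussian smoothing followed by the discrete 4-neighbour
   Laplacian. Bright blobs become negative peaks.
3. **FFT bandpass**, passing spatial periods between 2 and 20 px. The
   exact windowing of the classic implementation is undocumented, so the
   edge profile is a design choice: Gaussian roll-offs spanning 20% of
   each band edge in frequency (configurable). The DC gain is below
   $10^{-5}$, so zero-mean images stay zero-mean.
4. **Inversion and 8-bit quantization.** The published macro order is
   invert-then-convert; `eosiquant` rescales min–max to 0..255 first and
   then inverts, which is threshold-equivalent and makes a double
   application of the step an exact involution on the 8-bit result.
5. **Global threshold**: either the Rényi-entropy criterion
   (Sahoo–Wilkins–Yeager: entropic thresholds of orders 0.5, 1, 2
   combined with mass-dependent weights) or 1.4 times the image mean
   ("relative mean", used where finer control was needed). Pixels
   *strictly above* the threshold are foreground; ties go to background.
   The entropic threshold is checked against an exhaustive 0–255
   criterion scan on every random test image.
6. **Particle filtering**: 8-connected components, circularity
   $4\pi A/P^2$ (Crofton perimeter, clamped at 1) must be at least 0.5,
   and area must lie in $[(2\,\mathrm{px})^2\pi/4,\ (20\,\mathrm{px})^2\pi/4]$,
   i.e. the diameter window 2–20 px. The Crofton estimator uses four
   digital directions, $P = \tfrac{\pi}{8}(n_h + n_v + (n_{d1}+n_{d2})/\sqrt2)$,
   which reproduces continuum perimeters of discretized disks to a few
   percent.

All numeric defaults above are the published macro values and live in
`cars_config()` / `default_config()`.

## Cell segmentation and per-cell counts

Whole cells are delineated on a contrast-enhanced RGB composite
(red = CARS, green = TPEF, 3.5% tail saturation). The published workflow
used an interactive trainable segmentation tool; the tool is not the
mathematics, so `eosiquant` substitutes an explicit, reproducible
equivalent: a random-forest pixel classifier over an enumerated
multi-scale filter bank (Gaussian blur, gradient magnitude, Laplacian and
both structure-tensor eigenvalues at $\sigma \in \{1,2,4,8\}$ on both
channels), trained seed-deterministically on labelled example images and
thresholded at probability 0.5.

Mask cleaning follows the published two-step recipe: holes under 500 px
are filled, touching cells are split by a watershed on the distance
transform (h-maxima suppression depth 2 px by default — the watershed
variant of the original macro is unspecified, and suppression avoids
oversegmentation of noisy masks), and components under 2500 px or
touching the frame edge are excluded, each with an audited reason. The
interactive correction step becomes `apply_manual_edits()`, a replayable
edit script (remove / merge / add), so the semi-automated step is
deterministic and testable. A spot belongs to the cell containing its
centroid; spots on background go to an orphan tally, and retained +
excluded + orphaned counts must reconcile exactly at every stage.

## Fluorescence quantification

The reference implementation used proprietary detection methods, of which
only the gates are stated (nuclei: area > 5 µm²; spots: area > 2 µm²).
`eosiquant` uses behaviourally equivalent open surrogates: nuclei are
found by Gaussian smoothing, Otsu thresholding and watershed splitting;
spots by a white top-hat (disc radius 6 px) thresholded at 20% of the
top-hat maximum. Both apply the stated µm² gates, which is why pixel-size
metadata is mandatory. LBs/cell is reported per image and summarized as
the mean of image means ± SEM between images.

Two named morphology features are never defined in the original reports,
so they are defined here explicitly and monotone in the intuitive
direction: *symmetry* is one minus the normalized mismatch between an
object mask and its 180°-rotated self about the centroid; *compactness*
is area divided by convex-hull area. "Intensity" is the object mean;
"spot intensity" is the local-background-corrected mean (object mean
minus the median intensity outside all objects). Group profiles are
normalized to a designated reference group (reference mean ≡ 1). Group
comparison uses a Mann–Whitney test whose two-sided p-value is computed
by exact enumeration of all group assignments (with midranks under ties)
whenever $\binom{m+n}{m} \le 2\cdot10^5$, and by the tie-corrected normal
approximation otherwise; stars are mapped at 0.05 / 0.01 / 0.001 on raw
p-values, matching the figure conventions.

## Raman pipeline

*Cosmic-ray removal* (filter size 3, dynamic factor 8): a sample is a
spike when its positive deviation from the running median of its window
exceeds 8 times a robust scale. The scale is the MAD of the
median-filter residuals, floored at 2% of the spike-free peak-to-peak:
without the floor, a noise-free spectrum has a near-zero MAD and sharp
band tops (whose residual is bounded by band curvature at the 3 cm^-1
sampling) would be flagged; cosmic-ray transients exceed the floored
threshold by an order of magnitude. The filter is idempotent on cleaned
output.

*Baseline correction*: iterative polynomial fitting of degree 3 (fit,
clip the spectrum to the fit from above, refit). The clipping iteration
contracts slowly on noisy spectra — the per-step change decays roughly as
a power of the iteration count rather than geometrically — so the
convergence tolerance is 5×10⁻⁴ of the signal range within 200
iterations; tighter tolerances are not reachable in any reasonable
iteration budget and would not change band areas, which are preserved to
within 5% on constructed band-on-cubic inputs. Non-convergence is an
error, not a warning.

*Band integration* is a trapezoidal integral after subtracting the local
linear baseline through the window endpoints; distribution images use the
published windows (organic matter 2800–3030, lipids 2830–2900, nuclei
780–800 cm^-1).

*Class extraction*: k-means (Lloyd, k-means++ seeding, 10 restarts, fixed
seed, best inertia kept) on vector-normalized spectra, k = 4 — the three
biological classes plus off-cell background, since measured cubes contain
off-cell pixels. Normalization removes focal-volume intensity
differences; spectra whose fingerprint-region norm falls below 10% of the
98th-percentile norm (noise-only background pixels) are scaled by that
floor instead of their own norm, because unit-normalizing pure noise
yields isotropic random directions that defeat any clustering. Clusters
are auto-labelled by marker scores (highest 2830–2900 integral → LB;
highest 780–800 → nucleus; lowest 2800–3030 → background; remainder →
cytoplasm), and a cluster winning two markers is a hard error rather than
a silent relabeling.

*Unsaturation*: the 1660/1440 cm^-1 integrated-intensity ratio
(half-widths 20 and 25 cm^-1; only the band centers are standard, the
widths are configurable choices), calibrated against reference fatty-acid
spectra of known C=C count (oleic 18:1, linoleic 18:2, α-linolenic 18:3).
The synthetic references make the 1660 band area exactly proportional to
the C=C count with an identical 1440 band, so ratio-versus-count is
linear through zero with $R^2 = 1$ to machine precision, and the
calibration inverts exactly at the nodes and on noise-free mixtures.
Integrated intensities are used rather than peak heights (protocol
descriptions vary between the two; integrals are the default, heights remain an
option via narrow windows).

*Statistics*: one-way ANOVA across stimulation groups with per-pair Welch
t-tests against the control (raw p-values with star codes, matching the
figure captions; Dunnett-style adjustment was the alternative and the
choice is recorded in the result). Cytoplasm PCA operates on mean-centred
(optionally vector-normalized) per-cell mean spectra restricted to
600–1800 cm^-1; whether the original analysis used per-cell means or all
pixels is not stated, and per-cell means are the default here with a
per-pixel path available. Loadings are sign-fixed so each loading's
largest-magnitude element is positive.

## Per-cell count statistics

Per-cell LB counts are heavily tied, zero-inflated and far from normal —
the largest fraction of cells shows no LB in the focal plane — so
dispersion is summarized by percent ranks rather than standard
deviations. `percent_rank()` uses the nearest-rank convention
(`sorted[ceiling(p/100 * n)]`), which makes the "percentiles fall
together" behaviour of heavily tied data visible instead of smoothing it
away by interpolation; the median is defined as the 50th percentile under
the same convention. `count_histogram()` and `zero_fraction()` are exact
integer summaries.

## The synthetic-data module

The generators emulate exactly the statistical structure the analysis
assumes, with every random draw flowing from one explicit seed:

* **CARS/TPEF scenes**: non-overlapping round cells (default radius 34 px,
  comfortably above the 2500 px area gate) on a jittered grid; cytoplasm
  = low-amplitude smoothed-noise texture on a base level, so background
  subtraction is exercised nontrivially; LBs are isotropic Gaussian spots
  whose "radius" is defined as 2σ (a thresholded spot then covers roughly
  $\pi r^2$ px, making the 2–20 px diameter gate meaningful), radii 3–6 px,
  peak amplitude ~4× the cytoplasm level with additive Gaussian noise
  ~1% of peak (the high-SNR regime of well-acquired CARS frames); the
  TPEF channel carries Gaussian nucleus blobs. Per-cell LB counts follow
  a pluggable law — constant, Poisson, or zero-inflated Poisson
  (zero-inflation mirrors the observed excess of LB-free focal planes).
  Spot placement keeps LBs isolated (pairwise separation at least the
  sum of radii plus a buffer, geometrically relaxed if a heavy count
  cannot be placed strictly); infeasible cell packings fail loudly.
* **Fluorescence scenes**: 0.65 µm/px; nuclei as smooth-edged discs of
  10 µm diameter (≈78.5 µm², far above the 5 µm² gate); BODIPY spots
  with radii 2.4–3.2 px, whose thresholded areas stay above the 2 µm²
  gate at the detector's relative-height threshold.
* **Raman cubes**: per-pixel nonnegative mixtures of four component
  spectra (lipid, protein, DNA, EPO — with the marker bands at their
  literature positions, e.g. lipid 2850/1744/1660/1440/1304/1269 cm^-1,
  DNA in 780–800 cm^-1, EPO 753/1311/1374/1554/1564/1588 cm^-1) on a
  600–3102 cm^-1 axis at 3 cm^-1 spacing, plus a polynomial baseline
  (degree ≤ 3), Bernoulli cosmic-ray spikes with recorded positions, and
  Gaussian noise.

What the generators deliberately do **not** model: optical physics (no
PSF convolution of the full scene, no nonresonant CARS background, no
shot-noise scaling), overlapping or clumped cells, out-of-focus LBs, and
spectral unmixing ambiguities. Passing recovery tests therefore
demonstrates that the *operator chain is faithful and unbiased under its
own assumptions* — not that those assumptions hold for any particular
instrument.

## Validation by parameter recovery

`simulate_cars_recovery()`, `simulate_fluor_recovery()` and
`simulate_unsaturation_recovery()` generate data whose ground-truth group
mean equals the group means reported for the measured specimens
(CARS per-cell: control 1.94, BA 3.89 LBs/cell; fluorescence: EoL-1 2.35,
BA 3.08 LBs/cell; control-cell unsaturation: 1.5 C=C bonds), run the full
pipelines and compare the recovered means against the generating values
within three standard errors of the ground-truth sample. Problem sizes
are chosen at desk scale: 150–450 cells across 512×512 CARS frames
(25 cells/frame), 4 fluorescence images of 75–100 cells each, and 50
mixture spectra; these sizes put the sampling SEM near the precision at
which the group means are quoted. `scripts/acceptance.R` re-runs all
five recoveries from scratch under a caller-supplied seed, at the upper
end of those sizes so that Poisson sampling noise stays small against
the quoted group means.

## Known limitations

* Single focal plane only: like any single-plane workflow, per-cell counts
  undercount LBs away from the focal plane; comparisons are valid within
  a modality, not across modalities.
* The bandpass stage can produce faint ringing sidelobes next to tight
  spot clusters; at high SNR this yields a ~1% false-positive rate that
  passes the area gate, consistent with the ≥95% precision the detection
  chain is validated to.
* The Columbus-style morphology surrogates (symmetry, compactness,
  spot intensity) are defined quantities, not re-implementations of the
  proprietary features; absolute values are not comparable to Columbus
  output, normalized group contrasts are.
* `clean_mask()` fills holes before the watershed (the published order);
  holes re-opened by the watershed ridge lines are not re-filled.
* "Congruent areas" in the published cleaning recipe is read as
  "connected components".
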