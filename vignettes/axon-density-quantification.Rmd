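---
title: "Quantifying axon density and afferent organization in 3D fluorescence stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying axon density and afferent organization in 3D fluorescence stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axonquant)
```

## The measurement problem

Anterograde tract tracing labels the axons a brain region sends into a
target structure. To compare innervation strength across target
subregions — here, the medial mediodorsal thalamus (MDm), the MDm–PVT
transition zone and the calretinin-rich core of the paraventricular
thalamus (PVT) — one needs a per-volume measure of how much axon is
present in a confocal z-stack. Counting pixels fails because axon
brightness and thickness vary; the robust quantity is the **total
midline length of the axons divided by the physical volume of the
stack** (µm of axon per µm³ of tissue).

axonquant implements that measurement as a chain of five stages, each
exposed as its own function so every intermediate can be inspected and
tested:

1. **Bouton removal** (`segment_boutons()`, `remove_boutons()`). Axonal
   boutons are swellings, en passant along the shaft or drumstick-like at
   terminals, that are much thicker than the shaft. Left in place they
   locally inflate the apparent axon calibre and corrupt the midline.
   A random-forest voxel classifier (`train_bouton_classifier()`) over a
   hand-crafted feature stack — raw intensity, neighbourhood mean and
   variance, gradient magnitude, Laplacian, difference of Gaussians, a
   third-derivative magnitude and the Hessian eigenvalues at several
   scales (`compute_feature_stack()`) — marks bouton voxels, and the
   stack is multiplied by the resulting 0/1 mask, zeroing them.
2. **Tubeness** (`tubeness()`). The stack is smoothed with an isotropic
   Gaussian of physical standard deviation σ and each voxel scored by the
   classical bright-tube measure: with Hessian eigenvalues sorted by
   signed value (λ₁ ≥ λ₂ ≥ λ₃), the score is √(λ₂·λ₃) where λ₂ and λ₃
   are both negative, else 0. A bright cylinder on a dark background has
   two strongly negative cross-sectional curvatures and one near-zero
   axial curvature, so the score ridges along the tube midline while
   rejecting flat background.
3. **Thresholding** (`threshold_tubeness()`). Two-level hysteresis:
   voxels scoring at least `high` seed the foreground, voxels scoring at
   least `low` are kept when 26-connected to a seed. Setting
   `low == high` recovers plain thresholding.
4. **Skeletonization** (`skeletonize()`). The binary foreground is
   thinned to a one-voxel-wide curve skeleton.
5. **Length and density** (`skeleton_length()`, `axon_density()`). The
   skeleton length is the sum, over every unique pair of 26-adjacent
   skeleton voxels, of the step length — voxel size × 1, √2 or √3 for
   face, edge and corner adjacency — and density is length divided by
   the stack volume.

Around this core the package provides the two companion analyses used
to interpret densities anatomically: a systematic ROI grid with region
parcellation and line-intensity profiles (`build_grid()`,
`assign_regions()`, `measure_grid()`, `line_profile()`), and
normalization plus phenotype classification of retrograde cell-count
tables (`normalize_counts()`, `summarize_regions()`,
`classify_region()`, `coverage_summary()`), together with the
statistical battery those comparisons require (`correlate()`,
`ttest_groups()`, `anova_oneway()`, `anova_rm()`).

## Parameters that matter

| Parameter | Default | Unit | Meaning |
|---|---|---|---|
| `voxel_size_um` | 0.09 | µm | isotropic voxel edge of the stacks |
| `sigma_um` | 0.32 | µm | tubeness scale; matches the minimum axon diameter of 0.32 µm so the thinnest axons of interest still produce a full-strength ridge |
| `low`, `high` | data-driven | score | hysteresis thresholds; `high` defaults to Otsu's threshold over the strictly positive scores, `low` to half of it |
| `grid_window_um` | 89.51 | µm | ROI side length |
| `grid_spacing_um` | 100 | µm | ROI centre-to-centre interval |
| ratio thresholds | 0.2, 5 | – | afferent phenotype rule (below) |

σ is converted to voxels as `sigma_um / voxel_size_um` (0.32/0.09 ≈ 3.56
voxels), preserving the physical scale whatever the sampling. Scales
below one voxel are rejected as undersampled.

The **phenotype rule** for retrograde counts takes the ratio
r = (vGLUT2⁺ fraction)/(vGAT⁺ fraction) per region: r < 0.2 (five-fold
GABAergic dominance) calls the region GABAergic, r > 5 glutamatergic,
and the closed interval [0.2, 5] mixed. One-sided zero fractions map to
the corresponding extreme; a region with both fractions zero is not a
valid input region. The rule is scale-invariant, so it can be applied
to raw counts or percentages alike. The threshold glosses pin the
convention: "five times more vGAT⁺" must mean the vGLUT2/vGAT ratio is
small, and a vGAT-dominant example region with ratio 0.18 is called
GABAergic; the package follows that reading.

## What the synthetic generator emulates — and what it does not

No imaging data ship with the package; every claim its tests make is
grounded in synthetic stacks with exact ground truth
(`generate_axon_stack()`):

* **Centerlines** are unit-speed random walks whose direction receives a
  Gaussian kick of standard deviation `tortuosity · √step` per step
  (default tortuosity 0.3 µm^-1/2, i.e. a directional persistence length
  of roughly 10 µm — gently curved at the scale of these stacks). Walks
  run from a random interior point to the stack faces in both
  directions, mirroring the fact that axon shafts cross an imaged
  volume rather than terminating inside it.
* **Tubes** are rendered as isotropic Gaussian profiles of standard
  deviation `axon_radius_um / 2` (default radius 0.16 µm, diameter
  0.32 µm), max-combined along the densely resampled centerline: a
  diffraction-blurred stand-in for a thin neurite.
* **Boutons** are brighter Gaussian spheres (default radius 0.4 µm,
  double the tube's peak) at Poisson-distributed arc positions (default
  0.2 µm⁻¹), en passant; terminal "drumstick" placement is available via
  `terminal_boutons`.
* **Noise** is Gaussian read noise (default sd 5 AU on a 200 AU tube
  peak) with optional Poisson shot noise.

The generator records the exact centerlines, their total length, and
every bouton, so recovery can be scored against truth. It deliberately
omits optical PSF anisotropy, spectral bleed-through, depth-dependent
attenuation and tissue deformation. Passing the recovery tests
therefore shows the geometry pipeline is unbiased and calibrated on
clean tube phantoms; it does not certify performance on real tissue,
where the bouton classifier in particular must be retrained on manual
annotations.

Companion generators produce the other two test substrates: a
three-region intensity field with the core > transition > MDm gradient
and its exact label map (`generate_region_field()`), and multinomial
per-region cell-count tables for two genotypes
(`generate_count_table()`), for which the published per-region mean
percentages (`pvt_input_fractions()`) serve as a realistic generating
profile.

## Numerical choices

**"Bilateral" thresholding as hysteresis.** The two-level scheme was
chosen as the most useful reading of a two-threshold binarization: it
keeps faint shaft segments only when they connect to confident ones,
and degenerates to the simplest reading (`low == high`) on request.

**Skeletonization.** Thinning is distance-ordered homotopic thinning:
border voxels are peeled in increasing chamfer-(3,4,5) distance to the
background, and a voxel is deleted only when it is *simple* — its
removal changes neither the number of 26-connected foreground
components in its neighbourhood nor the 6-connected background
components touching it — and not a curve endpoint (a voxel with at most
one foreground neighbour). Peeling inside-out keeps the surviving curve
on the medial line of the sleeve; within a distance level the six face
directions alternate so ties are resolved symmetrically. The operation
preserves topology (components and cycles) and is idempotent.

**Length bias.** Measuring a digital curve with the (1, √2, √3) step
weights systematically overestimates the continuous length of obliquely
oriented lines — a well-known property of local chain metrics, of the
order of +5 to +15 % depending on orientation and curvature. The
ground-truth recovery tolerance (15 %) covers this bias plus thinning
jitter; the bias largely cancels in ratios of densities, which is how
regional comparisons are consumed.

**Default thresholds.** Otsu's threshold over the positive tubeness
scores seeds the hysteresis (`high`), with `low = high/2`. Both are
data-driven because absolute tubeness values scale with image contrast;
both can be overridden, and all comparative analyses in the test-suite
fix them across arms when ablating a stage, since a data-driven
threshold re-estimated under a different stack composition would
confound the comparison.

**Bouton training labels.** When training from synthetic truth
(`labels_from_truth()`), bouton voxels are labeled out to 1.5× the
nominal bouton radius so the class covers the whole blur-skirted
swelling. Labeling only the core would leave a bright shell after mask
multiplication, and the shell's rim responds to the tubeness filter as
spurious structure.

**Repeated-measures ANOVA.** The within-subject F uses the
subject-by-condition interaction as error; the p-value applies the
Greenhouse–Geisser sphericity correction, computed from the condition
covariance matrix, to both degrees of freedom (reported as fractional
df). Tukey pairwise comparisons use the interaction mean square with
its uncorrected df. The correction matters because regional intensity
measurements on the same animals are strongly and unevenly correlated.

**Region tie-break.** A grid window whose covered pixels split exactly
evenly between two regions is excluded from analysis, as is any window
dominated by unlabeled tissue — ambiguous windows should not vote.

## Problem sizes

The test-suite and the acceptance script run on 48³–64³ voxel stacks
(4.3–5.8 µm cubes at the 0.09 µm default), 1–4 axons each, mirroring
the ~5 µm stack depth the geometry was designed around while keeping a
full run in minutes on one CPU. ANOVA calibration uses 10,000 simulated
null datasets of three groups of six; count-table recovery uses three
animals per genotype at ~470 cells per animal, matching the scale of
the retrograde experiments the generator emulates.

## Known limitations

* The bouton classifier shipped in tests is trained on synthetic
  phantoms; real stacks need their own sparse manual annotations.
* Hole-cutting removal of boutons at high bouton rates on very short
  axons can remove a large share of the measurable length; on
  realistic window sizes the removed fraction is small.
* Densities are length densities; no attempt is made to count boutons,
  identify synapses or trace axon identity across windows.
* The digital length metric's orientation-dependent bias (above) makes
  absolute densities comparable only within a fixed protocol; ratios
  and region contrasts are the robust quantities.
* Anisotropic voxels are rejected rather than resampled; registration
  to an atlas and anatomical delineation of regions are out of scope —
  label maps are supplied by the user (or the synthetic generator).
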