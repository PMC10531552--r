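---
title: "Multiparametric habitat analysis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiparametric habitat analysis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mphabitat)
```

## The problem and the model

Neuroblastic tumors are internally heterogeneous: undifferentiated, highly
proliferative tissue, necrosis, and maturing (ganglioneuromatous) tissue can
coexist in one lesion, and change differentially under chemotherapy. Two
quantitative imaging channels see complementary aspects of this: the
standardized uptake value (SUV, unitless) from [¹⁸F]FDG-PET measures
glucose metabolism, and the apparent diffusion coefficient (ADC, carried
here in 10⁻⁶ mm²/s) from diffusion-weighted MRI falls with cellular
density. Highly vital tissue is expected to show high SUV with restricted
diffusion (low ADC), necrotic or matured tissue the opposite — and the two
channels should correlate negatively where tissue vitality varies within a
compartment.

The pipeline treats every voxel of a tumor VOI as an observation of the
pair (ADC, SUV) and proceeds in two complementary ways:

* **Fixed-threshold classification** into virtual tissue groups using
  literature cutoffs (SUV 2.5; ADC 1250 × 10⁻⁶ mm²/s). The quadrant rule is
  a *partition*: vital (SUV > 2.5 ∧ ADC < 1250), low-vital
  (SUV < 2.5 ∧ ADC > 1250), equivocal otherwise. The source description of
  the low-vital group as an OR-condition overlaps the equivocal definition;
  the AND (quadrant) reading is the only one consistent with the four
  enumerated quadrants, and is what this package implements. Exact
  threshold equality is mapped to equivocal — the inclusive inequalities
  appear only on the equivocal clauses in the source description, and the
  choice has measure zero on continuous data.

* **Unsupervised mixture clustering**: a 3-component Gaussian mixture on
  pooled, z-normalized values, so subregions ("habitats") emerge from the
  data rather than from fixed cutoffs, with demarcation thresholds defined
  by density intersections in the 1D mode.

Assumptions the analysis inherits from the data model: inputs are
co-registered in world coordinates (only grid resampling is performed —
the vendor's non-rigid fusion is out of scope and is replaced by this
contract); the VOI excludes vessels and hematomas; SUV and ADC are
comparable across patients after pooled z-normalization.

## Grid harmonization and units

All analysis happens on the MR grid of 0.7 × 0.7 × 5 mm (voxel volume
2.45 mm³ = 0.00245 mL); PET volumes (native 2.8 × 2.8 × 2 mm) are resampled
onto it with trilinear interpolation. Trilinear is our choice — the
original vendor interpolator is unknown; it is exact for affine fields
(tested against the closed form) and preserves constants. Masks and label
volumes use nearest-neighbour. Voxels outside the source extent become
missing and are dropped with a count, never extrapolated.

ADC is canonically 10⁻⁶ mm²/s, so the threshold is the literal number 1250.
Files stored in mm²/s are detected by magnitude (median of positive voxels
< 0.1) and converted with a message. Voxel indices are 0-based and arrays
are indexed (x, y, z) in NIfTI header order; one stated convention
prevents silent transposition.

## Key parameters

| parameter | default | unit | why |
|---|---|---|---|
| `suv_cut` | 2.5 | – | literature cutoff malignant vs low-vital uptake |
| `adc_cut` | 1250 | 10⁻⁶ mm²/s | literature diffusion cutoff |
| `adc_outlier` | 50 | 10⁻⁶ mm²/s | voxels at/below are artifacts; excluded |
| `n_target` (standardization) | 1000 | voxels | equal weight per tumor/timepoint |
| GMM `k` | 3 | – | three habitats; model-order selection is a non-goal |
| GMM `tol` / `max_iter` / `n_init` | 10⁻⁶ / 500 / 5 | – | relative log-likelihood stop; seeded restarts |
| covariance floor | 10⁻⁶ | normalized units² | keeps collapsed components positive-definite |

Standardization to *exactly* 1000 voxels subsamples uniformly without
replacement when the tumor is larger and bootstraps with replacement when
smaller. "Extrapolation" is not specified in the source; the bootstrap
preserves the empirical distribution without inventing values, which is why
it was chosen. It is applied per tumor per timepoint (the per-tumor-overall
alternative is not implemented; the source is silent, and per-timepoint is
the only reading under which both timepoints contribute equally to the
pooled fit).

Normalization uses the population (divide-by-n) standard deviation so that
the unit-variance postcondition is exact (|mean| and |sd − 1| below 10⁻¹⁰
are asserted, not approximated), and pools all patients and timepoints in
one cohort pass; a per-patient variant is deliberately not the default.
The constants are returned for exact inversion.

## The mixture model

EM is implemented in the package: E-step responsibilities via log-sum-exp
(no underflow at habitat-scale n), M-step weighted moments, covariance
eigenvalues floored at 10⁻⁶, initialization by seeded k-means++-style
center seeding plus one hard-assignment moment step, best of 5 restarts
kept. The log-likelihood trace is stored; monotonicity is a test invariant
on every fixture.

The source is ambiguous about dimensionality: intersection-derived
demarcation thresholds are inherently 1D, while the published cluster
clouds are bivariate. Both are implemented; the pipeline default is the 2D
fit on (ADC_norm, SUV_norm) with maximum-responsibility assignment, and the
1D mode (default variable: normalized SUV, the metabolic axis; the original
choice of variable is unstated) cuts at the demarcation thresholds. For
two weighted 1D Gaussians the intersections solve a quadratic obtained from
the log-densities; the root lying between the two component means is the
demarcation threshold, and if none lies between (extreme weight or variance
imbalance) the midpoint of the means is substituted with a warning.

Label switching is resolved deterministically: the component with the
highest mean normalized SUV minus ADC is `vital`, the lowest is
`low_vital`, the remainder `equivocal`. This is invariant to component
permutation (tested by permuting fitted components).

Clustering is fitted per display subset (baseline, post-response,
post-progression) by default, mirroring how the cluster distributions are
reported per subgroup; a pooled single fit is available via
`cluster_scope = "pooled"`.

## Statistics

Wilcoxon signed-rank for paired data drops zero differences (classical
convention, not Pratt), uses midranks for ties, reports W = min(W⁺, W⁻),
and computes the two-sided p exactly for effective n ≤ 15 as
P(min(W⁺, W⁻) ≤ W_obs) over the full sign-assignment distribution
(dynamic-programming convolution; doubled ranks keep midranks integral).
Beyond 15 it uses the normal approximation with tie correction and a 0.5
continuity correction. All p-values are two-sided. Null calibration uses
cohorts of 10 exchangeable pairs because the exact test size there
(4.88%) is the achievable level closest to nominal 5% — the statistic is
discrete, so "5%" is only approachable, not attainable.

Point-biserial correlation is computed as Pearson on 0/1 coding (they are
identical; the identity is pinned by tests), used to relate per-group
subvolume changes to response status; R² of the simple regression equals
the squared Pearson correlation by construction.

## What the phantom emulates — and what it does not

The generator produces, per patient and timepoint: an ellipsoidal VOI on
the MR grid; *contiguous* compartments (a seeded nearest-seed-point
partition of the mask into blobs of ~250 voxels, assigned to compartments
along a random cell order so empirical fractions track the targets with
error bounded by one cell); per-voxel bivariate Gaussian (ADC, SUV)
emission truncated to ADC > 0, SUV ≥ 0 by rejection; additive Gaussian
measurement noise (ADC 20, SUV 0.1); and SUV gridded onto the PET grid by
averaging the MR-grid values covered by each PET voxel.

Defaults state the world once: baseline fractions 26.3/37.9/35.8 %
(vital/equivocal/low-vital); emission means vital (850, 4.0), equivocal
(1100, 1.8), low-vital (1700, 1.2) with SDs 200 / 0.7 — chosen to straddle
the thresholds at realistic tissue overlap, not taken from any table — and
ADC–SUV coupling −0.4 inside the vital compartment (0 elsewhere). Therapy
transforms shrink the mask (response total-volume factor 0.2, progression
0.5), redraw fractions (response 0.03/34.3/65.7 %, progression
41.8/33.3/24.9 %) and shift means (response ADC +200, SUV −0.4;
progression the reverse signs), so cohort mean ADC rises and mean SUV falls
under response and vice versa. Blob size is a free texture parameter, not
an inference target.

Deliberate non-features: no PET physics (attenuation, scatter,
reconstruction; partial volume only via grid averaging), no MR artifacts,
no non-rigid deformation between timepoints, and irregular VOI shapes are
not simulated — an ellipsoid already exercises every boundary code path.

Hence a green recovery test establishes that classification, clustering
and the statistics recover a known generating structure through the real
code path; it does not establish scanner-level realism. Two consequences
worth knowing:

* Recovery tests read the *latent* MR-grid emission (`phantom_table(...,
  use = "latent")`). The pipeline route through PET gridding and trilinear
  resampling intentionally smears SUV across compartment borders (a
  partial-volume effect), biasing the classified vital fraction low at
  default overlap — visible in the README example. Direction-of-change
  conclusions survive this; absolute fractions do not have to.
* "Well-separated compartments" in the recovery criteria is made precise
  a priori: every compartment mean at least ~2 effective SDs (emission SD
  plus measurement noise in quadrature) from both thresholds, putting
  analytic cross-threshold leakage below 3% per channel by the normal CDF.
  The generator defaults are *not* that separated — by design — so the
  acceptance fixtures override the SDs.

The published cohort quantities that depend on the unavailable patient data
(exact Table-style proportions, per-cluster R values) are treated as
qualitative direction checks on phantoms, never as numeric targets.

## Numerical choices and degenerate inputs

* Percentiles: linear interpolation between order statistics (type 7); the
  source names no convention, this one makes tests exact.
* Volumes are kept unrounded internally and rounded to the nearest mL only
  in reports.
* Constant input to `znormalize` is a refused degenerate error, as is a
  pair of identical components in `gaussian_intersections` (infinitely
  many intersections).
* A mixture fitted to one true component must not crash: extra components
  either lose weight or hit the covariance floor (tested).
* All randomness is seeded through a save/restore wrapper, so library
  calls never perturb the caller's RNG stream; derived seeds stay below
  2³¹.
* NIfTI-1 I/O is implemented in base R (no R-side NIfTI package is
  available in the supported environment): single-file `.nii`/`.nii.gz`,
  common datatypes, diagonal affines, slope/intercept scaling on read.
  Doubles are written as float64, so round trips are bit-exact. The layer
  is cross-validated against an independent Python reader when one is on
  PATH.

## Known limitations

Only axis-aligned affines are supported in the NIfTI layer; deformable
registration, lesion-wise subdivision, DICOM, survival modeling and
data-driven threshold optimization are out of scope. The bootstrap reading
of "extrapolated", the 1D clustering variable, and the boundary-equality
tie rule are documented interpretations of an underspecified source; each
is isolated behind one function so alternative readings are one-line
changes.
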