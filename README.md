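# mphabitat

Voxel-wise combined metabolic–functional habitat analysis of tumor volumes
from hybrid PET/MRI, aimed at heterogeneous pediatric tumors such as
neuroblastoma, where vital, necrotic and maturing tissue coexist inside one
lesion and a single biopsy cannot characterize the whole mass.

The package is written for imaging scientists who have, per patient and
timepoint, a standardized-uptake-value (SUV) map from [¹⁸F]FDG-PET, an
apparent-diffusion-coefficient (ADC) map from DWI, and a tumor VOI mask —
co-registered, in NIfTI — and who want reproducible subvolume statistics
across a therapy course. A synthetic phantom generator with known ground
truth makes every stage testable without patient data.

## What it computes

For each voxel inside the VOI (on the MR analysis grid of
0.7 × 0.7 × 5 mm³, so one voxel is 2.45 mm³ = 0.00245 mL):

1. **Virtual tissue groups** by fixed thresholds. With SUV cut 2.5 and ADC
   cut 1250 × 10⁻⁶ mm²/s (voxels with ADC ≤ 50 excluded as outliers):

   - *vital*: SUV > 2.5 and ADC < 1250 (metabolically active, cellular)
   - *low vital*: SUV < 2.5 and ADC > 1250 (necrotic / matured)
   - *equivocal*: the two discordant quadrants (ties included)

2. **Size standardization and normalization.** Each tumor/timepoint dataset
   is reduced (subsampling) or extrapolated (bootstrap) to exactly 1000
   voxels, then ADC and SUV are z-normalized, pooled over the whole cohort:
   x_norm = (x − mean(x)) / sd(x).

3. **Mixture-model habitats.** A 3-component Gaussian mixture is fitted to
   the normalized (ADC, SUV) values by EM (implemented in the package, with
   log-sum-exp responsibilities, seeded k-means++ restarts and a covariance
   floor). In 1D mode, the intersection points of adjacent weighted
   component densities — solved in closed form from the quadratic in the
   log-densities — become the demarcation thresholds between subregions.

4. **Cohort statistics.** Subvolume proportions and volumes (count × voxel
   volume), pre/post deltas, within-cluster Pearson ADC–SUV correlation,
   point-biserial correlation and linear regression of subvolume changes on
   response status, and Wilcoxon signed-rank paired tests (exact p by full
   sign enumeration up to n = 15, tie-corrected normal approximation
   beyond).

## Worked example

```r
library(mphabitat)

ph  <- generate_phantom(phantom_config(seed = 11))
round(phantom_truth_fractions(ph), 3)
#>     vital equivocal low_vital
#>     0.281     0.333     0.386

tab <- phantom_table(ph, use = "pipeline")   # PET->MR resampling + masking
tab <- filter_outliers(tab)
tab <- classify_voxels(tab)
voxel_summary(tab)
#> voxels: 5920  volume: 15 mL
#>   ADC: mean 1.26e+03  median 1.2e+03  p5 662  p95 1.93e+03
#>   SUV: mean 1.54  median 1.34  p5 0.629  p95 3.48

post <- apply_therapy_course(ph, "response")
ptab <- classify_voxels(filter_outliers(phantom_table(post, use = "pipeline")))
compare_timepoints(group_proportions(tab), group_proportions(ptab))
#>       group  pre post delta direction
#> 1     vital 0.12 0.00 -0.12  decrease
#> 2 equivocal 0.42 0.16 -0.26  decrease
#> 3 low_vital 0.46 0.84  0.38  increase
```

The summary reads: 5920 retained voxels (15 mL) with cohort-typical ADC
(mean ≈ 1260 × 10⁻⁶ mm²/s) and SUV (mean ≈ 1.5). After the simulated
response, the vital subvolume collapses and low-vital tissue dominates —
the direction of change expected under effective chemotherapy. Note the
classified baseline vital fraction (0.12) is below the generator truth
(0.28): PET-grid averaging smears high-SUV voxels across compartment
borders (a partial-volume effect the phantom reproduces on purpose).

A full synthetic cohort (6 responders, 2 progressors, baseline + post):

```r
res <- run_pipeline(cohort_config(seed = 1), out_dir = "cohort_out")
res$tests$wilcoxon_mean_adc_response$p   # paired signed-rank, mean ADC
```

writes `result.json`, `proportions.csv`, `clusters.csv` and a readable
`report.md`. A CLI wrapper lives at `inst/cli/mphabitat.R`
(`generate`, `run`, `summarize` subcommands; YAML configs).

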