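# fatquant

Computer-assisted quantification of supraspinatus muscle atrophy and
fatty infiltration on scapular Y-view shoulder MRI.

Rotator-cuff tear severity is routinely judged from two indices measured
on the scapular Y-view (the most lateral T1 sagittal-oblique slice where
the scapular spine meets the scapular body): the **occupation ratio**
(muscle area / supraspinatus-fossa area, an index of atrophy) and
**fatty infiltration** (the share of fat within the muscle, classically
graded 0–4 by eye on the Goutallier scale). Manual measurement is slow
and only moderately reliable. `fatquant` provides the computational
half of an automated reading: given a slice and fossa/muscle region
masks (drawn by a clinician or predicted by the bundled segmentation
network), it computes both indices objectively and reproducibly.

The package is aimed at musculoskeletal-imaging researchers who want a
scriptable, testable implementation of region-restricted adaptive Otsu
fat quantification, plus the scaffolding around it: segmentation
agreement metrics, leakage-safe augmentation, a k-fold harness, cohort
statistics, and a phantom generator with exact ground truth.

## The method in brief

Fat is bright on T1. Within the muscle mask, the 256-bin gray-level
histogram is thresholded by Otsu's criterion — maximize the
between-class variance σ<sub>B</sub>²(t) = ω₀ω₁(μ₀−μ₁)² over t ∈ 0…255 —
and pixels strictly above the threshold count as fat:

FI (%) = 100 · (fat pixels) / (muscle pixels).

Two refinements make this clinically usable:

* **Adaptive equalization gate.** Severely degenerated muscle shows fat
  at several intensity levels, which can defeat a two-class threshold;
  when the ROI's population SD is ≥ 35 gray levels, histogram
  equalization (computed from and applied to ROI pixels only) is run
  first, converting intensity gaps into probability-mass gaps. Below
  the gate, equalization is withheld because it washes out low-severity
  ROIs.
* **Separability safeguard.** A fat class is only declared when the best
  two-class split explains ≥ 70% of the ROI intensity variance (Otsu's
  effectiveness ratio η; a single noisy tissue population caps at
  2/π ≈ 0.64). Otherwise the ROI is reported fat-free with the
  threshold at the ROI maximum — a healthy muscle yields 0% fat, not an
  invented ~50% split of its noise.

Everything runs on a fixed 8-bit per-slice normalized scale. The
package reads 8-bit PNG, NIfTI-1 (slices and ITK-SNAP-style integer
label maps) and single-frame uncompressed DICOM.

## Worked example

```r
library(fatquant)

# a synthetic Y-view phantom with known truth: occupation ratio 0.55,
# 30% fat, noiseless
spec <- phantom_spec(image_size = 256L, occupation_ratio_true = 0.55,
                     fat_fraction_true = 0.30, intensity_sd = 0, seed = 42L)
case <- generate_phantom(spec)
case
#> <phantom_case seed 42> 256x256, OR true 0.550, FF true 0.300, fat px 3143

occupation_ratio(case$masks)
#> [1] 0.55

quantify_fat(case$slice, case$masks$muscle)
#> <otsu_result> threshold 178, ROI SD 54.99 (gate 35, equalized: TRUE), FI 30.00% (3143 / 10476 px)
```

The quantifier recovers the planted 30% fat fraction exactly: the ROI SD
(54.99) is above the gate, so the ROI was equalized before thresholding,
and the 3143 pixels above the threshold are precisely the planted fat
pixels. On a fat-free muscle with realistic noise, the separability
safeguard keeps the reading at zero instead of splitting the noise:

```r
noisy <- generate_phantom(phantom_spec(image_size = 256L,
                                       fat_fraction_true = 0,
                                       intensity_sd = 10, seed = 43L))
quantify_fat(noisy$slice, noisy$masks$muscle)
#> <otsu_result> threshold 100, ROI SD 9.97 (gate 35, equalized: FALSE), FI 0.00% (0 / 10414 px)
```

Batch processing, including per-case JSON, fat-mask PNGs (white = fat,
black = muscle), a cohort CSV and grade-wise statistics, goes through
`run_pipeline()`, or from a shell via the thin CLI:

```sh
Rscript inst/cli/fatquant.R phantom --n 10 --out ph/
Rscript inst/cli/fatquant.R fi --image ph/case-001.png \
    --labels ph/case-001_labels.nii.gz --out fi.json
Rscript inst/cli/fatquant.R pipeline --manifest manifest.csv --out results/
```

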