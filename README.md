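# adipoquant

Quantification of abdominal adipose tissue from hybrid PET/MR imaging.

Visceral adipose tissue (VAT, the fat packed around intra-abdominal organs)
and subcutaneous adipose tissue (SAT, the fat between skin and abdominal
wall) carry very different cardiometabolic risk: excess VAT is independently
associated with metabolic syndrome, atherosclerosis and cardiovascular
disease, and is a key imaging biomarker in obstructive sleep apnea and
obesity research. Hybrid FDG-PET/MRI measures both the *volume* of each
depot (from fat-phase MRI, where adipose tissue is bright) and its
*metabolic activity* (SUVmean, the mean standardized uptake value of the
co-registered PET).

`adipoquant` is an R toolkit for the full analysis chain used in such
studies:

* **Annotations to masks.** Per-slice polygon contours labelled `EXT`
  (external body outline), `INT` (internal abdominal wall) and `EXC`
  (exclusion organs: kidneys, spinal bone marrow, which would otherwise
  contribute false FDG signal) are rasterized to binary masks
  (boundary-inclusive, even–odd fill).
* **Depot construction.** SAT = `EXT ∧ ¬INT`; VAT = `INT ∧ ¬EXC`
  intersected per slice with an adaptive intensity threshold
  `T_s = μ_s + k·σ_s` (statistics over the INT region; keep `≥ T_s`) that
  discards dark lean tissue.
* **Volumes and SUVmean.** Depot volume = voxel count × `dz·dy·dx`;
  each depot mask is resampled onto the coarser PET grid by
  nearest-neighbour interpolation in world millimetres, and the global
  SUVmean is the unweighted average of slice-wise means.
* **Evaluation.** Mask Dice and contour Dice (Dice of the 3×3
  morphological-gradient boundary rings — far more sensitive to boundary
  placement than mask Dice), ICC(2,1) absolute agreement, Bland–Altman bias
  ± SD with 95% limits of agreement (`bias ± 1.96·SD`), and the paired
  Wilcoxon signed-rank test (exact up to n = 12).
* **Synthetic phantoms.** A seeded 3-D abdominal phantom generator (fat
  ring, visceral fat blobs, kidney/spine exclusion organs, co-registered
  coarser PET with VAT uptake ≫ SAT uptake) with ground-truth contours and
  label maps, so every stage runs and is testable without any scan data.
* **Segmentation harness.** A small encoder–decoder network (pure R) on
  2-D slices with the standard contract — resize to 224×224, per-slice
  z-score, three sigmoid channels, binary cross-entropy — plus a closed-loop
  annotate → correct → retrain procedure producing staged checkpoints
  V1, V2, V3, each initialized from the previous round's weights.

## Worked example

```r
library(adipoquant)

# a noise-free synthetic scan with known ground truth
spec <- phantom_spec(dims = c(40, 96, 120), noise_sd = 0, seed = 4)
ph <- generate_phantom(spec)

m <- measure_scan(ph$mri, ph$pet, ph$truth_rois, threshold_policy(k = 0))
m
#>   sat_volume_cm3 vat_volume_cm3 vat_sat_ratio sat_suv_mean vat_suv_mean
#> 1       219.9951       133.1035     0.6050294         0.24         0.75
```

SAT and VAT volumes equal the generator's voxel counts times the voxel
volume exactly, and the SUVmeans recover the generator's uptake constants
(0.24 for SAT, 0.75 for VAT) exactly — the adaptive threshold at `k = 0`
separates the phantom's bright-fat/dark-lean intensities cleanly, and the
nearest-neighbour mask resampling lands on PET voxels carrying the depot's
constant uptake.

Evaluating an imperfect segmentation (a smoothly perturbed copy of the
truth, 1-voxel amplitude) reproduces the characteristic pattern of high
mask Dice with visibly lower contour Dice:

```r
pred <- perturb_roi(ph$truth_rois, magnitude = 1, seed = 2)
evaluate_segmentation(ph$truth_rois, pred)
#>   label mask_dice contour_dice pooled
#> 1   EXT 0.9845769    0.7569633   TRUE
#> 2   INT 0.9820206    0.7601742   TRUE
#> 3   EXC 0.8397369    0.7812734   TRUE
```

Agreement statistics over a cohort of paired measurements:

```r
ba <- bland_altman(paired_series(1:10, manual_values, predicted_values))
icc <- icc_absolute_agreement(paired_series(1:10, manual_values, predicted_values))
```

## Command line

`inst/cli/adipoquant.R` exposes `phantom`, `quantify`, `evaluate`, `agree`,
`train`, `predict`, `closed-loop` and an end-to-end `pipeline` demo:

```sh
Rscript inst/cli/adipoquant.R phantom --out ph1 --seed 4 --noise-sd 0
Rscript inst/cli/adipoquant.R quantify --mri ph1/mri.nii.gz --pet ph1/pet.nii.gz \
    --roi ph1/truth_rois.json --out measurements.csv --scan-id demo
Rscript inst/cli/adipoquant.R pipeline --n-cases 4 --out-dir pipe --seed 2
```

Volumes travel as NIfTI-1 (`.nii` / `.nii.gz`), annotations as a small JSON
schema (documented in `?read_roi_json`), tables as CSV.

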