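---
title: "Methods: abdominal adipose quantification from PET/MR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: abdominal adipose quantification from PET/MR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the science it implements:
the measurement model and its assumptions, the parameters that matter, the
numerical conventions that had to be pinned down, what the synthetic
phantom emulates, and the known limitations. It states no empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## The measurement model

A scan consists of a fat-phase MRI volume (adipose tissue bright, lean
tissue dark; typical geometry 291 × 360 in-plane, 80–100 slices, voxels
1.39 × 1.39 × 2.09 mm) and a simultaneously acquired, hence inherently
co-registered, FDG-PET volume on a coarser grid. Annotations are per-slice
closed polygons over the abdominal range (pelvic floor at the L4–L5
interspace up to the diaphragm) with three labels:

* `EXT` — the external body outline,
* `INT` — the internal abdominal wall,
* `EXC` — exclusion organs (kidneys, spinal bone marrow) whose high FDG
  uptake would otherwise contaminate the visceral fat signal.

From rasterized masks the two depots are

* **SAT** (subcutaneous): `EXT ∧ ¬INT`, the ring between skin and
  abdominal wall;
* **VAT** (visceral): `INT ∧ ¬EXC`, further intersected per slice with the
  adaptive intensity keep-mask `{I ≥ T_s}` where `T_s = μ_s + k·σ_s`.
  Fat is bright on fat-phase MRI, so thresholding at the region mean
  discards the dark lean interior (bowel, muscle, fluid) that the coarse
  `INT` polygon necessarily encloses.

Depot volume is the voxel count times the voxel volume `dz·dy·dx` (reported
in cm³). For metabolic quantification the binary depot mask — never the PET
activity — is resampled onto the PET grid by nearest-neighbour lookup in
world millimetres, and SUVmean is computed slice-wise and averaged,
unweighted, over slices containing at least one masked voxel.

## Parameters and conventions

| parameter | default | meaning / rationale |
|---|---|---|
| `k` | 0 | SD multiplier in `T_s = μ_s + k·σ_s`. The source method states only "mean and standard deviation"; `k = 0` (threshold at the mean) is the least-assumption reading and cleanly splits a bimodal bright-fat/dark-lean mixture. |
| `stat_region` | `INT_REGION` | Population over which `μ_s, σ_s` are computed. Whole-slice statistics would be dragged down by background air; the INT interior is the relevant mixture. `WHOLE_SLICE` is retained as an option. |
| `apply_to_sat` | `TRUE` | Whether the threshold also applies to the SAT ring. The source is contradictory (its figure applies the threshold to both depots, its text only to VAT); both behaviours are one flag apart. |
| comparator | `≥ T_s` | Keep is boundary-inclusive; pinned so the all-equal-intensity slice keeps everything. |
| SD form | population (1/N) | Immaterial at slice pixel counts but pinned for exactness of tests. |
| fill rule | even–odd, boundary-inclusive | A pixel is inside if its centre is inside or on the polygon boundary; pixel centres sit at integer voxel coordinates, 0-based, axis order `(slice, row, col)` everywhere. The experts' tool's exact fill convention is unknowable; agreement statistics absorb sub-pixel discrepancies. |
| nearest-neighbour ties | toward the lower index | `index = ceiling(u − 0.5)` on the axis coordinate `u`; deterministic. PET centres outside the MRI field of view map to `FALSE`. |
| global SUVmean | unweighted slice average | The stated procedure averages slice-wise means; the voxel-weighted pooled mean is also returned (`voxel_weighted_mean`) since the two differ when slice mask sizes vary. Slices with empty masks are skipped, not counted as zeros. |
| Dice pooling | volume-pooled | Intersections and sizes are summed over slices before dividing; insensitive to tiny-slice instability. Slice-averaged is available (`pooled = FALSE`) since the published choice is unstated. |
| empty-mask Dice | both empty → 1, one empty → 0 | Perfect agreement on absence. |
| morphology | 2-D, 3 × 3, `FALSE` padding | The contour is `dilate ∧ ¬erode` per slice; the quoted kernel is planar and annotations are per-slice. |
| ICC | ICC(2,1) | Two-way random effects, absolute agreement, single measurement — the correct variant for method interchangeability (a systematic offset must lower it). The source never names its variant. |
| LOA multiplier | 1.96 | Fixed normal quantile, not a t-quantile: the published limits reproduce as `bias ± 1.96·SD` (e.g. 91 + 1.96·223 = 528.08 ≈ printed 528). |
| bias SD | sample (n−1) | Convention for Bland–Altman at cohort size n = 10. |
| Wilcoxon | drop zeros, midranks, exact ≤ 12 | Exact branch enumerates all 2ⁿ sign assignments of the observed ranks (valid under ties); above n = 12 a continuity-corrected normal approximation with tie correction (`Var = Σr²/4`). |

Multiple `EXT` or `INT` contours on one slice are rejected as invalid
rather than unioned — anatomy implies one body outline per slice, and
failing loudly catches annotation export bugs. Multiple `EXC` contours
(several organs) are unioned.

## The synthetic phantom

`generate_phantom()` produces a seeded, fully reproducible case: a tapered
elliptical body whose outer/inner contours delimit a subcutaneous fat ring
(thickness ~6 voxels at test scale), a visceral fat compartment made of a
central fat column plus random blobs inside the abdominal cavity, two
kidney-like ellipsoids and one spine-like posterior column as exclusion
organs, and a PET volume on a 2× coarser in-plane grid with constant
per-tissue uptake (defaults 0.24 for SAT, 0.75 for VAT, 0.05 for lean and
organ tissue — visceral fat markedly hotter, matching the magnitudes
reported for such cohorts).

Design points worth knowing:

* **Truth is rasterized, not parametric.** The label map is derived from
  the emitted polygons via the package's own rasterizer, so `SAT` is
  *exactly* `EXT ∧ ¬INT` and zero-noise recovery through the full pipeline
  is exact by construction, voxel for voxel. Rasterization itself is
  validated independently against a brute-force point-in-polygon oracle,
  so this is consistency, not circularity.
* **Every annotated slice carries visceral fat** (the central column),
  which keeps the slice mean strictly between the lean and fat levels so
  the `k = 0` threshold classifies every voxel correctly at zero noise.
* **Intensity model**: fat ~ N(900, σ), lean ~ N(100, σ), organs
  ~ N(150, σ), σ default 50. These are artifact-level numbers, not
  published values; the ~8σ fat/lean separation mirrors the strong
  contrast of fat-phase MRI. The visceral fat fraction of the cavity
  (~30%, giving VAT/SAT ratios around 0.65–0.8) matches the ratios
  reported for obese sleep-apnea cohorts; it also determines how far the
  slice mean sits above the lean level, and hence the threshold's noise
  margin.
* **PET/MRI alignment**: the PET grid is centre-aligned with the MRI world
  frame, then nudged half an MRI voxel in-plane so PET centres coincide
  with MRI centres rather than sitting exactly on the nearest-neighbour
  tie midpoint — a knife-edge that float32 NIfTI headers would otherwise
  resolve arbitrarily.
* **`perturb_roi()`** displaces contour vertices radially by a smooth
  low-frequency sinusoid with peak amplitude `magnitude` voxels,
  simulating an imperfect annotator or model. Star-shaped contours remain
  simple for amplitudes small relative to their radius.

What a green phantom test does *not* establish: performance on real
anatomy (irregular body outlines, partial-volume mixtures at depot
boundaries, bias fields, respiratory motion, PET counting noise), the
published cohort Dice/ICC values (which depend on ten real scans and
trained weights), or the experts' fill convention. The phantom establishes
that the arithmetic chain — rasterize, threshold, subtract, count,
resample, average — is exactly right, and that the statistics reproduce
their printed arithmetic.

## The segmentation harness

No deep-learning framework is assumed: the network is a deliberately small
fully-convolutional encoder–decoder in pure R (im2col convolutions on BLAS
matrix products) — 3×3 conv → 2×2 average pool → 3×3 conv → nearest
upsample with skip concatenation → 3×3 conv → 1×1 sigmoid head. What *is*
faithful to the original training contract: 224 × 224 default input,
per-slice z-score normalization (SD floor 1e-8), three independent sigmoid
output channels (`EXT`/`INT`/`EXC` nest spatially, so no softmax),
per-channel binary cross-entropy, and staged weight initialization —
round r of `closed_loop_train()` starts from round r−1's checkpoint and
trains on the union of all corrected batches so far, with an oracle
corrector that replaces any predicted label whose Dice against ground
truth falls below a threshold (the desk-scale stand-in for expert
correction). Optimizer (Adam), learning rate (0.01), epochs and batch size
are artifact-level defaults the source does not specify. Reproducing a
pre-trained ResNet-50 backbone is explicitly out of scope; `init` accepts
a user-supplied checkpoint instead.

Tests scale this harness down (48 × 64 inputs, 2 slices per case, ~25
epochs) to keep the suite inside desk runtime; the single-slice overfit
check and the 3-round closed loop with a held-out case are the
optimization sanity oracles.

## Numerical and degenerate-input choices

* Empty statistics region on an annotated slice: VAT is empty there with a
  warning (the SAT builder falls back to ring statistics so an annotated
  ring is not silently dropped).
* Zero SAT volume: the VAT/SAT ratio is reported as `NA`, not an error;
  likewise SUVmean of an empty resampled depot.
* The NIfTI reader/writer is a minimal, axis-aligned NIfTI-1
  implementation (no R NIfTI package exists in the supported dependency
  set): both endiannesses on read, float32/uint8 and friends, sform/qform
  translation only, rotations rejected loudly. Masks round-trip exactly;
  float volumes to float32 precision (~1e-7 relative).
* Checkpoints round-trip bit-wise (`saveRDS`); training is deterministic
  given `cfg$seed` up to BLAS reduction order.

## Known limitations

Fat-fraction (Dixon water/fat) modelling, partial-volume correction,
DICOM/RT-STRUCT input, SUV body-weight normalization variants, PET
reconstruction, boundary-distance metrics (Hausdorff, average surface
distance) and any GUI are out of scope. The contour Dice of very small
structures (organs a few voxels wide on coarse test grids) approaches the
mask Dice by construction — the boundary ring nearly *is* the mask — so
boundary-sensitivity claims are only meaningful at realistic in-plane
resolution.
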