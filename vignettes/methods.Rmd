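---
title: "Methods: de-identified brain volumetry from clinical MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: de-identified brain volumetry from clinical MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models, numerical
choices and limitations. Nothing stated here goes beyond what the test
suite and `scripts/acceptance.R` themselves compute.

## The problem

Clinical PACS archives hold millions of brain MR examinations acquired
for care, not research. Turning them into volumetric biomarkers (ICV,
brain, CSF/GM/WM volumes) requires four capabilities: removal of patient
identity from headers and image content, tolerance of heterogeneous
acquisitions (vendors, field strengths, sequences), automatic quality
gates for series that cannot support volumetry, and a segmentation that
adapts itself to each subject's contrast rather than assuming a fixed
intensity scale. `mriharvest` implements all four behind plain
filesystem interfaces, plus the statistics stage that consumes the
resulting cohort table.

## De-identification

Header scrubbing is driven by a declarative `scrub_policy()`. The default
covers the name/location/identifier/date subset of the DICOM basic
confidentiality profile as represented in a `header_record`: names,
patient ID, accession, institution, referring physician, operators and
free-form identity strings are blanked; *all* private (odd-group)
elements are removed, since vendor fields cannot be audited for identity
content; birth and study dates are reset to January 1 of their year, so
ages and acquisition years — covariates of the analysis stage — survive
while exact dates do not. Patient sex is deliberately retained as an
analysis covariate. Scrubbing is idempotent, and the audit log names
modified elements without ever recording their removed values.

Defacing multiplies the image with a binary keep mask (no blurring): an
atlas is registered affinely to the subject, the atlas face-exclusion
mask is carried over with nearest-neighbour resampling, and face voxels
are set to zero while kept voxels remain bit-identical. Regions mapping
outside the atlas domain default to "keep", so an imperfect registration
can only under-deface, never destroy brain. UIDs in written output are
remapped through a keyed hash, preserving referential integrity within a
series without a reversible link to the original.

Ages are computed (floor of elapsed calendar years) *before* scrubbing
destroys the dates; pseudonymization is a guarded bijection with an
exclusion list that halts a request with an auditable condition rather
than silently skipping.

## Registration

All spatial correspondence — defacing, the field-of-view check, and
atlas-label transfer for segmentation — comes from one engine: histogram
mutual information (MI) maximized over an affine model (3 rotations, 3
translations, optionally 3 log-scales), refined by a coarse
control-lattice displacement field. MI permits cross-contrast
registration, which is what makes T1w atlases usable on PDw/T2w subjects.

Numerical choices that matter:

* **Off-grid metric sampling.** The metric is evaluated at a strided
  sample of fixed-image positions jittered by up to half a voxel
  (deterministically seeded). Without this, an identity alignment of
  same-grid images enjoys an interpolation-sharpness advantage that traps
  the optimizer at zero rotation.
* **Soft binning.** Moving-image intensities enter the joint histogram
  split linearly between their two nearest bins, so the metric varies
  smoothly with the transform instead of jumping at bin crossings
  (32 bins by default).
* **Optimization.** Nelder–Mead over three resolution levels (block-mean
  pyramid, 200 iterations per level), each level optimized in scaled
  offset space starting at zero offset — the simplex then has a
  controlled initial extent (about 3 degrees / 2 mm) regardless of the
  current estimate — followed by a fine and, at the finest level, a
  small-simplex polish round. Initialization is identity rotation with a
  center-of-mass translation. If the search ends below the
  initialization MI, the initialization is returned and flagged.
* **Non-rigid stage.** A displacement lattice at 48 mm spacing,
  trilinearly interpolated, optimized by greedy per-knot coordinate
  descent (steps 3 mm then 1.5 mm) under a 10 mm displacement cap. Two
  guards keep it honest: moves must not shrink the metric overlap (MI
  spuriously rises when samples fall off the moving image), and must
  improve MI by at least 0.005 nats (scaled up when fewer metric samples
  are used), which filters noise-level fluctuations — on identical images
  the field stays exactly zero. Knots whose support contains no
  foreground sample are frozen.
* **Presets.** The package default (`reg_config()`) follows the
  hyperparameters above with 6,000 metric samples. Pose-recovery
  demonstrations use a precision preset (24,000 samples), where measured
  errors are well within half a voxel for translations up to 10 mm and
  one degree for rotations up to 10 degrees; pipeline batch work uses a
  fast preset (2 levels, 100 iterations, 2,000 samples) whose residual
  error is small against the anatomical margins involved (the face-brain
  gap is over 10 mm; mask fusion averages six atlases).

Transforms map fixed-space points into moving space (the resampling
convention); intensities resample trilinearly, labels and masks strictly
nearest-neighbour — linear interpolation of labels is a contract
violation and is rejected.

## Quality assurance

Sequence classification is a deterministic decision table over scanning
sequence code, TR, TE, TI, flip angle, diffusion b-value and temporal
positions. Clinical sites publish few exact thresholds, so the table
encodes textbook ranges (e.g. spin echo with TR < 1000 ms and TE < 30 ms
is T1-weighted; TR ≥ 2000 ms splits PDw/T2w on TE at 30/80 ms;
inversion-prepared gradient echo is T1w) and is fully overridable; a
series matching no row is `unknown`, a value rather than an error.
Diffusion and functional rules fire first, since echo-planar diffusion
series also carry ordinary TR/TE values.

The field-of-view check transfers an atlas brain mask to the subject and
measures the brain fraction on the six outer planes of the volume. More
than 20 % brain on any outer plane excludes the series; the threshold is
strict, so a plane at exactly 20 % passes. Preference order for
segmentation input is T1w, else PDw+T2w as a two-channel feature.

## Tissue segmentation

* **Bias correction.** A low-order (quadratic) polynomial of the
  log-intensity is fitted to a bright-tissue band — foreground voxels
  within ±15 % of the 90th foreground percentile, so a single tissue
  class anchors the fit and anatomy is not absorbed into the field — and
  iterated twice. Coordinates are normalized to the foreground bounding
  box with constant extrapolation beyond it, keeping corner extrapolation
  mild; the field is clamped to `exp(±0.7)` and normalized to preserve
  the mean foreground intensity exactly.
* **Probability maps.** Each atlas is registered (affine, then the
  non-rigid refinement) and its labels resampled nearest-neighbour; the
  per-class probability at a voxel is the fraction of atlases voting for
  the class — always a multiple of 1/n, the four classes summing to one.
  A failing atlas registration drops that atlas with a warning.
* **Masks.** The cerebrum (skull-stripping) mask is fused from the
  per-atlas transformed masks by majority voting at threshold 0.8 (5 of
  6 atlases include a voxel; 4 of 6 do not) — the conventional,
  deliberately conservative rule for skull stripping, where including
  skull is costly. The intracranial mask, which directly determines ICV,
  is fused at the 0.5 majority instead: 0.5 voting is the unbiased
  median-surface estimator, whereas a 0.8 vote erodes the boundary
  wherever the per-atlas votes disagree. At a 3 mm grid that erosion is
  roughly half a voxel of the outer CSF shell — a 5–7 % conservative ICV
  bias — while 0.5 fusion reduces it to a fraction of a percent (brain
  volume, buffered by the CSF shell, is unaffected either way). Both
  thresholds are exposed in the configuration.
* **Training.** Voxels with unanimous atlas agreement (probability 1.0)
  supply up to 2,000 training samples per class (seeded uniform
  subsample); if a class has fewer than k candidates the threshold drops
  stepwise by 1/n with a warning. Features are bias-corrected intensity
  (two channels for PDw+T2w input).
* **Classification.** k = 45 by default. Because DICOM intensities are
  integers, exact distance ties are common; the neighbourhood of a query
  is defined as *every* training sample within the k-th smallest distance
  (ties included), which makes the result independent of training-sample
  order and lets an exhaustive brute-force scan reproduce it exactly.
  Vote ties go to the class with smaller mean neighbour distance, then to
  the fixed order CSF < GM < WM. Voxels outside the intracranial mask are
  background; inside it, background is not a class. The 1-D intensity
  path runs on sorted arrays with prefix sums (O((n+m) log n)), so
  full-volume classification takes seconds.
* **Volumes.** Tissue volume is voxel count × voxel volume / 1000 (ml);
  `icv = csf + gm + wm` and `brain = gm + wm` hold exactly by
  construction. The cerebrum-mask-restricted brain volume is reported as
  a separate column (`cerebrum_brain_ml`) rather than replacing the
  intracranial brain volume, since whether cerebellum belongs in "brain
  volume" is a cohort-level choice.

## The synthetic phantom: what it does and does not emulate

The phantom is a schematic head of nested ellipsoids — WM (38/46/30 mm
semi-axes) inside GM (49/58/41) inside CSF (55/64/47) inside skull
(62/72/54), with an anterior face lobe — on a 64×64×48 grid at 3 mm
isotropic spacing. Tissue volumes are analytic (4/3 π abc shells: ICV
693 ml, brain 488 ml), poses are applied analytically (membership is
tested at inverse-posed coordinates), so ground truth is exact under any
rotation/translation/scale. Intensities are per-class Gaussians (noise
SD defaulting to 5 % of the smallest between-tissue mean separation)
under a quadratic multiplicative bias field of ±10 % amplitude — the
reference test conditions of the package. Atlases are six phantoms with
independent pose jitter (±5°, ±4 mm, ±3 % scale — pairwise label Dice
around 0.8–0.95, i.e. distinct but anatomically close) and their masks
derived from ground truth labels.

What it deliberately does not emulate: MR physics (no k-space, no
partial-volume mixing beyond voxelization), real anatomical variability
(atlas-subject differences are affine, so the non-rigid stage is only
lightly exercised), pathology, motion, and realistic intensity
distributions. Passing tests therefore demonstrate the correctness of
the machinery — I/O, de-identification, rules, registration recovery,
classifier exactness, volume arithmetic — not clinical segmentation
accuracy.

One systematic effect the phantom surfaces faithfully is the voxel-scale
behaviour of majority-vote mask fusion discussed above: per-atlas pose
voxelization smears the boundary votes over about one voxel, so
high-threshold voting erodes the mask while 0.5 voting tracks the median
surface. The effect shrinks linearly with voxel size; measuring it is
what motivated the split mask thresholds.

## Statistics

Ordinary least squares with dummy-coded factors: gender (reference F),
diagnostic group (reference: the open/mixed group), sequence (reference
T1w), scanner model (reference Philips NT Intera), numeric age, field
strength, and ICV as head-size covariate in the brain-volume model.
Adjusted means are explicit design-row predictions at age 60.5 years and
ICV 1,150 ml with factors at reference and remaining numeric covariates
at their sample mean; intervals are t-based from `x'Vx`. Pairwise group
contrasts use the residual degrees of freedom with Bonferroni correction
over the number of pairs. The implementation is plain linear algebra on
the `lm` fit; an independent reference-grid computation (emmeans) is used
in the tests as a cross-check and agrees to 1e-8. Changing reference
levels changes coefficients but not fitted values, adjusted means or
contrasts (verified as an invariance test).

The IQR outlier rule excludes records strictly outside
[Q1 − 1.5·IQR, Q3 + 1.5·IQR] with type-7 (linear interpolation)
quartiles, applied per group by default (a pooled option exists); groups
of fewer than 4 records are left untouched with a warning. The age
filter is inclusive at 45 years.

`simulate_cohort()` draws a synthetic cohort from the brain-volume model
with known coefficients: five diagnostic groups in the proportions of a
mixed clinical population (83/79/76/70/344 per 652), truncated-normal
ages above 45 centred at 60.5, four scanner models, two field strengths,
a gender effect on ICV of 128 ml and residual SD 20 ml — values chosen
to be realistic for an elderly clinical population. It exists to
validate the fitting machinery (exact recovery at zero noise; 95 % CI
coverage under noise), not to imitate any particular dataset.

## Pipeline and accounting

Examinations are processed independently (read → demographics →
pseudonymization → scrub → QA → deface → segment → volumes), stopping at
the first failure with a recorded reason; batch results are
order-invariant because each examination's seed derives from its
pseudo-ID. Outputs are keyed by pseudo-ID and contain no input identity
element — a byte-level sweep over the output tree for planted identity
strings is part of the acceptance suite. The step-wise accounting
(selected → retrieved → QA → biomarker → plausibility screen) reports
each step as a percentage of the selected count and rejects increasing
counts as a pipeline bug; an automated plausibility screen (positive
finite volumes, brain below ICV) stands in for visual inspection.

## Problem sizes and determinism

Test and acceptance workloads run on the default 64×64×48 / 3 mm grid
(pipeline-level tests use a 32×32×24 / 6 mm grid of the same physical
extent): ten phantom examinations for volume recovery, twenty posed
examinations for the de-identification gate, two hundred cohort
replicates at n = 650 for CI coverage. Every random quantity flows
through an explicit seed — phantom noise, atlas jitter, training
subsampling, metric jitter — and fixed seeds reproduce label volumes and
cohort CSVs bit-for-bit.

## Known limitations

* The registration engine is a behavioural implementation (MI,
  multi-resolution, affine + coarse non-rigid); it is validated on
  phantom pose recovery, not against any external registration package.
* Multi-frame (enhanced) DICOM and compressed transfer syntaxes are out
  of scope; classic single-frame explicit-VR little endian only.
* Series with mixed echo times (multi-echo) are flagged rather than
  interpreted.
* The ICV mask's conservative bias at coarse resolution is documented
  above; at clinical (≈1 mm) resolution the same rule would bias ICV by
  well under 2 %.
* Free-text de-identification of report bodies is not attempted; report
  tables are assumed pre-anonymized.
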