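---
title: "Group analysis of anisotropic rodent structural MRI: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group analysis of anisotropic rodent structural MRI: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratvbm)
```

## The problem

Mild traumatic brain injury rarely produces focal lesions visible in
structural MRI; what it can produce are subtle, time-dependent changes in
the cerebral vasculature — dilation of the superior sagittal sinus (SSS),
contrast enhancement of vessels in the subarachnoid space, perivascular
signal changes deep in the brain. Detecting such effects in a longitudinal
rodent study requires a full group-analysis pipeline: every scan must be
skull-stripped, corrected for intensity inhomogeneity, spatially normalized
into a common atlas space, and then compared across imaging days with
voxel-level and region-level statistics that control the error rate of tens
of thousands of simultaneous tests. On top of that, preclinical protocols
often acquire highly anisotropic 2D multi-slice images (here 0.137 mm
in-plane but 1.0 mm slices placed at 1.5 mm intervals), so a third of the
brain along the slice axis is never sampled at all, and the unsampled
bands land in different anatomy in every session.

`ratvbm` implements this pipeline as a reusable, fully testable R package.
Because the animal data that motivated it are not publicly distributable,
the package ships a synthetic phantom generator that reproduces the
*statistical structure* of such a study — geometry, noise, bias fields,
pose variability, interslice gaps, and injected vascular effects with known
ground truth — so that every stage can be validated end to end.

## Pipeline model

Scans are 3D volumes with a voxel-to-world affine (RAS frame: +x right,
+y rostral, +z dorsal; voxel centres, half-open extents, sform
authoritative). The processing chain per scan is:

1. **Skull-stripping.** An affine transform from scan to atlas is estimated
   by maximising normalised cross-correlation (NCC) with a multi-resolution
   regular-step gradient descent; the atlas brain mask is carried back
   through the inverse transform with nearest-neighbour resampling. When an
   atlas template image is available the correlation is evaluated against
   the template within the (dilated) brain mask; correlation against a
   rendering of the mask itself is available as a fallback, but a flat
   silhouette carries no interior contrast, so its scale accuracy is
   limited to a few percent — the template route is the default in the
   pipeline and is what meets the package's accuracy targets.
2. **Bias-field correction** (below), then **global intensity rescaling**
   so each scan has masked mean 1000 — an arbitrary fixed constant that
   makes sessions exchangeable in group statistics.
3. **Spatial normalization.** Post-injury scans are rigidly registered to
   the same subject's first baseline scan; each subject's baseline is
   affinely registered to a reference subject; the reference is affinely
   registered to the atlas. The composite is a single 4x4 world-to-world
   matrix with an exact inverse; scans are resampled (linear) onto the
   atlas grid. Atlas voxels whose source position falls outside the
   acquired slab — or inside an interslice gap — are recorded in a
   *validity mask* rather than silently zero-filled, so downstream
   statistics can restrict to genuinely observed tissue and the gap
   confound can be audited (see QC below).
4. **Contrast difference imaging.** The post-contrast gradient-echo scan is
   rigidly registered onto its pre-contrast partner and subtracted
   voxelwise, isolating contrast uptake.

### Group statistics

* **Region-based**: mean intensity over each atlas region (80 by default),
  then a pooled-variance two-tailed Student's t-test of each post-injury
  day group against the pooled baseline group, with Benjamini–Hochberg FDR
  correction across regions at level 0.05, applied per day contrast.
  Regions left unobserved by the slice gaps are dropped listwise with
  their n reported. The t statistic is positive where the post-injury mean
  exceeds baseline.
* **Voxel-based**: scans are smoothed with a separable Gaussian whose
  standard deviation matches the coarsest acquisition resolution
  (0.2734 mm in-plane — two voxels on the 0.1367 mm atlas grid, since
  in-plane k-space was zero-filled — and 1.5 mm through-plane, oriented by
  the acquisition plane). Voxelwise pooled t-tests are thresholded at
  two-tailed uncorrected p < 0.001; connected components are formed
  separately for positive and negative voxels (26-connectivity by
  default). The cluster-size cutoff at corrected alpha = 0.05 comes from a
  label-permutation null: group labels are reassigned at random
  (preserving group sizes), the t map is recomputed, and the maximum
  cluster size over both signs is recorded; the cutoff is the
  `ceiling((1 - alpha) * N)`-th order statistic and clusters smaller than
  it are excluded. Direct permutation is self-contained and
  assumption-light, which is why it is used here instead of an
  autocorrelation-model simulation of the null field. Surviving clusters
  are reported with size, signed peak t, peak location as a bregma offset
  (RL, VD, RC in mm) and the atlas region at the peak.
* **Sinus caliber**: a sphere is grown from a seed placed in the sinus
  lumen until the mean image-gradient magnitude over the sphere surface
  (central differences, trilinearly sampled at 300 quasi-uniform
  Fibonacci-lattice points) reaches its first strict local maximum after a
  3-point moving average, ties toward smaller radii; the sphere's diameter
  estimates the vessel caliber. Defaults: radius step a quarter of the
  voxel spacing, search range one voxel to 2 mm. Day groups are compared
  with one-way ANOVA followed by all pairwise pooled t-tests at
  alpha = 0.05; a summary-statistic mode computes the same pooled t
  directly from printed (n, mean, SD) triples. The default seeds are the
  two stereotaxic lumen sites (0, −1.07, −0.22) and (0, −0.53, −5.55) mm
  relative to bregma. The pairwise tests are unpaired: with unequal group
  sizes strict within-subject pairing is not even well defined, and
  unpaired tests are consistent with the rest of the pipeline.

### Slice-gap QC

For each anisotropic scan the interslice gaps are mapped into atlas space
through the same transform used for normalization (a voxel counts as gap
when its centre lies within the slab but farther than half a slice
thickness from the nearest slice centre), and summed over scans into an
overlap-count map. The QC report compares, along the slice axis, the mean
profile of |t| with the overlap profile: their correlation and the
fraction of profile variance at the slice-spacing frequency. It is
deliberately descriptive — a visual/numerical audit, not a hypothesis
test. For the default geometry the gap fraction inside the slab is
analytically 0.5/1.5 = 1/3, which the tests verify.

## Bias-field correction

The field is modelled in the log domain as an order-3 polynomial. A plain
least-squares fit of the polynomial to log intensities would absorb
anatomy, so the fit alternates with a crude tissue model: voxels (on a
boundary-eroded mask, since edge voxels are partial-volume mixtures) are
classified into four intensity classes by 1D Lloyd iterations, the
class-conditional mean is subtracted, and the polynomial is refit to the
residual with Huber reweighting. Five or six alternations separate the
piecewise-constant anatomy from the smooth multiplicative field. The
returned field is strictly positive, and is scaled so the corrected
image's masked mean equals the input's exactly (its masked mean is
therefore 1 only to first order). On bias-free phantoms the estimated
field deviates from unity by under 2%; correction removes over half of the
excess intensity variation induced by a 20% synthetic field and is
idempotent to well under 1% RMS. The internal algorithm is a package
design choice; only this contract is guaranteed or tested.

## The phantom generator

`phantom_spec()` + `make_atlas_phantom()` build a brain-shaped template,
an 80-region label volume and a bregma frame; `synthesize_scan()` and
`make_study()` turn them into multi-subject, multi-day, multi-modality
NIfTI studies with a truth manifest. The model, and what each piece
emulates:

* **Anatomy**: an ellipsoidal brain (semi-axes 7 x 13 x 5.5 mm, the scale
  of an adult rat brain) with a white-matter core, a small CSF
  compartment, and a caudal-ventral lobe standing in for the cerebellum.
  The lobe is not cosmetic: a pure ellipsoid is nearly a surface of
  revolution, leaving one rotation unconstrained for shape-based
  registration. Thin extracerebral shells — dark skull, dimmer scalp —
  exercise skull-stripping. Tissue intensities are a single contrast
  shared by all modalities; sequence physics (TR/TE contrast, T2W vessel
  hypointensity) is out of scope, so vessels are bright in every modality
  and effect *directions* in synthetic T2W tests follow the phantom, not
  real T2W physiology.
* **The sinus analogue**: a tube of baseline diameter 0.96 mm (the
  published baseline rostral group mean) running along the dorsal surface
  at 1 mm depth. Bregma is placed on the dorsal midline at the position
  where the two published stereotaxic seed offsets both land exactly on
  the tube centreline — solved numerically from the ellipsoid geometry, so
  the defaults of `default_sss_seeds()` are meaningful on the phantom.
  The tube is one of the 80 atlas regions; the other 79 are contiguous
  equal-count parcels.
* **Injected effects**: per-day tube dilation with factors 1.30, 1.14,
  1.10, 1.00 on days P1/P2/P7/P14 (the published rostral time course,
  ~1.26/0.96 on P1, recovering by P14), restricted by default to the
  rostral segment (RC > −3 mm, 0.5 mm taper) so the caudal site stays
  null as in the study; post-contrast vessel-lumen enhancement (250
  intensity units every day — contrast agent fills the vessel, making the
  sinus visible in difference images); subarachnoid surface enhancement
  near the impact site on P1–P2 (120/60 units); and a focal deep
  perivascular enhancement (0.8 mm radius, 150 units, P1–P7) near the
  dorsal third-ventricle region. No quantitative enhancement magnitudes
  are available to calibrate against, so these amplitudes are free
  configuration constants chosen to be comfortably detectable at the
  default noise level, not calibrated values.
* **Acquisition**: per-subject affine pose (±2° rotations, ±0.5 mm
  translations, 3% SD scales), per-session rigid jitter (±0.5°, ±0.3 mm)
  and a ±1 mm FOV shift along the slice axis (the reported session-to-
  session slice-positioning variability); boxcar slice-profile averaging
  over the slice thickness, sampled at the slice spacing so gap tissue is
  never observed; a multiplicative bias field (exponential of a random
  order-2 polynomial scaled to 20% peak amplitude); additive Gaussian
  noise (sigma 20 ≈ 5% of grey matter). Gaussian rather than Rician noise
  is deliberate: magnitude-bias modelling is out of scope and the group
  statistics assume approximate normality anyway. All randomness derives
  from `rng_seed` via stable per-(subject, day, modality) hashing, so
  regenerating a study is bit-identical.

What passing tests on these phantoms does *not* show: robustness to real
neuroanatomy, real coil-profile bias, sequence-dependent contrast,
susceptibility artefacts, or imperfect slice profiles. The phantoms
validate the machinery and its error control, not the biology.

## Numerical choices and degenerate inputs

* Registration: NCC maximised by regular-step gradient descent with
  numeric central-difference gradients on a 3-level decimation pyramid
  (fixed-grid caps ~8k/30k/100k voxels). Parameter units are scaled so one
  unit of any parameter (rotation, log-scale, shear, translation) moves a
  point at the object radius by about 1 mm; without this the rotation
  gradient is orders of magnitude smaller than the translation gradient
  and the descent stalls. Initialisation: centre-of-mass alignment.
* Labels are always transported nearest-neighbour; intensities linear.
* Zero pooled variance in a t-test: equal means give t = 0, p = 1;
  unequal means give p = 0 flagged `degenerate`.
* Smoothing kernels are truncated at 4 sigma and renormalised over
  in-range taps at the boundary, so constants are preserved exactly.
* The sphere-growing profile's first-local-max rule stops at the first
  boundary; a uniform image has no maximum and returns `converged = FALSE`
  (with the global argmax when one exists). The estimator carries a known
  positive bias of about half an in-plane voxel: the mean gradient over a
  sphere peaks slightly outside the cylindrical shell it intersects, a
  geometric property of averaging over the sphere rather than along a ray.
  Within-study comparisons (ratios, day contrasts) are unaffected to first
  order; absolute calibers at 0.1367 mm resolution are accurate to about
  ±0.07 mm across the 0.6–1.6 mm range.
* Permutations are drawn without enforcing uniqueness; the seed is stored
  in the result. `n_permutations` must be at least `1/alpha_cluster`.

## Problem sizes

The shipped tests and the acceptance script run everything at desk scale,
as the package's own validation design: phantoms at 0.25–0.35 mm isotropic
spacing (the reference protocol's 0.1367 mm grid is used where resolution
itself is under test, e.g. caliber recovery), studies of 2–3 subjects over
3 days, 100–500 permutations, and 100–500 Monte-Carlo replicates for the
error-rate suites. All sizes are arguments; scaling a real analysis up to
10 subjects, 6 days and 10,000 permutations changes only runtime.

## Known limitations

* Affine-only normalization (no deformable registration), as in the
  original design; anatomy that an affine cannot align contributes
  residual variance.
* The thick-slice boxcar means two sessions of the *same* subject observe
  genuinely different tissue: on zero-noise phantoms at the 1.0/1.5 mm
  protocol, atlas-space agreement between sessions is r ≈ 0.88 (r > 0.98
  at near-isotropic slicing). This is the acquisition's information loss,
  not a pipeline defect, and it is the reason the validity-mask and gap-QC
  machinery exist.
* Sphere-growing assumes the seed sits inside a roughly tubular bright (or
  dark) structure; it measures caliber at a point, not a segmentation.
* The generator's modality model is a single shared contrast; tests that
  depend on modality-specific signs of effects are out of its scope.
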