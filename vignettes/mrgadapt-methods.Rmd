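---
title: "Methods: predicting the adaptive strategy in MR-guided radiotherapy"
author: "mrgadapt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: predicting the adaptive strategy in MR-guided radiotherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The clinical problem

On an MR-linac, every treatment fraction starts with a daily MR scan in the
treatment position. The team must then choose between two adaptive
strategies: **adapt to position** (ATP) — keep the reference plan and only
correct for the new position — or **adapt to shape** (ATS) — recontour and
fully replan on the daily anatomy. ATS gives better plans but costs far more
in-room time, so the choice matters for every fraction. The decision is
driven by how much the anatomy has deformed between the reference CT and the
daily MR, and `mrgadapt` implements a multi-stage deep-learning pipeline that
makes it automatically from the image pair alone:

1. **Registration stage.** A 3D U-Net `g_theta(f, m)` takes the daily
   (fixed) image `f` and the reference (moving) image `m` as a 2-channel
   volume (channel order m, f) and predicts a dense displacement field
   `u` mapping fixed-image coordinates to moving-image coordinates. A
   spatial transformer warps `m` into `w(x) = m(x + u(x))` with trilinear
   interpolation. Training is unsupervised with the composite loss

   `L = -MI(f, w) + lambda1 * L_smooth(u) + lambda2 * L_2(u)`

   where MI is mutual information (the similarity that survives the CT/MR
   modality gap), `L_smooth` penalises the squared spatial gradients of
   `u` (forward differences), and `L_2` penalises the squared
   displacements themselves.
2. **Classification stage.** The trained encoder is copied, frozen, and
   used as a feature extractor on the ROI-masked image pair (the planning
   target volume expanded by a margin). Its deepest feature maps are
   global-average pooled into one value per channel and passed through two
   fully connected layers ending in a sigmoid, trained with binary
   cross-entropy against dosimetric ground-truth labels. A probability
   strictly above the decision threshold (default 0.64) selects ATS.
3. **Ground-truth engine.** The dosimetric labeler evaluates the
   recalculated ATP plan's DVH metrics against twelve per-structure
   criteria with clinical tolerances (e.g. rectum D_max < 40 Gy with 0 Gy
   tolerance, bladder V_37Gy < 10 cc with +0.5 cc). If the ATP plan passes
   everything — strictly or within tolerance — the fraction is labelled
   ATP, otherwise ATS; if even the ATS plan fails, the label is still ATS
   but the case is flagged.

## Network and optimiser

The U-Net uses `n_levels = 4` stride-2 encoder convolutions (kernel 3,
LeakyReLU with slope 0.2), so every input axis must be divisible by 16 and a
256 x 256 x 128 input yields 16 x 16 x 8 deepest feature maps. The decoder
alternates nearest-neighbour upsampling, concatenation skip connections from
the matching encoder level, and stride-1 convolutions. The field head is a
linear 3-channel convolution initialised with tiny weights so training
starts at the identity warp; it predicts the displacement on a coarse
control grid (`field_stride`, default 2; the desk-scale recipes use 4 —
one control point per 12 x 12 x 24 mm at the default spacing), and
`register()` reconstructs the learned coefficients by trilinear
interpolation, like a free-form deformation. Why a coarse head: with a
per-voxel field, a short training run can raise the soft-binned MI by
sub-voxel "intensity painting" — each voxel's displacement nudges its
interpolated intensity toward a histogram-sharpening value without
aligning anything (we observed exactly this: MI rising past the
true-field optimum while Dice fell, even on training pairs). Restricting
the field to control cells larger than the intensity-texture correlation
length removes that failure mode while leaving organ-scale deformation
fully representable; inside the training objective the reconstruction is
block-constant (`field_expansion = "nearest"`) for the same reason.
Channel widths are `base_channels` (default 8) at the first level and
twice that below — deliberately narrow so the model trains on one CPU;
widening is a single config change. Optimiser defaults follow the
published recipe: Adam, learning rate 1e-4, 200 epochs, batch size 1 for
registration; 1e-5, 300 epochs, batch size 2 for the classifier head.

All layers, losses and gradients are implemented in the package
(reverse-mode, layer by layer), with the convolution inner loops in
C++/Armadillo; a pure-R reference convolution is kept and tested against
the compiled kernels.

## Mutual information estimator

The similarity loss needs a differentiable MI. We use Gaussian-Parzen soft
binning: intensities are min-max normalised to [0, 1], assigned to
`mi_bins` (default 32) equal-width bins with normalised Gaussian weights of
width `mi_kernel_width` (default one bin width), and the joint mass
function is accumulated from the soft assignments; `eps = 1e-10` guards the
logarithms. An exact hard-binned estimator with the same bin edges is
provided as the oracle; tests assert `MI(f, f) = H(f)`, the
`0 <= MI <= min(H(f), H(w))` bounds, near-zero MI for permuted pairs, and
that the soft estimate approaches the hard one as the kernel narrows. The
estimator is intentionally *not* re-derived from any library — it is the
heart of the method — but its oracle cross-checks are.

## Loss reduction and regulariser weights

The smoothness and L2 penalties are defined as sums over voxels, and
`smoothness_loss()` / `l2_penalty()` report exactly those sums (they match
brute-force nested-loop oracles to 1e-6). For *training*, however, a raw
sum makes the regulariser weight depend on the grid size: at 64 x 64 x 32
the smoothness sum is of order 1e3-1e4 while the MI term is of order 1, so
a weight of 1e-2 on the sum would pin the field at zero — at any grid
size, which is why we read the published weights as belonging to a
normalised parameterisation rather than to the raw voxel-unit sums.
`dlir_config(loss_reduction = "mean")` divides both penalties by the voxel
count inside the training objective; the default `"sum"` preserves the
printed form of the equations.

The desk-scale recipes set the per-voxel weights to `lambda1 = 1` and
`lambda2 = 0.02`. If the displacement is expressed in normalised grid
coordinates (components divided by half the grid size, a common
spatial-transformer convention), a weight of 1e-2 on the summed gradient
penalty corresponds to a per-voxel voxel-unit weight of a few — our
`lambda1 = 1` sits at that scale. The L2 weight is chosen so that a field
earns its magnitude: displacements that do not buy mutual information
(e.g. a spurious "floor" field applied to already-aligned pairs, which we
observed harming the near-identity cases) are pushed back to zero, while
genuine deformation-scale fields pay only a small fraction of their MI
gain.

Further stabilisers for the short CPU schedules: the global L2 norm of
the parameter gradient is clipped to `max_grad_norm` (default 1) before
each Adam step; the registration learning rate is 3e-3 stepped down to
1e-3 for the final third of training (about a thousand optimiser steps in
total, instead of the tens of thousands a GPU schedule would take); and
the classifier head trains at 1e-2 with weight decay 1e-2 on features
standardised to zero mean and unit deviation on the training set.

## The synthetic phantom generator

No imaging data ship with the package; every experiment runs on generated
phantoms designed to exercise exactly the properties the pipeline relies
on:

* **Anatomy.** Smooth overlapping ellipsoids on a 64 x 64 x 32 grid with
  3 x 3 x 6 mm spacing (a 192 mm pelvic field of view): a body ellipsoid,
  bladder-like, rectum-like and prostate-like blobs (the delineated
  structures), and two lateral bone spheres that create strong
  CT-specific contrast. Organ sizes are clinically plausible (prostate
  ~30 mm, bladder ~40 mm, rectum elongated axially).
* **Modalities.** The moving image renders the anatomy through a
  piecewise-linear CT transfer function (air -1000, soft tissue 0-100,
  bone 1200+); the fixed image renders the *deformed* anatomy through a
  saturating exponential MR transfer (bone compressed into the soft-tissue
  range) plus Gaussian noise (sigma 2 on a 0-100 scale). Both transfers
  are monotone in the anatomy scalar but non-affinely related, so
  voxelwise intensity difference is a poor similarity while MI is not —
  the property that makes the MI loss the one being exercised.
* **Texture.** A smooth random intra-tissue texture (amplitude 0.08 of
  the anatomy scale, correlation length 15 mm, body-only) is added to the
  anatomy scalar before rendering and deforms together with the anatomy.
  This matters: a piecewise-constant phantom leaves mutual information
  blind to any warp of its intensity plateaus, so a short training run
  can raise MI by reshaping histograms without aligning anything. Texture
  is the shared structure that makes spatial alignment the only way to
  increase MI — exactly the role it plays in real images. For the same
  reason, CT-like volumes are clipped to a soft-tissue window
  (-150 to 250) before min-max normalisation wherever they enter the
  network or the MI estimator, so the air-bone dynamic range does not
  compress tissue contrast into a fraction of a histogram bin; we verified
  on the MI-versus-field-scale landscape that with texture, windowing and
  32 bins the true deformation is a clear MI optimum.
* **Deformation.** Per-component white noise smoothed with a Gaussian of
  correlation length `deformation_smoothness` (default 30 mm, organ
  scale), rescaled to a peak magnitude of `deformation_amplitude`
  (default 8 mm). The stored field satisfies the registration convention
  exactly: warping the moving anatomy with the true field reproduces the
  fixed anatomy. A deformation large enough to pull structure voxels off
  the grid is an error, never a silent clip.
* **Labels.** A fraction is ATS when the mean displacement magnitude
  inside the ROI (prostate + 3 mm PTV margin, expanded by
  `roi_margin_mm = 50`) exceeds `label_threshold` (default 3 mm — the
  scale of a PTV margin, i.e. of anatomical change that genuinely
  threatens coverage). The paper-style dosimetric route is generated
  alongside: the ATS plan table always passes all criteria, and the ATP
  table degrades monotonically with the mean in-ROI displacement so that
  the dosimetric label agrees with the geometric one (the rectum D_max
  criterion, whose tolerance is zero, is the designed sentinel).
* **Cohorts.** `generate_cohort()` draws each fraction's intended label
  as Bernoulli(`ats_fraction_target`) and then scales the field so the
  mean in-ROI displacement lands in U(0.15, 0.7) x threshold for ATP or
  U(1.5, 3) x threshold for ATS. The regimes are deliberately separated:
  the generator states the study conditions, and nothing in the paper
  constrains the anatomical-change distribution between strategies.
  Patient identifiers allow leakage-free patient-level splits. All
  randomness flows from the spec's single integer seed through per-case
  derived seeds; identical inputs are bit-for-bit reproducible.

What the phantoms do *not* emulate: CT/MR physics (beam hardening, bias
fields, T2 contrast mechanisms), organ-specific biomechanics (bladder
filling does not look like a Gaussian random field), sliding interfaces,
and intensity pathologies such as rectal gas. Passing the synthetic
recovery studies therefore demonstrates that the architecture, losses,
gradients and training loop are correct and that the pipeline can extract
deformation-magnitude information from multimodal pairs — not that the
trained weights would transfer to clinical images.

## Desk-scale study sizes

The end-to-end checks run on one CPU inside a test suite, so the studies
are small and their sizes are fixed in the test helpers: registration
trains on 24 fractions (16 patients) of 64 x 64 x 32 voxels for 45 epochs
and is evaluated on 8 held-out fractions (Dice and Hausdorff distance of
warped versus daily structures against the unregistered baseline, and the
in-ROI residual `|u - u_true|` against the deformation magnitude — the
trained model must recover more than half on average). Classification uses
a fresh 36-patient, 108-fraction cohort with a 24/12 patient split and the
criterion test AUC >= 0.90 on held-out patients — intentionally stricter
than clinical reality because the phantom regimes are separable; it is a
pipeline-correctness bar, not a clinical claim. The classifier head's
hyperparameters (hidden width 64, learning rate 1e-2, 150 epochs, weight
decay 1e-2) were selected by patient-level cross-validation within the
training split only. The acceptance script repeats both studies from
scratch under a caller-supplied seed.

## Numerical choices and edge cases

* Out-of-grid samples in the spatial transformer clamp to the border
  (zero-fill would fabricate MI structure at the edges); the clamped
  direction contributes zero gradient.
* Intensities are min-max normalised per volume before entering the
  network and the MI loss; the classifier normalises using in-ROI
  intensities only and then zeroes everything outside the ROI, which makes
  predictions provably invariant to out-of-ROI perturbations (a tested
  property).
* Forward differences with zero boundary terms define the smoothness
  penalty, matching the oracle exactly.
* Dice of two empty masks is 1 (identity of emptiness); Hausdorff on an
  empty mask is an error. The Hausdorff distance is the classical maximum
  over surface voxels in physical units, with a percentile option.
* Ties: a probability exactly at the decision threshold yields ATP
  (strict inequality); ROC ties count half a concordance, so the
  trapezoidal AUC equals the Mann-Whitney statistic; threshold selection
  searches midpoints of sorted unique scores and breaks ties toward the
  larger threshold.
* A DVH value exactly at a relaxed limit is violated ("<" criteria demand
  `value < limit + tolerance`); a zero tolerance makes the
  within-tolerance band empty.
* Percentages in cohort summaries round half-up to integers.
* Undefined metrics (e.g. sensitivity with no positives) are `NaN` with a
  warning, never silently 0.

## Design choices where the method leaves room

* **Encoder-to-head bridge.** Flattening the deepest feature grid is the
  default; global average pooling is available via
  `dlsp_config(bridge = "gap")`. Pooling looked attractive a priori
  (shape-robust, few parameters) but fails empirically at desk scale:
  after ROI masking most deepest-feature cells are empty, so averaging
  dilutes the localised deformation signal (held-out AUC near chance,
  versus > 0.9 for the flattened features under an identically trained
  head). A purely linear two-layer cascade would collapse into one
  layer, so a LeakyReLU sits between the FC layers; `fc_hidden` defaults
  to 64.
* **ROI usage.** The ROI multiplies the *input channels* of the
  classifier rather than masking deep features — the simplest contract
  with a testable invariance.
* **Rigid pre-alignment** is translation-only (intensity centroid, or an
  exhaustive integer-shift MI search), since the generator controls
  misalignment; full 6-DOF alignment is out of scope.
* **Class imbalance** is left to plain unweighted BCE, matching the
  stated training recipe; a weighting option would be a one-line head
  change but defaults off.
* **Criteria boundary semantics** follow the printed strict inequalities.

## Known limitations

Training runs are short by construction; the registration quality bar is
"clearly better than identity", not state of the art. The MI estimator
uses global (not local/patchwise) histograms, so it can be insensitive to
spatially compensating errors. The generator's label rule is a geometric
surrogate for a physician's dosimetric judgement; its DVH tables are
plausible but synthetic, and the labeler's deterministic rule ("ATP
acceptable implies ATP") is the simplest codification consistent with
clinical practice, not a claim about physician behaviour.
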