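---
title: "Prior-guided adversarial segmentation of kidney MRI: models, choices, limits"
author: "priorseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prior-guided adversarial segmentation of kidney MRI: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Functional renal MRI of transplanted kidneys (T2-weighted, BOLD,
diffusion-weighted sequences) poses an unusual segmentation problem: the
graft is placed surgically, so its position and orientation vary far more
across patients than a native organ's would, and in the low-contrast
sequences the intensity distributions of kidney tissue and surrounding
structures overlap heavily. A network that sees only the grayscale volume
must solve both problems from intensity evidence alone. This package
implements a conditional adversarial segmenter that injects two sources of
complementary, data-driven guidance alongside the image:

* an **appearance prior** `P_app(x)` — the voxelwise likelihood that the
  observed local intensity belongs to kidney tissue, estimated from
  spatially stratified intensity histograms of the training cohort, and
* an **anatomical shape prior** `S(x)` — the voxelwise frequency with which
  training subjects' masks cover location `x` on a common kidney-centred
  lattice.

The condition volume `c = (g, P_app, S)` feeds a 3D conditional GAN whose
generator produces a logit volume; sigmoid activation and thresholding at
0.5 yield the final mask.

## The appearance prior

Each slice of a reference mask is partitioned into concentric iso-contour
bands of fixed thickness around the mask boundary: a voxel at unsigned
in-plane Euclidean distance `d` from the boundary falls in band
`ceil(d / thickness)`, boundary voxels (`d = 0`) in band 1, capped at `N_c`
bands, on **both** sides of the contour — background statistics are
modelled per band just like foreground ones. Per banded voxel a 3D
neighbourhood response is accumulated: the sum of quantized intensities
over same-band voxels within an in-plane Chebyshev radius on slices
`z-1, z, z+1`. Foreground and background histograms of these responses,
indexed by band, are summed over all training subjects.

At evaluation the kidney likelihood of response level `I` in band `c` is
the count ratio `H_K / (H_K + H_B)`. If the level has no support, the
lookup expands symmetrically to `I ± δ` (both sides pooled jointly) for
`δ = 1, 2, 3`; if support is still absent the voxel receives the neutral
value 0.5.

Choices worth spelling out:

* **Band geometry.** Bands are distance-to-boundary shells, not
  centroid-radius annuli: the contour is explicitly extracted per slice,
  and shells preserve the local geometry of the boundary that the method
  builds its statistics around. Defaults: `N_c = 8` bands of thickness 1
  in-plane voxel.
* **Response normalisation.** The raw neighbourhood response is a *sum* of
  intensities, whose magnitude depends on how many same-band voxels happen
  to fall in the window (1 to 27 with the default radius). Histograms
  indexed by raw sums would conflate intensity with neighbourhood
  occupancy, and a ±3 gray-level fallback would be meaningless across
  different occupancies. The response is therefore divided by the count of
  contributing voxels and rounded half-up, keeping every histogram on the
  8-bit quantized scale. This is a documented deviation needed for a
  consistent histogram domain.
* **Quantization.** Volumes are min–max quantized to 256 integer levels
  per subject before histogramming; the integer gray-level fallback
  presumes an integer scale, and 8 bits is the minimal faithful choice.
* **Inference-time bands.** A held-out subject has no ground-truth
  contour. Its band field is computed from the boundary of the binarized
  (`S ≥ 0.5`) shape prior on the common ROI lattice — the only mask-like
  structure available without touching the test mask. For consistency the
  *training* subjects' condition channels use the same shape-prior-derived
  band reference, so the `P_app` channel is computed identically for
  training and test subjects and carries no hidden ground-truth signal.
  (Model *fitting* still stratifies by each training subject's own
  ground-truth bands, which is what the histograms are defined over.)

## The shape prior

`S` is the voxelwise mean of the training-fold masks after every subject is
standardised onto a fixed-size kidney-centred ROI lattice (zero-padded at
volume borders). The crop centre is the *cohort-mean* training centroid,
common to all subjects, rather than each subject's own centroid. This is
deliberate: the held-out subject has no mask, so its crop can only use a
mask-free centre; recentring every training subject individually would
align each training mask perfectly with the lattice centre, teach the
network a positional prior that the test subject systematically violates,
and drain the positional variability out of `S` that the averaged mask
frequency is meant to encode (graded boundaries reflecting both shape
*and* placement variability). With a common centre, training and test
crops are identically distributed and `S` honestly carries the cohort's
placement spread. Values are exact rationals `k/N`;
recomputation per cross-validation fold and per modality keeps it adaptive
to the cohort at hand. No parametric shape model is imposed — transplant
cohorts are exactly the setting where landmark or basis-function shape
spaces are too rigid. The ROI convention is itself a design decision:
voxelwise averaging presumes voxel correspondence, and kidney-centred
cropping is the only alignment the protocol states; no deformable
registration is attempted.

## The adversarial network

The generator is a residual 3D U-Net; the discriminator a conditional 3D
PatchGAN judging `(mask, condition)` concatenations on a spatial logit
grid. Because slice spacing is much coarser than in-plane resolution in
these acquisitions, *all* resampling uses the anisotropic stride (1, 2, 2):
the slice axis is never downsampled. Encoder channels double per level from
64 up to 512 (4 levels); the discriminator doubles up to 256 before the
final 3×3×3 logit convolution. The losses are the standard conditional-GAN
pair: the discriminator minimises
`0.5·[BCE(D(y,c), 1) + BCE(D(ŷ,c), 0)]`, the generator
`BCE(D(ŷ,c), 1) + λ_rec·‖ŷ − y‖₁` with `λ_rec = 200`, where `ŷ` is the
sigmoid output. Training uses Adam (learning rate 4e-4, batch size 1, 200
epochs in the full-scale recipe), alternating one discriminator and one
generator step per sample.

Implementation choices made where the recipe is open:

* **No deep-learning runtime is used.** The environment provides none, so
  convolutions (im2col + GEMM, single precision), batch normalisation,
  trilinear upsampling, backpropagation and Adam are implemented natively
  in C++. With batch size 1, batch normalisation computes its statistics
  over the spatial volume of the single sample (instance-style), with
  running estimates used in eval mode.
* **Residual blocks** are two conv–norm–ReLU units with an identity
  shortcut (1×1×1 projection if channels ever differed; in this topology
  they do not).
* **Downsampling** is by strided 3×3×3 convolution, the standard pix2pix
  practice consistent with anisotropic stride factors.
* **Decoder fusion.** After trilinear upsampling and skip concatenation,
  channels are mixed by a 1×1×1 projection; the 3×3×3 spatial filtering of
  the decoder is carried by the residual decoding block that follows. A
  3×3×3 fusion convolution on the concatenated tensor would roughly double
  the decoder's cost for negligible benefit at these widths; with the
  residual block immediately downstream the receptive field is unchanged.
* **Adam betas** (0.5, 0.999) — the conventional conditional-GAN setting.
* **Model selection.** The protocol reserves a 20% validation split but
  states no selection rule; the best-validation-Dice checkpoint over
  epochs is returned (final weights are also kept). Without a validation
  split the final weights are used.
* **Tie-breaks.** `sigmoid(logit) = 0.5` (logit 0) maps to foreground,
  matching the `S ≥ 0.5` binarization convention.
* **D/G schedule.** One discriminator step then one generator step per
  sample; the generator's forward activations from the discriminator step
  are reused for its own update (its weights have not changed in between).

## Evaluation protocol

Leave-one-out cross-validation per modality: each subject is held out once;
the remaining subjects form the reference set from which *both* priors are
built; a seeded shuffle splits the reference set 80/20 into training and
validation for the network. Nothing derived from the held-out subject's
mask ever reaches a training stage — the held-out ROI is centred on the
cohort-mean training centroid, and the acceptance suite checks that
corrupting the held-out data after condition construction leaves priors,
weights and training history byte-identical.

Metrics: Dice and IoU for volumetric overlap; HD95 and ASSD in millimetres
for boundary accuracy. Surface distances are pooled symmetrically (every
boundary voxel of each mask to the nearest boundary voxel of the other),
with boundary voxels defined by face adjacency (volume faces count as
background) and distances computed under the anisotropic header spacing.
The 95th percentile uses linear interpolation between order statistics.
These two conventions (pooled-symmetric HD95, interpolated percentile) are
declared rather than inherited — the protocol does not state its
directional convention. Empty predictions make surface metrics undefined:
the metric layer raises an error and the harness records `NA` with a flag.
Aggregates are reported as mean, SD, and a seeded percentile bootstrap 95%
CI (2000 resamples); configuration comparisons use two-sided Wilcoxon
signed-rank tests on per-subject paired differences with Benjamini–Hochberg
adjustment across the metric family. The signed-rank p-value is computed
exactly by enumerating all `2^n` sign assignments for `n ≤ 15` — this
remains correct under tied differences, where the classical exact
distribution does not apply — and by normal approximation with continuity
correction beyond.

The ablation ladder mirrors the four input configurations: `raw` (the full
unstandardised grayscale volume — the fully convolutional network simply
runs on the larger grid), `roi` (kidney-centred crop), `roi_prob` (crop +
appearance map duplicated as channels 2 and 3), `full` (crop, appearance
map, shape prior).

## The synthetic phantom world

The patient cohort is private, so every end-to-end claim in this package is
made on synthetic phantoms designed to reproduce the statistical structure
the method targets — and nothing more:

* a single connected foreground object (a rotated ellipsoid with an
  optional bean-shaped dent, concavity 0.3) with per-subject pose
  variability: in-plane rotation ±25°, centre jitter up to ±6 in-plane
  voxels on the 64×64 reference grid (scaled for other grids) — the
  graft-placement surrogate;
* modality presets fixing contrast-to-noise: `dw_like` (fg 200, bg 50,
  noise SD 15; CNR 10), `bold_like` (fg 160, bg 100, SD 20, plus a 30%
  linear through-slice foreground decay as a crude multi-echo surrogate;
  CNR 3), `t2_like` (fg 130, bg 100, SD 20; CNR 1.5) — ordering the
  regimes the way the three sequences order their reliability;
* a smooth multiplicative bias field (sum of three low-frequency cosine
  modes, default amplitude 0.2/0.15) and additive Gaussian noise;
* acquisition spacings per preset: (6, 0.63, 0.63), (3, 1.25, 1.25),
  (4, 0.72, 0.72) mm.

Default test grid is 16×64×64 — divisible by 8 in-plane for the 4-level
network and fast on a single CPU; phantom kidneys are therefore scaled down
relative to real renal anatomy (a real graft at DW resolution would span
over a hundred in-plane voxels). What a green end-to-end test establishes
is that the pipeline learns, that priors help under low contrast, and that
no stage leaks held-out information; it does **not** establish clinical
accuracy, robustness to acquisition artefacts beyond the modelled ones
(no k-space physics, no susceptibility, no motion), nor clinical-cohort
Dice figures, which can only come from patient data.

Two scaled-down protocol runs back the acceptance claims: a 12-subject
high-contrast cohort (tiny 8→64-channel preset, 30 epochs, 3 LOOCV folds)
must reach mean held-out Dice ≥ 0.85, and an 8-subject low-contrast cohort
(3 seeds, 2 folds per seed, 12 epochs) must show non-decreasing
seed-averaged Dice along raw → roi → roi_prob → full within a 0.02
stochastic tolerance band. The ablation cohort's geometry differs from the
default phantom on purpose: the kidney is small relative to the 16×64×64
field of view (semi-axes 4–6, 8–11, 6–9 voxels) with centre jitter up to
±5 in-plane voxels and a 16×32×32 ROI, because the mechanism the ablation
ladder measures — raw input burdened by background volume and placement
variability, ROI cropping relieving it, priors adding evidence — only
exists when the organ does not fill the scan, as it does not in real renal
MRI. Placement jitter is kept below the kidney's own extent (ratio ≈ 0.5),
the regime of real graft placement; when jitter approaches the organ size
the shape prior under mask-free centring becomes actively misleading and
the full model degrades — a documented limitation, not the operating
regime. Epoch counts and grid sizes are fixed for CPU budget (minutes, not
hours); the tolerance band absorbs the seed-to-seed variance that short
training leaves behind.

## Numerical and degenerate-input conventions

* Intensity quantization: half-up rounding (`floor(x + 0.5)`), so results
  do not depend on the platform's banker's rounding; constant volumes map
  to level 0.
* Centroids round half-up to integer voxels; ROI crops of even size place
  the centre voxel at `size %/% 2 + 1`.
* Empty training masks are an error (centroid and bands undefined); empty
  slices simply leave their voxels unassigned, and unassigned voxels carry
  the neutral appearance value 0.5.
* A binarized shape prior that is empty everywhere (possible only in
  pathological cohorts) disables the band reference; the appearance
  channel then falls back to the neutral map.
* Weight initialisation is He-normal from a seeded Mersenne Twister; a
  fixed seed reproduces weights, shuffling, loss history and predictions
  exactly on a fixed platform.

## Known limitations

* The appearance model assumes per-subject min–max quantization makes
  intensities comparable across subjects; no histogram matching or bias
  correction is attempted (bias fields enter the histograms as blur).
* Inference-time ROI centring uses the cohort-mean training centroid; a
  subject whose kidney lies far from the cohort's typical placement will
  be partially cropped. The same applies to the shape prior itself, which
  is a positional prior as much as a shape prior.
* The native network backend is single-threaded CPU code sized for
  phantom-scale grids; it is not a general-purpose training framework, and
  full-resolution clinical volumes with the 64→512 preset would be slow.
* LOOCV variance estimates are optimistic relative to repeated k-fold;
  the harness reports per-subject scores so other resampling schemes can
  be applied downstream.
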