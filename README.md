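# priorseg

Prior-guided 3D adversarial segmentation of kidney MRI, with the full
evaluation stack needed to validate such a segmenter without patient data.

## The problem

Transplanted kidneys are imaged with functional MRI sequences (T2-weighted,
BOLD, diffusion-weighted) whose kidney-to-background contrast ranges from
good to very poor, while surgical graft placement makes the organ's
position and orientation vary widely across patients. Purely image-driven
networks struggle exactly where the clinical need is greatest — the
low-contrast sequences. `priorseg` conditions a volumetric adversarial
segmentation network on two data-driven priors computed from the training
cohort:

- **Appearance prior** `P_app : Ω → [0,1]` — per iso-contour band `c` around
  the kidney boundary, foreground/background histograms `H_c^K(I), H_c^B(I)`
  of 3D neighbourhood intensity responses are accumulated over training
  subjects; a voxel with response level `I` in band `c` scores
  `H_c^K(I) / (H_c^K(I) + H_c^B(I))`, with a ±δ gray-level fallback
  (δ ≤ 3) and a neutral 0.5 when no support exists.
- **Shape prior** `S(x) = (1/N) Σ_n M^(n)(x)` — the voxelwise average of the
  N training masks on a common kidney-centred ROI lattice.

The three-channel condition volume `c = (g, P_app, S)` feeds a 3D
conditional GAN: a residual 3D U-Net generator `G` (anisotropic strides
(1,2,2), channels 64→512) against a conditional 3D PatchGAN discriminator
`D` (up to 256 channels), trained with

    L_D = ½ [BCE(D(y,c), 1) + BCE(D(ŷ,c), 0)]
    L_G = BCE(D(ŷ,c), 1) + λ_rec · ‖ŷ − y‖₁ ,   λ_rec = 200

(Adam, lr 4·10⁻⁴, batch size 1). The final mask is `sigmoid(G(c)) ≥ 0.5`.
No deep-learning runtime is required: the network, backpropagation and
optimiser are implemented natively (C++/RcppArmadillo).

The package also provides Dice/IoU/HD95/ASSD metrics in physical units, a
leave-one-out cross-validation harness with an inner 80/20 split and a
leakage audit, the four-way input ablation (raw / ROI / ROI+appearance /
full) with exact Wilcoxon signed-rank + Benjamini–Hochberg comparisons, a
synthetic phantom generator emulating the three contrast regimes, and
minimal NIfTI-1 I/O.

## Worked example

Fit the full model on five synthetic high-contrast (DW-like) phantoms and
segment a sixth:

```r
library(priorseg)
coh  <- make_cohort(phantom_config(n_subjects = 6, grid = c(8, 32, 32),
                                   modality = "dw_like", seed = 7))
vols <- lapply(coh$subjects, `[[`, "volume")
msks <- lapply(coh$subjects, `[[`, "mask")

fit <- priorseg(vols[1:5], msks[1:5], roi_size = c(8, 32, 32),
                net = tiny_net(), validation = 5,
                train = train_control(epochs = 15, seed = 1))
fit
#> priorseg fit: configuration 'full' (3 channels), 5 subjects
#>   ROI 8x32x32, 256 gray levels; generator channels 8-16-32-64
#>   appearance prior: 8 bands, thickness 1, radius 1
#>   shape prior over 5 masks
#>   trained 15 epochs (lambda_rec = 200); best epoch 15, validation Dice 0.571

pred <- predict(fit, vols[[6]])           # never sees the sixth mask
seg_scores(pred, msks[[6]], spacing(vols[[6]]))
#>        dice       iou hd95     assd flagged
#> 1 0.7087379 0.5488722 2.88 1.036381   FALSE
```

The scores read as: 71% volumetric overlap (Dice), 55% intersection over
union, a 95th-percentile boundary error of 2.9 mm and a mean symmetric
boundary error of 1.0 mm — what 15 epochs of the tiny 8→64-channel preset
buys on an 8×32×32 grid. The acceptance-scale run (12 subjects, 16×64×64,
30 epochs) reaches held-out Dice above 0.9; `plot(fit)` shows the
adversarial losses, the L1 term and the validation-Dice trajectory, and
`run_loocv()` / `run_ablation()` + `aggregate_scores()` /
`paired_significance()` reproduce the full evaluation protocol.

A thin command-line front end is installed at `inst/cli/priorseg`
(`priorseg phantom ...` writes NIfTI cohorts, `priorseg loocv ...` runs the
cross-validation over a cohort directory).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

runs the package's main computation end-to-end — generates a phantom
cohort, executes leave-one-out folds for two input configurations
(priors, adversarial training, held-out inference), prints per-subject
scores, bootstrap aggregates and the paired signed-rank comparison — and
writes the JSON report to `--out`.
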