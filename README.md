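# mvseg

Automatic primary-tumor segmentation for multi-sequence head and neck MRI,
implemented end to end in R: population template construction, two-step
affine/rigid registration into a 1-mm "head and neck standard space",
class-rebalanced voxel sampling, tri-planar two-scale patch extraction, a
multi-view convolutional neural network (MV-CNN) trained with a batch-level
soft-dice loss, masked full-volume inference, and volumetric/spatial
evaluation. The intended users are medical-image-analysis researchers who
want a transparent, fully scriptable reference implementation of this kind
of 2.5D patch pipeline.

A case supplies a T1-weighted volume, a STIR volume, an optional
contrast-enhanced T1 (its channel is zeroed when absent), and a manual
reference segmentation on the T1 grid. The network sees, for every voxel,
six 32×32×3 inputs — axial, coronal and sagittal windows at two pyramid
scales (32×32, and 64×64 downsampled by 2×2 mean pooling) with the three
sequences as channels. Each of the six branches is
`conv 3×3 → batch norm → ReLU → max pool 2×2 → dropout 25% → dense`; branch
outputs are concatenated into two dense layers ending in a 2-way softmax.
Training uses Adam (lr 0.001, ×0.8 after every 5th epoch), batch size 512,
and the soft dice loss over each batch,

    L = 1 − (2 Σᵢ pᵢ gᵢ + ε) / (Σᵢ pᵢ + Σᵢ gᵢ + ε),

with voxels drawn as 50% of tumor and 1% of healthy voxels inside the
template occupancy mask. Evaluation reports the Dice similarity coefficient
(DSC), the single-measure absolute-agreement intraclass correlation
ICC(2,1) between manual and automatic volumes (per fold, summarized across
folds), subgroup DSC by T/N stage, site and tumor-volume groups
(V1: ≤3 cm³, V2: 3–7, V3: 7–15, V4: >15), and Wilcoxon rank-sum
comparisons.

No deep-learning or registration framework is used: the CNN (forward,
backprop, Adam, batch norm, dropout) is compiled RcppArmadillo code on top
of BLAS, and registration optimizes a correlation-ratio metric with
Nelder–Mead over a multi-resolution pyramid. Since the clinical cohort
of this kind cannot be redistributed, the package ships a phantom generator
(`generate_case()`, `generate_cohort()`) producing multi-sequence cases
with known ground-truth masks and transforms, which the whole test suite
runs on.

## Worked example

```r
library(mvseg)

# a synthetic cohort with known ground truth
coh   <- generate_cohort(6, seed = 20)
cases <- lapply(coh$cases, function(x) x$case)

# template space: non-zero average + 30% occupancy rule
tpl <- build_template_from_cases(cases, ref_index = 1)
tpl
#> <mvseg_template> dim 64x64x64, occupancy threshold 0.30, 77441 voxels in mask

# two-step registration of every case into template space
std      <- lapply(cases, function(cs) case_to_standard(cs, tpl))
prepared <- lapply(std, function(s) prepare_case(s$case, tpl$occupancy))

# hold out one small (V1) and one large (V4) tumor, train on the rest
hold <- c(1L, 4L)
fit  <- train_fold(prepared[-hold], train_config(epochs = 5, seed = 11),
                   model_config(), tpl$occupancy)
round(fit$history, 3)
#> [1] 0.251 0.042 0.018 0.007 0.005

# segment the held-out cases and score them
for (h in hold) {
  pred <- segment_volume(fit$params, prepared[[h]], tpl$occupancy)
  cat(sprintf("%s  DSC %.3f  ref %.1f cm3  pred %.1f cm3\n",
              prepared[[h]]$case_id,
              dsc(pred, prepared[[h]]$reference),
              predicted_volume_cm3(prepared[[h]]$reference),
              predicted_volume_cm3(pred)))
}
#> phantom001  DSC 0.462  ref 0.5 cm3  pred 1.0 cm3
#> phantom004  DSC 0.848  ref 4.5 cm3  pred 6.0 cm3
```

The loss history shows the batch soft-dice loss falling over the five
epochs. The held-out scores reproduce two behaviours the evaluation module
quantifies on real cohorts: segmentation quality grows with tumor volume
(the V4-group case far outscores the V1-group case), and the network
systematically overestimates the tumor, most visibly for small lesions —
the predicted volume of the half-cm³ tumor is roughly twice its reference.

The same stages are available from a shell via the bundled CLI
(`inst/exec/mvseg`): `simulate`, `build-template`, `preprocess`, `train`,
`segment`, `evaluate`, each honoring `--seed` and a YAML `--config`.

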