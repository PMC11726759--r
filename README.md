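# wavemorph

Deformable registration of multimodal 3D medical image volumes in R.

Pelvic CT/MR registration for image-guided radiotherapy faces two coupled
problems: organ deformation is large and locally discontinuous (bladder and
bowel filling), and the two modalities order tissue intensities differently,
so mono-modal similarity measures fail. `wavemorph` addresses both with a
four-stage coarse-to-fine cascade driven by wavelet multiresolution inputs
and a learned, modality-robust similarity.

Given a fixed image $I$ and moving image $M$, the package estimates a dense
displacement field $\phi$ (voxel units) such that
$(M\circ\phi)(x) = M(x+\phi(x)) \approx I(x)$:

1. **Multiresolution inputs.** A three-level 3D discrete wavelet transform
   (`db5`) splits each volume into subbands `aaa`…`ddd`. The coarsest stage
   aligns the level-3 low-frequency approximation `aaa` (global structure);
   the two middle stages align the enhancement image
   $E=\sum_b \lVert\nabla b\rVert$ fused from the seven level-1
   high-frequency bands (local edges); the final stage aligns the original
   intensities.
2. **Pyramid registration networks.** Each stage refines the accumulated
   field with a network built from two independent windowed self-attention
   encoders (one per modality) and a shared convolutional decoder that
   predicts the field coarse-to-fine, warping moving features with the
   upsampled previous field at every pyramid level. Refinements accumulate
   by field composition $\phi_{new}(x)=\phi_s(x+\phi_{acc}(x))+\phi_{acc}(x)$.
3. **Self-supervised similarity.** A residual 3D CNN is trained to predict
   the spatial error $\mathrm{mean}\,|M_2-M_1|$ between two randomly
   transformed copies of one volume, one of which is corrupted by
   dual-structure (ring) grey-scale morphology plus noise. The trained
   evaluator scores warped/fixed pairs across the modality gap and serves as
   the (differentiable) registration loss; local squared NCC is provided as
   an ablation.

Everything is implemented in R with Rcpp/RcppArmadillo kernels, including a
small reverse-mode automatic-differentiation tape that trains the networks.
Quality metrics (per-organ Dice, average symmetric surface distance, the
percentage of voxels with non-positive Jacobian determinant) and a synthetic
multimodal phantom generator with known ground-truth deformations are
included, along with NIfTI I/O and a CLI (`inst/exec/wavemorph`).

## Worked example

```r
library(wavemorph)

# paired pseudo-CT / pseudo-MR phantoms with known deformation
train <- lapply(1:12, function(i) generate_pair(phantom_spec(seed = i)))
test  <- generate_pair(phantom_spec(seed = 501))

# similarity evaluator from single-modality corrupted copies
vols <- lapply(1:20, function(i)
  normalize_intensity(generate_pair(phantom_spec(seed = 200 + i))$moving, "minmax")$data)
samples <- lapply(1:200, function(i) make_sample(vols[[(i - 1) %% 20 + 1]], seed = i))
ev <- train_evaluator(samples, epochs = 12, lr = 2e-3, seed = 1)

# four-stage cascade at desk scale
cc   <- cascade_config(c(64, 64, 16), embed = 8, depths = c(1, 1, 1, 1),
                       heads = c(2, 4, 4, 8), window = 4)
nets <- cascade_nets(cc, seed = 11)
tc   <- train_config(iterations = 300, base_lr = 1e-3,
                     similarity = "evaluator", lambda = 1, seed = 12)
fit  <- fit_cascade(train, cc, nets, tc, evaluator = ev)

reg <- register(test$fixed, test$moving, cc, nets)
print(reg)
#> <wm_registration 64x64x16: 4 stages, |u| mean 1.98 vox, JD<=0 0.000%>

metrics_report(test$fixed_labels, test$moving_labels, reg$field)
#> Registration metrics
#>  label      name status dsc_pre dsc_post dsc_gain assd_mm
#>      1      body     ok  0.7298   0.7785  0.04877  0.9841
#>      2   bladder     ok  0.7686   0.8090  0.04033  0.7834
#>      3       ctv     ok  0.3690   0.5131  0.14408  1.4143
#>      4     femur     ok  0.5066   0.4435 -0.06313  2.0301
#>      5 intestine     ok  0.1662   0.2777  0.11143  1.8720
#> JD<=0: 0.000% of interior voxels
```

(The printed numbers come from the seeds shown; `dsc_pre` is the overlap
before registration, `dsc_post` after warping the moving labels by the
recovered field, `assd_mm` the mean symmetric surface distance of the warped
labels, and `JD<=0` the folding percentage of the field — 0% means a
nowhere-folding deformation. On this particular test phantom four of five
structures improve, the overall overlap rises, and the field is smooth; over
ten held-out phantoms the mean organ Dice gain is about 0.05, which is what
the acceptance experiment below measures.)

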