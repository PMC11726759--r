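---
title: "Methods: wavelet-enhanced coarse-to-fine multimodal registration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wavelet-enhanced coarse-to-fine multimodal registration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The registration problem

Given a fixed volume $I$ and a moving volume $M$ of the same anatomy in two
modalities (the motivating setting is pelvic CT/MR in image-guided
radiotherapy, where bladder and bowel filling cause large, locally
discontinuous deformation), we seek a dense displacement field $\phi$ such
that the warped image $M \circ \phi$, defined by
$(M \circ \phi)(x) = M(x + \phi(x))$, is spatially aligned with $I$.
`wavemorph` implements an unsupervised, learning-based estimator of $\phi$
organised as a four-stage coarse-to-fine cascade with wavelet-derived stage
inputs, plus a self-supervised similarity evaluator that provides the
training signal across modalities.

## Multiresolution stage inputs

Each volume is decomposed by a three-level separable 3D discrete wavelet
transform (default basis `db5`). One level splits the image into eight
subbands coded `aaa` … `ddd` (letter order = axis order; `a` low-pass, `d`
high-pass); the `aaa` approximation of level $k$ feeds level $k+1$. The
seven level-1 high-frequency bands are fused into a single non-negative
enhancement image

$$E = \sum_{b \in \{aad,\dots,ddd\}} \lVert \nabla b \rVert,$$

the per-voxel sum of gradient magnitudes of the bands. The gradient is taken
per band with central differences (one-sided at the boundary); summing
*magnitudes* rather than signed gradients makes $E$ a non-negative edge-
emphasis map, which is what the coarse-to-fine schedule needs from it. $E$
is min–max rescaled to $[0,1]$ so all levels share an intensity scale.

The four cascade stages then see, coarse to fine: the level-3 `aaa`
approximation (global structure), $E$ resampled to the two intermediate
grids (local detail; the same level-1 enhancement is reused at both scales),
and the original min–max-normalised intensities at full resolution. Stage
grids default to 1/8, 1/4, 1/2 and 1 of the input resolution.

**Boundary handling.** The transform uses periodic (circular) boundary
extension with orthonormal Daubechies filters, and the inverse is the
adjoint filter bank. This choice makes the transform an orthogonal map:
subband shapes halve exactly per axis (a 384×256×32 volume ends at a
48×32×4 approximation after three levels), energy is preserved, and
reconstruction is exact to round-off — properties the package asserts in its
tests. Symmetric extension would enlarge subbands by half the filter length
and lose exact energy preservation.

## The stage network

Each stage runs a pyramid registration network: two *independent* encoders
(one per modality — deep features of different modalities converge while
shallow features differ, so sharing encoder weights across modalities is
counter-productive) and a *shared* convolutional decoder.

The encoder partitions its input into $K^3$ patches (default $K = 2$),
linearly embeds them to $D$ channels, and applies four stages of windowed
multi-head self-attention with residual pre-norm blocks and MLPs,
alternating plain and half-window-shifted windows so information crosses
window borders. No positional embedding is added: registration is a dense
prediction task and any spatial misplacement of the output is already
penalised by the loss, so the embedding can stay permutation-equivariant.
Patch merging between stages concatenates 2×2×2 neighbourhoods and projects
them to twice the channels, giving the resolution/channel progression
$\tfrac{1}{2K}, \tfrac{1}{4K}, \tfrac{1}{8K}, \tfrac{1}{16K}$ and
$D, 2D, 4D, 8D$. On thin axes (common at desk scale) the patch, window and
merge extents are clamped per axis so the same architecture applies
unchanged; window sizes always divide the padded feature grid. A CNN
encoder with the same pyramid contract is available as an ablation
(`encoder = "cnn"`), as is disabling the decoder skip pathway
(`use_skip = FALSE`).

The decoder predicts displacement fields coarse to fine. At the deepest
level the concatenated modality features yield the coarsest field through a
3×3×3 convolution head; at each finer level the previous field is
upsampled (trilinear on the vectors, magnitudes scaled by the grid ratio so
displacements remain in voxels of the current grid), the moving features
are warped by it, concatenated with the fixed features (plus the upsampled
decoder state when skips are on), convolved, and a head emits a refinement
that is added to the upsampled field. All heads are zero-initialised, so an
untrained network is exactly the identity transform — this keeps the early
cascade stable and makes the identity a testable contract.

## Cascade composition

The accumulated field enters each stage by upsampling to the stage grid;
the stage's moving input is warped by it before the network runs, so each
network only refines what remains. Refinements are folded in by field
composition

$$\phi_{\text{new}}(x) = \phi_{\text{stage}}(x + \phi_{\text{acc}}(x)) + \phi_{\text{acc}}(x),$$

i.e. the accumulated field is applied first. To avoid compounding
interpolation error, each stage warps the *original* stage representation by
the accumulated field rather than re-warping already-warped images.

## Self-supervised similarity evaluator

Mono-modal similarity measures fail across modalities because tissue
intensity orderings differ. The evaluator learns a modality-robust spatial
error score from a single modality: from a source volume $M$, two random
spatial transforms $K_1, K_2$ (per-axis rotation within ±3°, translation
within ±3 voxels, isotropic scaling within ±8%, plus a smooth random
per-voxel field) produce $M_1, M_2$; $M_1$ is then corrupted with a
dual-structure grey-scale morphology operator and Gaussian noise
(sd 0.05 of the unit intensity range — the corruption strength is part of
the generator's study conditions) to create an appearance gap, while the
training label is the true spatial error magnitude
$\text{mean}\,\lvert M_2 - M_1 \rvert$ computed from the *uncorrupted*
images. Both transforms are scaled by a per-sample magnitude factor drawn
uniformly in $[0,1]$ so the labels genuinely span from ~0 to the full
transform range; without the small-gap anchor the regressor has nothing to
calibrate its low end against.

The dual-structure morphology uses a ring element (the hollow shell between
balls of radius $R_a$ and $R_b$; outer radii drawn from {3, 5, 6, 7, 9},
ring width 2) together with an intermediate ball of radius
$\text{round}((R_a + R_b)/2)$: `dual_open(f) = erode(dilate(f, ring), mid)`
and `dual_close(f) = dilate(erode(f, ring), mid)`, with the associated
top-hats $f - \text{dual\_open}(f)$ and $\text{dual\_close}(f) - f$. The
glyph conventions of the defining equations are read as ⊕ = dilation and
⊙/Θ = erosion — the only reading under which the derived transforms are
top-hat-like. These ring operators are deliberately *not* idempotent; they
reshape structures at the ring scale, which is exactly the organ-scale
distortion they are meant to emulate. Elements are 3D balls by default
(a 2D slice-wise mode is available). Whether the defining equations are
meant per-slice or volumetrically is not decidable from their 2D notation;
volumetric application matches the 3D data.

The regressor itself is a compact residual 3D CNN (strided stem, two
residual blocks with one channel-doubling downsample, global average
pooling, linear head). A full-depth 2D classification backbone cannot
consume these 3D volumes and would be grossly over-parameterised at desk
scale; the residual structure is kept, the size is not. The output head is
raw linear — a softplus/ReLU output can saturate at 0 early in training and
kill the gradient — and predictions are clipped at 0 only when reported. The evaluator regresses a *scalar*
error (the ‖·‖₁ of the label image): the defining formulation is ambiguous
between a scalar and a per-voxel error image, and the scalar is both
directly usable as a loss term and much cheaper to learn at small sample
counts. Inputs are average-pooled by 2 before the stem; the network is
fully convolutional, so the same evaluator scores any stage grid.

## Training

The loss is similarity + $\lambda\,\cdot$ mean squared forward difference of
the accumulated field (diffusion regulariser, default $\lambda = 1$,
settable to 0). The defining method states no explicit regulariser yet
reports smooth fields; a diffusion term is the standard way to obtain them
and is kept configurable for fidelity runs. Deep supervision — applying the
similarity at every cascade stage to that stage's warped representation —
is on by default; it stabilises the coarse stages, whose gradient would
otherwise arrive only through three downstream warps. All four stage
networks are trained jointly (sequential training is possible by freezing,
but joint is the default). The optimiser is Adam with the step schedule:
base rate $10^{-4}$, multiplied by 0.6 for every 1000 iterations past
5000, 15 000 iterations at full scale. Two standard stabilisers are on by
default because iterations see a single image pair and the resulting
gradients are heavy-tailed: global-norm gradient clipping (threshold 1) and
Polyak averaging — the fitted model returned by `fit_cascade()` is an
exponential moving average (decay 0.98, an effective window of ~50
iterations) of the optimisation iterates, which removes most of the
iterate-to-iterate oscillation in held-out overlap. Both are configurable
off.

The similarity is either the trained evaluator (the method proper) or one
minus the mean local *squared* normalised cross-correlation (the `ncc`
ablation). In evaluator mode the learned similarity scores the finest
stage — the original-intensity images it was trained on — while the
auxiliary deep-supervision terms at the wavelet-representation stages use
local NCC: the approximation and enhancement representations are shared
across modalities, so a correlation measure is well-posed there, whereas
the evaluator is out of its training distribution on them. Applying the
learned metric to every stage representation invites the optimiser to walk
off the evaluator's data manifold — the classic failure mode of learned
similarities used as losses — so the hybrid assignment is the default. The squared form is sign-blind, which matters across modalities
with inverted contrast; the implementation adds the stabiliser $\epsilon$
to numerator and denominator alike so perfectly flat windows score as
correlated, making `ncc(v, v) = 0` exact, and normalises window sums by the
true (border-shrunken) window size so affine intensity invariance holds up
to the volume edge.

## Synthetic phantoms

The phantom generator emulates the clinical setting at desk scale: a
soft-tissue body with five labelled organ structures (large fluid-filled
bladder, adjacent target volume, two lateral bones, an intestinal blob),
rendered in two modalities whose tissue intensity tables have deliberately
different rank orderings (bone brightest on pseudo-CT and dark on
pseudo-MR; fluid the reverse), plus rendering blur and Gaussian noise. The
ground-truth displacement is a Gaussian-smoothed random field (RMS
magnitude 4 voxels, smoothness σ = 6) plus a radial bladder-centred
expansion (peak 1.5 voxels) emulating filling change. The moving label map
is warped by the true field to *define* the fixed anatomy, so the true
field maps moving onto fixed exactly and recovered fields can be scored
against it. Default grid 64×64×16 — divisible by 8 for the three dyadic
wavelet levels and matching a strongly anisotropic clinical z-resolution.

What the phantoms do not model: realistic organ texture, intensity
inhomogeneity fields, partial-volume effects, sliding interfaces, or
topology changes. Passing the phantom experiments therefore demonstrates
that the pipeline's mechanics work (multiresolution inputs, cross-modality
similarity, coarse-to-fine composition, near-diffeomorphic fields) — not
clinical-grade accuracy.

## Problem sizes and numerical choices

The package's experiments run at deliberately small sizes chosen as desk-
scale analogues of the full-scale protocol: evaluator training uses 200
samples from 20 phantoms (40 held out), 12 epochs, Adam at 2·10⁻³ with a
late step decay; cascade training uses 12 phantom pairs, 10 held-out test
pairs, embedding dimension 8, one attention block per encoder stage, 300
iterations at 10⁻³ (the full-scale schedule's decay point lies beyond this
horizon, so the published schedule is unchanged). Sampling is trilinear
with border clamping everywhere (no zero halo in the loss); label maps are
always warped nearest-neighbour. Degenerate inputs are contracts, not
accidents: constant images normalise to zero with a warning, empty
foreground crops return the input with a warning, an empty mask is an error
for surface distances, and both-empty label sets have Dice 1 by convention.
Jacobian folding fractions are computed over interior voxels (central
differences are one-sided at the boundary).

## Known limitations

* The windowed-attention encoder is small (no relative position bias, no
  dropout, modest depth); it targets correctness and desk-scale training,
  not state-of-the-art capacity.
* The evaluator is trained on one modality's corrupted copies; its
  cross-modality robustness is exactly as good as the morphology+noise
  corruption family is a proxy for the modality gap.
* Fields are plain displacements; no diffeomorphic integration or inverse
  consistency is enforced — smoothness is encouraged only by the penalty
  and the coarse-to-fine schedule.
* The learned similarity is unbounded below off-manifold; the smoothness
  term and small step sizes keep optimisation in range, but pathological
  warps could in principle exploit it.
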