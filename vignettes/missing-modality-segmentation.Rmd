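---
title: "Modality-robust PET/CT tumor segmentation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modality-robust PET/CT tumor segmentation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petctseg)
```

## The problem

Gross tumor volume (GTV) delineation for head-and-neck radiotherapy draws
on two co-registered volumes: CT, which shows anatomy in Hounsfield units
(HU) at high spatial resolution, and FDG-PET, which shows metabolic uptake
at coarse resolution but with high lesion contrast. Automated segmentation
models trained on both channels usually *require* both at deployment: when
one modality is missing (artifacts, protocol differences, unavailable
tracer), a fixed two-channel model degrades badly, because it has learned
co-adapted features that mix the two inputs.

`petctseg` implements a training-time remedy: **input-channel dropout**.
During training, each two-channel (CT, PET) input is kept intact with
probability $p$ (default 0.5) or has exactly one channel — chosen uniformly
— replaced by an all-zero array. Zero is the mean of each z-normalized
channel, so the replacement adds no information. The network therefore
cannot rely on the joint signal alone and learns usable single-modality
features, while at deployment a missing modality is simulated the same way
(zero-filled channel). A single trained model then serves all three
availability settings: CT-only, PET-only, and CT+PET.

## The segmentation network

The backbone is a 3D encoder–decoder (U-Net) with `n_levels` resolution
levels (5 at full scale). Each encoder block applies two 3×3×3
convolutions, each followed by instance normalization and a leaky ReLU
(slope 0.01); resolution is halved between levels by a stride-2
convolution. The decoder mirrors the encoder with 2×2×2 stride-2
transposed convolutions and concatenative skip connections. A *dilated*
variant replaces the stride-1 convolutions with dilation-2 convolutions of
the same kernel size, enlarging the receptive field without extra
parameters; the stride-2 downsampling convolutions keep dilation 1, since
dilating a resolution-reduction step would change the output geometry that
the deep-supervision bookkeeping relies on.

**Deep supervision.** Every decoder block carries a 1×1×1 convolution head
producing a per-voxel foreground probability at its own resolution. Each
head $i$ (finest first) is scored against a stride-downsampled copy of the
ground-truth mask with

$$\mathrm{CE}_i = -\tfrac1N \sum_v \bigl[y\log o + (1-y)\log(1-o)\bigr],
\qquad
D_i = -\frac{2\sum_v o\,y + s}{\sum_v o + \sum_v y + s},$$

and the total loss is $\sum_i w_i\,(\mathrm{CE}_i + D_i)$ with weights that
halve per level and are normalized to sum to one
(`supervision_weights(4)` = 8/15, 4/15, 2/15, 1/15). Two conventions are
deliberate: the cross-entropy is reduced as a voxel *mean* so the loss
magnitude is independent of patch size, and the Dice denominator is
$\sum o + \sum y$ (the sum of both masses — the alternative $2\sum o$
would make the loss independent of the label mass, which cannot be
intended). Smoothing $s = 10^{-5}$ and a probability clamp
$\varepsilon = 10^{-7}$ guard the logarithms and the empty-mask limit.

**Optimization.** Plain SGD with Nesterov momentum 0.99, initial learning
rate 0.01, and polynomial decay $\mathrm{lr}_0 (1 - t/T)^{0.9}$, batch
size 1 (one patch per iteration). These are the standard settings for
patch-based 3D segmentation trainers of this family. Training is
deterministic given the seed.

The network is implemented natively — no external deep-learning runtime —
with the forward and backward passes written out explicitly: convolutions
run in compiled kernels (with a cache-friendly same-padding fast path,
verified bit-for-bit against a naive reference kernel), and every layer's
analytic gradient is checked against central finite differences in the
test suite. This keeps the training loop fully inspectable — there is no
hidden autodiff state.

## Preprocessing

The fusion pipeline follows the fixed order **clip → normalize → resample
→ crop → concatenate**:

1. CT intensities are clipped to $[-1000, 600]$ HU (soft-tissue window).
   PET is not clipped.
2. Each image is z-normalized with its whole-volume mean and *population*
   SD (computed before resampling, on the full image).
3. Both images are resampled to an isotropic grid (1 mm default; the
   desk-scale experiments use 2 mm) by trilinear interpolation, labels by
   nearest neighbor. The output axis length is
   `round(n_in * spacing_in / target)` with voxel centers at
   `origin + index * spacing`, so physical extent is conserved to within
   one voxel and origins are preserved.
4. The two grids are cropped to their overlapping field of view, computed
   in continuous world coordinates and snapped to each grid (first voxel
   center inside the intersection starts the crop). If the two origins
   differ by a sub-voxel offset, the PET crop is shifted onto the CT crop
   grid by linear interpolation so both channels share one grid exactly.
5. The channels are stacked into a two-channel fused volume.

Coordinates are 0-based voxel indices with world position
`origin + index * spacing` (mm); array axis 1 is the left–right axis.

## Patch extraction and augmentation

Training samples are cubic patches (128³ at full scale, 16³ at desk
scale). At least half of all patches are forced to contain tumor: with
probability `fg_prob = 0.5` the patch centers on a uniformly drawn tumor
voxel (clamped to bounds). Patches are cut *enlarged* by a margin
covering the worst-case zoom-out (factor 0.7) plus in-plane rotation
support, augmented, and only then center-cropped to the network size, so
interpolation border artifacts never reach the input.

One subtlety matters when volumes are not much larger than the enlarged
patch: if patches were drawn only from positions where the enlarged crop
fits inside the volume, every training patch would come from (nearly) the
same central region, and the network would never learn what off-center or
border contexts look like — at sliding-window inference it would then
hallucinate foreground in windows it has never seen the like of. The
training loop therefore pads every case by the augmentation margin before
sampling, so patch centers range over the whole volume and the zero
borders seen in training match the zero padding sliding-window inference
applies at volume edges.

Augmentations and their probabilities: left–right flip 50% (head-and-neck
anatomy is approximately mirror-symmetric), isotropic spatial zoom 20%
with factor in [0.7, 1.4], brightness 15% (multiplicative factor in
[0.75, 1.25]), contrast 15% (scaling about the channel mean by a factor in
[0.75, 1.25], clipped back to the pre-transform range), additive Gaussian
noise 10%, and in-plane rotation up to ±30° 20%. Three conventions the
probabilities alone do not fix: the noise SD is drawn uniformly from
(0, 0.1) in normalized-intensity units; "scaling" is interpreted as a
spatial zoom (it sits among the resolution-affecting transforms in this
augmentation family) applied once per patch about the patch center; and
rotation is axial (in the left–right/anterior–posterior plane), where the
symmetry argument applies, with linear interpolation for channels and
nearest for labels.

## Inference and ensembling

Whole volumes are predicted with a sliding window the size of the training
patch, stride ¼ of the window, and a final window flush with the far edge;
overlapping window predictions (finest head only) are averaged uniformly.
With flip test-time averaging each window is also predicted left–right
flipped, un-flipped, and averaged 50/50. Probabilities are thresholded at
0.5 (tie → foreground, a convention fixed so tests can be exact). For
back-resampling to the native grid the default resamples the *probability
map* linearly and thresholds on the native grid; a `mask_resample =
"nearest"` switch instead thresholds first and carries the binary mask
over, reproducing the literal threshold-then-resample order. Ensembles
average member probability maps voxelwise before thresholding.

## Evaluation statistics

Per case: Dice similarity coefficient $2|X\cap Y|/(|X|+|Y|)$ (defined as 1
with a warning when both masks are empty) and the symmetric Hausdorff
distance over boundary-voxel centers in physical mm (undefined for an
empty mask; a percentile option, e.g. HD95, is available since the maximum
is noise-sensitive). Across cases: means and SDs, plus the intraclass
correlation of tumor volumes from a two-way ANOVA decomposition
(single-measure; consistency type by default, absolute agreement as an
option) with a seeded bootstrap SD over case resamples (1000 replicates by
default). Models are compared with unpooled two-sample z tests on the
per-case summaries; ICCs are compared treating bootstrap SDs as standard
errors. The ANOVA closed form is cross-checked against `aov()` mean
squares in the tests.

## The synthetic phantom

Clinical PET/CT with GTV annotations cannot be redistributed, so the
package generates paired phantoms that preserve the properties the method
actually exercises:

- two modalities on *different* grids — CT near 1.1×1.1×2.7 mm, PET near
  3.9×3.9×3.7 mm — with a small origin offset, so resampling and overlap
  cropping are genuinely tested;
- CT anatomy in HU with an air shell (≈ −1000), soft tissue (≈ 40 ± smooth
  texture), and an optional bone rod (≈ 800), so both clip bounds are hit;
- an ellipsoidal tumor (axis-aligned, smooth-edged — the simplest shape
  with an exact volume oracle) whose **full extent is hot on PET**
  (default 5× background) but blurred by a scanner point-spread-like
  partial-volume kernel (sigma 1.5 mm, ≈3.5 mm FWHM), while the **CT
  contrast covers only ~80% of the radius** at +40 HU with a sharp edge.
  This division of labor mirrors clinical PET/CT — PET localizes the
  lesion unambiguously but its boundary is fuzzy; CT has crisp edges but
  under-covers the tumor — so a jointly trained model genuinely benefits
  from fusing both, which is precisely the co-adaptation that channel
  dropout must break;
- per-modality Gaussian noise (20 HU; 0.15 uptake units), and per-case
  jitter of tumor center (SD 2 mm) and radii (SD 1 mm).

The ground-truth label lives on the CT grid (GTV contours are drawn at
CT-like resolution). What the phantom does *not* emulate: realistic
anatomy, attenuation-correction physics, metal artifacts, non-ellipsoidal
lesion shapes, and multiple lesions. Passing the end-to-end tests
therefore demonstrates that the training mechanics, the dropout effect,
and the evaluation chain behave as designed — not that any particular
clinical accuracy would be reached on patient data.

## Desk-scale experiment sizes

The ablation runner defaults are sized for a single CPU: 20 phantom cases
(16 training / 4 test, seeded 80/20 split), 64 mm field of view (CT
32×32×16 at 2×2×4 mm, PET 16³ at 4 mm), 2 mm fused grid (≈31³ voxels),
16³ patches, 3 network levels with 8 base filters, and 2000 training
iterations per model. A full-scale configuration (128³ patches, 5 levels,
32 base filters capped at 320, 500 000 iterations, 1 mm grid) is what the
architecture mirrors at clinical scale, but it is not exercised by the
tests. At desk scale a full three-model robustness run (PET-only model,
dual ± channel dropout) takes on the order of ten minutes.

## Numerical choices and degenerate inputs

- Probability clamp 1e−7 and Dice smoothing 1e−5 (above); instance-norm
  epsilon 1e−5.
- Thresholding ties go to foreground; both-empty DSC is 1 (warned); HD on
  an empty mask is an error and the case is excluded from HD aggregates
  with a warning.
- Constant volumes cannot be z-normalized (error) and constant volume
  tables have no ICC (error); degenerate bootstrap replicates are skipped
  and counted.
- A channel-dropout draw on an input that already lost a channel is an
  error; `simulate_missing` composed to zero channels warns.
- Zero-radius tumors give empty labels; `total_iterations = 0` returns
  the network unchanged with an empty trace.
- Seeds: every stochastic component (phantom noise, cohort jitter, split,
  weight initialization, patch sampling, augmentation, dropout draws,
  bootstrap) is derived from explicit integer seeds; all derived seeds
  stay below 2³¹.

## Known limitations

- The hand-rolled training loop is CPU-bound and desk-scale; it is not a
  route to full-resolution clinical training.
- The phantom's simple geometry means absolute metric values are not
  comparable to clinical benchmarks; only orderings and contrasts
  (dropout vs. no dropout, PET vs. CT information content) transfer
  qualitatively.
- Only binary (single-class) segmentation is supported.
- Anatomy-based field-of-view reduction (cropping to the head-and-neck
  region) is out of scope; the phantom controls its field of view
  directly.
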