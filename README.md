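# petctseg

Multimodal head-and-neck tumor segmentation from paired CT and FDG-PET,
robust to a missing modality.

## The problem and the method

Radiotherapy planning for head-and-neck cancer needs the primary gross
tumor volume (GTV) delineated on co-registered CT (anatomy, Hounsfield
units) and FDG-PET (metabolic uptake). A segmentation network trained on
both channels normally *requires* both at deployment; if PET or CT is
unusable (artifacts, protocol, tracer availability), performance
collapses, because the network has learned co-adapted cross-modality
features.

`petctseg` implements **input-channel dropout** as the remedy: during
training each two-channel (CT, PET) input is kept intact with probability
½, otherwise exactly one channel — chosen uniformly — is replaced by an
all-zero array (zero is the mean of each z-normalized channel, so no
information is injected). A missing modality at deployment is simulated
the same way. One model then serves CT-only, PET-only, and CT+PET inputs.

Around that core the package provides the full pipeline:

- a **3D encoder-decoder network** (conventional or dilated convolutions,
  instance norm + leaky ReLU, transposed-convolution decoder with skip
  connections) with **deep supervision**: each decoder block carries a
  1×1×1 probability head, scored with `CE + D` where
  `CE = -(1/N) Σ [y log o + (1−y) log(1−o)]` and
  `D = -(2Σoy + s)/(Σo + Σy + s)`, head weights halving per level and
  normalized to sum to 1 (`supervision_weights(4)` → 8/15, 4/15, 2/15,
  1/15); SGD (Nesterov 0.99) with polynomial learning-rate decay
  `lr₀(1 − t/T)^0.9`. Forward and backward passes are implemented
  natively (compiled convolution kernels + explicit analytic gradients,
  verified against finite differences);
- **fusion preprocessing**: CT clipped to [−1000, 600] HU, per-image
  z-normalization, isotropic resampling by trilinear interpolation,
  cropping to the overlapping field of view using header origins, channel
  concatenation;
- **patch extraction** with ≥50% tumor oversampling and the augmentation
  schedule (left-right flip 50%, zoom 20% in [0.7, 1.4], brightness 15%,
  contrast 15%, Gaussian noise 10%, ±30° in-plane rotation 20%) applied
  to enlarged patches followed by a center crop;
- **sliding-window inference** (stride = ¼ window, overlap averaging,
  left-right flip test-time averaging, threshold 0.5), back-resampling to
  the native grid, and probability-map **ensembling**;
- **evaluation**: Dice similarity coefficient `2|X∩Y|/(|X|+|Y|)`,
  Hausdorff distance in mm, two-way volume intraclass correlation with a
  bootstrap SD (n = 1000), and two-sample z tests;
- a seeded **synthetic PET/CT phantom generator** (differently gridded
  modalities, HU-layered CT anatomy, a PET-hot tumor only partially
  visible on CT) so the whole pipeline runs end-to-end without patient
  data, and an **ablation runner** reproducing the eight-model design
  (single-modality models, dual ± dropout, conventional/dilated, two
  ensembles) at desk scale.

## Worked example

```r
library(petctseg)

# four synthetic cases: CT and PET on different grids, offset origins
cohort <- generate_cohort(desk_phantom_spec(), n_cases = 4, seed = 7)
cases <- lapply(cohort, function(cs)
  preprocess_case(cs$ct, cs$pet, cs$label, target_spacing = 2))

# briefly train a small dual-input network with channel dropout
net <- build_network(network_config(n_levels = 3, base_filters = 8),
                     seed = 1)
fit <- train_network(net, cases,
                     train_config(total_iterations = 600, patch_size = 16,
                                  channel_dropout_enabled = TRUE, seed = 2))

# deploy the same model under all three availability settings
for (setting in c("CT-only", "PET-only", "both")) {
  prob <- predict_volume(fit$network, cases[[1]]$fused,
                         inference_config(window = 16,
                                          availability = setting))
  cat(sprintf("%-8s DSC %.3f\n", setting,
              dsc(cases[[1]]$label, binarize(prob))))
}
```

Output (about a minute on one CPU):

```
#> CT-only  DSC 0.466
#> PET-only DSC 0.843
#> both     DSC 0.832
```

One briefly trained dropout model already segments the phantom tumor in
every availability setting; the DSC ordering (CT alone weakest, PET alone
close to both) mirrors the information content of the two modalities.
Longer training at the ablation defaults below pushes the single-modality
scores much higher.

The desk-scale ablation (the package's main computation) is one call:

```r
res <- run_grid(experiment_grid(models = c(2, 3, 4)), "results/",
                seed = 1)
res$table
```

It trains the PET-only model (2) and the dual-input models without (3)
and with (4) channel dropout for 2000 iterations each on a 20-case
phantom cohort and scores the held-out split under all availability
settings, writing `ablation_table.csv`, `ztests.csv`, per-model training
logs, and `report.json`. The qualitative result mirrors the clinical
finding: without dropout the dual model collapses when PET is missing,
with dropout it stays usable in every setting, at no cost when both
modalities are present.

A thin command-line dispatcher is installed with the package
(`system.file("exec", "petctseg", package = "petctseg")`) with
`phantom`, `preprocess`, `predict`, and `experiment` subcommands.

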