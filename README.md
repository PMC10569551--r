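# murivess

Fully automatic segmentation of blood vessels in micro-magnetic resonance
imaging (μMRI) stacks of mouse brains.

In gadolinium-enhanced T1 μMRI of perfused mouse heads, blood vessels appear
as *dark* tubular structures inside bright brain tissue, occupying only
0.03–0.14 % of the brain's voxels. Manual segmentation of a single
400 × 400 × 320 stack takes days to weeks, and preclinical studies rarely
have more than a handful of annotated animals. `murivess` implements a
patch-based deep-learning pipeline built for exactly this setting — a small
number of training stacks and extreme foreground/background imbalance — for
researchers in preclinical vascular imaging who need reproducible,
quantitative vessel masks.

## The method

Given a raw uint16 stack, a binary brain mask, and (for training) a binary
vessel ground truth:

1. **Pre-processing** — crop the axis-aligned bounding box of the brain mask
   (voxels outside the mask are zeroed), zero-pad each axis up to the next
   multiple of 32, smooth with an isotropic Gaussian (σ = 0.5 voxels),
   min-max normalise the whole stack to [0, 1], and split into
   non-overlapping 32³ patches.
2. **Segmentation** — a *shallow* two-level 3D U-Net scores every voxel with
   a vessel probability. Each level applies two 3×3×3 convolutions
   (stride 1, same padding) with batch normalisation and ReLU; a 2³ max-pool
   links the encoder to the bottleneck, parameter-free nearest upsampling
   and a skip concatenation link it back; a 1³ convolution with a sigmoid
   produces the probability. The reference configuration has widths
   (32, 80 | 80, 80 | 80, 32) and exactly **831,105 trainable parameters**;
   the widths are fixed by exhaustive enumeration against that budget
   (`enumerate_configs_matching()`), which has a unique solution in the
   documented search space.
3. **Training** — binary focal loss with γ = 2 (no class-balancing weight),
   mean over voxels of
   `−[y (1−p)^γ log p + (1−y) p^γ log(1−p)]`,
   Adam (learning rate 10⁻⁴), an 80/20 patch-level split whose 20 %
   partition drives early stopping (patience 30, min_delta 10⁻⁴, best
   weights restored), and dataset enlargement by random x/y flips, a scalar
   brightness shift (σ = 0.1) and voxel noise (σ = 0.05).
4. **Post-processing** — either a plain threshold (`p ≥ t`) or seeded 3D
   region growing: voxels with `p ≥ s` seed a breadth-first growth through
   neighbours with `p ≥ t` (6- or 26-connectivity).
5. **Evaluation** — voxelwise confusion counts inside the brain mask;
   accuracy, recall, precision and Dice (`DSC = 2TP/(2TP+FP+FN)`);
   row-normalised confusion tables; unweighted averages across stacks;
   leave-one-out cross-validation over the stacks.
6. **Baseline** — a multiscale Hessian (Frangi) vesselness filter in
   dark-ridge polarity on the identically pre-processed volume, thresholded
   per stack (t ∈ [0.02, 0.03]).

Because the real μMRI stacks cannot ship with a package, `murivess` includes
a first-class synthetic phantom generator (`generate_phantom()`) that
reproduces the statistical structure of the data — uint16 intensities, a
bright ellipsoidal brain, dark branching tubular vessels at a configurable
per-mille foreground fraction, smooth per-stack brightness drift, noise, and
empty boundary slices — so the entire pipeline is testable end to end.

## Worked example

```r
library(murivess)

count_parameters(unet_reference_config())
#> [1] 831105

# a synthetic stack with ~0.13 % vessel fraction, like the real data
ph <- generate_phantom(phantom_config(shape = c(64, 64, 64),
                                      target_fg_fraction = 0.0013, seed = 42))
ph
#> <vs_phantom> 64 x 64 x 64, brain 33.5% of frame, vessels 0.1572% of brain

# vesselness baseline on the same pre-processing chain
seg <- vesselness_segment(ph$intensity, ph$brain_mask,
                          vesselness_config(threshold = 0.02))
compute_metrics(confusion_counts(seg, ph$vessel_gt, ph$brain_mask))
#> # A tibble: 1 × 4
#>   accuracy recall precision   dsc
#>      <dbl>  <dbl>     <dbl> <dbl>
#> 1    0.997      1     0.341 0.508
```

The Frangi baseline finds every vessel voxel (recall 1) but marks almost
three background voxels for each true one (precision 0.34), giving
Dice 0.51. Training a narrow network variant on three phantoms and
segmenting a fourth:

```r
phs <- lapply(1:4, function(s) generate_phantom(phantom_config(
  shape = c(64, 64, 64), n_vessels = 5, radius_range = c(1, 2.2),
  target_fg_fraction = 0.004, vessel_contrast = 0.85, noise_sigma = 250,
  gradient_amplitude = 0.1, seed = s)))
pool <- unlist(lapply(1:3, function(j) labelled_patches(phs[[j]], tag = j)),
               recursive = FALSE)
sp <- split_patches(pool, 0.8, seed = 7)
model <- build_unet(unet_config(filters = c(4, 8, 8, 8, 8, 4)), seed = 7)
model <- train_model(model, sp$train, sp$val,
                     train_config(max_epochs = 5, patience = 5,
                                  batch_size = 1, learning_rate = 3e-3,
                                  seed = 7))
model
#> <vs_unet> widths (4, 8, 8, 8, 8, 4), upsample nearest, final 1^3,
#>   8,833 trainable parameters

res <- segment_stack(model, phs[[4]]$intensity, phs[[4]]$brain_mask,
                     postprocess = postprocess_config("region_growing",
                                                      t = 0.3, s = 0.45))
compute_metrics(confusion_counts(res$segmentation, phs[[4]]$vessel_gt,
                                 phs[[4]]$brain_mask))
#> # A tibble: 1 × 4
#>   accuracy recall precision   dsc
#>      <dbl>  <dbl>     <dbl> <dbl>
#> 1    0.998  0.854     0.720 0.781
```

Five epochs on three small phantoms already give held-out Dice 0.78 — well
above the vesselness baseline on the same data, mirroring the comparison on
the real benchmark. `run_loocv()` wraps this train/predict/score cycle over
every held-out stack and post-processing setting and returns per-fold and
averaged metric tables; `autoplot(model)` plots the loss history, and
`plot_slice()` shows a stack layer with mask overlays.

A thin command-line wrapper is included (`inst/cli/murivess.R`) with
subcommands `phantom`, `preprocess`, `train`, `predict`, `segment`,
`baseline`, `evaluate` and `loocv` that compose through files on disk.

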