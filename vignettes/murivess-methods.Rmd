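---
title: "Methods: patch-based 3D U-Net vessel segmentation for murine μMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: patch-based 3D U-Net vessel segmentation for murine uMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(murivess)
```

This vignette is the package's account of its science: the model and its
assumptions, the parameters that matter, what the synthetic phantoms do and
do not emulate, and the design choices made where the published description
left the design open.

## The problem

Gadolinium-enhanced T1 μMRI of perfused mouse heads shows blood vessels as
dark tubular structures inside bright brain tissue. Three properties shape
every design decision here:

* **extreme class imbalance** — vessels occupy 0.03–0.14 % of the brain's
  voxels, so a classifier that answers "background" everywhere is 99.9 %
  accurate and useless;
* **tiny cohorts** — preclinical studies typically have fewer than ten
  annotated stacks, ruling out large architectures;
* **per-stack intensity drift** — stacks differ in brightness (one stack in
  a typical cohort can have a mean intensity three times the others') and
  carry a smooth brightness gradient, so absolute thresholds do not
  transfer between stacks.

## Pre-processing

The chain is fixed, in this order: ROI extraction → padding → Gaussian blur
→ min-max normalisation → patch separation.

* **ROI extraction** crops the bounding box of the brain mask and zeroes
  voxels inside the box but outside the mask, restricting everything
  downstream to the brain itself. Whether blurring should precede or follow
  this zeroing is genuinely open; we zero first and blur with *reflected*
  boundaries, which avoids smearing a dark halo into the brain edge.
* **Padding** extends each axis to the smallest multiple of the 32-voxel
  block that is ≥ the current length ("next bigger multiple" as a no-op when
  already divisible — strictly-bigger padding would add an empty 32-slab
  with no information). Padding is zero-valued and appended at high-index
  ends only, so the bounding-box offset remains the single inverse mapping.
* **Gaussian blur** uses σ = 0.5 voxels (default), sampled at integer
  offsets within 4σ and normalised to unit sum.
* **Normalisation** is per stack (min/max over the whole padded ROI), not
  per patch: per-patch normalisation would destroy intensity comparability
  between patches of the same stack. It maps every stack to [0, 1] and is
  what neutralises bright "runaway" stacks.
* **Patch separation** tiles the padded ROI into non-overlapping 32³ blocks
  in lexicographic (z, y, x) order. `reassemble(patchify(v))` is bit-exact;
  the geometry (crop offsets, pad amounts, original shape) is serialised to
  a JSON sidecar so results can be mapped back without the mask.

## The network

A shallow two-level 3D U-Net: encoder level (two 3×3×3 convolutions, stride
1, same padding, each followed by batch normalisation and ReLU), 2³
max-pool, bottleneck level (two such convolutions), upsampling back to full
resolution, concatenation with the encoder features, decoder level (two such
convolutions), and a 1³ convolution with sigmoid to one channel. Same
padding keeps output shape equal to input shape, which reassembly requires.

**Resolving the widths.** The published description fixes kernel, stride,
depth, normalisation, activations and the total of 831,105 trainable
parameters — but not the per-layer widths, the upsampling operator, or the
final kernel. `enumerate_configs_matching()` searches a documented space:
the strict channel-doubling family (F, F | 2F, 2F | F, F) and the
palindromic family (a, b | b, b | b, a), crossed with nearest vs transposed
upsampling, 1³ vs 3³ final kernel, and convolution bias on/off (bias-free
convolutions under batch norm are the standard convention, since the BN
shift makes a preceding bias redundant). Two findings fix the design:

* **no channel-doubling configuration matches the budget** for any width,
  so the often-assumed "channels double after pooling" reading is ruled out
  by the printed number itself;
* the palindromic configuration **(32, 80 | 80, 80 | 80, 32)** with
  parameter-free nearest upsampling ("up sampling" rather than a learned
  transposed convolution), a 1³ sigmoid head with bias, and bias-free
  hidden convolutions is the **unique** exact match: 831,105.

The phrase "resolution and depth … reduced to half" is read as the spatial
dimensions of the patches (depth = z), which is what pooling does; reading
it as channel depth contradicts the parameter budget. "Trainable
parameters" counts convolution weights/biases and batch-norm scale/shift,
excluding the running statistics (the convention of the major frameworks).

**Implementation.** No deep-learning framework dependency: the forward and
backward passes are authored here, with 3D convolution implemented as a sum
of per-kernel-offset GEMMs (contiguous z-column segment copies feed BLAS),
max-pool/upsampling as index maps, and batch normalisation with momentum
0.9 running statistics. The backward pass is verified against central
finite differences in the test suite at every layer type. Inference runs in
evaluation mode (running statistics), so it is deterministic.

## Training

Binary focal loss with γ = 2 and *no* class-balancing α weight (the
focusing exponent is the imbalance mechanism; empty-label patches stay in
training). Adam with learning rate 10⁻⁴, at most 100 epochs, early stopping
on the validation loss with patience 30 and min_delta 10⁻⁴, best-validation
weights restored. The 80/20 split is at patch level, pooled over the
training stacks; the 20 % partition is interpreted as the early-stopping
monitor (the alternative reading — a held-out patch test set — would leave
early stopping without a monitor, and per-stack evaluation happens on the
held-out stack anyway). Augmentation "enlarges" the training set: each
epoch adds `augment_copies` randomly augmented copies of every training
patch (flips along x, y or both applied identically to image and label; a
single scalar brightness shift σ = 0.1; voxelwise noise σ = 0.05; each
transform independently with probability 0.5, since no probabilities are
published). Batch size is never published; the default is 16 patches.

All randomness (weight init, split, augmentation, shuffling) derives from
explicit seeds, so training is bit-reproducible.

## Post-processing

Two binarization routes for the reassembled probability map:

* **threshold** — foreground iff p ≥ t. The test is inclusive so that
  region growing with s = t degenerates *exactly* to thresholding.
* **region growing** — seeds {p ≥ s} grown through neighbours with p ≥ t;
  equivalently, the union of connected components of {p ≥ t} containing a
  seed. Default connectivity is 6 (face neighbours — conservative for thin
  vessels); 26 is available. The result always satisfies
  {p ≥ s} ⊆ result ⊆ {p ≥ t}.

The published pseudocode applies post-processing inside the patch loop
while the accompanying figure applies it after reassembly; vessels cross
patch seams, so growth confined to a patch can lose continuity. Rather than
silently resolving this, both are provided (`scope = "full_volume"`,
default, and `scope = "per_patch"`); full-volume growth runs on the padded
ROI frame so its result is always a superset of the per-patch result.

## Vesselness baseline

Multiscale Hessian (Frangi) tube-likelihood on the identically
pre-processed volume (all steps except patch separation), with eigenvalues
|λ₁| ≤ |λ₂| ≤ |λ₃| and the ratios R_A = |λ₂|/|λ₃| (plate vs line),
R_B = |λ₁|/√|λ₂λ₃| (blob suppression) and S = √Σλᵢ² (structureness).
Vessels are dark here, so the sign condition is λ₂, λ₃ > 0 (dark ridges) —
the polarity is not published but follows from the data description. The
exact filter parameterisation is also unpublished; defaults are scales
{0.5, 1, 1.5, 2} voxels, α = β = 0.5, and c = half the maximum Frobenius
norm of the Hessian per scale, the filter's customary defaults. Second
derivatives are scale-normalised (γ = 2, i.e. multiplied by σ²). The
per-stack binarization threshold is a config value; the reference protocol
selects it manually within [0.02, 0.03], and no automatic selection is
implemented.

## Evaluation

Confusion counts are accumulated **inside the brain mask only** — the
pipeline never predicts outside the brain, and this convention is the one
under which the published accuracy values recompose exactly from the
row-normalised confusion entries and the foreground prevalence
(acc = TNR·prev(BG) + TPR·prev(FG)), which the acceptance checks verify.
Metrics with zero denominators are reported as 0. Cross-stack averages are
unweighted arithmetic means (not voxel-pooled). Leave-one-out
cross-validation trains from scratch per fold on the other stacks' patches;
stack provenance tags guarantee no patch of the held-out stack leaks into
training.

## The phantom generator

`generate_phantom()` defines the study conditions for all synthetic
experiments. It emulates: uint16 quantisation; a bright ellipsoidal brain
(default tissue mean 12,000 — the real stacks average roughly 9,000–15,000)
inside a dim frame; dark branching tubular vessels (default contrast 0.85,
i.e. vessel voxels at ~15 % of local tissue intensity — "nearly black");
vessel fractions in the per-mille range (default target 0.12 %, inside the
observed 0.036–0.134 % band, enforced within ±30 % by regenerating with
corrected centreline lengths); a smooth multiplicative brightness ramp in a
random direction (default amplitude 15 %); additive Gaussian noise (default
σ = 400); and empty first/last 3 % boundary slices. Vessel trees are
branching random walks with momentum; radii are drawn from 0.5–2.0 voxels
(the real radius distribution is unpublished; this range brackets
capillary-scale to arteriole-scale structures at the ~50 μm voxel size).

It deliberately does **not** emulate MRI physics: no partial-volume point
spread, no Rician noise (Gaussian suffices for pipeline testing and matches
the augmentation model), no anatomical tree topology (no Murray's law), no
skull/extracerebral tissue. Passing tests on phantoms therefore demonstrate
the *machinery* — geometry, losses, optimisation, post-processing, metrics
— under the data's statistical regime, not segmentation quality on real
μMRI; the sharp vessel boundaries and high contrast of phantoms make them
easier than real data.

## Scaled-down experiments and numerical choices

The full protocol (eight 400×400×320 stacks, ~1,700 patches each, 100
epochs, eight-fold cross-validation) is a multi-hour GPU workload; the
package's tests run a scaled replica: four 64³ phantoms (0.4 % vessel
fraction, radii 1.0–2.2, contrast 0.85, noise 250, gradient 0.10), a
narrow-width variant of the same topology (4, 8 | 8, 8 | 8, 4), batch size
1, three augmented copies per patch, 10 epochs, threshold t = 0.45, against
the Frangi baseline at t = 0.02. One condition is deliberately rescaled:
the learning rate. The published 10⁻⁴ belongs to a budget of ~10⁵ Adam
steps; at the replica's ~10³ steps, Adam's per-step movement (≈ lr per
parameter) cannot traverse the logits from initialisation to a decision
boundary, so the replica uses 3·10⁻³. The package default remains 10⁻⁴.
Under these fixed conditions the held-out Dice exceeds both the 0.5 floor
and the Frangi baseline, reproducing the qualitative ordering of the
full-scale comparison. Unit tests use 32³–48³ phantoms and 2–4-channel
widths for speed.

Other numerical choices: probabilities are clipped to [10⁻⁷, 1−10⁻⁷] inside
the focal loss; batch-norm ε = 10⁻⁵; convolution weights use He-normal
initialisation and biases start at zero; min-max normalisation of a
constant volume returns all zeros; metric ratios with empty denominators
return 0; the mask binarization contract maps any nonzero voxel to 1.

## Known limitations

* Training is CPU-bound R/BLAS code: fine for the scaled experiments and
  small cohorts at reduced width, but full-width training on eight real
  stacks would be slow; the architecture and training loop are faithful, so
  weights could equally be trained elsewhere and loaded via the JSON+RDS
  model serialisation.
* Batch-norm statistics come from momentum averaging over small batches;
  with batch size 1 this behaves like an instance-norm/batch-norm hybrid
  during training. Inference always uses the stored running statistics.
* The phantom's vessel radii and contrast are assumptions recorded in the
  config, not measurements of the real data.
* No overlapping-patch tiling with blending, no anisotropic voxels, no
  DICOM/Bruker raw input, no surface-distance or topology metrics — all out
  of scope.
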