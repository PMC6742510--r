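---
title: "Weakly-supervised deformable registration: model, losses and phantom experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weakly-supervised deformable registration: model, losses and phantom experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The registration problem this package addresses

Aligning a pre-procedural MR volume to an intra-procedural 3D ultrasound
volume of the same organ is a multimodal registration problem for which no
reliable intensity-similarity measure exists: the two modalities produce
correlated-looking structures that are anatomically different, so
mutual-information-style metrics converge to false alignments.  `weakreg`
implements the weakly-supervised alternative: a convolutional network is
trained to predict a dense displacement field (DDF) `u` on the fixed-image
grid from the *unlabelled* image pair alone, while the training signal comes
entirely from corresponding anatomical label masks (gland segmentations,
apex/base regions, zonal boundaries, urethra, patient-specific cysts and
calcifications) that exist only in the training set.  At inference the
network needs nothing but the two intensity volumes and runs in a single
forward pass.

## Training utility and two-stage sampling

With `N` image pairs and `M_n` label pairs on pair `n`, the training
objective is the expected label similarity

    J = (1/N) sum_n (1/M_n) sum_m S( l_B(m,n), warp(l_A(m,n), u_n) )

maximised over network parameters, regularised as `-J + alpha * Omega(u)`
where `Omega` is the bending energy (or, optionally, the mean squared L2
norm of the displacement gradients).  The number of labels varies per pair,
so minibatches are built by two-stage sampling: draw `K` image pairs
uniformly (with replacement), then exactly one label pair uniformly within
each.  Every (n, m) pair is then visited with probability `1/(N*M_n)` —
precisely its weight in `J` — which makes the minibatch gradient an
unbiased estimator of the full gradient while keeping the per-step memory
footprint independent of `M_n`.  `tests/testthat/test-training.R` checks
this empirically against a closed-form toy objective.

Sampling with replacement in stage 1 is a deliberate choice: it makes the
unbiasedness argument exact and the sampler stateless.

## Multiscale label similarity

Raw overlap measures saturate: once two structures stop overlapping, Dice is
0 regardless of how far apart they are, so no gradient points the right
way.  The package therefore filters both label fields with isotropic
Gaussians at a ladder of scales (`multiscale_config`; 0, 1, 2, 4, 8, 16,
32 mm at full scale, truncated to 0–8 mm on 16^3 desk grids) and averages
the soft Dice

    S_Dice(a, b) = 2 sum(a_i b_i) / (sum(a_i) + sum(b_i))

over the ladder with equal weights `1/Z`.  Scale 0 is the unfiltered label
(a Dirac-delta filter).  Two conventions needed fixing where the formula is
silent:

* empty-vs-empty soft Dice is defined as 1 (perfect agreement of empty
  labels; the formula itself is 0/0);
* kernels are truncated at 3 SDs and renormalised to unit sum, with zero
  padding at the borders (mass loss below 0.3% away from faces).

The multiscale cross-entropy variant scores
`mean( a log b' + (1-a) log(1-b') )` per scale with the warped label
clipped to `[1e-6, 1-1e-6]` for numerical stability; it is implemented as a
similarity (negative cross-entropy, higher is better) so the two measures
plug into the same `-J + alpha*Omega` objective.  Sums versus means over
voxels/scales are not pinned down by the formulas; means are used so
`alpha` keeps a comparable meaning across grid sizes.

In the pre-filtered mode (`prefiltered = TRUE`) the labels are filtered
once up front and each filtered moving label is warped per scale, with the
plain soft Dice evaluated per scale afterwards.  Without a warp in between
the two orders agree to machine precision (asserted in the tests); with a
warp they differ by the commutation error of filtering and resampling,
which is small for smooth fields but not zero — this is exactly the
trade-off the pre-filtered training variant accepts in exchange for speed.

## Regularisation and deformation diagnostics

The bending energy is the mean over voxels of the summed squared second
derivatives of each displacement component, including the doubled mixed
terms — the standard thin-plate form.  Derivatives are taken with
matrix-stencil finite differences in world mm: central differences in the
interior, one-sided at boundaries, with the boundary rows chosen so that
*any* affine field has exactly zero bending energy and a spatially constant
Jacobian — properties the tests assert at 1e-8/1e-6.  The same operators
feed the diagnostics (`jacobian_determinant`, `ddf_statistics`): per-voxel
`det(I + du/dp)`, displacement magnitudes, gradient L2 norms, and the
count/fraction of non-positive Jacobian determinants (folding).

## Network family

All networks consume the moving and fixed volumes as two channels of one
input tensor (the figures of the source architecture show both images
entering one network without specifying the fusion; channel concatenation
is the simplest consistent reading).

The baseline is a 3D encoder–decoder with `levels = 4` stages, initial
channel count `n0` doubling per stage, 7^3 kernels in the very first
convolution and 3^3 elsewhere, and three kinds of summation shortcuts:
per-level summation skips across the network, two-convolution residual
blocks, and trilinear additive upsampling summed over each transpose
convolution.  Each block holds exactly two convolution+BN+relu layers with
a residual sum over the pair; since the first convolution of a block
changes the channel count, the identity shortcut runs from the output of
the first convolution layer to the output of the second (`h1 +
BN(conv2(h1))`), giving the expected eight residual pairs overall.  Every
decoder level (plus the bottleneck) feeds a displacement head — one 3^3
convolution to 3 channels with bias, no BN, no nonlinearity — whose output
is trilinearly upsampled to the input resolution; the DDF is the sum of the
summands `delta_0..delta_4`.  Variants: `delta0_only` keeps only the
finest head, `delta1_4` drops it, `no_additive_upsampling` removes the
third shortcut type.

Heads are zero-initialised by default, so *every* untrained variant maps
any input pair to the exactly-zero DDF: training starts from the identity
alignment, where the warped labels produce meaningful first gradients.
All other parameters use Xavier initialisation.  Batch norm uses
per-minibatch statistics during training and running averages (momentum
0.9) at inference.

The affine `Global-Net` reuses the four encoder blocks, applies global
average pooling and a 12-output linear head (zero-initialised, so the
initial prediction is the identity transform) parameterised as raw numbers
added to the identity, taken about the grid centre for conditioning.  The
`Composite-Net` warps the moving image by the global DDF, feeds the result
to a baseline ("local") network and composes the two fields with
`compose_ddf`; both sub-networks train jointly, with gradients flowing
through the resampling operations (the trilinear sampler exposes exact
gradients with respect to both its field and its sample positions).

Because no deep-learning framework is available in this package's target
stack, the layer zoo (3D convolution via im2col+GEMM, transpose
convolution as zero-stuffing + convolution, max-pooling, batch norm,
trilinear upsampling, the differentiable trilinear resampler) is
implemented in R/Rcpp with hand-written analytic backward passes.  Every
backward pass is finite-difference-checked in the test suite at 1e-3
relative tolerance, on 8^3 inputs.

## What the phantom generator emulates — and what it does not

`phantom_spec()` / `generate_cases()` build fully synthetic two-modality
cases: an ellipsoidal gland (semi-axes 5–6.5 mm) with an inner-zone
sub-ellipsoid, a curved tube through the gland, and 2–6 spherical
landmarks (radius 2–2.6 mm) per case — emulating the variable-count,
variable-type label sets of real annotation campaigns.  A known smooth
deformation (random affine within ±6° rotation, 0.96–1.04 scale, ±1.5 mm
translation, plus a Gaussian-smoothed random field of 1.5 mm peak
amplitude and 4 mm smoothing SD) is drawn per case and *verified* to have
strictly positive Jacobian determinants (redrawn otherwise).  The moving
frame is produced by evaluating the analytic shapes at inverse-mapped
coordinates (fixed-point inversion to 0.05 voxel), so the stored
ground-truth DDF is exactly the field a backward-warping predictor should
recover.  The two renderings use non-monotonically related intensity maps
(rank correlation below 0.9 by construction), multiplicative speckle on
the "US-like" fixed image — including a spurious bright interface at the
inner-zone boundary, the kind of structure that defeats intensity
matching — and additive noise on the "MR-like" moving image.

Not emulated: ultrasound physics (real speckle statistics, shadowing),
MR bias fields, annotation noise in the labels, and anatomy whose
deformation departs from the smooth invertible family.  Passing the
phantom experiments therefore demonstrates that the estimator and its
training machinery recover known smooth deformations from label
supervision alone — not that clinical-grade accuracy transfers to real
MR/TRUS data.

One discretisation limit is worth stating: at the desk resolution (16^3
voxels, 1 mm) the binarised trilinear warp of the smallest structures
(2–3 mm radius) cannot exceed a Dice of roughly 0.85 against their exact
rasterisation, whatever the deformation — a surface-to-volume artefact of
re-binarisation, measured directly in the test suite by sweeping sphere
radii.  The generator's structures are sized so the gland and inner zone
recover above 0.9 under the ground-truth warp while all labels keep
sub-voxel centroid error, which is the quantity the TRE actually uses.

## Desk-scale experimental protocol

The package's standard experiment (`desk_train_config()`, also what
`scripts/acceptance.R` runs) uses 16 training and 8 test cases on 16^3
grids at 1 mm, network width `n0 = 4`, sigma ladder 0–8 mm, minibatch
K = 4, alpha = 0.5, per-side random-affine augmentation (±5°, 0.97–1.03
scale, ±1 mm), and Adam.  The full-scale defaults (`train_config()`)
keep the source protocol: K = 4, lr = 1e-5, alpha = 0.5, n0 = 32, no
weight decay.  For the desk-scale network the learning rate is Adam's
conventional 1e-3 — the 1e-5 rate belongs to the full-size configuration
and barely moves the tiny network within a desk-scale budget — with a
tenfold reduction (1e-4) for the affine Global-Net and the Composite-Net,
mirroring the divergence-avoiding reduction the affine head needs at full
scale.  The headline run trains 2000 steps; the variant comparisons
(Global-Net ordering, low-alpha smoothness contrast, pre-filtered
equivalence) use shorter runs of 300–400 steps of the same pipeline, which
is where their qualitative orderings already stabilise.  These sizes are
the package's chosen desk protocol; they complete a full
simulate–train–evaluate cycle in minutes on one CPU core.

Evaluation follows the split-metric convention: TRE is the per-case RMS of
centroid distances between warped moving landmarks and their fixed
counterparts (landmarks only — the gland is scored separately, and a flag
exposes the alternative), with intensity-weighted centroids so small
landmarks do not jitter under re-binarisation; DSC is the binary overlap
of the warped (re-binarised at 0.5) and fixed gland.  Run summaries report
the median and the 10th/25th/75th/90th percentiles, computed with linear
interpolation between closest ranks (R's type-7 quantile; percentile
values at this sample size depend on the rule, so it is pinned here and
cross-checked in the tests).

```{r}
library(weakreg)
train_cases <- generate_cases(phantom_spec(), n_cases = 16, seed = 101)
test_cases <- generate_cases(phantom_spec(), n_cases = 8, seed = 202)
fit <- train_network(train_cases, desk_train_config(max_iters = 2000))
before <- evaluate_run(test_cases, net = NULL)   # zero-DDF reference
after <- evaluate_run(test_cases, fit$net)
print(before); print(after)
```

## Numerical conventions, degenerate inputs, known limitations

* Displacements are stored in mm with backward (pull-back) semantics:
  the warped value at fixed voxel `p` samples the moving volume at
  `p + u(p)`.  The loss warps the *moving* label onto the fixed grid, so
  backward warping makes that a single resampling.
* Sampling outside a volume's extent returns 0 (absent anatomy), for
  images, labels and inner fields of `compose_ddf` alike.
* Labels are binary on disk (scaled encodings like 0/255 are rescaled and
  thresholded at 0.5 on load); fractional values appear only after
  interpolation and are re-binarised for storage and binary DSC, while the
  loss path keeps them.
* `normalize_intensities` uses the population SD and rejects constant
  volumes; normalisation is idempotent to 1e-6.
* Constant volumes resample to constants; resampling a volume to its own
  spacing is the identity; label centroids stay within a voxel diagonal of
  their world position under resampling.
* Grids must be divisible by `2^levels`; violations are reported as shape
  errors before any work is done.
* Ties in max-pooling are broken toward the first corner in column-major
  order (only relevant for exactly-equal activations).
* The DDF family is unconstrained: topology preservation is encouraged by
  the bending energy but not enforced, and at small `alpha` folding does
  occur — the diagnostics quantify it, and the acceptance experiments use
  exactly that contrast.
* Training runs single-threaded; the layer implementations favour clarity
  and checkability over peak throughput, which bounds practical problem
  sizes to the tens-of-voxels-per-axis regime the phantom experiments use.
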