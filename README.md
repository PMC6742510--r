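# weakreg

Weakly-supervised deformable registration of multimodal 3D volumes, for
image-analysis researchers who need to align image pairs (the motivating
case: pre-procedural MR to intra-procedural transrectal ultrasound of the
prostate) where no trustworthy intensity-similarity measure exists.

## The idea

A convolutional network predicts a dense displacement field (DDF) `u` on
the fixed-image grid directly from the unlabelled image pair.  The training
signal never touches intensities: with `N` training pairs carrying `M_n`
corresponding anatomical label pairs each (gland, zonal boundaries,
urethra, patient-specific landmarks — any mix, any count), the network
maximises the expected label similarity

    J = (1/N) Σ_n (1/M_n) Σ_m S( l_B(m,n), warp(l_A(m,n), u_n) )

regularised by bending energy: `θ̂ = argmin_θ [ -J + α·Ω(u) ]`.  The
similarity `S` is a multiscale soft Dice — the soft Dice
`2Σab/(Σa+Σb)` averaged over Gaussian-filtered versions of both labels at
scales σ ∈ {0, 1, 2, 4, 8, 16, 32} mm — which keeps gradients informative
when structures do not yet overlap.  Minibatches use two-stage sampling (K
image pairs uniformly, then one label pair per image pair), which visits
each pair with probability `1/(N·M_n)` and therefore yields unbiased
gradients of `J` at constant memory in the label count.  At inference the
trained network registers a pair in a single forward pass with no labels
and no initialisation.

The package implements the full framework in R: NIfTI volume/DDF I/O and
preprocessing, differentiable warping and affine/DDF composition, the
multiscale Dice / cross-entropy losses and bending-energy / gradient-L2
regularisers, the baseline encoder–decoder with per-level displacement
summands δ₀–δ₄ plus its ablations and the affine Global-Net /
Composite-Net, the training loop (Adam, per-side random-affine
augmentation), landmark-centroid TRE and gland-DSC evaluation with DDF
diagnostics (Jacobian determinants, folding counts), and a synthetic
two-modality phantom generator with known ground-truth deformations so the
whole pipeline is testable at desk scale.  The conv-net core (3D
convolutions, transpose convolutions, batch norm, trilinear
upsampling/resampling) is hand-implemented in R/Rcpp with analytic,
finite-difference-verified backprop.

## Worked example

Generate phantoms, train the desk-scale baseline, evaluate on held-out
cases:

```r
library(weakreg)
train_cases <- generate_cases(phantom_spec(), n_cases = 16, seed = 101)
test_cases  <- generate_cases(phantom_spec(), n_cases = 8,  seed = 202)

fit <- train_network(train_cases, desk_train_config(max_iters = 2000, seed = 1))

evaluate_run(test_cases, net = NULL)   # initial (zero-DDF) alignment
evaluate_run(test_cases, fit$net)      # after registration
```

On one CPU core this takes about ten minutes and prints:

```
<weakreg_evalreport: 8 case(s)>
  TRE mm  median 1.59, percentiles [1.09, 1.21, 2.05, 2.21]
  DSC     median 0.798, percentiles [0.730, 0.752, 0.840, 0.850]
  folding voxels: 0 (fraction 0)
<weakreg_evalreport: 8 case(s)>
  TRE mm  median 0.63, percentiles [0.48, 0.53, 0.83, 0.87]
  DSC     median 0.893, percentiles [0.876, 0.888, 0.909, 0.922]
  folding voxels: 0 (fraction 0)
```

i.e. the trained network recovers the known synthetic deformations well
enough to cut the median landmark TRE by more than half (1.59 mm to
0.63 mm) while raising the median gland Dice from 0.80 to 0.89, with zero
folding voxels thanks to the bending-energy weight α = 0.5.  Warping by
the stored ground-truth DDF bounds what is achievable: TRE ≈ 0.16 mm, the
interpolation floor.

The same workflow is scriptable from a shell via `inst/cli/weakreg.R`
(subcommands `simulate`, `train`, `register`, `evaluate`), each run writing
its fully resolved config next to its outputs.

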