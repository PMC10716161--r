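---
title: "Group-wise LSFP reconstruction for real-time interventional MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group-wise LSFP reconstruction for real-time interventional MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Monitoring a needle or electrode as it advances through brain tissue
requires images every few tens of milliseconds. No acquisition samples
k-space fully at that rate, so the reconstruction must recover each
frame from a handful of radial spokes - an acceleration factor of 10 to
40 relative to the Nyquist spoke count `round(N * pi / 2)`. What makes
the problem tractable is its structure: the anatomy barely changes from
frame to frame, while the interventional feature is small, localized
and advances steadily.

`imri` implements this program end to end: golden-angle radial
trajectories with a group-periodic schedule, the multi-coil non-uniform
Fourier encoding operator, the LSFP variational model and its
primal-dual fixed-point (PDFP) solver, an unrolled-network variant with
learned sparsifying transforms, a synthetic intervention simulator, and
evaluation utilities (PSNR, SSIM, tip-depth tracking).

## The LSFP model

A group of `fpg` consecutive frames `x` is reconstructed jointly from
its spokes by decomposing `x = L + S` and solving

```
min_{L,S}  1/2 ||E(L + S) - d||^2 + lambda_L ||L||_*
           + lambda_s ||Dt S||_1
           + lambda_L^psi ||psi L||_1 + lambda_S^psi ||psi S||_1
```

where `E = Omega F C` is the encoding operator (coil maps `C`,
non-uniform Fourier transform `F`, radial sampling `Omega`), `||.||_*`
is the nuclear norm of the Casorati reshaping of `L` (pixels x frames),
`Dt` the forward temporal difference, and `psi` a framelet transform
applied to both components - the distinguishing feature of LSFP
relative to the classical L + S model is that *both* the slowly varying
background and the sparse dynamic component carry a spatial sparsity
penalty.

The decomposition plays two roles. `L` captures the quasi-static
anatomy: over 5 frames its Casorati matrix is near rank one. `S`
captures what moves - the advancing needle - which is sparse both
spatially and in its temporal differences.

### Group-wise acquisition

A frame uses `spf` spokes and a group holds `fpg` frames
(`p = spf * fpg` spokes per group, `p = m x n` in the acquisition
notation). The golden-angle increment `90 * (sqrt(5) - 1) = 111.2461`
degrees makes any contiguous subset of spokes near-uniform in angle;
repeating the trajectory with a period of one group means the gridding
plans and the trained network are reusable for every group. The helper
arithmetic (`full_spoke_count()`, `acceleration_factor()`,
`frame_duration_ms()`, `group_duration_and_total()`) reproduces the
protocol numbers: 201 spokes for full sampling at 128, R = 20 at 10
spokes/frame, 80 ms/frame and 400 ms/group at TR = 4 ms with 20
spokes/frame, 732.8 ms/volume for 8-partition stack-of-stars at
TR = 4.58 ms.

## The PDFP solver

With `z = (L, S)`, smooth term `f(z) = 1/2 ||E(L+S) - d||^2`, partial
prox `h(z) = lambda_L ||L||_*` and dual term
`g(Bz) = lambda_L^psi ||psi L||_1 + lambda_S^psi ||psi S||_1 + lambda_s ||Dt S||_1`,
one iteration is

```
zbar    = z_k - gamma (E^H r, E^H r),   r = E(L_k + S_k) - d
y       = prox_{gamma h}(zbar - lam B^H v_k)
v_{k+1} = (I - prox_{(gamma/lam) g})(B y + v_k)
z_{k+1} = prox_{gamma h}(zbar - lam B^H v_{k+1})
```

`prox_{gamma h}` is singular-value thresholding on the Casorati matrix
of `L` (an economy decomposition: with `fpg <= 10` the SVD cost is a
`fpg x fpg` eigenproblem); the dual prox is blockwise complex soft
thresholding. Each of the three regularizers keeps its own dual block.

Step sizes are auto-set from power iterations: the joint gradient has
Lipschitz constant `2 ||E||^2`, so `gamma = 0.9 / (2 ||E||^2)`, and
`lam = 1 / ||B||^2` with
`||B||^2 = 1 + 4 sin^2(pi (fpg - 1) / (2 fpg))` (Parseval framelet plus
the temporal-difference path Laplacian). These conservative choices
give a monotone objective in practice, which the test suite asserts on
random instances.

### Defaults and scaling

The regularization weights default to `lambda_L = 0.01` and
`lambda_s = lambda_L^psi = lambda_S^psi = 0.005`, each multiplied by
`max |E^H d|` at run time. Data-scaling makes the behavior independent
of image intensity and resolution, which matters because weights are
otherwise tuned per dataset. Iterations cap at 60 with a relative
iterate-change tolerance of `1e-5`.

### The framelet

The built-in `psi` is a single-level undecimated Haar frame: 1D filters
`(1/2, 1/2)` and `(1/2, -1/2)` with periodic boundary, giving four 2D
subbands with `|h^|^2 + |g^|^2 = 1`. The frame is Parseval-tight, so
synthesis is the plain adjoint and `synthesis(analysis(x)) = x` to
machine precision - invariants the tests assert exactly rather than
approximately. The transform is pluggable; Haar was chosen because the
tight-frame property is exact in floating point, keeping the solver's
verification contract crisp.

### Temporal boundary

`Dt` uses forward differences with a zero boundary and no circular
wrap: an intervention is not periodic, and the symmetric handling makes
time-reversal equivariance exact (asserted in the tests with fixed step
sizes, since the auto-set steps see permuted operators and differ at
the fourth decimal).

### The classical baseline and a non-identifiability caveat

`ls_baseline_reconstruct()` implements the classical L + S alternation:
a shared data-consistency gradient step, then SVT claims the low-rank
part from `M - S` and the temporal-TV prox keeps the remainder (the TV
prox solved by a short projected dual ascent). This is a genuinely
different splitting from PDFP, which the cross-checks exploit.

One caveat discovered while verifying the two routes against each
other: with the framelet weights set to zero, the model cannot identify
the L/S split. A time-constant component of `S` is invisible to
`||Dt S||_1`, so moving static content between `L` and `S` changes the
nuclear term but nothing stops `S` from hoarding it - the objective has
a long, nearly flat valley, PDFP drains `L` only by `gamma * lambda_L`
per iteration, and the Gauss-Seidel baseline parks at a different point
of the valley than PDFP does at any practical iteration count. The two
solvers therefore agree (to a few percent) on the reconstruction
`x = L + S`, which is what the data identify, but not on the split; the
cross-check tests compare reconstructions, not objective values. With
the framelet terms active - the full LSFP model - both components are
penalized and the split is identified; this is a concrete reason the
framelet terms are not cosmetic.

## The unrolled network

`build_net()` unrolls `n_blocks` PDFP iterations. Per block, the four
transform roles (`psi_L`, `psi_L^T`, `psi_S`, `psi_S^T`) become four
independent stacks of `n_conv_layers` 3D convolutions (3 x 3 x 3
kernels over y, x and frame; ReLU between layers; complex images split
into two real channels at transform entry and recombined at exit). The
first analysis layer takes 2 channels and the last synthesis layer
emits 2; hidden layers carry `n_features` (default 32, matching the
full-scale architecture; the desk-scale experiments below use fewer).
The SVT prox is kept exact with a learnable threshold, and the step
sizes and all soft-threshold levels are per-block learnable scalars
initialized from the solver's auto-set defaults. Setting
`transforms = "haar"` freezes the transforms to the framelet frame,
which makes the net mathematically identical to the classical solver -
the equivalence harness the tests rely on.

Because no automatic-differentiation framework is involved, the
backward pass is hand-derived: conv layers via im2col/col2im (the
gradient with respect to the input is correlation with the flipped
kernel, exact for zero padding; the inner kernels are compiled C++),
the complex soft threshold via its Wirtinger Jacobian
`g_in = (1 - tau/(2|z|)) g + (tau u^2/(2|z|)) conj(g)` on the active
set, and SVT through the Hermitian matrix-function identity
`SVT(M) = M h(M^H M)`, `h(x) = max(1 - tau/sqrt(x), 0)`, whose
vector-Jacobian product needs only the Daleckii-Krein divided
differences of an `fpg x fpg` eigendecomposition. A finite-difference
check over randomly sampled parameters (at a jittered point, away from
the ReLU kink that the zero-bias initialization sits on exactly) pins
the implementation to 1e-3 relative.

Training is Adam (`beta1 = 0.9`, `beta2 = 0.999`, `epsilon = 1e-8`,
batch size 1) on complex mean squared error against the simulated
ground truth; the loss function of the original full-scale training is
not documented anywhere we could rely on, so MSE - the standard choice
for unrolled reconstruction - is the default and is recorded as a gap.
The default learning rate is 1e-4; the desk-scale experiments in the
test suite use 3e-3, appropriate for their much smaller parameter
counts and few hundred update steps.

## The synthetic intervention generator

`make_background()` builds a deterministic nested-ellipse head phantom
(skull rim, two hemispheres, ventricle-like hypointense regions) plus
smooth seeded texture, in [0, 1]. It stands in for volunteer brain
images, which are external data; `background = "user-image"` ingests a
real slice when one is available. `simulate_intervention()` advances a
flat-capped needle mask of configurable width along the entry-target
segment at constant speed, multiplying covered pixels by
`needle_contrast` (default 0.1: a ceramic needle appears as a signal
void; the DBS variant uses a hyperintense tip instead). Four setups -
two unilateral, two bilateral with mirrored second needles - mirror the
simulated study design, with 200 frames per sequence at full scale. The
programmed depth at frame `i` is exactly `min(i * speed, full length)`,
which is what makes parameter-recovery tests possible downstream: at
the phantom-experiment speed of 1.525 mm per frame, frame 40 sits at
61 mm.

`acquire()` applies the forward operator with simulated ring-of-
Gaussians coil maps (normalized so the sum of squared magnitudes is 1;
a single coil degenerates to the uniform unit map so conjugate-symmetry
checks of real phantoms are exact) and optional circular complex
Gaussian noise, defaulting to noiseless as in the simulated study.

What the generator does *not* emulate: MR signal physics (relaxation
contrast, flip angles), susceptibility artifacts near the needle,
tissue deformation, coil geometry of any particular array, and phase
structure of real anatomy (truth phase defaults to zero). Passing tests
therefore demonstrate the pipeline's correctness and the method's
behavior under controlled conditions, not clinical image quality.

## Numerical choices

- k-space coordinates in cycles/pixel in `[-0.5, 0.5)`, DC at the
  matrix center, orthonormal FFT scaling: Parseval checks are exact.
- Gridding NUFFT: oversampling 2, Kaiser-Bessel width 6 (the standard
  accuracy/speed point), analytic deapodization; agreement with the
  brute-force non-uniform DFT is ~1e-5 on random images, and the
  adjoint is the exact conjugate transpose of the implemented forward
  map, so dot-product tests pass at machine precision independent of
  gridding accuracy.
- The objective's data term always uses the plain adjoint. The
  density-compensated adjoint (per-spoke angular Voronoi gaps times a
  radial ramp, with the DC cell given its area-equivalent radius
  `Delta k / 4`) is an initialization and display aid only. One-shot
  ramp regridding leaves a few dB of low-frequency shading - the known
  limitation that iterative density-compensation schemes address - and
  that is acceptable for its role here.
- Degenerate cases: `fpg = 1` yields an empty temporal-difference
  array and skips the TV term; a zero needle depth yields an empty
  mask (flat caps, so no entry-disk artifact); identical images report
  the documented 99 dB PSNR cap.
- Divided-difference guards in the SVT backward switch to the
  derivative when eigenvalues are within `1e-9` of each other.

## Desk-scale problem sizes

The test suite runs the full pipeline at reduced scale, chosen so the
suite exercises every claim in minutes: operator tests at 16-128
matrix sizes; solver descent on 16 x 16 x 3 instances; the depth-
tracking experiment at the full 128 x 128 with 1 x 1 mm pixels, 20
spokes/frame, 5 frames/group, 8 coils and 40 frames; network training
at 32 x 32 with 2 coils, 3-frame groups, 6 spokes/frame, 2 hidden
features and 2 blocks, 16 training samples, 50 epochs at Adam
learning rate 3e-3; and the block-count sweep at 32 x 32 over 1-3
blocks with 6 training samples and 10 epochs. The architecture defaults
(`n_features = 32`, `n_blocks = 3`, `n_conv_layers = 3`) match the
full-scale design; the desk-scale experiments deliberately shrink
everything else and state so here rather than pretending to full-scale
results.

## Known limitations

- Coil maps are assumed known (ground truth in simulation); no
  ESPIRiT-style calibration.
- No gradient-delay or off-resonance correction; trajectories are
  ideal.
- Spoke sharing across neighboring groups (a sliding-window variant)
  is exposed by reconstructing overlapping groups explicitly, but the
  default grouping is disjoint; the exact sharing window of the
  original acquisition scheme is not documented.
- The unrolled net trains on one fixed trajectory/coil configuration
  per build; generalizing across configurations would need retraining.
- PDFP convergence along the L/S-exchange direction is slow when the
  framelet weights are zero (see the non-identifiability caveat).
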