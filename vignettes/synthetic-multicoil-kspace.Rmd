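---
title: "Synthesizing complex-valued multicoil k-space from magnitude images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthesizing complex-valued multicoil k-space from magnitude images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synthmri)
```

## The problem

Clinical MRI archives keep coil-combined magnitude images; the image
phase and the per-coil raw k-space needed to develop physics-based
reconstruction methods are discarded at the scanner. `synthmri`
implements a pipeline that turns a magnitude-only image back into
plausible complex-valued multicoil k-space: a conditional GAN translates
magnitude into a synthetic phase map, ESPIRiT supplies coil sensitivity
profiles from raw calibration data, and the exact Cartesian signal model
assembles the three into per-coil spectra. The product is evaluated the
way it is meant to be used — as training data for an unrolled
variational-network reconstruction model — by comparing networks trained
on k-space carrying different phase models (ground truth, GAN, sinusoidal,
random, zero) on one shared ground-truth test set.

## Signal model

A 2D slice is the complex image $m(x,y) = |m|\,e^{j\angle m}$, acquired
through $C$ receiver coils with smooth complex sensitivities $S_c(x,y)$.
The acquired spectrum of coil $c$ is $M_c = F\,(S_c\, m)$ with $F$ the
2D Fourier transform, and accelerated scans sample $M_c$ on a column
mask. Package conventions, fixed once and used everywhere:

* `image_to_kspace()` / `kspace_to_image()` are **centered, unitary**
  DFTs: the DC sample sits at matrix index `floor(N/2)+1` and Parseval
  holds exactly. The continuous transform fixes neither choice; this is
  the common Cartesian-MRI discretization, and unitarity makes the
  forward and adjoint SENSE operators `sense_forward()` /
  `sense_adjoint()` exact adjoints, which the tests verify to 1e-10.
* Arrays are indexed (row, column) with the coil axis last: `(H, W, C)`.
* `make_equispaced_mask(width, R, cf)` keeps a contiguous block of
  `round(width*cf)` central columns and a *total* of `round(width/R)`
  columns, the remainder on a constant stride through the non-center
  columns. The total-budget rule makes the effective acceleration
  exactly `width / round(width/R)`; how the fully sampled center
  interacts with the budget is a convention, and this one keeps R exact
  up to rounding. The mask is one-dimensional over columns (the
  phase-encode axis), replicated over rows and coils, with a fixed
  offset 0 by default.

## Phantoms: the study conditions

No external data ships with the package; every experiment runs on
seeded brain-like phantoms (`phantom_spec()`, `generate_dataset()`)
whose three components emulate the qualitative features of raw brain
acquisitions:

* **Magnitude** — an elliptical "skull" support holding nested
  elliptical tissue regions with distinct intensities in (0, 1], plus a
  mild (8%) low-frequency modulation so tissue is not piecewise
  constant.
* **Phase** — a random order-2 polynomial background (low spatial
  frequency), a constant offset per tissue region drawn uniformly from
  [-1, 1] rad (tissue phase contrast), and noise confined to the
  zero-magnitude background, Gaussian with sigma = 0.5 rad by default
  (a `"uniform"` mode draws from $[-\pi,\pi)$ instead). Real phase
  statistics are described only qualitatively in the literature this
  emulates — low-frequency structure, tissue contrast, noisy
  background — so these parameters are conventions, not fits, and they
  are frozen as the package's study conditions rather than tuned per
  experiment.
* **Coil maps** — Gaussian magnitude bumps centered on a circle of
  radius `0.6 * min(H, W)` around the image with width `0.5 * min(H,W)`
  and smooth linear phase ramps, RSS-normalized pixelwise so that
  root-sum-of-squares coil combination reproduces the magnitude
  exactly.

Each k-space is *constructed* by the forward model, never fit, so the
self-consistency identity (inverse FFT + RSS equals the magnitude) is
exact and the tests assert it below 1e-6. What the phantoms do **not**
emulate: anatomy, B0 susceptibility fields, acquisition noise in
k-space, T2 decay, partial-volume texture. Passing tests therefore
demonstrate that the pipeline's operators, estimators and training loops
behave correctly and that the comparison machinery can resolve
phase-model differences — not that the GAN meets radiological realism
on clinical data.

## ESPIRiT

`estimate_maps()` is the eigen-analysis estimator: all
`kernel_size`-square patches of the central calibration block form a
block-Hankel matrix; right-singular vectors above `sv_threshold` times
the leading singular value span the local signal subspace; transformed
to image space they define, per pixel, a small operator whose leading
eigenvector is the sensitivity vector and whose leading eigenvalue is
close to 1 inside the coil support. Defaults (kernel 6, calibration 24,
singular-value threshold 0.02, eigenvalue support threshold 0.95, one
map per pixel) follow common practice for the reference eigenvalue
formulation. The eigendecomposition is computed directly per pixel —
exact and simple at 2D desk scale — rather than by iterative power
methods. Maps are zeroed outside the eigenvalue support (giving a clean
RSS identity for testing), unit-norm across coils inside it, and
phase-normalized so the first coil's map is real and non-negative; the
per-pixel global phase is unobservable, so tests compare maps after a
per-pixel phase alignment.

## The conditional GAN

The generator (`build_generator()`) is a U-Net with
`generator_depth = 8` stride-2 4x4 encoder convolutions and 8 mirrored
transposed convolutions with skip connections — 16 convolutional layers
— taking the magnitude normalized to [-1, 1] by its per-image maximum
and emitting one phase channel through `pi * tanh`, so outputs live in
$(-\pi,\pi)$. The latent code $z$ is realized as dropout (rate 0.5) in
the three innermost decoder stages, active at training *and* inference;
no explicit noise channel is used. The discriminator
(`build_discriminator()`) is a patch classifier over the
channel-concatenated (magnitude, phase) pair: three stride-2 and two
stride-1 4x4 convolutions, giving each element of its N x N logit map a
receptive field of exactly 70x70 input pixels —
`discriminator_receptive_field()` measures this by gradient probing
rather than trusting the arithmetic. For training images smaller than
70 pixels the `d_layers` option shrinks the patch size; the
(`d_layers = 3`) default is the 70x70 configuration.

Training (`train_phase_gan()`) alternates one discriminator and one
generator Adam step per image (batch size 1, learning rate 2e-4,
momentum 0.5/0.999, 50 epochs by default) on the hybrid objective: the
conditional adversarial value plus `lambda_l1 = 100` times the mean
absolute phase error. Choices the underlying description leaves open,
resolved here:

* `lambda_l1 = 100` — the customary weight for this architecture family;
  surfaced in `gan_config()`.
* Non-saturating generator loss (ascend `log D(x, G)`) instead of
  descending `log(1 - D)` — standard stabilization with the same
  optimum.
* "16 layers" counted as convolutional layers (8 down + 8 up).
* No normalization layers: at batch size 1 and desk scale they add
  state without measurable benefit, and omitting them keeps training
  bit-reproducible from the seed alone.
* Early stopping is replaced by a fixed step budget plus a
  best-validation-l1 checkpoint, since a qualitative stopping rule is
  not mechanizable.

## The variational network

`varnet_forward()` unrolls `n_cascades` iterations of

$$k^{(t+1)} = k^{(t)} - \eta_t\, M (k^{(t)} - k^{(0)})
  + F S\, \mathrm{CNN}_t(S^H F^{-1} k^{(t)}),$$

with learned per-cascade data-consistency weights $\eta_t$ (initialized
at 1) and a learned refinement CNN per cascade applied to the
real/imaginary channels of the SENSE-combined image; the output is the
modulus of the final SENSE combine, and `n_cascades = 0` yields the
zero-filled reconstruction. Sensitivity maps are fixed inputs, not
learned. The refinement network is a small encoder–decoder (two
stride-2 stages down and up around a 3x3 bottleneck) rather than a
flat 3x3 stack: equispaced undersampling folds aliases a quarter field
of view away, and a refinement whose receptive field cannot reach the
alias distance cannot remove it. Defaults (2 cascades, 32 channels,
Adam at 1e-3, 10 epochs, l1 magnitude loss) were fixed once at desk
scale; l1 on the output magnitude was preferred over an SSIM training
objective because it needs no window machinery in the backward pass and
optimizes the same reconstructions effectively at this scale, with SSIM
retained as an evaluation metric.

## Metrics and the comparison experiment

`compute_metrics()` reports NMSE, PSNR with the peak taken as the
reference maximum (MRI images have no bit depth), and SSIM with
Gaussian-weighted 11x11 local statistics (sigma 1.5, population
covariances, data range = reference maximum); the SSIM implementation
is pinned to an independent reference implementation in the tests.
`split_dataset()` shuffles at volume level and assigns
`round(n * 0.1)` volumes each to validation and test.

`run_phase_comparison()` is the evaluation harness: for every phase
model and acceleration it synthesizes undersampled training k-space
from the training split's magnitudes under that model (same magnitudes,
same maps, same masks — only the phase differs), trains a variational
network per cell, and evaluates every cell on the same ground-truth
test split, per-slice on RSS references. The package's own comparison
runs use 40 volumes of 64x64 4-coil phantoms per seed, a 1-cascade
8-channel network trained 400 steps per cell, and a generator trained
1000 steps per seed, repeated over 3 seeds — sizes chosen so the full
grid resolves the arm ordering in minutes on one CPU. The acceptance
suite asserts the orderings this harness is meant to detect — the GAN
arm above the sinusoidal arm, the ground-truth arm no more than 1 dB
below the GAN arm, degradation with R — and reports failures rather
than absorbing them. At this scale the ground-truth arm typically leads
the GAN arm by about 1 dB: phantom phase is intentionally
non-deterministic given the magnitude (real MR phase is not a function
of anatomy alone), so the GAN matches the phase *population* rather
than each image, and k-space synthesized from it is a slightly
mismatched training distribution relative to the exact ground truth.

## Numerical and degenerate-input conventions

* Phase wrapping maps to $[-\pi, \pi)$; `wrap_phase(pi)` is $-\pi$.
* `assemble_complex()` with zero magnitude erases phase exactly.
* An all-zero reference makes the metric triple undefined and errors;
  identical images report `psnr = Inf`, `nmse = 0`, `ssim = 1`.
* An all-zero calibration region is a degenerate-estimation error.
* `round()` ties follow R's IEEE round-half-even; no mask or split size
  in the tested grids sits on a tie.
* All randomness flows through R's RNG from explicit seeds; derived
  per-sample seeds are reduced modulo 2^31 so they stay valid R
  integers. Training is single-threaded and bit-reproducible.

## Known limitations

* The GAN cannot reproduce per-pixel background phase noise (an l1
  objective drives it toward the conditional median), but background
  pixels carry zero magnitude and therefore contribute nothing to
  synthesized k-space; the limitation is cosmetic at phantom scale.
* Only one ESPIRiT eigenmap per pixel is produced; soft-SENSE-style
  multi-map support is out of scope.
* Cartesian column masks only; no non-Cartesian trajectories,
  random-density masks, or partial Fourier.
* Desk-scale training budgets demonstrate learning trends, not
  converged reconstruction quality.
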