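---
title: "Phase-aware conjugate-artifact removal for FD-OCT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-aware conjugate-artifact removal for FD-OCT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octccr)
```

## The problem

Frequency-domain OCT detects a real-valued spectral interference fringe
for every A-line and reconstructs depth by a Fourier transform.  Because
the detected fringe is real, its transform is Hermitian-symmetric,
`X[N-k] = Conj(X[k])`: every reflector at depth `+z` has a mirror twin at
`-z`.  Instruments avoid the resulting *complex conjugate artifact* (CCA)
by keeping the sample entirely on one side of the zero-delay position and
displaying only half of the depth range.  When the sample is placed at
the zero delay — the position that makes best use of the depth range and
of the depth-dependent sensitivity — the mirror image folds onto the
structure and the image becomes ambiguous.

This package removes the folded artifact with a conditional GAN that
translates an artifact-corrupted B-scan into its artifact-free
counterpart.  Its central scientific point is that the *phase* of the
reconstructed tomogram, usually discarded, carries information that the
magnitude does not: conjugation negates phase (`arg Conj(z) = -arg z`)
while leaving magnitude untouched.  A model that sees both the intensity
and the phase image (the 2-channel, phase-aware variant) can therefore
resolve ambiguities that are provably invisible to an intensity-only
model.

## Image formation

`reconstruct()` applies a columnwise FFT to real fringes and keeps the
positive-depth half (`N/2` bins) by default; full-range retention and
Hann apodization are options.  `to_intensity()` maps `20*log10(|z| +
1e-12)` linearly onto 0-255 over a dB window, either a fixed window
recorded in `norm_params()` (invertible via `denormalize()`, exact to
half a gray step) or per-image min-max; the degenerate constant image
maps to 0.  `to_phase()` wraps the argument into `[0, 2*pi)` and
quantizes by `floor(256*phi/(2*pi))`, clipped to 255, with zero-magnitude
pixels assigned phase 0.

A note on the phase quantizer: the floor rule is bijective on the 256
phase bins, but it makes the conjugation identity
`p' = (256 - p) mod 256` exact only for bin-aligned phases; for interior
phases conjugate pairs land in bins summing to 255, i.e. the identity
holds to within one quantization step.  An odd (round-based) quantizer
would make the identity exact everywhere at the cost of wrapping phases
just below `2*pi` to pixel 0.  We keep the floor rule and state the
identity at quantization precision; no downstream computation depends on
the distinction.

The analytic axial resolution for a Gaussian source,
`(2 ln 2 / pi) * lambda0^2 / (n * dlambda)`, is exposed as
`axial_resolution()`.  For a 1300 nm / 90 nm source it gives 8.3 µm at
`n = 1`, the value commonly quoted as "around 8 µm"; at a tissue index
of 1.38 the same formula gives 6.0 µm.  Because the convention behind
quoted in-tissue values varies, the refractive index is an explicit
argument rather than a hidden assumption.

## The synthetic paired acquisition

No public paired CCA dataset exists, so the package ships a physics-based
simulator (`phantom()`, `synth_fringe()`, `make_pair()`,
`generate_dataset()`) that emulates the zero-delay-shift protocol: scan
once with the sample at a depth offset (`z_offset_um`, default half the
depth range) so the mirror artifact falls outside the displayed range —
the ground truth — and once, without moving the sample, with the
reference delay set so the sample sits at the zero delay — the input,
with the fold superposed on the structure.  Both passes share the same
scatterers and speckle phases; only the reference offset and the
detection noise differ.  The two passes are deliberately not
pixel-aligned in depth.

The fringe model is the standard FD-OCT forward model: each scatterer at
optical depth `z` with reflectivity `r` and phase `phi` contributes
`r * S(k) * cos(2 k (z + z_offset) + phi)`, with `S(k)` a Gaussian
envelope whose FWHM is set by the source bandwidth and `k` sampled
linearly (a phase-stable swept source without resampling).  Extended
structures are clouds of sub-resolution scatterers with uniform random
phases — the standard random-phasor model of fully developed speckle.
Additive white Gaussian noise is calibrated so that the mean noise-bin
magnitude sits at `noise_floor_db` relative to a unit reflector.  Frames
within a volume emulate adjacent scan positions: fresh speckle phases
plus a rigid common-mode axial shift (sheet thickness is preserved, as
for a rigid sample).

### Why phase — and only phase — encodes the fold side

The simulator's `layered` phantom is designed so that the fold side is
*provably* invisible in intensity yet readable from phase.  This took
some care, and the reasoning is part of the method:

* The phantom is a single polymer-sheet analog whose two faces carry
  specular reflections with reflection phases differing by `pi/2`.  The
  displayed phase difference between the two interface peaks is
  `kappa*T + (phi_bottom - phi_top)`, with `T` the sheet thickness and
  `kappa` an effective carrier; under conjugation (the fold) the face
  term flips sign, so the two fold sides differ by `pi` — a dataset-wide
  constant signature.  A Fresnel-like face-phase difference of 0 or
  `pi` would be *fold-invariant*: the quarter-wave face pair is the
  designed disambiguation mechanism.
* The thickness (37.5 µm) is an integer multiple of the depth-bin
  spacing at the samplings the package uses by default, so both faces
  sample the transform's per-bin phase alternation at the same
  fractional offset; the signature survives quantization and rigid
  axial jitter.
* The sheet stays strictly on one side of the zero delay, several
  point-spread widths away, and the faces are several point-spread
  widths apart.  Deterministic-phase reflections that straddle the zero
  delay (or overlap each other) interfere with their own mirror and
  imprint their relative phase onto the *intensity*, which would leak
  the fold side; during development each of these leaks was measured by
  checking that an intensity-only network commits to the correct side
  at no better than chance on fresh volumes.
* The canonical experiment apodizes the fringe (Hann) because its sweep
  covers only one to two spectral FWHMs: truncation sidelobes otherwise
  form a skirt across the deep rows whose shape depends on the fold
  side.
* Fold sides alternate across volumes and the held-out test volumes
  contain both sides, so a model that guesses one side gains nothing on
  average.

The `skin_like` and `eye_like` kinds are qualitative fixtures (bright
bands with a duct analog; curved arcs); they make no anatomical claim.

## The model

`ccr_gan()` fits the translation model: a U-Net generator (stride-2 4x4
convolutions, instance normalization, leaky-ReLU 0.2 encoder / ReLU
decoder, skip connections, tanh output; depth 7 by default, feature
widths doubling from `base_features` and capped at 8x) against a
conditional 5-layer patch discriminator (strides 2,2,2,1,1, sigmoid
patch scores, the four internal feature maps exposed).  Images are
mapped to [-1, 1] at the network boundary; sides that are not multiples
of `2^depth` are reflect-padded and cropped back (864 pads to 896 at
depth 7).  Input is the intensity image alone (`in_channels = 1`) or
intensity plus phase (`in_channels = 2`); the output is always the
artifact-free intensity image.

The objective is the conditional min-max game with an L1 term,

    min_G max_D  L_GAN(G, D) + lambda * E|y - G(x)|,

with `L_G = theta_g * BCE(D(x, G(x)), 1)` (non-saturating) and
`L_D = theta_d * (BCE(D(x, y), 1) + BCE(D(x, G(x)), 0)) / 2` plus a
perceptual feature term `L_perc`: the sum over the discriminator's
internal layers of mean L1 distances between feature maps of generated
and real images.  Two placements of `L_perc` are provided.  Added
verbatim to the discriminator loss (`perc_mode = "paper_literal"`) it
would reward the discriminator for *collapsing* its features on real and
fake images, degenerating the very representation the term measures; in
the perceptual-adversarial formulation the generator minimizes the
feature distance while the discriminator keeps it above a margin,
`max(0, m - L_perc)`.  The default is the latter (`perc_mode = "pan"`,
margin 1, generator weight 1); the literal form is retained for audits.
Weights not fixed by convention are `lambda = 100`, `theta_g = theta_d
= 1` (the usual conditional-GAN settings).  The discriminator is
conditional (input concatenated with the candidate), batch size is 1,
and normalization is instance-style — stable at batch 1.

Optimization is Adam with learning rate 1e-4 and betas (0.5, 0.999),
for up to 140 epochs by default.  GAN losses oscillate, so after every
epoch the mean PSNR on a held-out validation split (5 % of training
B-scans by default, the 95:5 convention) is logged and the returned
model carries the generator of the best validation epoch.  `predict()`
runs single-image inference; `save_checkpoint()` / `load_checkpoint()`
round-trip to identical outputs.

### Determinism

Everything stochastic is seeded: weight initialization, shuffling,
phantom geometry, speckle, noise, subsampling.  The convolution kernels
(`src/conv.cpp`) deliberately use plain-loop matrix products rather than
BLAS: training feeds its own outputs back through these products
thousands of times, so run-to-run bitwise reproducibility across
machines requires a fixed summation order, which BLAS backends do not
guarantee across CPU types.  At the tensor sizes involved the cost is
minor, and the same configuration and seed reproduce the same model to
the byte.

## Evaluation

`psnr()` (10·log10(255²/MSE), capped at 100 dB for identical images),
`ssim()` (11x11 Gaussian window, sigma 1.5, C1 = (0.01·255)²,
C2 = (0.03·255)²) and `fid()` (Fréchet distance between Gaussian fits to
embedded feature clouds) quantify agreement with ground truth;
`fid_with_errorbars()` reports mean, SD and per-run values over seeded
subsample runs, and `f_test()` compares the variances of two per-image
score lists (two-sided variance-ratio test, `2*min(cdf, 1-cdf)`).
Because the canonical pretrained FID embedder requires a network
download, the default embedder is a seeded fixed random convolutional
projection; FID values are comparable only within one embedder, and
reports record the embedder identity.  An adapter hook (`embed_fn`)
accepts an external pretrained embedder.  The F-test is applied to
per-image metric lists; with only "F-test" specified, the two-sample
variance-ratio form, two-sided, is the natural reading for bar-plot
error-bar comparisons.

`run_experiment()` orchestrates the full comparison: generate a paired
dataset, split at the volume level (test volumes held out whole; the
95:5 train/validation split applied at B-scan level within training
volumes, the finer granularity being unspecified by convention), train
the intensity-only and phase-aware variants at matched budget with
shared seeds, evaluate on the held-out volumes, and compare the
per-image score distributions.

## Problem sizes used by the test suite

The shipped tests exercise the full pipeline at sizes chosen so the
whole suite completes in minutes on one CPU core: the reproducibility
smoke test uses 2 volumes x 8 frames of 64x64 pixels for 2 epochs; the
headline intensity-vs-phase comparison uses 14 volumes x 3 frames of
32x32 pixels (42 pairs), a depth-5 U-Net with 8 base features, 96
epochs, 4 held-out test volumes covering both fold sides, and 3 seeds,
asserting that the phase-aware variant's mean held-out PSNR and SSIM
are at least those of the intensity-only variant.  The same comparison
at a scale closer to a real acquisition (216 pairs of 128x128 B-scans,
layered and skin-like phantoms, depth-7 U-Net) is provided as
`scripts/phase_advantage.R`; it takes on the order of hours per seed on
a CPU and is not part of the default suite.

```{r example, eval = FALSE}
ex <- run_experiment(experiment_config(seed = 1,
                                       test_volumes = sprintf("vol%02d", 11:14)))
ex            # mean held-out PSNR/SSIM of both variants, F-test p-values
plot(ex$model_p)
```

## What passing tests do and do not show

The simulator produces fringes from the exact forward model the
reconstruction assumes: linear-in-k sampling, Gaussian envelope, additive
white Gaussian noise, rigid samples, no dispersion mismatch, no
sensitivity roll-off, no motion.  Success on synthetic pairs therefore
demonstrates the mechanism — that phase input lets a conditional GAN
resolve the conjugate fold — not clinical performance on in vivo data,
where phase stability, dispersion and motion all degrade the phase
channel.  The fold-side cue in the layered phantom is deliberately
engineered to be phase-exclusive; real tissue offers weaker, less
structured phase cues, and a model trained on one sample type does not
transfer to another.  Reconstruction of the *phase* of the output is
out of scope: the generator emits intensity only.

## Known limitations

* Full-resolution (864x1024) training is supported but unexercised by
  the test suite; at that size training is compute-bound and
  single-threaded.
* The discriminator requires inputs of at least 32x32 pixels; the U-Net
  requires sides of at least `2^generator_depth`.
* The identical-image PSNR sentinel (100 dB) keeps aggregates finite
  but makes means of mixed identical/non-identical sets scale-dependent.
* FID with the built-in embedder is a relative measure only; absolute
  values are not comparable with published FID numbers.
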