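---
title: "Streaming ptychography: simulation, phase retrieval and an online surrogate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Streaming ptychography: simulation, phase retrieval and an online surrogate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptychostream)
```

## The problem

Ptychography scans a coherent beam across a sample in overlapping steps and
records only far-field intensities; the exit wave's phase — which carries the
image — must be recovered computationally. Iterative engines such as rPIE do
this well but are orders of magnitude slower than modern detectors, and they
need substantial spatial overlap between neighbouring illumination spots,
which multiplies the dose delivered to the sample. `ptychostream` implements
the alternative workflow in which a lightweight convolutional surrogate is
trained *online*, during the experiment, on pairs of (diffraction frame,
iteratively retrieved phase patch); once trained it inverts each frame
independently in a single pass, so the overlap constraint (and most of the
dose) disappears for subsequent scans.

Everything here runs on simulated data from the package's own forward model,
which lets every claim be scored against a known ground truth.

## Forward model

A scan is described by a `detector_geometry` (energy, distance, frame side
`N`, pixel pitch), a complex `probe` on the object-plane grid, a `phantom`
(phase and amplitude maps), and a spiral `scan_plan`. The object-plane pixel
size is the standard far-field sampling relation λz/(Np). For each position
the exit wave ψ = P·O over the probe window is propagated by a centred
orthonormal FFT and the intensity is scaled so that the expected photon
count in the frame is `flux_scale · exposure_ms · Σ|ψ|²`; orthonormal
scaling makes this bookkeeping exact (Parseval), which the tests verify to
1e-6. Poisson noise is optional and seeded; noiseless stacks store the
real-valued expected counts so that conservation identities hold exactly,
while Poisson stacks hold integer counts.

Probes come in two styles. The `annulus` style models a defocused Fresnel
zone plate: a ring aperture is propagated by the angular-spectrum method to
a defocus distance selected so the intensity FWHM matches the requested spot
size within 5%, preserving the characteristic donut (central intensity dip
below half the ring peak). Because free-space propagation of a ring first
*narrows* the azimuthally averaged spot (axial self-focusing), the aperture
is constructed slightly oversized and the defocus search walks the FWHM down
through the target. The `gaussian` style is a smooth filled spot for
controls.

Phantoms emulate binary etched test structures: two phase levels inside a
declared range (default (−0.4, 0) rad, well inside (−π, π) so wrapping never
occurs), edges softened over about one pixel. `random_etch` thresholds
smoothed noise; `letters` stamps glyphs from a built-in bitmap font — a
feature class deliberately disjoint from the random blobs, useful for
"never seen" generalization checks.

Spiral plans use a constant-arc-length Archimedean spiral, r = aθ with
a = S/2π, stepped so consecutive chords equal the step S; the turn pitch
then also equals S, giving uniform areal density (median nearest-neighbour
spacing = S within 5%). The overlap ratio of such a scan is 1 − √3·S/B for
beam size B. The paper-scale defaults reproduce the reference experiment:
963-point spirals, 800 nm spot, 50 nm training step (overlap 0.9).

## Iterative phase retrieval (rPIE)

`rpie_reconstruct` is a sequential projection solver: per position, exit
waves are formed for every probe mode, propagated, the measured modulus
√I replaces the model modulus (distributed across modes in proportion to
their intensities), and the back-propagated difference drives the object
update with the rPIE denominator (1−α)|P|² + α·max|P|², plus the standard
PIE probe update when enabled. Defaults: 500 iterations, α = 0.25, β = 0.9,
3 probe modes, probe frozen for the first 10 iterations, noise modes seeded
at −20 dB and kept orthogonal by Gram–Schmidt. α and β are declared package
defaults (the reference implementation's values are not published); both are
exposed in `rpie_options`. The per-iteration trace records the normalized
modulus mismatch Σ(√I − |Ψ|)²/ΣI. Two exact properties anchor the tests:
a ground-truth initialization is a fixed point (error ≤ 1e-10), and an
all-zero object scores exactly 1.

## The surrogate network

`network_spec`/`build_network` define a fully convolutional encoder–decoder
mapping one N×N diffraction frame to an N×N phase patch. Each encoder stage
is two 3×3 convolutions (ReLU) followed by 2×2 max pooling; the bottleneck
applies two further convolutions; each decoder stage is nearest-neighbour
2× upsampling (checkerboard-safe) followed by two 3×3 convolutions, except
the final stage which upsamples and applies the π·tanh output head, bounding
phases to (−π, π). There is no amplitude branch. With the default widths
(16, 32, 64, 128) the network counts 733,921 trainable parameters — the
"0.7M, half-width, phase-only" configuration — and the count is independent
of the input side. The layer kernels (im2col + BLAS gemm, with exact
backpropagation verified against finite differences) live in compiled code.

Inputs are preprocessed as `sqrt(counts · scale_factor) / norm_const`, where
`norm_const` is the 99.9th percentile of the transformed training corpus,
recorded on the model so inference always matches training. The square root
matters: a diffraction frame spans many orders of magnitude between the
central beam and the weak high-angle fringes that actually encode the fine
structure, and with raw intensities the optimizer stalls near the mean-image
baseline (we measured per-pixel informative variation of ~1e-4 after raw
normalization). The amplitude-like transform stabilizes the variance; raw
intensity remains available via `input_transform = "intensity"`.

## Online training and the retraining policy

`prepare_training_pairs` interpolates the reconstructed phase onto a regular
fov_side × fov_side grid centred at each beam position (bilinear; reduces to
a direct crop on grid nodes), one label per frame — the label FOV is chosen
to match the probe FWHM, since a single frame physically encodes only the
illuminated neighbourhood. `train_incremental` appends new pairs to the
corpus (append-only within a campaign), then runs 50 epochs (default) of
Adam on the mean absolute error with a triangular cyclic learning rate
(defaults 1e-4 → 5e-4, one cycle per increment; both exposed — the published
workflow cites the cyclic policy without bounds), re-drawing a random 10%
validation split every epoch and returning the epoch snapshot with the
lowest validation loss. Each campaign starts from a freshly initialized
network.

`retrain_policy_step` stitches the current model's inferences on the newest
scan, compares them with that scan's iterative reconstruction by SSIM, and
retrains when the mismatch (100 − SSIM%) is at or above the tolerance
(default 10 points; equality triggers retraining). Below tolerance the
automatic reconstruction/retraining services are suspended pending periodic
checks, and they resume when a mismatch reappears — e.g. on a data
distribution shift. `run_stream_demo` wires measurement, training and
per-frame inference into one in-process event loop with a totally ordered,
version-stamped event log; it replaces the multi-facility transport of a
production deployment by design.

## Stitching and evaluation

`stitch` resamples every patch bilinearly onto a common grid (spacing = the
reconstruction pixel size, origin anchored to the first patch corner so
pixel-aligned patches are placed verbatim) and averages per pixel, optionally
weighting by the probe modulus; uncovered pixels are NaN and excluded from
all metrics. No per-patch offset harmonization or seam blending is applied —
plain averaging suffices, and a residual global phase offset is removed at
evaluation time.

`ssim_accuracy` is SSIM with an 11-pixel Gaussian window (σ = 1.5),
K1 = 0.01, K2 = 0.03, dynamic range = max−min of the reference, reported
×100; the mean masked phase difference is subtracted first (global phase is
unobservable in ptychography). `frc_resolution` estimates resolution as the
first crossing of the Fourier ring correlation below the 1/2-bit information
threshold (fixed 0.5 optional); identical inputs report the Nyquist limit of
2 pixels. `overlap_sweep` reproduces the sparse-sampling analysis: starting
from a dense scan it keeps every k-th spiral point (k = squared step ratio,
since spiral density is uniform), reconstructs each subset iteratively,
stitches the surrogate's single-shot inferences on the same subset, and
scores both against the ground truth, alongside the mean dose of each
subset (dose falls as S⁻² at fixed per-shot flux).

## Problem sizes used by the tests

The package's test campaigns are scaled to a single CPU while keeping every
structural property of the full-scale workflow. The solver oracle uses a
64-pixel probe window (8 nm pixels, 300 nm donut) and a 200-point
overlap-0.9 spiral on a 192×192 phantom; rPIE reaches SSIM ≥ 0.95 against
the phantom from a random start within 100 iterations. The end-to-end
campaign uses a 32-pixel window (240 nm donut, matching the 256 nm label
FOV), an 800-point overlap-0.9 spiral at training dose
(400 ms × 1e6 photons/ms), a (8, 16, 32)-width surrogate, and five 60-epoch
increments; the second increment appends a quarter-exposure,
Poisson-re-sampled rendition of half the pairs, emulating the wide range of
count rates a real campaign's scans span (training exposures in the
reference experiment varied by orders of magnitude) — this exposure
diversity is also what gives the trained model its tolerance to moderate
count-rate changes at inference time. The zero-overlap evaluation stitches
the model's inferences on the density-matched sparse subset of the same
scan — exactly the protocol of the full-scale sparse-sampling analysis,
where the dense scan's iterative phase serves as ground truth and the
surrogate has been trained on the campaign's stream. The low-count analysis
divides the training intensities by 10⁴ (Poisson re-sampled) and retrains
from scratch on the dimmed corpus.

What the synthetic campaign does *not* emulate: partial coherence, detector
point spread and dead pixels, scan-position jitter, sample drift, and the
sheer diversity of a 108,819-pair beamline corpus. Passing tests therefore
demonstrate the correctness and the qualitative behaviour of the workflow
(overlap/dose trends, count-variation tolerance ladder, continual-learning
improvement), not beamline-grade absolute accuracies; the reference
experiment's 86% low-count accuracy and 35/20 nm FRC resolutions are
data-specific and are deliberately not reproduced.

## Numerical choices and degenerate inputs

- FFTs are centred (shift before and after) and orthonormal; all power
  bookkeeping relies on this convention.
- The default `flux_scale` (1e8 photons per unit probe power per ms) is
  calibrated once so that the reference dense scenario — 963 spiral points
  at 50 nm step under the 800 nm probe, 1 ms exposure — deposits an average
  dose near 2×10⁴ photons/nm². Absolute beamline flux is not modelled;
  doses are meaningful as ratios.
- Sub-pixel scan positions are rounded to the nearest object pixel in the
  forward model and solver; bilinear interpolation is reserved for labels
  and stitching, where it defines the contract.
- The modulus update guards against zero model intensity with an 1e-12
  floor; a NaN in the object aborts with the iteration index.
- The Poisson mean/variance and downscaling checks test pixels with enough
  photons for the asymptotics to hold (counts > ~20–50).
- `overlap_ratio` is returned unclamped; non-positive values are flagged
  `no_overlap` rather than clipped, so sweeps can represent "beyond zero
  overlap" states faithfully.
- Checkpoints are single-file RDS archives carrying weights, spec,
  normalization and version; loading restores bit-identical inference.

## Known limitations

- The rPIE implementation is single-process and CPU-bound by design; no
  halo exchange, position refinement or multislice.
- The surrogate has no amplitude branch (by construction) and its accuracy
  is bounded by the iterative labels it is trained on.
- The streaming demonstration is an in-process event queue; real detector
  transport, remote execution and edge deployment are out of scope.
- Stack files use multi-page 32-bit float TIFF + CSV + JSON rather than a
  single hierarchical container; integer counts round-trip exactly below
  2^24.
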