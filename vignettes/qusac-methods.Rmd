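---
title: "Methods: simulation-trained quantitative-ultrasound attenuation estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation-trained quantitative-ultrasound attenuation estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

The ultrasound attenuation coefficient (AC) of liver parenchyma, expressed in
dB/cm/MHz, rises with hepatic fat content and is a validated non-invasive
marker of steatosis severity. Estimating it from pulse-echo data is hard
because the received echo intensity at a given depth mixes the liver's
attenuation with everything else along the propagation path: skin, fat and
muscle layers of variable thickness and attenuation, blood vessels with
near-zero echogenicity and their acoustic shadows, and the scanner's own
depth-dependent gain and diffraction. `qusac` implements a
simulation-trained, B-mode-guided regression approach to this problem end to
end: phantom generation with known liver AC, fast plane-wave acquisition
simulation, image formation, the neural estimator, its training and
evaluation protocol, and the clinical agreement statistics used to validate
attenuation imaging against MRI proton-density fat fraction (PDFF).

## Synthetic phantoms

`sample_phantom()` draws a randomized 2-D abdominal scene on a regular grid
(default 40 mm lateral x 80 mm depth at 0.2 mm cells; the desk-scale profile
uses 0.4 mm cells):

* **Superficial layers.** 6-10 laminae (skin on top, then fat/muscle in
  random order) stacked within the top 30 mm.
* **Liver.** One ellipse with semi-axes drawn independently from 50-80 mm,
  centered near the lateral midline with its upper edge a few millimetres
  below the layer zone. This emulates an intercostal liver view in which
  parenchyma fills the deep field — the acquisition geometry the clinical
  protocol aims for.
* **Vessels.** 0-9 circles centered inside the liver ellipse. Radii span
  3-50 mm with a truncated-exponential size law (3 mm + Exp(mean 7 mm),
  capped at 50 mm): vascular trees have many small branches and few large
  trunks, and a uniform size law over 3-50 mm would tile most of the liver
  with vessel lumen, leaving no parenchyma to measure. Vessel-lumen speckle
  is suppressed 20-fold (blood is nearly anechoic), so vessels appear as
  dark regions in B-mode — the morphological cue the estimator is meant to
  exploit.
* **Properties.** Each tissue instance draws speed of sound, AC and density
  uniformly from its class range (`tissue_property_table()`); the liver draw
  is the phantom's ground truth AC, uniform on [0, 1] dB/cm/MHz.
* **Scatterers.** Sub-wavelength scatterers are placed uniformly at k per
  wavelength-squared area (k drawn from 1-9; the wavelength reference is
  3 MHz at 1550 m/s), with densities 800-1200 kg/m^3 and echo amplitude
  proportional to the density contrast against the host tissue.

`warp_axial_grid()` models coupling to a convex probe: every lateral column
shifts deeper by the arc sag of the probe face, and the space above the
tissue becomes couplant. The shear is volume-preserving in the interior, so
interior labels are conserved exactly; rows pushed past the deep edge of the
grid are necessarily lost (at the default 60 mm curvature this affects a few
percent of the deepest class only).

## Forward model

Full-wave pseudospectral simulation is replaced by a fast frequency-domain
scatterer-summation model (`simulate_planewave()`, compiled core): every
scatterer and every impedance step between layers returns a delayed replica
of the transmit pulse, spectrally shaped by `10^(-A f / 20)` where `A` is the
two-way path integral of the attenuation map along the scatterer's axial
column (in dB/MHz). Times of flight use the local speed-of-sound profile;
receive spreading (`1/sqrt(r)`) and element directivity are frequency-flat.
Path integrals are quantized to 0.1 dB/MHz bins, each bin owning a
pre-computed attenuated waveform; the worst-case amplitude error at 3 MHz is
0.15 dB. Receiver noise is white Gaussian at a configurable SNR (default
40 dB), seeded. The model deliberately ignores refraction, multiple
scattering and nonlinear propagation: the estimator consumes echo
*statistics*, and the dominant effect — frequency-dependent amplitude decay —
is exact by construction. Two independent checks pin this down: a
point-target spectral ratio reproduces the closed-form `alpha f d` law to
0.5 dB, and a classical spectral-log-difference estimator
(`sld_estimate()`) recovers homogeneous-phantom AC within 0.1 dB/cm/MHz.

A pluggable interface is unnecessary ceremony at this scale: the forward
model is one documented function with a stable contract
(`map, probe, angle -> channel data`), and a higher-fidelity backend can be
substituted behind the same signature.

## Image formation and features

`compound_bmode()` beamforms each of the five steered frames by
delay-and-sum on a common pixel grid (f-number 1.5, speed 1540 m/s), sums
them coherently, applies a scanner-style time-gain curve (geometric
spreading plus a nominal 0.5 dB/cm/MHz at the center frequency — without
TGC, high-attenuation phantoms fall below the display floor and the deep
field carries no information, exactly as on a real system with gain
misconfigured), envelope-detects along depth, log-compresses and
max-normalizes into a 60 dB dynamic range.

Network inputs are reduced representations: each of the five envelope frames
becomes a 16-channel x 128-sample log-envelope map (TGC-compensated,
clamped at -60 dB, scaled to [0, 1]), and the B-mode image is block-averaged
to 32 x 32 pixels.

## The estimator

The network (`build_ac_network()`) follows the B-mode-guided design:

1. **Per-angle encoders.** Five architecturally identical but independently
   parameterized 1-D convolutional stacks (kernel 7, stride 2, one residual
   block per stage) encode the time-varying intensity of each envelope
   frame; outputs are concatenated channel-wise.
2. **B-mode-guided adaptive denormalization (BGN).** The fused feature map
   is standardized (population standard deviation, epsilon 1e-5) and
   re-modulated per time slice:
   `X_t = gamma_t (x_t - mu) / sigma + beta_t`, with `gamma_t`, `beta_t`
   produced from the B-mode image by 4 shared convolutional layers followed
   by 4 fully connected layers per parameter. Two readings of the
   normalization axis exist. Standardizing each time slice across channels
   is the most literal rendering of the defining equation; standardizing
   each feature channel across time is the adaptive-instance-normalization
   convention the layer descends from ("normalized in the time domain").
   The package implements both (`bgn_axis`), and defaults to the time axis
   on substantive grounds: per-slice normalization does not actually remove
   echo-intensity information from the features (encoder nonlinearities leak
   absolute level into the cross-channel pattern), so the no-B-mode ablation
   matches the guided model and the layer's conditioning is vestigial —
   inconsistent with the large reported value of B-mode guidance. Per-channel
   time standardization removes the first-order decay profile (a standardized
   linear ramp loses its slope entirely), making the B-mode pathway the
   carrier of the morphology-and-decay information it is designed to supply;
   under this axis the guided model beats the ablation on every training
   seed. Scalars per slice are the default modulation; a
   per-slice-and-channel mode is available (`bgn_per_channel = TRUE`). The
   algebraic contract of the transform — identity at `gamma = sigma`,
   `beta = mu`; output moments `beta` and `|gamma|` — is enforced by tests.
3. **Trunk and head.** The denormalized map passes through 2-D convolutions
   with batch normalization, global average pooling, and fully connected
   layers onto a bounded output `0 + 1.2 * sigmoid(u)` dB/cm/MHz — the
   physical range with headroom, preventing degenerate extrapolation.

The ablation variant replaces BGN with plain per-slice standardization
(`gamma = 1`, `beta = 0`) and removes the B-mode branch; everything else is
identical, so the comparison isolates the value of morphological guidance.
All layers, backpropagation and the Adam optimizer are implemented in the
package; gradients are verified against finite differences in the test
suite.

## Training and evaluation

`build_dataset()` assembles phantom/acquisition/feature records and assigns
an 8:1:1 train/validation/test split by phantom id (disjoint by
construction; `train_network()` re-asserts it). Training minimizes L1 loss
with Adam and L2 regularization and early-stops on the validation loss
(patience 20 epochs, minimum delta 1e-4), returning the best-validation
checkpoint. The reference protocol's learning rate (5e-6) and split sizes
(8000/1000/1000) are the `train_config()` and full-profile defaults; the
desk-scale profile trains 250 records at a learning rate of 1e-3 — at 1/40
of the data and a far smaller network, the reference rate would not move the
loss perceptibly within a sensible epoch budget. Three stabilizers keep the
small-sample optimization well behaved, all standard practice: global
gradient-norm clipping, near-identity initialization of the modulation heads
(training starts at plain normalization and learns the B-mode modulation
gradually), and data augmentation by the two exact symmetries of the
acquisition — lateral mirroring (which also reverses the steering-angle
order) and small lateral translations. Checkpoints snapshot the batch-norm
running statistics together with the weights; a checkpoint is only
reproducible with both.

Accuracy is summarized as the mean normalized absolute error,
`MNAE = 100 * mean(|ac_hat - ac|) / R` with `R = 1.0` dB/cm/MHz, the span of
the ground-truth AC range. Range normalization is used because per-sample
truths may be zero, making truth-relative normalization undefined; this
choice is stated wherever MNAE is reported. The mean-predictor baseline
(predict the train-split mean everywhere) is reported alongside every
evaluation, and `run_ablation()` reports the seed-averaged relative
improvement `100 (MNAE_abl - MNAE) / MNAE_abl` of guidance over ablation.

## What the generator does and does not emulate

The synthetic cohort exercises the estimator under tissue-property ranges,
acquisition geometry and speckle statistics matching the stated study
conditions, with exactly known ground truth — something no in-vivo dataset
offers. It does not emulate refraction and aberration through curved fascia,
reverberation clutter, patient motion, operator-dependent probe pressure, or
the biological coupling between fat fraction and speed of sound. Passing the
reduced-scale criteria therefore demonstrates that the method's machinery —
forward physics, feature path, BGN conditioning, optimization — is correct
and that B-mode guidance adds information under controlled conditions; it
does not by itself establish clinical accuracy.

## Numerical choices and degenerate inputs

* BGN standard deviation uses the population convention with an epsilon
  floor of 1e-5; constant slices are stabilized, not errors.
* Attenuation path bins: 0.1 dB/MHz; pulse bank of 64 samples at the
  12 MHz sampling rate.
* The closed-form attenuation check is evaluated at the transmit center
  frequency in the spectral domain; an envelope-peak reading would
  under-read the law by ~1 dB because linear-in-frequency attenuation
  downshifts the pulse spectrum.
* Grading is threshold-inclusive (value >= cutoff attains the grade).
* ROC confidence intervals use a 2000-replicate stratified bootstrap; the
  ICC intervals use the standard F-distribution construction for two-way
  random-effects absolute agreement. Degenerate statistics inputs (single
  class, zero variance, constant vectors) raise typed input errors.
* The cohort generator clamps measurements to physical ranges and
  pre-corrects the latent mean so post-clamp marginal means match their
  targets; comparator devices load on the PDFF latent factor, which keeps
  the implied correlation matrix valid by construction.
* Dataset containers use versioned native-R serialization with explicit
  format and version markers; readers reject unversioned or mismatched
  files rather than guessing.

## Problem sizes

The test and acceptance runs use the desk-scale profile: 250 records
(200/25/25 split) on a 0.4 mm grid with the narrow network
(8-12-16 encoder widths), three training seeds for the ablation comparison,
10,000 phantom draws on a 1 mm grid for the sampling-law audit, and
homogeneous calibration phantoms for the physics checks. The full profile
(`default_project_config("full")`) mirrors the reference protocol
(10,000 records, 8000/1000/1000, 16-32-64 widths, learning rate 5e-6) and
is the recommended setting when hours of compute are available.

## Known limitations

* 2-D phantoms and acquisition; no elevational effects.
* Straight-ray attenuation integration ignores refraction at layer
  interfaces.
* The delay-and-sum beamformer assumes a single speed of sound.
* At desk scale the MNAE carries visible seed variance, and the ablation
  margin is noise-limited: across dataset realizations the seed-averaged
  improvement of B-mode guidance ranges from clearly positive to slightly
  negative. The log-compressed envelope features leak echo-level information
  through the encoder nonlinearities even after per-channel standardization,
  so the no-B-mode ablation remains surprisingly capable at a few hundred
  records. Conclusions about the *magnitude* (or even a robust sign) of the
  improvement require the full profile; the package reports per-seed results
  so that variance is never hidden.
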