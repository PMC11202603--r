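# qusac

Simulation-trained **q**uantitative-**u**ltrasound liver **a**ttenuation-**c**oefficient
estimation, with the clinical statistics used to validate attenuation imaging
against MRI proton-density fat fraction (PDFF).

## The problem

The ultrasound attenuation coefficient (AC, dB/cm/MHz) of liver parenchyma
rises with hepatic fat content and grades steatosis non-invasively. Estimating
it from pulse-echo data is confounded by everything else on the acoustic path:
superficial skin/fat/muscle layers, vessels and their shadows, scanner gain
and diffraction. `qusac` implements a B-mode-guided neural regression approach
to this problem, trained entirely on simulated data with known ground truth:

* **Phantoms** — randomized 2-D abdominal scenes (layered superficial tissue,
  an elliptical liver with 0–9 vessels, sub-wavelength scatterer fields) with
  per-tissue acoustic properties drawn from published ranges; the liver AC
  draw (uniform on 0–1 dB/cm/MHz) is the regression target.
* **Acquisition** — a fast scatterer-summation forward model of five-angle
  (−7.2°…7.2°) 64-channel plane-wave pulse-echo imaging with exact
  frequency-dependent attenuation `10^(−α·f·d/20)` along the two-way path,
  envelope detection, and delay-and-sum compounded B-mode formation.
* **Estimator** — five per-angle convolutional encoders fused channel-wise,
  a **B-mode-guided adaptive denormalization** (BGN) layer

  `X_t = γ_t · (x_t − μ) / σ + β_t`

  whose per-time-slice scale/shift vectors γ_t, β_t are computed from the
  B-mode image (4 shared convolutional layers, then 4 fully connected layers
  per parameter), a 2-D convolutional trunk with batch normalization, and a
  bounded regression head. Training minimizes L1 loss with Adam + L2
  regularization and validation-based early stopping. A no-B-mode ablation
  (γ = 1, β = 0) isolates the value of morphological guidance. Accuracy is
  reported as MNAE, `100·mean(|α̂ − α|) / 1.0 dB/cm/MHz`.
* **Clinical statistics** — steatosis grading by PDFF (5 / 16.3 / 21.6 %) and
  by AC cutoffs (0.36 / 0.46 / 0.53 dB/cm/MHz), two-way random-effects
  absolute-agreement ICC(2,1)/ICC(2,k) with F-based CIs, ROC analysis with
  Youden operating points and bootstrap CIs, Spearman/OLS regression, and a
  Gaussian-copula synthetic cohort generator.

## Worked example

```r
library(qusac)

# one phantom -> five-angle acquisition -> B-mode
map   <- warp_axial_grid(sample_phantom(phantom_spec(seed = 7)), 60)
acq   <- acquire_frameset(map, probe_config())
bmode <- compound_bmode(acq)
map$liver_ac_truth
#> [1] 0.4591037

# classical spectral-log-difference estimate on a homogeneous phantom
frames <- acquire_frameset(homogeneous_phantom(0.5, seed = 11), probe_config())
sld_estimate(frames)
#> [1] 0.5267281

# reduced-scale dataset, training, evaluation
ds  <- build_dataset(250, phantom_spec(grid_shape = c(200, 100), cell_size = 0.4),
                     probe_config(), seed = 42)
fit <- train_network(ds,
                     network_config(encoder_widths = c(8, 12, 16),
                                    bgn_conv_channels = 4, bgn_fc_width = 16,
                                    trunk_widths = c(12, 16), head_width = 16),
                     train_config(lr = 1e-3, epochs = 110, batch_size = 16,
                                  patience = 20, min_epochs = 50, seed = 1))
ev <- evaluate_model(fit, ds, "test")
ev
#> <eval_report> test split, n=25: MNAE 9.36% (mean-predictor baseline 25.17%)
```

An MNAE of ~10 % at this desk scale means the network recovers the liver AC
to ~0.1 dB/cm/MHz on held-out phantoms — clearly better than the 25 %
mean-predictor floor, approaching the few-percent regime the method reaches
at full scale (10,000 records, wide network). `autoplot(ev)` draws the
predicted-vs-true scatter; `glance(fit)` and `tidy(fit)` expose the training
history.

Clinical statistics operate on ordinary data frames:

```r
cohort <- synth_cohort(200, rho_ac_pdff = 0.9, seed = 1)
roc_analysis(cohort$qus_ac, grade_from_pdff(cohort$pdff) >= 1)
icc_two_way_random(cbind(r1 = cohort$qus_ac,
                         r2 = cohort$qus_ac + rnorm(200, sd = 0.02)))
```

A command-line entry point (`inst/exec/qusac`) wraps the same functions as
`simulate | train | evaluate | ablate | stats` verbs.

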