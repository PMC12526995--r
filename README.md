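# mdcpr

Micro-Doppler radar analysis of CPR chest-compression depth, in R.

Effective cardiopulmonary resuscitation needs compressions about 5 cm
deep, but nothing at an out-of-hospital scene measures that. A 77 GHz
FMCW radar pointed at the chest can: every compression advances the
slow-time phase of the radar return by 4πr/λ (~161 rad per 5 cm cycle),
and the corresponding micro-Doppler frequency f = 2v/λ traces the motion
in a time–frequency map. `mdcpr` implements the full analysis chain on
synthetic data, with no hardware required:

* **Simulator** — raised-sine compression kinematics with per-subject
  bias/jitter, aspect-angle projection (r = d·cosθ), phase-level signal
  synthesis exp(+j4πr/λ) + AWGN, and a full chirp-level IF path with
  range processing; multi-subject campaign generation.
* **Time–frequency tools** — STFT spectrogram, Wigner–Ville distribution
  (exact time marginal, single-bin chirp localization) and the smoothed
  pseudo-WVD (Hamming time/lag smoothing, >10× cross-term suppression),
  plus normalized spectrogram-image export.
* **Three depth estimators** —
  1. *Doppler integration*: envelope detection at the maximum energy
     derivative over frequency (with tone-calibrated edge debiasing),
     local-minima cycle segmentation, per-lobe integration
     d = (λ/2)∫f dt, angle compensation d = r/cosθ;
  2. *polynomial regression* of depth on per-cycle peak Doppler
     frequency, solved in closed form from the normal equations
     XᵀXw = Xᵀy;
  3. a *CNN regressor* (18 fixed layers, 283,329 parameters at 64×64
     input) on single-compression spectrogram crops, trained with
     SGD-momentum and early stopping by a built-in, gradient-checked
     training engine.
* **Evaluation statistics** — RMSE, cohort summaries (mean, sample sd,
  Student-t 95% CI), paired t-test, leave-one-subject-out protocol, and
  the packaged per-subject reference RMSE tables of the measurement
  campaign this toolkit models, with `reproduce_printed_tables()`
  recomputing every printed summary cell.

## Worked example

```r
library(mdcpr)

cfg <- radar_config()            # 77 GHz, 3.99 GHz sweep, PRF 2000 Hz
cfg$wavelength_m * 1e3           # 3.893409  (mm)
cfg$range_resolution_m * 1e2     # 3.756798  (cm)

# simulate 10 s of 5 cm compressions at 100 CPM and estimate per cycle
tr  <- simulate_kinematics(compression_scenario(5, 100, duration_s = 10), cfg)
sig <- phase_synthesize(tr, cfg)
est <- estimate_depths(sig, cfg)
nrow(est); mean(est$depth_cm)
#> 16
#> 5.035339
```

The estimator segments 16 complete cycles and recovers the 5 cm target
with a mean of 5.04 cm (+0.7%). An oblique view is projected and
compensated the same way:

```r
sig30 <- phase_synthesize(project_radial(tr, 30), cfg)
mean(estimate_depths(sig30, cfg, aspect_angle_deg = 30)$depth_cm)
#> 5.034801
```

Reproducing the published summary arithmetic from the shipped
per-subject tables:

```r
s <- summarize_rmse(reference_tables("integration")$case1)
round_half_away(c(s$mean, s$sd))     # 0.558 0.179
rep <- reproduce_printed_tables(verbose = TRUE)
all(rep$match | rep$expected_fail)   # TRUE
```

A thin command-line front end ships in `inst/cli/mdcpr`
(`simulate | estimate | tfr | reproduce-tables`).

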