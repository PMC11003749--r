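# vsdmask

Simulation and analysis of voltage-sensitive dye imaging (VSDI) detection
experiments in primary visual cortex under **orientation similarity
masking** — the phenomenon in which a small oriented target becomes harder
to detect as the background's orientation approaches the target's (the
basis of camouflage).

The package is aimed at systems-neuroscience analysts who work with
widefield imaging of V1: it implements the full analysis chain of a
masking experiment and, because every stage is validated on synthetic
sessions with known ground truth, it doubles as a test bed for decoding
and normalization-model analyses without any recorded data.

## What it computes

**Preprocessing.** Image stabilization with the separable motion model
`I(x,t) = I0(x,t) + α(x)·v(t)` (global translation `v(t)` from the central
image quarter, per-pixel coupling `α(x)` by least squares), dF/F
normalization against a −80–0 ms baseline, 0.8–3.0 cycles/mm columnar
bandpass, and 5 Hz flash-response extraction for template estimation.

**Decoding.** Reliability-weighted linear template decoders at the two
spatial scales of V1's representation:

- retinotopic: `r_ret(t) = R(x,t)·Ĥ_ret / ‖Ĥ_ret‖`, `Ĥ_ret = H_ret/σ²_ret(x)`
  with `H_ret` a fitted 2D Gaussian point image;
- columnar 0°–90° axis: projection on `Re(H_ori)/σ²_col(x)`, where
  `H_ori = H_ret · A · e^{2iθ}` is the complex columnar map;
- a 12-channel population decoder (orientation bins −75°…90° in 15° steps),
  each channel the reliability-weighted mean of columnar-band activity over
  its pixel subset, summarized per frame by the complex population vector
  `Σ_k r_k e^{2iθ_k}` (angle/2 = decoded orientation).

**Behavior.** Signal-detection summaries with unconditionally scaled
proportions (`P̂ = 0.005 + 0.99P`): `d' = Φ⁻¹(P_hit) − Φ⁻¹(P_fa)`,
criterion, `PCmax = Φ(d'/2)`, reaction-time statistics, and the
inverted-Gaussian masking fit `d'(θ) = c − A·e^{−θ²/2σ²}`.

**Statistics.** SVD-based cross-experiment response scaling with
reliability weights `w = 1/scale²`, the pooled weighted mean/SD estimator,
modified z-scoring, reaction-time censoring, flat-vs-Gaussian trend
selection by nested F test, and the trial-count-weighted Pearson
correlation with entropy-based effective sample size
`n_eff = exp(−Σ p·log p)`.

**Model.** A delayed, orientation-tuned divisive-normalization population
model: per channel, `r(t) = r_e^p / (r_n^p + r0^p)` with excitation and
normalization drives built by convolving effective-contrast fields with
separable Gaussian × gamma kernels. The normalization pool is slower and
more broadly tuned than the excitation; that combination reproduces the
biphasic masking dynamics (early enhancement by target–background
similarity, late suppression) and the early-negative / late-positive
correlation between neural response and behavior.

## Worked example

```r
library(vsdmask)

# behavioral masking in a simulated detection session
maps <- make_ground_truth(grid_shape = c(48, 48), mm_per_pixel = 8/48, seed = 2)
session <- simulate_session(session_design(trials_per_orientation = 60),
                            maps, seed = 2, render_images = FALSE)
behavior <- behavior_summary(session)
behavior$masking_fit
#> <masking_fit> d'(theta) = 2.55 - 1.65 exp(-theta^2/(2 31.3^2))
```

The session was generated from the masking law `d'(θ) = 2.5 −
1.5·e^{−θ²/(2·30²)}`; with 60 trials per orientation the fit recovers
A = 1.65, σ = 31.3°, c = 2.55 — the sensitivity dip at the matched
orientation and its ~30° tuning width.

```r
# the normalization model: background-only response dynamics
resp <- simulate_population(stimulus_spec(background_contrast = 0.12))
resp
#> <model_response> 40 frames x 12 channels; popvec magnitude peaks at 90 ms

# frame-by-frame correlation of the modeled target-evoked response with
# the behavioral profile: negative early, positive late
ms <- simulate_model_set(background_orientations = c(0, 15, 30, 45, 60, 90))
dprof <- predict(behavior$masking_fit, c(0, 15, 30, 45, 60, 90))
mb <- model_behavior_correlation(ms, dprof)
round(subset(mb, t_ms %in% c(50, 70, 100, 200))$rho, 2)
#> [1] -0.75 -0.78  0.94  0.97
```

The population-vector magnitude of the background-only response rises,
peaks (90 ms frame), and falls — the signature of normalization lagging
excitation — and the model–behavior correlation flips sign between 70 and
100 ms: during the early transient, V1-like responses are *anti*-correlated
with detectability, and only the late phase mirrors behavior.

`run_pipeline(pipeline_config(...))` chains every stage (simulate →
stabilize → dF/F → templates → decode → population vectors → behavior →
statistics → model) and writes per-stage CSV tables plus a JSON summary.

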