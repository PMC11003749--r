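---
title: "Methods: simulating and decoding V1 similarity masking with vsdmask"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and decoding V1 similarity masking with vsdmask}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vsdmask)
```

## The scientific problem

Detecting a small oriented target becomes harder as the orientation of the
background it sits on approaches the target's orientation — *similarity
masking*, the basis of camouflage. In primate V1 this interaction can be
measured with voltage-sensitive dye imaging (VSDI): the target evokes a
mm-scale retinotopic activity envelope, and orientation information rides on
top of it as sub-millimeter columnar "ripples" (0.8–3.0 cycles/mm).
`vsdmask` implements, end to end, the analysis chain of such an experiment —
from raw fluorescence stacks to a normalization model of the masking
dynamics — and, because real recordings are not needed for any of it, ships
a first-class synthetic-session generator so every stage is testable in a
closed loop against known ground truth.

## The synthetic sessions: what they emulate, and what they do not

`make_ground_truth()` builds the generative maps: a 2D Gaussian retinotopic
envelope (default sigma 1 mm over an 8×8 mm field at 128×128 px, the
post-downsampling resolution of the imaging protocol it mirrors; 512×512 is
available by configuration) and a columnar orientation map defined as the
angle-halved argument of a complex Gaussian field whose spectrum is strictly
confined to 0.8–3.0 cycles/mm. Band-limiting by a hard spectral annulus
makes the containment property exact by construction.

`render_trial_stack()` composes the noiseless dF/F signal

```
gain * k(t) * [ C_T env(x) (1 + m A(x) cos 2(theta(x) - theta_T))
              + C_B       (1 + m A(x) cos 2(theta(x) - theta_B)) ]
```

— a target response shaped by the envelope, a spatially uniform background
response (the background grating extends beyond the imaged area), and
columnar modulation of depth `m` (default 0.15) on each. The temporal kernel
`k(t)` is the stimulus on/off trace convolved with a 40 ms-latency gamma
density (shape 3, scale 20 ms), normalized to unit peak so the peak dF/F of
a render is exactly `gain * contrast`; this reproduces target responses that
rise ~40 ms after onset and peak around 100 ms. The same machinery renders
5 Hz flash trains (60 ms ON / 140 ms OFF, 1 s) for the fixation blocks used
in template estimation.

Noise is white pixel noise (default SD 2e-3 dF/F) plus a spatially
correlated component (Gaussian-filtered white field, 0.5 mm correlation
length, SD 1e-3) and an optional global ~2 Hz heartbeat sinusoid. The
amplitudes are package choices — the noise statistics of a real VSD
preparation are not published alongside the method — picked so that
single-trial columnar decoding operates at a realistic signal-to-noise
ratio (columnar pooled SNR of order 3). Motion is injected through the
separable model `I = I0 + alpha(x) . v(t)` with `alpha` the spatial gradient
of the baseline pattern, i.e. the first-order effect of true sub-pixel
translation.

What the generator does **not** emulate: optical blurring and dye
photophysics, eye-position jitter, non-rigid motion beyond the separable
first-order term, trial-to-trial response-gain variability, and noise that
is non-Gaussian or heartbeat-locked in a structured way. Closed-loop tests
passing on these sessions therefore validate the *analysis pipeline's
correctness*, not the robustness of the method to every pathology of real
recordings.

Behavior is generated by the inverse of the analysis model: an
equal-variance Gaussian observer with `P(hit) = pnorm(d'/2 - c)` and
`P(FA) = pnorm(-d'/2 - c)`, with the d-prime profile across background
orientation following the inverted-Gaussian masking law
`d'(theta) = c - A exp(-theta^2 / (2 sigma^2))` (defaults A = 1.5,
sigma = 30 deg, c = 2.5, criterion 0.5 — values in the range of macaque
performance on this task). Reaction times are a 75 ms-shifted log-normal
floored at the 75 ms minimum allowed reaction time; the analysis only ever
uses their measurement, so the generative RT law is a free choice.

## Preprocessing

**Motion.** The separable motion model is estimated in two steps: a global
per-frame translation `v(t)` from the central quarter of the image (integer
shift by FFT cross-correlation against the mean pre-onset frame, refined by
one gradient-based least-squares step — sub-pixel accuracy ~0.01 px on
planted motion). The refinement includes the reference image itself as an
illumination nuisance regressor, so that stimulus-evoked fluorescence
changes — which are to first order proportional to the baseline image —
are not read as translation and later subtracted as spurious motion
artifact. Then per-pixel coupling coefficients `alpha(x)` follow by least
squares of intensity on the mean-centered `v(t)`. Centering is necessary
because the model is only identified up to a constant image; the
least-squares step uses a pseudoinverse so that purely one-dimensional
motion (a rank-deficient `v`) is still fitted within its span.
`stabilize()` subtracts `alpha . v`; it is idempotent and leaves metadata
untouched.

**dF/F.** `(F - F0)/F0` with F0 averaged over −80 to 0 ms; any pixel with
non-positive baseline aborts with pixel diagnostics rather than producing
silent infinities.

**Columnar band.** An annular FFT mask over 0.8–3.0 cycles/mm with 0.1
cycles/mm raised-cosine edges (to limit spatial ringing; the hard band edges
alone are the specified filter, the taper width is a numerical choice). DC
is always removed. The filter is linear, and idempotent on band-interior
content.

**Flash responses.** Per-pixel Fourier amplitude/phase at the 5 Hz flash
frequency over the stimulation window, truncated to a whole number of flash
periods, which makes the amplitude exactly invariant to the flash's
temporal phase.

## Templates and decoders

The retinotopic template is a rotated elliptical 2D Gaussian with offset,
fitted to the flashed-target amplitude map by Levenberg–Marquardt with
moment-based initialization (internally parameterized as a quadratic form,
which stays regular where an explicit rotation parameter becomes
unidentifiable for circular maps). Amplitude maps of noise carry a Rician
positive floor that biases the fitted widths downward, so repeated flash
trials should be averaged coherently — dF/F stacks first, amplitude
extraction after — as [run_pipeline()] does; with 16 averaged trains at
the default noise the planted envelope sigma is recovered within 5%. The columnar map comes from the angle-doubled
vector sum of the bandpassed grating responses,
`z(x) = sum_k resp_k(x) e^{2 i theta_k}` (magnitude A, preference
arg(z)/2), assembled as `H_ori = H_ret A e^{2 i theta}` and windowed to the
pixels inside 2 template SDs (configurable). Pixels are partitioned into 12
orientation bins, −75° to 90° in 15° steps with half-width ±7.5°; a pixel
exactly on a bin edge goes to the lower bin.

All decoders are linear projections with reliability weighting: template
pixels divided by the per-pixel variance of condition-mean-subtracted
residuals (columnar-scale residuals are bandpassed first). Variances are
floored at their 1st percentile so quiet pixels cannot dominate the
weights. The retinotopic and 0°–90° axis decoders divide by the Euclidean
norm of the weighted template, making "frame = template" decode to
`||template||`. The 12 population channels instead divide by the *summed*
magnitude of their weighted field, i.e. each channel is the
reliability-weighted mean of columnar-band activity over its pixel subset.
This realizes exactly the stated intent that every sub-population be
equally represented: with a Euclidean norm each bin acquires a gain
proportional to the square root of its effective pixel count, which varies
~10% across the bins of a finite map — more than the 3.4% cosine-tuning
margin between adjacent 15° bins — and can displace the tuning peak by one
bin even without noise. Missing channels (empty bins) propagate as `NA`,
never as zeros.

The population vector is `sum_k r_k e^{2 i theta_k}`; its angle/2 is the
decoded orientation, and "coherence" (the normalized amplitude used for
the 0.2 trajectory-masking threshold) is defined as the modulus divided by
the summed absolute channel values, a 0–1 quantity. Negative channel
values are retained in the sum — they rotate the vector by 90°, matching
the balanced ± decomposition of a zero-mean columnar field. In closed-loop
checks the *heading* of the trial-averaged population vector is the robust
readout of "peak tuning" (it averages per-bin gain noise away), and it
recovers the true background orientation to within one bin at the default
SNR with as few as 4 trials per orientation.

## Statistics

Cross-experiment pooling follows the printed estimators verbatim even where
they are unconventional. The SVD pooling scale interpolates each
experiment's target-only reference responses to the union contrast grid
(linearly, clamped at the edges with a warning), stacks the −100–200 ms
frames, and scales every experiment to the largest first-singular-component
loading; reliability weights are `1/scale^2`. The pooled mean/SD estimator
keeps the weights *inside* both sums with divisor n — not a conventional
weighted mean, but the published estimator, so it is implemented as
printed. The modified z-score divides responses by the weighted SD of
condition-mean-subtracted residuals in the 50–250 ms window.
Reaction-time censoring supports both integration up to the saccade frame
and frame-wise trial dropout.

The trial-count-weighted correlation uses weights inside the covariance
sums and tests significance with `t = rho sqrt((n_eff - 2)/(1 - rho^2))` on
`n_eff - 2` (possibly non-integer) degrees of freedom, where
`n_eff = exp(-sum p log p)` is the entropy-based effective sample size.
(The source formula prints the exponent without the minus sign, which would
give `1/n` at equal weights; the sign here follows the estimator's stated
meaning, `n_eff = n` at equal weights.) Orientation trends are compared by
a nested F test between a line `m theta + c` and a dc-shifted Gaussian
`A exp(-theta^2/(2 sigma^2)) + c` — the Gaussian printed as `e^{-theta^2 /
sigma^2}` elsewhere is read with the conventional 2 sigma^2 denominator for
consistency with the behavioral masking fit — with numerator df 1 and
denominator df n−3, alpha defaulting to 0.05. The empirical type-I error of
this selection under white noise is ~0.05 (the two families are not
strictly nested; the F approximation is checked by simulation in the test
suite). Per-frame correlation p-values are reported raw, without
multiple-comparison correction across frames, and should be read
accordingly.

Behavioral proportions are rescaled to `[0.005, 0.995]` *unconditionally*
before the quantile transforms (not only at degenerate 0/1 cells), which
keeps every d-prime finite; `PCmax = pnorm(d'/2)`. RT summaries use hit
trials only.

## The delayed divisive-normalization model

Each of 12 orientation channels receives an excitation and a normalization
drive, each the spatiotemporal convolution of an effective-contrast field
with a separable kernel — unit-integral 2D Gaussian in space, unit-integral
gamma density in time — evaluated at the stimulus center, and responds as

```
r(t) = r_e(t)^p / (r_n(t)^p + r0^p)
```

with the reference parameters p = 2, r0 = 0.03125, excitation (sigma_e =
15°, s_e = 0.28°, gamma a_e = 9, b_e = 8 ms), normalization (sigma_n = 20°,
s_n = 0.28°, a_n = 9, b_n = 10.64 ms). The two properties that carry the
phenomenon: the normalization pool is *slower* (gamma mean 95.8 vs 72 ms),
which makes responses transiently overshoot and produces the biphasic
target-evoked dynamics; and it is *more broadly orientation-tuned*, which
converts the late phase into similarity-dependent suppression. Setting
`sigma_n = Inf` gives the orientation-flat control: the late
behavior-consistent phase disappears. (A normalization pool tuned equally
to the excitation, sigma_n = sigma_e, is *not* that control — any tuned
pool retains similarity-dependent late suppression.)

Numerical choices: dt = 1 ms on a 400 ms horizon; a 0.02°-step spatial grid
over ±3° (the 0.28° pooling SD and the 0.14° target envelope demand
sub-envelope resolution; 4 c/deg luminance patterns are sampled at 12.5
samples/cycle); temporal kernels evaluated at bin midpoints, truncated at
1e-6 of peak, renormalized to unit sum; orientation differences wrapped to
the acute angle before the tuning Gaussian (the raw difference would break
180° periodicity); the stimulus pulse is a unit box of the stimulus
duration (250 ms default). Output is box-averaged into 10 ms frames stamped
at the end of each bin, mirroring a 100 Hz camera.

Drives are kept in raw Michelson-contrast units and r0 is applied in those
units; the final responses are divided by the 24%-contrast target-only
response of the target's channel averaged over 50–200 ms, purely a
reporting scale. This reading was selected by prototyping the alternatives:
rescaling the drive signals themselves to the reference breaks every
qualitative signature (the background-only population-vector magnitude then
peaks at 50 ms and the biphasic ordering disappears), whereas the raw-units
reading reproduces them all. Under it, the background-only
population-vector magnitude at 12% contrast rises, peaks in the 90 ms
frame, and then falls — the delayed-normalization signature, with the peak
one frame earlier than the ~100 ms the phenomenon is usually quoted at;
the discrepancy is robust to the raised-cosine-window reading and to
rms-versus-Michelson drive units (80–90 ms in all variants).

For target-plus-background stimuli the effective contrast combines the two
patterns in quadrature with a phase correction,
`c_TB = lambda(x) sqrt(c_B^2 + c_T^2)`, with
`lambda = C_TB / sqrt(C_B^2 + C_T^2)` and `C_TB(x)` the local rms contrast
(Gaussian window of SD s_e) of the summed luminance patterns. The rms is
evaluated in closed form for two cosine patterns with locally constant
amplitudes: `C_TB^2 = C_T^2 + C_B^2 + 2 gamma(x) C_T C_B`, where the phase
coherence `gamma(x) = a(dtheta) cos(dphi(x))` combines the patterns' phase
difference at `x` with the window attenuation of their difference wave,
`a = exp(-2 (2 pi f s_e sin(dtheta/2))^2)`. (A naive numerical windowed rms
is *wrong* here: the 0.28° window is twice the width of the target
envelope and washes the target out of `C_TB`.) The construction is exact in
the limits the phenomenon pins down — linear contrast addition at the
center for the in-phase 0° background, quadrature (lambda = 1) for
orthogonal orientations — and interpolates smoothly for oblique
backgrounds, where no closed form is dictated.

Sublinearity — the combined response falling below the sum of the
component responses — holds at the displayed readout (the
target-orientation channel) with a large margin (~0.9 reference units)
once the onset transient has passed. It is *not* a per-channel theorem of
this model: for near-aligned backgrounds, weakly driven channels combine a
coherent contrast boost (lambda > 1) with the expansive exponent below the
normalization knee (`r_n` comparable to `r0`) and remain mildly
superadditive (up to ~0.06 during their prolonged transients, ~0.004
late). The acceptance check asserts the readout-level property.

The model–behavior correlation correlates, frame by frame across
background orientations, the target-evoked response readout against the
behavioral d-prime profile. The default readout is the response of the
channel tuned to the target; the real-part-of-population-vector projection
is also available but is *not* used for the tuned-vs-untuned control,
because suppressing negative-projecting (orthogonal-preferring) channels
inflates that projection even with a flat pool, masking the control's
effect.

## Problem sizes and design choices in the tests

Unit tests run on 48×48 maps (8 mm field, keeping the columnar band below
Nyquist) with noiseless renders wherever the property is analytic, and
seeded noise where it is statistical. The closed-loop recovery checks run
at the full 128×128 default with 4 background-only trials per orientation
and 500 behavioral trials per orientation for the masking-curve recovery —
enough for the stated tolerances (heading within one bin; A within ±0.3) —
and the F-test type-I rate uses 1000 null simulations. The pipeline
determinism check uses a reduced session (6 orientations × 4 trials) and
asserts byte-identical JSON summaries across repeated runs.

## Known limitations

* The generator's noise amplitudes, columnar modulation depth and response
  gain are assumptions; absolute decoder outputs are meaningful only in
  the modified z-score units, not in physical dF/F.
* The motion estimator assumes one global translation per frame; the
  separable coupling absorbs static non-rigid structure but not
  time-varying distortions.
* `lambda(x)` for oblique target/background phase interactions is a
  modeling construction (above), not an empirical quantity.
* Per-frame correlation significance is uncorrected across frames.
* The masking fit is on signed orientation by default; pass absolute
  orientations to pool clockwise/anticlockwise disparities (mirrored
  pooling of trajectories is likewise left to the caller).
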