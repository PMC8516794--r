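---
title: "Analysing a day-long ear-EEG auditory oddball: models, pipeline and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing a day-long ear-EEG auditory oddball}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(earp3)
library(dplyr)
```

## The scientific setting

`earp3` implements the complete analysis chain for an auditory oddball
experiment recorded with around-the-ear EEG (cEEGrid) across a full workday.
Two task variants alternate over five blocks: a **rapid** oddball (inter-trial
interval uniform on 0.5–0.9 s, about nine targets per minute, completed seated
in ~5.5 minutes) and a **sporadic** oddball (inter-trial interval uniform on
56.2–61.2 s, one target per 3.33 minutes on average, performed while the
participant goes about office work). Each block presents 160 scored double
tones — 112 standards and 48 targets — where the stimulus is a 700 ms tone, a
100 ms gap and a 500 ms tone sharing one fundamental. Only targets require a
response.

Because no recordings ship with the package, a first-class synthetic-session
generator produces EEG, gyroscope, event and behavioural streams with the
statistical structure the analysis assumes, so every stage of the pipeline is
testable end to end and the mixed models can be validated by
simulation-refit parameter recovery.

## Generative models

### Behaviour

Reaction times follow an inverse-Gaussian GLMM with an **inverse link**: the
link-scale linear predictor is
$\eta = \beta_0 + u_{0i} + (\beta_1 + u_{1i})\,x$, with $x$ the sporadic
indicator, and the response-scale mean is $1/\eta$. Defaults are
$\beta_0 = 0.91$, $\beta_1 = -0.39$ (so rapid mean RT $1/0.91 \approx 1.10$ s
and sporadic $1/0.52 \approx 1.92$ s), with independent by-participant random
intercepts and slopes (SD 0.05 each on the link scale — deliberately small,
since the recovery checks target the fixed effects) and shape
$\lambda = 6.9$, which puts the RT coefficient of variation near 0.4; no
dispersion estimate is available to pin this more precisely, so it is a fixed
package choice. Misses follow a binomial GLMM with logit link,
$\beta_0 = -3.31$ (rapid miss chance $\approx 3.5\%$), $\beta_1 = 1.15$, and
independent random effects with SD 0.25 — a plausible inter-individual spread
on the logit scale.

### EEG

Every stimulus adds a stereotyped response on the **vertical bipolar cEEGrid
channel** `mean(R2, R3) − mean(R6, R7)`: an early negative Gaussian component
(peak 150 ms, SD 25 ms, −1 µV) and a positive P3-like Gaussian (SD 70 ms)
peaking at 312 ms (rapid) or 384 ms (sporadic). The P3 gain is solved in
closed form so that the template's mean over *peak ± 100 ms* equals the
configured window-mean amplitude exactly — 1.07 µV for rapid standards with a
+1.75 µV target increase, and 1.63 µV / +1.20 µV for sporadic — making
noise-free window means exact by construction. Channel loadings place +0.5 on
R2/R3 and −0.5 on R6/R7 (their left homologues mirrored, a linear gradient
elsewhere), so the bipolar contrast reproduces the template at unit gain; only
the contrast is constrained by the target values, per-channel amplitudes are
free parameters. The background is 1/f ("pink") noise at 4 µV RMS per channel
plus 25%-RMS white sensor noise, a realistic level for filtered ear-EEG.

What this generator does **not** emulate: ocular or cardiac artifact
morphology, inter-channel noise correlation beyond the shared ERP topography,
non-stationary daily-life noise, or real electrode drift. Passing tests
therefore demonstrate that the pipeline recovers what it assumes, not that it
is robust to everything real data contain.

### Movement

The gyroscope stream is a three-state semi-Markov process (still / fidget /
ambulatory; exponential dwell times of 30 / 4 / 20 s) scaling the per-axis
angular-rate SD by 1, 6 and 12. Rapid blocks draw states at 95/5/0%
occupancy, sporadic blocks at roughly 78/10/12%, and the last sporadic block
carries one long forced ambulatory "lunch" bout (20% of the block). These
occupancies were calibrated once so that the fraction of samples below the
individual movement-free threshold comes out near 95% in rapid and 75% in
sporadic blocks, the regime the analysis is designed for. Units are deg/s at
the EEG clock rate; all downstream thresholds are scale-equivariant, so the
unit convention is immaterial.

## The cleaning chain

`clean_recording()` runs a fixed order: zero-phase low-pass (10 Hz, order
330) → zero-phase high-pass (0.1 Hz, order 8250) → flatline channel detection
(runs ≥ 60 s; strict) → ASR burst correction (burst criterion 20) → amplitude
(±500 µV) and spectral (2 SD) channel rejection → block discard or
spherical-spline interpolation.

Numerical choices worth knowing:

* **Filters** are Hamming-windowed sinc kernels built directly from the ideal
  impulse response, normalised to unit DC gain; the high-pass is the spectral
  inversion of the complementary low-pass, so its DC gain is exactly zero and
  both are linear-phase. Group delay is removed after FFT convolution. A
  recording shorter than the high-pass kernel (33 s at 250 Hz) falls back to
  channel-mean removal, the DC limit of the same filter.
* **Flatline tolerance** is an absolute successive-difference bound of
  10⁻⁶ µV; the criterion is strict (a 59-s run at the 60-s setting passes).
  Because the high-pass kernel spans ±16.5 s, a flat segment is eroded by up
  to the kernel half-width before detection; segments comfortably longer than
  60 s (as hardware faults are) are still caught.
* **Amplitude criterion**: a channel is bad when |x| exceeds 500 µV in more
  than 0.1% of samples (the aggregation is configurable; a single clipped
  sample should not kill a channel).
* **Spectral criterion** z-scores band-averaged log power over 1–10 Hz —
  the band that actually carries power after the 10 Hz low-pass.
* **ASR** is implemented from its definition: principal axes of the (mean)
  calibration covariance, per-component sliding-window RMS thresholds at
  mean + 20 SD, per-window eigendecomposition with the threshold ellipsoid
  projected onto the window's axes, and flagged directions reconstructed from
  the retained ones via the calibration covariance (conditional-expectation
  subspace projection), with Hann-weighted overlap-add. Windows with no
  flagged direction pass through unchanged, and a run that never flags
  returns the input bit-for-bit. It is validated by behavioural invariants —
  near-identity on clean data, ≥50% RMS suppression of planted bursts — not
  by numerical equality with any other implementation. Calibration uses each
  block's designated 1-minute rest segment; absent that, an automatic
  clean-window heuristic (windowed log-power z-scores within [−3.5, 5.5]).
* **Spherical interpolation** uses the Perrin spline (order m = 4, series
  truncated at degree 7, ridge 10⁻⁸) on idealized unit-sphere cEEGrid
  coordinates shipped with the package (`ceegrid_coords()`); these are
  synthetic stand-ins, as no digitised positions exist for this montage.
* The block-discard rule fires when bad channels reach half the montage or
  fewer than four survive; ASR's channel, line-noise and window criteria are
  deliberately disabled.

## Epochs, rejection and P3 scoring

Epochs span the half-open interval [−0.2, 0.8) s — exactly 250 samples at
250 Hz, a choice the endpoint convention leaves open — and are
baseline-corrected on [−0.2, 0) s. The first two scored epochs of every block
and missed targets are excluded (only the missed target's own epoch, not its
neighbours). Joint-probability rejection estimates each channel's pooled
value distribution with a fixed 100-bin histogram, scores each epoch by its
summed log bin probability, and rejects at |z| > 2 locally (any channel) or
globally (channel mean), in a single pass.

The P3 window is *peak ± 100 ms*, with the peak defined as the **maximum**
(the P3 is a positivity; ties break to the earliest latency) of the
per-condition grand-average bipolar waveform inside 200–600 ms. The grand
average pools both tone roles — that is what "per-condition" means here, and
it matters: with the sporadic design's sparse targets, a target-only average
estimates the peak too noisily and the resulting window misalignment
attenuates every downstream amplitude. Per-participant averages enter the
grand average with equal weight regardless of trial counts; the mixed model
downstream is what accounts for unequal trials.

One property of the rejection stage is worth stating plainly, because the
tests quantify it: on strongly bimodal synthetic data (large target increase
relative to noise) the joint-probability criterion trims extreme *target*
epochs preferentially, attenuating the fitted target–standard contrast by
roughly 5–10%. This is inherent to the rule, not a defect; the
construction-oracle invariant for the ERP chain is therefore checked with the
rejection stage disabled (`recover_erp(..., jointprob = FALSE)`), while the
headline recovery runs keep it, as the original analysis did.

## Statistics

`fit_glmm()` wraps lme4 behind a single two-level-contrast interface:
inverse-Gaussian/inverse for RT, binomial/logit for misses,
Gaussian/identity (ML, via `lmer`) for ERP amplitudes, with a random
intercept and an **independent** by-participant random slope by default —
the correlated structure exists but is non-identifiable at n = 8 for the ERP
model, and the behavioural covariance structure is not pinned down by
anything stronger, so independence is the default everywhere. Singular or
non-converged fits are flagged, never silently refit. Wald χ² is
(β̂/SE)² on 1 df; `compare_models()` ranks by log-likelihood and applies
likelihood-ratio tests only to nested pairs (same family and link), flagging
the rest. `rm_anova()` is the classical one-way within-subject decomposition
with generalized eta squared
$\eta_G^2 = SS_{effect}/(SS_{effect}+SS_{subject}+SS_{error})$ and
Bonferroni-corrected pairwise paired t tests. The candidate set for RT model
comparison spans {inverse-Gaussian, gamma, Gaussian} × {inverse, identity,
log}; the full ranked table is reported rather than only a winner.

## Validation strategy and problem sizes

Three layers of tests back the package:

1. **Closed-form oracles**: window rule, Wald identities, displacement and
   threshold arithmetic, filter responses, noise-free ERP construction.
2. **Property suites**: ASR near-identity and burst suppression,
   planted-outlier joint-probability rejection, rejection-rate monotonicity,
   quantile monotonicity, seed determinism, round-trip persistence.
3. **Simulation-refit recovery** at the generative estimates: 100 replicates
   at n = 8 participants for the RT, miss and ERP models, each required to
   land within 3 Monte-Carlo standard errors of its generative value; plus a
   null simulation (500 replicates) checking the Wald test's size.

The full-pipeline ERP recovery simulates 8 participants per seed with the
four bipolar-relevant channels; rapid runs use the complete 160-trial design,
sporadic runs use 24 scored trials per block while keeping the true
56.2–61.2 s inter-trial distribution — a full sporadic block spans ~160 min
of continuous signal, and 24 trials (~24 min) already give every pipeline
stage realistic input while keeping a 100-seed run tractable. These sizes
are the package's validation design, stated here so results are read at the
right scale.

## Known limitations

* The ASR implementation uses the mean covariance and no spectral weighting;
  it is contract-equivalent, not numerically identical, to other tools.
* Electrode coordinates are idealized; interpolation accuracy on real
  digitised cEEGrid positions may differ.
* The generator's artifact menu (bursts, flatlines, broadband channels,
  transients) is deliberately stylized; detection thresholds tuned here
  should be re-examined on real recordings.
* XDF containers are not read; the documented native layout (float64 binary +
  JSON header + TSV events/gyro) is the canonical format.
* Reported epoch-rejection *percentages* depend on real-data artifact
  structure and are intentionally not asserted against any external value.
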