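---
title: "Estimating intraoperative nociception from ECG, PPG and EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating intraoperative nociception from ECG, PPG and EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Under general anesthesia a patient cannot report pain; what remains is
*nociception* — the physiological response to noxious stimuli such as tracheal
intubation, skin incision and extubation. Anesthesiologists titrate analgesia
against indirect signs (heart rate, blood pressure, drug dosing), and several
single-source indices exist (the Surgical Pleth Index from PPG, the Analgesia
Nociception Index from heart-rate variability), but each is confounded by
non-nociceptive autonomic activity. `nocipipe` implements a multimodal
alternative: eight features drawn from three simultaneously recorded signals —
ECG, photoplethysmography (PPG) and a single frontal EEG channel — feed small
neural regressors trained against expert nociception assessments (NOA, a
0–100 score), and the resulting index is evaluated for agreement, for its
response at standardized surgical events, and for event discrimination (ROC).

Because no public recording of this kind exists, the package ships a
first-class synthetic operating-room simulator with complete ground truth, so
that every stage — peak detectors, band extraction, normalization, training,
evaluation — is testable end to end.

## Signal processing and the feature matrix

All channels are analyzed on a common sliding grid: **64 s windows advanced
in 5 s steps** (consecutive windows share 59 s), each window identified by its
end time; sample indexing is half-open `[start, end)` and 0-based in time.
Eight features are produced per window:

| channel | source | definition |
|---|---|---|
| `delta`…`gamma` | EEG | in-band spectral power, five bands: 0.5–3.5, 4–7.5, 8–12, 13–30, 30.5–48 Hz |
| `rrhf_ps` | ECG | spectral power of the 0.15–0.5 Hz (high-frequency) RR component |
| `ppga` | PPG | pulse-wave amplitude trend (16 s moving average of per-beat amplitudes) |
| `ppg_auc` | PPG | trapezoidal area of the rectified, band-passed waveform per window |

The processing chain:

* **R peaks** — classical Pan–Tompkins stages (5–15 Hz band-pass, derivative,
  squaring, 150 ms moving integration, adaptive dual thresholds with
  search-back), 200 ms refractory, with the final peak refined against the
  band-passed ECG.
* **RRHF** — the RR tachogram is cubic-interpolated to a uniform 4 Hz grid
  (the HRV-community convention; the dyadic wavelet bands then straddle the
  HF band), decomposed with a periodized Daubechies D4 filter bank, and
  rebuilt from detail levels d3 (0.25–0.5 Hz) and d4 (0.125–0.25 Hz); a
  zero-phase 0.15–0.5 Hz Butterworth band-pass removes the residual leakage
  of the dyadic split. Whether to transform the uneven RR series directly or
  a resampled tachogram was an open choice; resample-first is simpler to
  analyze and is what the tests certify.
* **Power estimation** — every 64 s window is split into four non-overlapping
  16 s subsegments; each is tapered with a Kaiser window (shape β = 5, a
  near-Hamming sidelobe compromise) and its periodogram summed over the band
  of interest; the four estimates are averaged on the linear scale and then
  converted to dB (`10·log10`, floored at −120 dB relative to unit variance).
  Linear-then-dB averaging was chosen over averaging dB values because power
  is additive on the linear scale.
* **PPG** — Chebyshev II fifth-order 0.5–8 Hz band-pass (20 dB stopband
  design), applied zero-phase as a high-pass/low-pass cascade for numerical
  stability at the 0.5 Hz edge; peaks via AMPD (automatic multiscale-based
  peak detection) with the comparison scale capped at 2 s to bound memory,
  and scale ties resolved toward the largest scale, which suppresses
  sub-beat ripples.

Windows with incomplete coverage of any channel are dropped, never imputed.

## Online normalization

Feature scales differ widely between patients, and at surgery start nothing is
known about the current patient. Each channel is therefore mapped through a
blend of a **group reference** (pooled training-split patients — training-split
only, to keep held-out evaluation leakage-free) and the patient's own
**accumulated** samples. The individual weight follows

$$w(t) = 0.7\,\min(t/600\,\mathrm{s},\,1),$$

i.e. the group transformation starts at 100 % weight and hands over linearly
until 10 minutes of individual data exist; thereafter the weights are fixed at
0.7 (individual) / 0.3 (group). Elapsed time is wall-clock seconds since the
first analysis window. The accumulated pool is updated *before* normalizing
the current value, so the current sample is always a member of its own pool.

Three maps are provided. With $F$ an empirical cdf (mid-rank convention,
linearly interpolated between order statistics, clamped to $[0,1]$ outside the
pool):

* **histogram**: $X = w\,F_{\text{ind}}(x) + (1-w)\,F_{\text{grp}}(x)$
* **z-score**: $X = w\,\frac{x-\mu_{\text{ind}}}{\sigma_{\text{ind}}} + (1-w)\,\frac{x-\mu_{\text{grp}}}{\sigma_{\text{grp}}}$
* **min–max**: the analogous blend of min–max maps, clipped to $[0,1]$
  (early-surgery values outside the group range would otherwise leave the
  range the regressors were trained on).

Degenerate individual pools are guarded: a zero-spread pool contributes 0 to
the z-score blend and mid-scale 0.5 to the min–max blend, with a warning. The
offline ("perfect") reference uses the complete series as the individual pool
with $w$ fixed at 0.7; methods are scored by comparing their online pass to
this reference via MAE and Pearson correlation, each min–max-rescaled across
the candidate methods (MAE inverted) and averaged into a percentage score.
The cross-method rescaling is the one under-specified step of that score; a
plain min–max over the compared methods is used.

```{r}
library(nocipipe)
bundle <- simulate_session(session_spec(duration_s = 900, seed = 1))
feats  <- build_feature_matrix(bundle$ecg, bundle$ppg, bundle$eeg)
group  <- group_reference(list(feats))
score_normalization_methods(feats, group)
```

## Rater assessments

Multiple experts score the same case with different start/stop times, personal
bias and spread. The panel is synchronized to $[L, U]$ = [latest start,
earliest end], resampled to the 5 s grid by previous-value interpolation
(assessments are event-anchored annotations, not continuous measurements), and
screened: a one-way ANOVA across raters plus a per-rater Holm-adjusted test
against the pooled remainder flags systematic outliers. Flagged raters are
*candidates* for exclusion; dropping them requires the explicit
`drop_flagged = TRUE` switch so the decision stays auditable. Agreement is
quantified by ICC(2,1) — two-way random effects, absolute agreement, single
rater, the variant appropriate for a fixed panel scoring the same subjects —
with a McGraw–Wong F-based confidence interval, and by pairwise Bland–Altman
bias, SD and 95 % limits of agreement. The consensus target is the pointwise
mean of the retained raters.

## Models

Both regressors consume the normalized 8-channel matrix and predict the scaled
consensus score (score/100; the 0–1 scale keeps the MSE loss in a numerically
comfortable range):

| | hidden layers | batch | epochs | learning rate | optimizer | output |
|---|---|---|---|---|---|---|
| MLP | 50 / 30 (ReLU) | 125 | 50 | 0.001 | Adam | ReLU |
| LSTM | 100 / 200 (sigmoid gates) | 256 | 50 | 0.0001 | Adam | ReLU |

The MLP sees one window at a time; the LSTM sees sliding sequences of 5
consecutive windows (stride 1, stateless across batches) and predicts at the
last window, so its first prediction lags the MLP's by four steps. Training
runs a fixed 50 epochs without early stopping; the LSTM additionally clips the
global gradient norm at 1.0 as a stability guard. Splits are always by
patient, never by window. Both networks and backpropagation (through time for
the LSTM) are implemented in base-R matrix code and are finite-difference
gradient-checked in the test suite; training is deterministic under the
configuration seed. Predictions are rescaled to 0–100 and clipped.

## Evaluation

* **Regression**: MAE, MSE, Pearson r, $R^2$ per held-out patient.
* **Event response**: for each of intubation (t1), incision (t2) and
  extubation (t3), the prediction mean over the 180 s before versus after the
  event (a one-window, 5 s guard gap around the instant is excluded from both
  sides, so the transition itself is never labeled), the difference of means
  with its standard error, and a two-sided Mann–Whitney U test per event.
  The 180 s span is a package default, exposed in the configuration.
* **ROC**: pre-event points labeled 0, post-event 1, pooled across a
  patient's events; AUC via the rank statistic with mid-rank ties; one curve
  and AUC per patient, summarized by the mean. Fully tied traces yield
  AUC 0.5; single-class labelings are reported as undefined.
  F1/precision/recall are deliberately not computed.

## The synthetic simulator

`session_spec()` fixes the study conditions; `simulate_session()` renders one
"patient". The simulator emulates exactly the properties the pipeline
measures, with ground truth returned for each:

* a **latent nociception trace** on the 0–100 scale: baseline plus, per
  surgical event, a smoothed step (30 s linear rise, exponential decay with a
  300 s time constant — sustained but fading post-stimulus elevation) plus a
  slow AR(1) drift;
* **ECG**: Gaussian-derivative QRS complexes (morphology is irrelevant
  downstream; only R timing matters) whose RR intervals carry a sinusoidal
  0.15–0.5 Hz modulation, amplitude mildly suppressed by nociception;
* **PPG**: one skewed Gaussian pulse per beat; peak amplitude couples
  *negatively* and pulse width (hence waveform area) *positively* to the
  trace, so the amplitude and area features are separable. The default
  couplings (−0.15 amplitude, +0.7 width) were calibrated once, at design
  time, so that the extracted PPGA and PPG-AUC channels carry the intended
  opposite signs after band-pass filtering — filtering makes the rectified
  area sensitive to amplitude as well, so the raw coupling signs alone do
  not determine the feature signs;
* **EEG**: five band-limited noise processes; delta and gamma power rise
  with the trace, alpha falls, theta and beta stay flat;
* **raters**: trace + per-rater bias + Gaussian noise, clipped to the scale,
  randomly truncated at both ends (up to 30 s by default) to exercise the
  synchronizer. Default biases {−2, −1, +2, +5} and spread 6 reproduce
  pairwise difference SDs near $6\sqrt{2} \approx 8.5$, the magnitude
  reported for real expert panels.

One session seed fans out to per-channel substreams, so identical
specifications yield bit-identical bundles and individual channels can be
regenerated independently.

**What the simulator does not model** — and hence what passing tests do *not*
establish about clinical data: pharmacokinetics, arrhythmia, motion and
electrocautery artifacts, multi-lead/multi-channel montages, non-Gaussian
rater behavior, and any realistic coupling strength between physiology and
expert scores. The end-to-end recovery results certify that the pipeline is
self-consistent (signals generated with known couplings are recovered), not
that the clinical effect sizes are attainable.

## Study conditions and problem sizes

The packaged end-to-end study (used by the acceptance script and the
heaviest test) simulates **25 patients of 30 minutes each** — 20 training, 5
held-out — with events near 300/900/1500 s (±30 s jitter), a latent step of
15 score points per event, baseline 45, and per-patient heart rates drawn
from 55–90 bpm. These sizes give each patient ~348 analysis windows and the
training split ~7000 supervised pairs, enough for stable training while
keeping a full run in the minutes range on one core. The nociception scale
is taken as 0–100 throughout; the assessments and reported errors in the
motivating literature are consistent with that scale, though it is nowhere
stated explicitly.

## Numerical choices and degenerate inputs

* Kaiser β = 5; dB floor −120 dB; subsegments non-overlapping.
* Flat ECG/PPG inputs return empty peak sets (with a warning), not errors.
* PPGA windows with no beats in their trailing 16 s are linearly interpolated
  from neighbours and flagged.
* The empirical cdf uses mid-ranks, so the group median maps to 0.5 exactly
  for odd pool sizes; values outside the pool clamp to 0/1.
* AMPD scale ties resolve to the largest tied scale.
* Mann–Whitney on fully tied samples reports p = 1.
* ICC with zero between-subject variance is reported as undefined rather
  than 0.

## Limitations

The regressors are intentionally small and the training protocol fixed; no
hyperparameter search is performed (the configuration is exposed for users
who want one). The EDF format common on physiological monitors is not read
directly — signals enter as columnar CSV with a metadata header. Agreement
statistics assume a complete panel (every retained rater scores every grid
point after synchronization). All validation is against synthetic sessions;
clinical deployment would require recalibration of the group reference and
retraining on real assessments.
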