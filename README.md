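# nocipipe

Multimodal estimation of intraoperative **nociception** — the physiological
response to noxious stimuli under general anesthesia — from three
simultaneously recorded signals: ECG, photoplethysmography (PPG) and a single
EEG channel. The package is aimed at anesthesia-monitoring researchers who
want a fully testable, end-to-end reference pipeline: every stage runs
against a bundled synthetic operating-room simulator with complete ground
truth, so no clinical data are required to exercise it.

## What it computes

Eight features on a sliding grid of 64 s windows advanced in 5 s steps
(59 s overlap), one value per window per channel:

* **delta, theta, alpha, beta, gamma** — EEG band powers (0.5–3.5, 4–7.5,
  8–12, 13–30, 30.5–48 Hz), each estimated as the average over four
  non-overlapping 16 s Kaiser-tapered subsegments, in dB;
* **rrhf_ps** — spectral power of the high-frequency (0.15–0.5 Hz) component
  of the RR-interval series, extracted by wavelet decomposition of the 4 Hz
  RR tachogram (R peaks via Pan–Tompkins);
* **ppga** — PPG pulse-wave amplitude trend (AMPD peak detection on the
  Chebyshev-II 0.5–8 Hz filtered waveform, 16 s moving average);
* **ppg_auc** — area under the rectified filtered PPG per window.

Each channel is normalized online by blending a group reference with the
patient's accumulating statistics,

X_norm = w·T_individual(x) + (1 − w)·T_group(x),  w = 0.7·min(t/600 s, 1),

where T is an empirical-cdf (histogram), z-score or min–max map. Two
regressors — an MLP (hidden layers 50/30) and a stacked LSTM (100/200,
sequences of 5 windows) trained with Adam for 50 epochs on expert consensus
nociception assessments (NOA, 0–100) — produce the index, which is evaluated
by regression metrics, before/after analysis at the surgical events
intubation (t1), incision (t2) and extubation (t3) with Mann–Whitney tests,
and per-patient ROC discrimination of those events. Inter-rater agreement is
quantified with ANOVA screening, ICC(2,1) and pairwise Bland–Altman limits
of agreement.

## Worked example

```r
library(nocipipe)

bundle <- simulate_session(session_spec(duration_s = 900, seed = 1))
#> <session_bundle> 900 s session, 4 raters, 3 events, seed 1

feats <- build_feature_matrix(bundle$ecg, bundle$ppg, bundle$eeg)
# 168 windows x 8 channels

agree <- agreement_report(bundle$raters)
#> <noci_agreement> [L, U] = [10, 875] s, 4 raters (4 kept)
#>   ICC(2,1) = 0.436 [0.316, 0.545]

group <- group_reference(list(feats))
score_normalization_methods(feats, group)
#>      method    mae correlation mae_norm corr_norm score_pct
#> 1 histogram 0.0393       0.986    0.985     1.000      99.2
#> 2    minmax 0.0376       0.979    1.000     0.000      50.0
#> 3    zscore 0.1443       0.985    0.000     0.875      43.7

norm <- normalize_online(feats, group, "minmax")
fit  <- train_model(model_config("mlp", seed = 1),
                    make_dataset(norm, agree$consensus, "mlp"))
#> <noci_model> MLP (50/30), 50 epochs, final train loss 0.001628, R2 train 0.576

pred  <- predict(fit, norm)
trace <- tibble::tibble(time_s = pred$window_end_s, value = pred$prediction)
event_response(trace, bundle$events)
#>   label event_time_s mean_before mean_after difference    se  p_value
#> 1    t1          150        48.9       57.0       8.14 0.508 2.48e-11
#> 2    t2          450        57.0       59.5       2.49 0.520 3.61e-06
#> 3    t3          750        58.6       61.8       3.19 0.495 8.66e-08

roc_at_events(trace, bundle$events)
#> <noci_roc> AUC = 0.735 (87 pre / 99 post points)
```

Reading the numbers: the synthetic raters (bias −2…+5, spread 6) agree at
ICC 0.44 with each other; the three normalization candidates are scored by
closeness of their online pass to the offline (w = 0.7) reference. The
trained index rises by 8 points at the first event with p ≪ 0.01; the later
events sit closer together in this short 900 s session because the latent
trace is still elevated from the previous stimulus when the next one
arrives, which compresses the before/after contrast and the pooled AUC. The
packaged full-scale study (30-minute sessions, events 10 minutes apart)
separates events much more cleanly.

A full synthetic study — 25 patients, 20/5 patient-level split, both models,
normalization, event analysis and ROC — is one call:

```r
report <- run_pipeline(pipeline_config(seed = 1))
report$summary
```

`autoplot()` methods exist for feature matrices, fitted models and ROC
curves; `plot_bland_altman()` and `plot_event_response()` cover the
agreement and event analyses. A thin command-line front end with
`simulate / extract / normalize / agree / evaluate / run` subcommands is in
`inst/cli/nocipipe.R`.

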