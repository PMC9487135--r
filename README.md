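# rppgfilter

Recurrent (LSTM) deep filtering and quality assessment for remote
photoplethysmography (rPPG) signals.

Camera-based pulse measurement extracts a 1-D blood-volume-pulse trace from
skin-color variations in video. The trace is noisy (sensor noise,
illumination drift, motion), and the classical remedies — bandpass
filtering over the cardiac band, wavelet sub-band denoising,
Savitzky–Golay smoothing — remove out-of-band energy but leave in-band
alterations that corrupt heart-rate estimates and pulse-shape analysis.
This package implements a sequence-to-sequence LSTM *deep filter* for such
traces, the classical baselines it is compared against, the standard
signal-quality metrics of the field, a synthetic corpus generator, and
subject-independent evaluation protocols. It is aimed at researchers in
camera-based vital-sign measurement who work with already-extracted 1-D
traces (video processing is out of scope).

## The model

An $L$-sample window (default $L = 125$, 5 s at 25 Hz) slides over the
trace with step 1. Three stacked LSTM layers ($3 \times 125$ units, tanh)
feed one linear output unit:

* **MTO (many-to-one)** forecasts the next clean sample from the preceding
  window:
  $\hat y_{[j]} = y_{[j]}$ for $j \le L$ (passthrough), and
  $\hat y_{[j]} = \varphi_o(y_{[j-L:j-1]}; \theta)$ for $j > L$.
* **MTM (many-to-many)** denoises each window whole,
  $\tilde y(j) = \varphi_m(y_{[j:j+L-1]}; \theta)$, and rebuilds the trace
  by overlap-add over all covering windows,
  $\hat y_{[j]} = \sum_{l,\,j-l+1>0}^{L} \tilde y(j-l+1)_{[l]}$
  (averaged over the per-position contribution count by default, so
  amplitudes are preserved).

Training minimizes MSE with Adam (staged learning rate
0.002 / 0.001 / 0.0005 / 0.0001 at epochs 1–10 / 11–20 / 21–50 / 51+,
batch 32, dropout 0.2 on the first two layers, Glorot-uniform init). The
LSTM forward pass and backpropagation through time are implemented in
single-precision RcppArmadillo — no external deep-learning runtime.

Quality is quantified per recording by four metrics: window-wise
heart-rate MAE (bpm) and Pearson *r* against the contact ground truth
(15-s windows, 0.5-s step, FFT peak in 0.7–3.5 Hz), harmonic-band SNR
(dB), and template match correlation (TMC, pulse-shape uniformity).

## Worked example

```r
library(rppgfilter)

# a 0 dB synthetic corpus: 12 pairs of (noisy rPPG, clean reference)
corp <- generate_corpus(
  12,
  default_config_sampler(snr_mean_db = 0, snr_sd_db = 0,
                         duration_range_s = c(30, 30)),
  seed = 1
)
pairs <- lapply(corp$pairs, preprocess_pair)

# train a small many-to-many filter on 10 pairs, hold out 2
cfg <- train_config(units = 32, L = 125, stride = 5, epochs = 5, seed = 1)
ws  <- build_training_set(pairs[1:10], "mtm", cfg)
model <- train_deep_filter(build_model("mtm", cfg), ws)

p <- pairs[[11]]
filtered <- apply_mtm(model, p$rppg)
evaluate_pair(p, filtered)
#> <quality_report> S011: MAE 0.36 bpm, r 0.680, SNR 1.79 dB, TMC 0.813 (29 windows)
snr_db(p$rppg, ref_hr = hr_series(p$gt))   # the unfiltered input
#> [1] -0.2561007
```

The report reads: on the held-out recording the filtered trace estimates
heart rate to 0.36 bpm of the reference, raises the harmonic-band SNR
from about 0 dB (the corpus target) to 1.8 dB, and pulls the pulse-shape
uniformity (TMC) up to 0.81 — with only a desk-scale model and five
epochs. The full-scale recipe is the default `train_config()`.

A command-line front end wrapping the same functions ships at
`system.file("cli", "rppgfilter", package = "rppgfilter")` with
subcommands `synth`, `preprocess`, `train`, `filter`, `evaluate`,
`experiment`.

## Package layout

| | |
|---|---|
| `rppg_signal`, `signal_pair`, CSV I/O | containers and plumbing |
| `resample_signal`, `align_pair`, `preprocess_pair` | 25 Hz alignment, detrend, [-1, 1] scaling |
| `generate_clean_pulse`, `corrupt_to_snr`, `generate_corpus` | synthetic corpora with closed-loop SNR targeting |
| `bandpass`, `wavelet_denoise`, `savgol` | classical baselines |
| `build_model`, `train_deep_filter`, `apply_mto`, `apply_mtm` | the deep filter |
| `hr_series`, `mae`, `pearson_r`, `snr_db`, `tmc`, `evaluate_pair` | metrics |
| `subject_kfold`, `stratified_fraction`, `quality_groups`, `run_experiment` | protocols |

See the vignette (`vignettes/rppg-deep-filtering.Rmd`) for the model,
metric definitions, generator design and known limitations.
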