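# movemux

Analysis pipeline for simultaneous behavioral-video and fiber-photometry
recordings from head-fixed mice, built around three questions about a bulk
neural population signal (here, hypothalamic hypocretin/orexin neurons
recorded with GCaMP6s):

1. **Does the signal track the instantaneous magnitude of body movement?**
   A video-derived *movement metric* — the summed absolute per-pixel
   difference between consecutive frames, convolved with a 60 s exponential
   kernel whose half-life matches the indicator (1.796 s), then z-scored —
   is compared with the preprocessed photometry trace by whole-session
   Pearson correlation, cross-correlation lag, and mixed-effects model
   comparison (behavior labels vs movement as predictors, ranked by AIC).
2. **Do movement and blood glucose occupy distinct frequency bands of the
   same signal?** The signal is decomposed by empirical mode decomposition
   (EMD) into intrinsic mode functions (IMFs); each IMF
   `IMF_n = β0 + β1·(glucose derivative) + β2·(movement) + ε` is fit by
   OLS and the weights binned by characteristic frequency (0.01–0.1 Hz vs
   < 10⁻³ Hz).
3. **Is movement phase-aligned to the signal's oscillations?** Per-IMF
   instantaneous phase (normalized Hilbert transform, crest at π/2) is
   summarized by the weighted first trigonometric circular moment, with
   weights from the positive ("active") or negative ("quiescent") part of
   the z-scored movement metric.

Supporting modules cover photometry preprocessing (first-minute trim,
triple-exponential bleaching subtraction, z-scoring, isosbestic QC),
movement-bout detection with k = 2 k-means size clustering, behavior-label
smoothing and transition analysis, pupillometry (Nelder-Mead circle fits to
confident landmarks, blink interpolation), PLS drop-one feature
contributions, and a synthetic-session generator with known ground-truth
coupling so the entire chain is testable without any recordings.

## Worked example

```r
library(movemux)

s  <- generate_session(session_params(seed = 1))        # 20 min @ 20 Hz
mt <- movement_metric(s$motion_raw, gcamp_kernel(fs = 20), 20)
ph <- preprocess_photometry(s$photometry$signal, s$photometry$isosbestic, 20)

session_correlation(ph$signal, mt$values)
#> [1] 0.904
crosscorr_lag(ph$signal, mt$values, 20)
#> $lag_s  [1] 0      # negative would mean photometry precedes movement
#> $peak_r [1] 0.904

b <- cluster_bouts(detect_bouts(mt), mt)
nrow(b); table(b$cluster)
#> [1] 32
#> large small
#>    24     8

is_ <- exclude_slow_imfs(sift(ph$signal, 20))
is_
#> <imf_set> 9 IMFs over 22800 samples @ 20 Hz
#>  imf char_freq_hz power_pct
#>    5      0.05150     36.42   # max power in the 0.1-0.01 Hz band
#>    6      0.02570     28.10
#>    7      0.01100     22.73   # (other rows omitted)
k <- max_power_imf(is_)
phase_preference(is_$phase[k, ], mt$values, "active")
#> $preferred_phase 1.56   # ~pi/2: movement at the oscillation crest
#> $coupling_strength 0.46
```

The correlation of 0.90 reflects the generator's unit movement gain and low
noise; the max-power IMF falls in the 0.1–0.01 Hz band where the bout
process concentrates its energy; and the active-epoch preferred phase near
π/2 says movement coincides with the crest ("upstate") of the dominant
signal oscillation.

`run_pipeline(run_config(seed = 1))` chains every stage (simulate → metric →
preprocess → emd → bouts → behavior → pupil → analyze) and stamps the result
bundle with a configuration hash for reproducibility.

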