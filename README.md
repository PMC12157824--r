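# radmotion

Markerless human-motion classification from continuous-wave (CW) radar
micro-Doppler signatures, trained once with optical motion-capture markers.

## The problem

Optical motion capture tracks reflective markers with millimetre accuracy,
but markers hinder natural movement and camera rigs are expensive and
immobile. A CW radar sees the same movement without markers: every body part
at range $r_i(t)$ contributes the baseband phasor
$A_i e^{-j4\pi r_i(t)/\lambda}$, and limb micro-motions frequency-modulate
the return (the micro-Doppler effect). `radmotion` implements a hybrid
protocol for exercise recognition (squat, lunge, front kick, front lateral
raise, arm curl): marker coordinates are used **only during training** to
build per-marker reference signals; test motions are classified from the
radar signal alone.

## The method

1. **Basis functions.** Marker $k$'s range history gives the unit-modulus
   reference $b_k(t) = e^{-j4\pi r_k(t)/\lambda}$.
2. **Features.** For a signal window $s(t)$ of length $T$, feature $k$ is
   the maximum circular cross-correlation amplitude
   $A_k = \max_\tau |\frac1T \sum_t s(t)\, b_k^*(t-\tau)|$, computed by FFT;
   a basis-matched signal of amplitude $A$ returns exactly $A$, and cross
   terms from other periodic scatterers average out.
3. **Training database.** Each 4-s recording is clipped into 1.2-s windows
   every 0.02 s (140 per class); window features form an
   $N_c \times N_{tr}$ matrix, min-max normalized per feature.
4. **Compression + decision.** PCA keeps $d$ dimensions (4 by default —
   0.07% of a 6000-sample window); a 1-nearest-neighbour rule on Euclidean
   distance assigns the class.

The package also ships the synthetic study conditions: a seeded generator of
sinusoidal marker micro-motions for the five classes, the CW baseband
simulator with AWGN injection, spectrogram rendering, and an experiment
harness (SNR × dimension grids, training-stride and window-length sweeps,
and robustness studies: time scaling, two-motion mixtures, amplitude/phase
perturbation). See the vignette
`vignettes/radar-motion-classification.Rmd` for the model, parameter
choices and limitations.

## Worked example

```r
library(radmotion)
# one synthetic subject at desk scale: 12 markers, 1 kHz baseband
cfg <- experiment_config(n_markers = 12, rate = 1000, dt_tr = 0.1,
                         n_test = 20, snr_db = c(0, 10), seed = 7)
db <- build_synthetic_db(cfg, seed = 7)        # train: 5 classes x 28 windows
print(db)
#> <training_db> 12 features x 140 segments, 5 classes, PCA d = 4
grid <- run_snr_d_grid(cfg, dims = c(3, 4), seed = 7)
print(grid$results)
#>   snr_db d   Pc
#> 1      0 3 0.95
#> 2      0 4 0.98
#> 3     10 3 0.97
#> 4     10 4 0.99
print(grid$confusions[["snr0_d3"]])
#>      predicted
#> truth  1  2  3  4  5
#>     1 18  2  0  0  0
#>     2  1 19  0  0  0
#>     3  0  0 20  0  0
#>     4  2  0  0 18  0
#>     5  0  0  0  0 20
res <- validate_residual(n_trials = 10, seed = 7)
cat(sprintf("residual check: mean A1 = %.4f, max |Rs| = %.4f\n",
            mean(res$A1), max(res$Rs_abs)))
#> residual check: mean A1 = 2.0165, max |Rs| = 0.1408
```

Reading the output: accuracy `Pc` is the fraction of 100 noisy 1.2-s test
windows (20 per class) assigned their true exercise; it improves with SNR
and with the retained PCA dimension. In the 0 dB confusion matrix above the
few errors sit between squat and lunge (mutually) plus a couple of raises
drifting toward squat, while front kick and arm curl stay perfect.
The residual check recovers a matched scatterer's amplitude (truth 2) from a
four-scatterer sum with random micro-motions; the cross-scatterer residual
`|Rs|` stays far below the amplitude.

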