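# fwaver

Extraction of atrial fibrillatory waves (F-waves) from **single-lead** ECG
recordings by optimized resonance-based signal decomposition.

## The problem

During atrial fibrillation (AF) the P-wave disappears and a continuous
fibrillatory waveform — the F-wave, typically 3–12 Hz and a few tens of µV —
takes its place.  Its spectrum and amplitude carry clinically useful
information about AF type and recurrence, but on a single lead it is buried
under QRST complexes an order of magnitude larger that overlap it in both
time and frequency.  Multi-lead cancellation methods (spatiotemporal QRST
cancellation, ICA) do not apply to single-lead wearables, and beat-template
methods (average beat subtraction, beat-stacking PCA) break down on irregular
or ectopic beats.

`fwaver` is aimed at researchers in cardiac signal processing who need a
beat-alignment-free extractor plus the simulation and evaluation machinery
to study it.

## The method

The trace is modelled by morphological component analysis (MCA) as

    x = S1 W1 + S2 W2 + r,       minimize  ||x − S1W1 − S2W2||₂²
                                           + λ1 ||W1||₁ + λ2 ||W2||₁

where `S1` is the synthesis operator of a **high-Q** tunable Q-factor wavelet
transform (TQWT, Q = 6.42 by default) whose long oscillatory atoms sparsify
the sustained F-wave, and `S2` a **low-Q** TQWT (Q = 1.35) whose short atoms
sparsify the transient QRST complexes.  The objective is minimised by SALSA
(an ADMM-type solver; the Parseval-frame property of the TQWT makes the
data-consistency step exact), the F-wave estimate is `x̂_osc = S1 W1*`, and a
genetic algorithm can select the Q pair by maximising the kurtosis difference
between the transient and oscillatory components.  A parametric simulator
(sawtooth atrial model + synthetic ventricular beats + noise) provides ground
truth, and `abs_extract()` / `pca_extract()` provide the classical baselines.

Package tour:

| area | functions |
| --- | --- |
| transform | `tqwt()`, `tqwt_inverse()`, `tqwt_max_levels()`, `tqwt_wavelet_norms()` |
| decomposition | `dual_q_config()`, `resonance_decompose()`, `fwave_extract()`, `calibrate_regularization()` |
| Q optimisation | `ga_config()`, `run_ga()`, `ga_fitness()`, `kurtosis()` |
| simulation | `fwave_params()`, `gen_fwave()`, `gen_ventricular()`, `add_noise()`, `compose_record()` |
| evaluation | `rmse()`, `nmse()`, `welch_psd()`, `dominant_frequency()`, `spectral_concentration()`, `evaluate_extraction()` |
| baselines & I/O | `abs_extract()`, `pca_extract()`, `stack_beats()`, `write_record()`, `read_record()`, `run_benchmark()` |

A thin command-line front end (`inst/cli/fwaver`) exposes `simulate`,
`decompose`, `optimize-q`, `evaluate` and `benchmark` subcommands.

## Worked example

Simulate a 10-s AF record (8-Hz type-B F-wave on synthetic ventricular
beats), extract the F-wave, and evaluate it against the known truth:

```r
library(fwaver)

rec <- compose_record(fwave_params("B", "II"), noise_uV = 0, seed = 7)
rec
#> simulated AF ECG: 10 s @ 500 Hz, F-wave type B lead II
#>   12 beats (0 PVC), noise E|n| = 0 uV, seed 7

rms <- sqrt(mean(rec$x^2))
d <- fwave_extract(rec, dual_q_config(lambda_osc = 0.3 * rms,
                                      lambda_trn = 0.1 * rms, n_iter = 200))
evaluate_extraction(rec$fwave_truth, d$fwave, rec$fs)
#> F-wave extraction report:
#>   RMSE 32.4 uV | NMSE 0.942 | DF 3.00 Hz | SC 0.818
```

Reading the report: RMSE/NMSE compare the extracted waveform with the
simulated atrial truth in the time domain (NMSE = 1 is the score of an
all-zero estimate — single-lead F-wave extraction is a hard problem, and
published NMSE values for this task sit around 0.5–0.7); the dominant
frequency is the Welch-PSD peak in 3–10 Hz, ideally the simulated 8 Hz; the
spectral concentration is the fraction of extracted power in the 3–12 Hz
fibrillatory band.  The same record pushed through the baselines:

```r
rmse(rec$fwave_truth, abs_extract(rec, per_type = FALSE))
#> [1] 23.6
rmse(rec$fwave_truth, pca_extract(rec))
#> [1] 24.7
```

Reading the comparison: on a clean record with well-behaved beats, template
cancellation is competitive or better in the time domain; the proposed
method's advantage appears under added noise and ventricular premature
beats, where template cancellation degrades sharply while the morphological
decomposition barely moves — `run_benchmark()` reproduces exactly that
comparison, and the methods vignette
(`vignettes/fwave-extraction-methods.Rmd`) documents the models, parameter
choices and limitations in detail.

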