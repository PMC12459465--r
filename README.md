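# flimspine

Quantitative analysis of single-spine structural plasticity experiments:
two-photon FLIM-FRET binding-fraction estimation, ΔF/F₀ spine-volume time
courses, uncaging-locked sweep analysis of pH-sensitive reporter release,
and release-event statistics for TIRF recordings — together with a
synthetic-data generator so that every stage of the pipeline can be
validated against known ground truth without raw microscopy data.

The package is aimed at imaging labs analysing glutamate-uncaging
structural LTP (sLTP) experiments: TrkB FRET-sensor activation measured by
time-correlated single-photon counting (TCSPC), spine enlargement measured
as fluorescence change of a cytosolic marker, and vesicular release of
tagged cargo (e.g. superecliptic-pHluorin fusions) measured either as
uncaging-locked fluorescence transients or as discrete TIRF release
events.

## The models

**FLIM decay.** The donor fluorescence decay is a two-lifetime mixture
convolved with a Gaussian pulse response:

```
F(t) = F0 [ P_D  H(t, t0, τ_D,  τ_G) + P_AD H(t, t0, τ_AD, τ_G) ]

H(t, t0, τ, τ_G) = ½ exp(τ_G²/2τ² − (t−t0)/τ) · erfc((τ_G² − τ(t−t0)) / (√2 τ τ_G))
```

where `P_AD` is the fraction of donor bound to the FRET acceptor
(`P_D = 1 − P_AD`), `τ_D` the free-donor lifetime (fixed at 2.6 ns for
eGFP donors), `τ_AD < τ_D` the bound-donor lifetime, `τ_G` the instrument
timing width, and `t0` the arrival-time offset. `fit_decay()` maximises
the Poisson likelihood of the binned photon counts with `τ_D` held fixed;
`H` is evaluated in an erfc-stable form so it never overflows.

**Binding fraction from the mean lifetime.** For ROIs too small to fit,
the mean photon arrival time `⟨t⟩` gives the mean lifetime
`⟨τ⟩ = ⟨t⟩ − t0` and the closed-form estimator

```
P_AD = τ_D (τ_D − ⟨τ⟩) / [ (τ_D − τ_AD)(τ_D + τ_AD − ⟨τ⟩) ]
```

which is exact when photon yield is proportional to amplitude × lifetime.
Traces are reported as `P_AD − P_AD0` (baseline-subtracted), and cells
with a baseline binding fraction above 45% are excluded by
`qc_filter_cells()`.

**Volume and release.** `delta_f_over_f()` computes
`ΔF/F₀ = (F − F₀)/F₀` against the mean of the first five to seven
baseline points; `phase_averages()` summarises transient (1–3 min) and
sustained (9–11, 12–15 or 15–20 min) phases. The sweep module cuts a
7.8-Hz trace into 16-frame sweeps (2.048-s uncaging periods), normalizes
each sweep to its own first two frames, averages uncaging pulses 2–18
(sweeps 9–25 after 7 baseline sweeps) and quantifies the peak as the mean
ΔF/F₀ of the three frames after the pulse (0.128–0.384 s). The TIRF
module estimates basal vs. stimulated release-event frequencies and bins
release times in 10-s intervals over the 60-s stimulation window.

## Worked example

```r
library(flimspine)

truth <- decay_params(p_ad = 0.30, tau_ad = 1.3, tau_g = 0.2, t0 = 1)
h <- simulate_photon_histogram(truth, n_photons = 3e5, seed = 42)
fit <- fit_decay(h, tau_d_fixed = 2.6)
print(fit)
#> FLIM decay fit (mle, converged): 300000 photons, logLik = -938.6
#> FLIM decay parameters
#>   p_ad = 0.3038 (free fraction 0.6962)
#>   tau_d = 2.6 ns, tau_ad = 1.288 ns
#>   tau_g = 0.202 ns, t0 = 1 ns, f0 = 1.363e+05

binding_fraction_from_mean(mean_arrival_time(h) - fit$params$t0,
                           tau_d = 2.6, tau_ad = 1.3)
#> [1] 0.3061
```

Both estimators recover the simulated 30% binding fraction to within the
photon-noise limit. The end-to-end demonstration runs every stage on
synthetic data:

```r
res <- run_pipeline(analysis_config(seed = 1L))
#> [flim] whole-image fit: p_ad=0.188 tau_ad=1.303 t0=0.998 (converged)
#> [qc] 1/2 cells retained (threshold 0.45); excluded: cell2
#> [sweeps] SEP: mean paired diff 0.0480, p = 1.069e-08
#> [sweeps] Gamillus: mean paired diff 0.0018, p = 0.5078
#> [events] mean basal 0.037 Hz, stimulated 0.377 Hz, one-sided p = 7.17e-14
```

The SEP reporter shows a significant uncaging-locked excess over the
volume channel while the pH-stable Gamillus control does not, and the
stimulated release-event frequency rises detectably above the basal rate
— the qualitative contrasts the analysis is designed to resolve.

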