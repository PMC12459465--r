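---
title: "Methods: FLIM-FRET binding fractions and spine plasticity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: FLIM-FRET binding fractions and spine plasticity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flimspine)
```

This vignette documents the models, the numerical choices, and the design
decisions behind the package, in the order the data flow through the
pipeline.

## The FLIM decay model

Time-correlated single-photon counting of a FRET donor yields a histogram
of photon arrival times within one laser repetition period. When a
fraction $P_{AD}$ of donor molecules is bound to the acceptor, the decay
is a two-lifetime mixture, each component an exponential convolved with a
Gaussian instrument pulse response of width $\tau_G$:

$$F(t) = F_0\left[P_D\,H(t, t_0, \tau_D, \tau_G) +
  P_{AD}\,H(t, t_0, \tau_{AD}, \tau_G)\right],$$

$$H(t, t_0, \tau, \tau_G) = \tfrac12
  \exp\!\left(\frac{\tau_G^2}{2\tau^2} - \frac{t-t_0}{\tau}\right)
  \operatorname{erfc}\!\left(\frac{\tau_G^2 - \tau(t-t_0)}
  {\sqrt2\,\tau\,\tau_G}\right).$$

The erfc argument used here is the standard exponentially-modified
Gaussian form; `decay_component()` was verified against direct numerical
quadrature of $e^{-u/\tau}\,\mathbf 1(u>0)$ convolved with a unit-area
Gaussian (agreement to $10^{-12}$), and its integral over the real line
equals $\tau$.

**Numerical stability.** The exponential prefactor alone overflows when
$\tau \ll \tau_G$ while erfc underflows. Both factors are folded into one
exponent via $\log\operatorname{erfc}(x) = \log 2 +
\log\Phi(-x\sqrt2)$, computed with `pnorm(..., log.p = TRUE)`, which is
accurate for arbitrarily large $|x|$. $H$ is therefore finite and
non-negative for all arguments.

**Amplitude vs. photon fractions.** $P_D$ and $P_{AD}$ are *amplitude*
fractions. A component of amplitude $P$ and lifetime $\tau$ contributes
$\propto P\tau$ photons, so the fraction of photons from the bound donor
is $P_{AD}\tau_{AD}/(P_D\tau_D + P_{AD}\tau_{AD})$. This convention is
what makes the closed-form inversion below exact, and the simulator uses
it when assigning photons to components.

## Fitting

TCSPC counts are Poisson, so `fit_decay()` maximises the Poisson
likelihood of the binned counts. The overall amplitude is profiled out
analytically, reducing the objective to a multinomial fit of the curve
*shape* in $(P_{AD}, \tau_{AD}, t_0, \tau_G)$ — equivalent to the full
Poisson ML for the shape parameters and more robust. A weighted
least-squares objective (weights $1/\max(c_i, 1)$) is retained as a
documented fallback (`method = "wls"`).

Constraints are enforced by the parameterization rather than by penalty:
$P_{AD}$ is fitted on a logit scale (so $P_D + P_{AD} = 1$ and
$0 \le P_{AD} \le 1$ hold by construction), $\tau_{AD}$ on a logit scale
mapped into $(0.1\,\mathrm{ns}, \tau_D)$, and $\tau_G$ on a log scale
clamped to $[10^{-4}, 10]$ ns against line-search under/overflow. $\tau_D$
is never altered by the optimizer; for eGFP-based donors it is fixed to
2.6 ns, the lifetime of free eGFP.

Deterministic initialisation: $\tau_{AD} = \tau_D/2$, $P_{AD} = 0.2$,
$\tau_G = 0.15$ ns, and $t_0$ at the rising-edge half-maximum of the
histogram. Because the half-maximum guess can sit a bin or two off, each
start is first refined by Nelder-Mead and then polished by BFGS; three
deterministic starts ($P_{AD}$ = 0.05, 0.2, 0.5) guard against local
optima.

**The null ridge.** When the donor is essentially free, the likelihood is
flat along the ridge $\tau_{AD} \to \tau_D$, on which $P_{AD}$ is
unidentifiable and tends to absorb noise (estimates of 0.03-0.07 on truly
donor-only data). `fit_decay()` therefore also fits the nested
single-component model and keeps it — reporting $P_{AD} = 0$ — unless the
two-component model improves the likelihood beyond a
$\chi^2_2$ 95% threshold. With any appreciable true binding the
improvement is orders of magnitude larger and the reduction never
triggers.

The model is evaluated at bin centers by default; bins are narrow
relative to the lifetimes, and exact trapezoid bin integration is
available behind `bin_integration = "trapezoid"`. Laser-period
wrap-around (incomplete decay) is *not* modelled; the simulator uses a
25-ns period, about ten times $\tau_D$, so truncation is negligible. This
is a documented limitation for data acquired at high repetition rates.

Photon floors are configurable and default to $10^4$ for whole-image
fits, 10 per pixel for lifetime maps, and 100 per frame for ROI traces.

## The closed-form binding-fraction estimator

For small ROIs (spines, dendrite segments) a per-frame fit is
impractical; instead the pooled mean photon arrival time
$\langle t\rangle$ gives $\langle\tau\rangle = \langle t\rangle - t_0$
with $t_0$ from the whole-image fit, and

$$P_{AD} = \frac{\tau_D(\tau_D - \langle\tau\rangle)}
  {(\tau_D - \tau_{AD})(\tau_D + \tau_{AD} - \langle\tau\rangle)}.$$

Under the amplitude-fraction convention this inverts the photon-weighted
mixture mean
$\langle\tau\rangle = (P_D\tau_D^2 + P_{AD}\tau_{AD}^2)/(P_D\tau_D +
P_{AD}\tau_{AD})$ *exactly*; the property suite verifies machine-precision
round trips over random parameter draws. Photon noise can push the
estimate outside $[0,1]$; such values are returned as-is and flagged,
with clipping strictly opt-in, because silent clipping biases averaged
traces toward the interior. Binding traces are reported baseline-
subtracted ($P_{AD} - P_{AD0}$, baseline = mean over the pre-stimulus
window), and cells with baseline binding above 0.45 are excluded by
`qc_filter_cells()` — high initial binding indicates a saturated or
unhealthy sensor.

## Volume time courses

`delta_f_over_f()` uses $\Delta F/F_0 = (F - F_0)/F_0$ with $F_0$ the
mean of the first five to seven pre-stimulus points (default 7 when
available, hard bounds configurable). Phase windows are closed on both
ends, with timestamps in minutes from uncaging onset: the phrasing
"1 to 3 min" naturally includes both endpoints, and the convention is
stated because results change slightly with half-open windows. An empty
window is an error, never a silent zero.

`expansion_correct()` implements both readings of the expansion factor —
the literal area ratio and its square root (the linear magnification) —
because dividing average nuclei *areas* yields an area ratio while the
fold-expansion language suggests a linear factor. The convention is an
explicit argument and is never inferred; the default follows the literal
area-ratio text.

## Uncaging-locked sweep analysis

Release of a pH-sensitive reporter rides on top of the much larger and
slower volume signal. The sweep pipeline isolates the fast per-pulse
component: the 7.8-Hz trace is cut into 16-frame sweeps (2.048-s uncaging
periods), each sweep is normalized to the mean of its *own* first two
frames (removing accumulated volume growth and prior releases), the
sweeps for uncaging pulses 2-18 are averaged frame-wise (with 7 baseline
sweeps these are rows 9-25), and the peak is the mean of the three frames
after the pulse — latencies 0.128-0.384 s at the 0.128-s frame interval.
The 7.8-Hz-vs-0.128-s rounding is resolved in favour of the printed
0.128-0.384-s window. Per-spine SEP and volume-channel peaks are compared
with a two-tailed paired t test (`stats::t.test`); a zero-variance
nonzero difference is flagged as degenerate rather than tested.

The uncaging pulse is taken to fall midway between frames 2 and 3 of each
sweep; sub-frame pulse latency is not modelled. In the simulator this
means the first post-pulse frame samples a release transient at half a
frame interval of decay.

## TIRF event statistics

`detect_events()` is deliberately simple plumbing — local maxima above
baseline mean + $k$·SD with a minimum separation, reported at onset — for
use on synthetic traces; laboratory recordings would normally come with
event times from dedicated detection software, which the rest of the
module consumes directly. The baseline defaults to the whole trace,
valid when events are sparse.

Frequencies are counts over half-open windows $[s, e)$ divided by window
length; release-time histograms use left-closed right-open 10-s bins over
the 60-s stimulation window (events exactly at the window end excluded),
a convention stated explicitly because it is otherwise ambiguous. Event
kinetics use the 10-90% rise time (linear interpolation) and a
mono-exponential decay fit — an explicit choice where the measurement
method is otherwise unspecified; `nls` failures on noiseless data fall
back to an exact log-linear fit, and non-decaying segments are flagged.
The stimulation schedule helper encodes the LTP field protocol (30 bursts
of 20 × 1-ms impulses at 83 Hz, repeated at 0.5 Hz, 60 s total) and the
uncaging train (30 × 6-ms pulses at 0.5 Hz).

## The synthetic-data generator

The generator produces every input the pipeline consumes, with a
ground-truth manifest, and defines the package's study conditions:

* **Photon histograms** — component chosen with probability
  $\propto P\tau$, arrival $t_0 + \mathrm{Exp}(\tau) +
  \mathcal N(0, \tau_G)$, out-of-period arrivals rejected and redrawn so
  counts are conserved. Pure Poisson statistics at the photon level.
* **FLIM series** — spatially uniform binding inside the ROI following a
  supplied profile, donor-only background, Poisson photons per pixel.
* **Spine movies** — volume transient (rise constant 30 s toward a
  sustained plateau of 0.4 with a transient component peaking at 1.0 and
  decaying with 240 s) shared by both channels; SEP mode adds per-pulse
  release steps (default amplitude 0.15 ΔF/F₀, decay 1.5 s, success
  probability 0.5 — the success probability is not quantified anywhere
  and 0.5 is a declared default) while Gamillus mode adds none. Noise is
  multiplicative Gaussian with SD $\propto \sqrt{\text{signal}}$ (3% at
  baseline), a shot-noise proxy appropriate for ROI-summed traces.
* **Event trains** — piecewise-homogeneous Poisson, basal rate outside
  and stimulated rate inside the stimulation window, on the concatenated
  two-movie timeline (recording 0-180 s, stimulation 64-124 s).

Identical seed and configuration give byte-identical outputs; every
stochastic routine takes an explicit seed and touches no hidden state
beyond R's RNG.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: optical blur and spine morphology,
bleaching and focus drift, pH dynamics beyond on/off reporter visibility,
vesicle diffusion, correlated noise between channels, and laser-period
wrap-around. Parameter recovery here demonstrates correctness of the
estimators under the stated statistical model, not robustness to every
artefact of real microscopy.

## Problem sizes

The test and acceptance runs use sizes chosen to keep Monte-Carlo error
comfortably below the assertion tolerances while remaining quick on a
single CPU: $10^4$ parameter draws for the inversion identity; 20 seeds ×
4 binding levels × $3\times10^5$ photons for estimator recovery (median
absolute error ≤ 0.03 per level); 13 spines per sweep scenario (matching
the per-group spine counts of typical uncaging experiments); 100 Poisson
trains for rate unbiasedness and 20 paired recordings for the rate-step
detection.

## Units and conventions

Nanoseconds inside the FLIM module, seconds for traces and events,
minutes for phase windows; conversions happen at module boundaries, never
implicitly. User-facing frame and pulse indices are 1-based (the pulse
falls "between the second and the third frame"); internal arithmetic is
0-based where convenient and the boundary is documented in each
function's reference page.
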