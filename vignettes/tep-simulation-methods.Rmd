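---
title: "Simulating TMS-evoked potentials with a delay-coupled Jansen-Rit network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating TMS-evoked potentials with a delay-coupled Jansen-Rit network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vtep)
```

## The scientific question

TMS-evoked potentials (TEPs) — the averaged EEG deflection sequence
following a single transcranial magnetic stimulation pulse — are larger
in patients with major depressive disorder than in healthy controls,
while several lines of evidence point to a GABAergic (inhibitory)
deficit in the same patients. `vtep` implements an in-silico experiment
probing whether specific local inhibitory deficits can produce such a
global TEP amplitude increase: a whole-brain network of Jansen-Rit
neural masses is perturbed by a virtual TMS pulse, projected to EEG,
and the two inhibitory parameters of the model are swept while the TEP
amplitude is tracked.

## The model

Each of the `n` brain regions contains three coupled neural
populations: pyramidal cells (PC), excitatory interneurons (EIN) and
inhibitory interneurons (IIN). Presynaptic firing rates are converted
to mean postsynaptic potentials (PSPs) by the kernel

\[ h(t) = H \frac{t}{\tau} e^{-t/\tau}, \qquad t \ge 0, \]

with maximum PSP \(H\) (excitatory \(A = 3.25\) mV, inhibitory
\(B = 22\) mV) and time constant \(\tau\) (reciprocals: excitatory
decay rate \(a = 100\,/s\), inhibitory decay rate \(b = 50\,/s\)).
PSPs are converted back to firing rates by the sigmoid

\[ S(v) = \frac{2 v_{max}}{1 + e^{r (v_0 - v)}}, \]

with \(v_{max} = 2.5\,/s\), threshold \(v_0 = 6\) mV and steepness
\(r = 0.56\,/mV\). Writing each kernel as two first-order ODEs gives
six state variables per region (`y0`-`y5`); the synapse-count
constants are \(C_1 = 135\), \(C_2 = 0.8\,C_1\),
\(C_3 = C_4 = 0.25\,C_1\). All external input — long-range coupling,
constant background drive `qcon`, the TMS pulse and noise — enters the
EIN equation only; `b` and `C4` appear only in the IIN equation, which
is what makes them clean "GABA knobs": `b` controls the *timing* of
inhibition, `C4` its *strength* (number of inhibitory synapses onto
PC).

Regions interact through the structural connectome: region `k`
receives \(x_k(t) = \sum_l M_{kl}\,[y_{1,l} - y_{2,l}](t - d_{kl})\),
the weighted, delayed sum of the other regions' PSPs, with delays
\(d_{kl}\) = distance / conduction speed (2.5 m/s) rounded
(half-to-even) to integration steps. Zero-step delays are allowed for
very short tracts. The summed input passes through a second sigmoid
(`coupling_sigmoid()`) before entering the EIN equation.

Integration uses a stochastic Heun scheme (predictor-corrector, the
same noise increment in both stages) with a ring-buffer delay history,
written in C++ with connections grouped by delay so each step costs
one multiply-add per nonzero connection. The default step is
`dt = 0.1` ms — `max(a, b) * dt = 0.01`, comfortably inside the
stability region, and the single-node convergence test verifies the
expected O(dt^2) error scaling. Output is decimated to 1 kHz. Noise is
drawn from R's RNG (one `N(0, std)` value per region and step, held
constant over the step), so every simulation is exactly reproducible
from its seed; divergence (any PSP beyond 1e6 mV) aborts with an error
naming the offending parameter values.

## Study conditions

`study_conditions()` fixes the operating point of the whole-brain
experiment:

* background drive `qcon = 45 /s` — below the oscillatory range of the
  model, so an isolated region rests at a stable fixed point;
* coupling saturation `gmax = 90 /s` — long-range input then places
  strongly connected (hub) regions close to the oscillation onset;
  the remaining coupling-sigmoid values keep the classical firing-rate
  sigmoid's shape (`gmid = 6` mV, `ga = 0.56`), as the reference for
  these constants is not available;
* EIN noise `std = 45 /s`, and a rectangular TMS pulse of 1 ms with
  focal amplitude 4000 /s, Gaussian-graded over the five stimulated
  regions.

At this point the network produces a TEP-like response: the pulse
evokes a damped, propagating deflection sequence on top of modest
ongoing fluctuations, and the response amplitude is sensitive to the
inhibitory parameters, which is the phenomenon under study. The
classical single-node default (`jr_params()` with `qcon = 220 /s`)
is retained for the isolated-node alpha-rhythm regime and its tests.

Choosing `qcon` involved a genuine trade-off, documented here because
the design was open. At high drive (inside the alpha limit cycle),
lowering `b` silences the network (the integrated inhibition
\(\propto B C_4 / b\) grows as `b` falls) — the opposite of the
target phenomenon. Just below the oscillation threshold, lowering `b`
or `C4` pushes part of the network across into large-amplitude
oscillation, raising the global mean field amplitude the way the
MDD-like deficit should. `qcon = 45` with `gmax = 90` places the
fixture network in that subthreshold regime with a wide spread of
regional operating points (see the connectome below), which makes the
amplitude-versus-parameter curves graded rather than all-or-none.

## Synthetic data

All inputs are generated, so the full pipeline runs without downloads:

* `synth_connectome(n, seed)` — coordinates uniform in a 140 mm
  sphere, Euclidean distances, weights = log-normal magnitudes times
  `exp(-distance / 40 mm)`, symmetrised, zero diagonal. The fixture
  then applies `log(1 + w)` scaling (`normalize_weights()`), a
  per-region log-normal strength factor (sd 0.4 on the log scale)
  emulating the hub structure of empirical and per-subject optimized
  connectomes, and scales the matrix to mean row sum 1 so the summed
  delayed input lives on the scale of a single region's PSP.
* `synth_leadfield(channels, regions, seed)` — electrodes on a
  Fibonacci lattice over the upper scalp hemisphere, randomly oriented
  unit dipoles per region, inverse-square falloff.
* `synth_stimulus(n, indices, amplitude)` — exactly the listed regions
  nonzero, Gaussian falloff from the focal region; the fixture places
  five adjacent left-hemispheric regions, emulating an M1 coil site.
* `synth_target_tep(spec, lf)` — Gaussian-windowed deflections at
  45/60/100/185 ms with alternating signs (N45, P60, N100, P185),
  built in source space then projected, scaled to 5-10 uV channel
  peaks, plus 0.1 uV channel noise. Building the target in source
  space keeps the connectivity-fitting problem well posed.

Two presets exist: `"test"` (20 regions, 16 channels; seconds to
simulate, used in unit tests) and `"paper"` (200 regions, 62
channels, the reference configuration). What the generator does *not*
emulate: realistic head-model lead fields, subject-level anatomical
variability, and empirical noise spectra — so green tests show the
pipeline's internal consistency and the model's qualitative physiology,
not agreement with any empirical recording.

## Connectivity fitting

`optimize_sc()` adjusts the (symmetric, non-negative) weight matrix so
the simulated, lead-field-projected epoch matches a target TEP. The
default loss is the epoch MSE plus `0.01 * ||M - M0||^2`,
regularising toward the initial template. Gradients are estimated by
simultaneous perturbation (SPSA; two simulations per iteration,
Rademacher directions, standard decaying gains, per-entry step capped
at 10% of the weight scale) — the choice that scales to 200-region
networks — with a finite-difference mode for small problems where
exact gradients are affordable; there the largest gradient component
is scaled to a fraction of the weight scale and annealed. Within an
iteration the noise seed is frozen so both probes see the same
realisation. The best-loss iterate is returned, and the reported
Pearson correlation comes from a noise-free final evaluation. On the
10-region recovery benchmark (10% of connections tripled, noise-free
target) the finite-difference mode reduces the loss to about 1% of its
initial value in 25 iterations.

## Sweeps and TEP amplitude

`run_sweep()` alters one parameter at a time (`b`, `C4`, the
supplementary `C3`, or `b` and `C4` jointly) over a symmetric percent
grid — by default -50% to +50% in 2% steps, 51 values including the
default; `alter_parameter()` guarantees every other parameter stays at
default. Amplitude is quantified by the global mean field power (GMFP:
across-channel standard deviation, divisor K) integrated over 15-300
ms post-stimulus (trapezoidal rule) — the global mean field amplitude
(GMFA). The first 15 ms are excluded to mirror the empirical exclusion
of the stimulation artifact; per-peak GMFAs use the same integral
restricted to the N45 (30-57 ms), P60 (58-80 ms), N100 (81-144 ms) and
P185 (145-250 ms) windows. Window edges are configuration, not
physiology. Every repetition is normalised to *its own*
default-parameter run (relative GMFA, 100% at default by
construction), then averaged over repetitions and weight sets. Failed
simulations at extreme grid values are recorded as missing with a
warning and dropped listwise from the regression.

## Regression model selection

The mean relative GMFA curve is fit by three models: linear (OLS, Wald
test on the slope), quadratic (OLS, overall F-test) and exponential
\(y = c + \alpha e^{\beta x}\) (Levenberg-Marquardt NLS, standard
errors from the covariance matrix, p-value from the t-statistic of
\(\beta\); initialisation from a log-linear fit tried in both
orientations plus fixed-rate fallbacks, with \(\beta\) bounded so the
exponent stays below 700). The minimum-SSE model is selected; ties
within 1e-9 of the response's total sum of squares go to the model
with fewer parameters. The goodness of fit is reported as
\(r = \sqrt{1 - SSE/SST}\), the multiple correlation of the fitted
model — a plain Pearson correlation between `x` and `y` would be
near zero for a symmetric U-shaped relation however perfect the fit.

```{r regression-example}
x <- make_sweep_grid(50)$value
y <- 100 + 0.08 * (x - 52)^2          # a U-shaped response
fit_models(x, y)$selected
```

## What the desk-scale experiment reproduces

At the reference conditions (200-region fixture, 51-value grids, 5
noise-seeded repetitions — run by `analysis/03_sweep_inhibition.R` and
`scripts/acceptance.R`):

* The `b` sweep yields a smooth U-shaped mean relative GMFA with its
  minimum strictly inside the grid; the quadratic model is selected
  with \(r > 0.99\). Amplitude rises steeply as `b` falls — slow
  inhibition recruits part of the network into large slow
  oscillations, the MDD-like amplitude increase.
* The `C4` sweep selects the exponential model: amplitude is strongly
  elevated at -50% (reduced inhibition) and decays toward the
  default. Its goodness of fit plateaus near \(r \approx 0.9\) at
  this scale, short of the full-scale value: to first order this
  network's amplitude responds to the inhibition *integral*
  \(\propto C_4/b\), so the over-inhibition branch that makes the `b`
  curve rise below default also bends the `C4` curve up above default
  and places a burst onset at the extreme low-`C4` corner. Averaging
  over thousands of heterogeneous optimized connectomes — the
  full-scale design, 20 subjects x 100 optimization repetitions
  (`plan_repetitions()`) — suppresses that branch; a single fixture
  with five noise seeds cannot.

## Numerical choices and degenerate inputs

* Epoch windows are half-open `[start, end)`: `(0, 0.3)` s at 1 kHz is
  exactly 300 samples.
* Delay rounding is round-half-to-even; doubling the conduction speed
  halves pre-rounding delays exactly.
* The weight diagonal is forced to zero before simulation (no
  self-coupling through the long-range term).
* All-zero weight matrices cannot be `max_one`-normalised, GMFP needs
  at least two channels, relative GMFA needs a positive default —
  each raises an informative error rather than returning NaN.
* Text round trips are exact: matrices are written with `%.17g`.
* One master seed fans out to stage seeds via a string hash
  (`derive_seed()`), keeping every stage independently reproducible
  and below 2^31.

## Known limitations

* The coupling-sigmoid constants, `qcon`, noise level and TMS gain are
  package choices (config-exposed); the reference values for the
  original study are in its supplementary material, which this package
  does not use.
* Lead fields are spherical stand-ins; no BEM/FEM head model.
* SPSA on a 200-region network explores a 19,900-dimensional space
  with two simulations per iteration; at desk scale it polishes rather
  than globally optimizes. The finite-difference mode is exact but
  only affordable for small networks.
* The C4 sweep's goodness of fit at desk scale is discussed above.
* Problem sizes in the test suite: 20-region preset for pipeline and
  sweep mechanics, 6-10 regions for fitting benchmarks, the 200-region
  preset for the two headline sweeps.
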