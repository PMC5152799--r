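---
title: "Methods: probe-aware autocorrelation inference of bursting kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: probe-aware autocorrelation inference of bursting kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msburst)
```

## The signal model

A transcribing gene is discretised into `r` sites of 150 bp, the footprint
of one polymerase, traversed at one site per `step_time_s` seconds
(default 6 s, which is also the promoter blocking time: a new polymerase
can initiate at most once per step while the promoter is ON). The promoter
state `X(t)` is binary; a polymerase that initiated at step `t - i` sits at
site `i` at step `t` and carries `L_i` fluorescing MS2 loops, so

```
F(t) = sum_{i=1..r} L_i X(t - i).
```

The loop function `L_i` is zero before the cassette, ramps linearly across
it (fractional values are intentional: loop and polymerase lengths do not
coincide, and the exact sub-step shape of the ramp is not observable at the
6-s step resolution), and saturates at the loop count afterwards. The first
`r` steps of any state history are a loading transient; simulated
steady-state traces discard them, and `fluorescence_from_states()` flags
them. Splicing, variable elongation speed, polymerase traffic and MCP
binding kinetics are outside the model; elongation speed enters only
through `step_time_s`, and traces sampled on grids incommensurate with the
step are handled exactly (below), so a modest error in the assumed speed
deforms the lag axis smoothly rather than corrupting the fit.

## Promoter models

* **Two-state (telegraph):** exponential dwell times, rates `k_on`, `k_off`
  (s^-1). `P_on = k_on / (k_on + k_off)`; ON–ON propagator
  `A(t) = P_on + (1 - P_on) exp(-(k_on + k_off) t)`.
* **Cycle:** one ON state and `K` sequential OFF states left at rates
  `k_1..k_K`; `A(t)` is the (ON, ON) entry of the matrix exponential of the
  chain generator, evaluated through an eigendecomposition. With `K = 1`
  this reduces exactly to the telegraph model (a pinned test). The labels
  `k_1, k_2` are interchangeable in every observable statistic, so the
  rates are stored sorted and only the ratio `k_1/k_2 <= 1` is reported.
* **Gamma:** an effective two-state promoter whose OFF waiting times follow
  Gamma(shape `alpha`, rate `beta`). For integer `alpha` and equal cycle
  rates `beta` this is *exactly* the Erlang/cycle model, which is the
  cross-model oracle in the test suite.
* **Poisson-like:** initiation fires at Poisson rate `r`, each event
  blocking the site for `tau_block`; occupancy
  `P_on = tau_block/(tau_block + 1/r)`, and steps are uncorrelated
  (`A(n) = P_on` for `n >= 1`). Its normalised autocorrelation is therefore
  the probe autocorrelation alone, independent of the firing rate — a
  property pinned by a test. Simulation draws independent per-step
  initiation events; a renewal simulation with literal deterministic
  blocking would put a small negative correlation at lag 1 that the model
  class itself ignores.

The printed per-step exponential form `e^(delta-1)n` with
`delta = 1 - (k_on + k_off) dt_step` is the canonical propagator; the exact
discrete-chain form `delta^n` is kept as a test oracle, and the two agree
to second order in the per-step rates (pinned for per-step rates up to
0.1).

All rates are stored in s^-1 and converted at the model/signal boundary.

## Autocovariance with probe geometry

Writing `w_d = sum_i L_i L_{i+d}`, the stationary connected autocovariance
of the fluorescence is

```
C(tau) = P_on * sum_d w_d [ A(|tau - d * step|) - P_on ],
```

and a cross-covariance between two colour channels uses
`w_d = sum_i L^A_i L^B_{i+d}`, which makes the curve asymmetric in the lag
sign (the downstream probe lags). Because `A` is continuous in time, the
curve is evaluated *exactly* at any real lag; no interpolation between
polymerase steps is needed even when the sampling interval (e.g. 4.3 s) is
not a multiple of the 6-s step.

For the Gamma model no closed form exists. The propagator's Laplace
transform, from alternating-renewal theory, is
`h(s) = [k_off + s - k_off (1 + s/beta)^-alpha]^-1`; the package inverts it
on a frequency grid. A Lorentzian with the matched relaxation rate
`lambda = k_off + beta/alpha` — chosen because `(1 - P_on) lambda = k_off`
makes the two integrands share their leading `1/omega^2` tail — is
inverted analytically and subtracted, leaving an integrand that decays like
`omega^-3`; the trapezoidal grid extends its cutoff until the tail is below
1e-6 of the peak. The inversion reproduces the telegraph closed form at
`alpha = 1` to ~1e-7 and the Erlang cycle at `alpha = 2` to ~1e-5.

## Finite-trace correction

For a trace of `K` samples the empirical mean `m` is correlated with every
sample, which biases the connected autocorrelation: the pair-weighted sum
of the estimator over all lags is identically zero, so short traces show a
spurious negative valley. Rather than transcribing a closed-form corrected
curve, the package computes the *exact expectation* of the estimator. With
`Sigma` the true covariance matrix of the sampled signal,

```
E[(v_i - m)(v_j - m)] = Sigma_ij - (R_i + R_j)/K + S/K^2,
```

where `R_i = sum_l Sigma_il` and `S = sum_il Sigma_il`; averaging over the
`K - r` pairs at each lag and normalising at lag 1 gives the corrected
curve. This form is linear in `Sigma`, exact for any sampling scheme, and
verified two ways in the tests: against brute-force averaging of the
mean-subtracted autocovariance over thousands of simulated traces, and
against short-trace Ornstein–Uhlenbeck ensembles (`generate_ou_traces()`),
whose closed-form `exp(-lambda t)` autocovariance makes them an
implementation-independent oracle.

Two conventions connect this to data:

* **Sampling grid.** Simulated signals are step-held; observation samples
  are assigned to their nearest polymerase step, and `Sigma` is built on
  the same nearest-step map. This removes the small-lag bias a continuous
  evaluation would have when `dt` is incommensurate with the step time.
* **Variance normalisation.** The classical per-trace estimator divides
  each trace's curve by that trace's own empirical variance, which cancels
  nucleus-to-nucleus intensity scales but adds a ratio bias of a few
  percent for ~60-sample traces — clearly resolvable at a few thousand
  nuclei. The correction above describes the constant-denominator
  (trace-averaged variance) estimator, so `connected_autocorrelation()`
  defaults to that pooled convention and offers `variance = "per_trace"`
  for uncalibrated data. The pooled form also keeps all-silent nuclei in
  the ensemble, where the per-trace ratio would have to drop them (0/0) and
  thereby condition on activity.

Lag 0 carries all temporally uncorrelated noise (shot noise, free
fluorophore fluctuations) and is never used: curves are normalised at the
second time point and fits start at lag 1.

## Inference

1. **Calibration.** `I0 = mean(per-trace max) / sum(L)`; the mean of maxima
   rather than the global maximum avoids overestimating saturation from one
   bright outlier. At low `P_on` traces rarely saturate, so `I0` is biased
   low and `P_on` correspondingly high; the timescale fit is insensitive to
   this because `P_on` only pins the rate *ratio*.
2. **Ratios.** `P_on` fixes `k_on/k_off` (telegraph),
   `k_off^-1 / sum k_m^-1` (cycle) or `beta/(alpha k_off)` (Gamma).
3. **Timescale.** The remaining scale minimises the pair-count-weighted MSE
   between the empirical and corrected model curves over lags
   `1 .. min(K - 2, 3 tau_buff / dt)`. Beyond a few buffering times the
   curve is noise; the pair-count weights `K - r` already downweight long
   lags, and the cap makes the objective insensitive to them entirely. A
   25-point log-spaced scan over [1e-4, 1] s^-1 followed by golden-section
   refinement is cheap, avoids local minima, and warns when the optimum
   sits on the scan boundary or the objective is flat (degenerate fits,
   e.g. Poisson-like-looking data). The cycle model adds a small grid over
   `k_1/k_2`; the Gamma model fits `k_off` on a half-integer `alpha` grid,
   treating `alpha` as an effective OFF-state count.

Uncertainties come from repeating the whole inference (calibration
included) on 20 random 60% subsets of the nuclei. Model discrimination
(`discriminate_cycle_vs_two_state()`) reports the fitted `k_1/k_2` with a
0.5 classification threshold; models of different complexity are *not*
compared by information criteria, because the effective number of
independent samples in correlated traces is unknown — the package follows
the practice of comparing fitted ratios across repeated datasets instead.

## Readout precision

A promoter resets its measurement of the nuclear environment once per
correlation time `tau_i = 1/(k_on_eff + k_off)`, so a window `T` holds
roughly `T/tau_i` independent measurements and the relative error of the
produced mRNA for a two-state promoter is
`sqrt(2 tau_i (1 - P_on) / (T P_on))` (the factor 2 corrects the naive
count; valid for `T >> tau_i`). The Poisson-like counterpart is
`sqrt(tau_block (1 - P_on) / T)`. `relative_error_monte_carlo()` is the
finite-`T` ground truth: the SD/mean of the time-averaged ON indicator
across realisations. For the two-state model it converges to the closed
form as `T` grows (within 10% by `T ~ 10 tau_i`, a pinned test). For the
Poisson-like model the occupancy Monte Carlo scales as the closed form
divided by `sqrt(P_on)`: the closed form describes the error of the firing
*count* per independent window rather than of the occupancy average, and
no occupancy-based simulation reproduces it away from `P_on = 0.5`. The
package keeps the closed form (which matches the cross-architecture
comparisons it is used for) and documents the occupancy estimator as a
distinct quantity rather than silently redefining either.

Empirical precision is the per-spatial-bin SD/mean over nuclei of the
time-averaged (or integrated, or binarised) activity, with bins of 10% egg
length and a 3-nucleus minimum. Lineage integration adds half the mother's
and a quarter of the grandmother's integrated signal, the expected dilution
of stable mRNA across divisions.

## Synthetic data

`generate_embryo_dataset()` fixes the study conditions the package is
tested under: 4 embryos sampled at 13.1/10.2/5.1/4.3 s, cycles 11–13 of
360/540/780 s with nuclei doubling and lineage links, and a two-state
promoter whose `k_on` decays along the AP axis with the Bicoid length
scale (100 µm on a 500 µm embryo, flat anterior to 17.5% egg length —
giving a mid-anterior to mid-boundary ON-rate ratio of ~5) while `k_off`
rises with a 275 µm scale. The anterior rates `k_on = k_off = 0.015 /s`
set a ~33 s anterior switching timescale with `P_on = 0.5`; the `k_off`
scale is the one value that simultaneously yields boundary occupancy near
0.1 with that ON-rate ratio. Each interphase starts OFF with an empty gene
(activation ramp), ends with 120 s of forced silence (decay), and the
plateau in between is what `select_steady_state()` recovers: the smoothed
(3-sample moving average) ensemble-mean intensity must stay above 80% of
its cycle maximum, with first/last crossings as bounds — both knobs are
exposed, since the underlying rule is qualitative. A monotonically rising
mean never plateaus and raises an error instead of guessing.

What the generator deliberately does *not* emulate: photobleaching,
segmentation/tracking errors, background-subtraction artifacts,
nucleus-to-nucleus calibration differences (available separately as
`noise_sd` and the `per_trace` estimator), Bicoid dynamics, or nuclear
movement. Passing tests on these fixtures therefore demonstrates
correctness of the estimators under the stated stochastic model, not
robustness to imaging pathology.

Problem sizes in the test suite are chosen to keep the full run at a few
minutes while leaving Monte-Carlo margins of at least ~3 SE: ensembles of
2000 nuclei for theory-vs-simulation checks (10000 for the 60-s short-trace
case), 200–1000 nuclei for recovery sweeps, 12 repeats per condition for
the discrimination experiment, and 400–1500 windows for precision Monte
Carlo.

## Known limitations

* Inference assumes steady state inside the selected window; activation
  and shutdown transients must be excluded (the package refuses traces
  without a marked window rather than silently using them).
* The blocking time bounds the inferable rates: switching faster than
  `1/tau_block ~ 0.17 /s` is invisible in principle. Within the scanned
  range the estimator is unbiased but its variance grows steeply above
  ~0.1 /s at a few hundred nuclei.
* Traces in one fit share a common window length (the shortest); strongly
  heterogeneous windows waste data.
* The Gamma-model fit is the slowest path (numerical inversion per
  objective evaluation) and `alpha` is restricted to a half-integer grid.
* Calibration from the mean of maxima biases `P_on` upward at low
  occupancy and short traces; only ratios, not `P_on` itself, should be
  trusted below ~0.15 occupancy.
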