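---
title: "Models and methods behind rxnkinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rxnkinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxnkinetics)
```

`rxnkinetics` emulates, at desk scale, the workflow of an automated
kinetic-measurement platform: a reaction is simulated, observed through
synthetic NMR or UV-Vis spectra on an acquisition schedule, and analysed
by the standard toolbox of reaction-progress kinetics. This vignette
documents the models, the tunable parameters and the design decisions,
so that the numbers the package produces can be interpreted — and
distrusted — correctly.

## The kinetic model

A `reaction_network()` is a list of steps with mass-action rate laws

$$ r = k \prod_{\text{reactants}} [S]^{\,\alpha_S} , $$

where each exponent defaults to the stoichiometric coefficient and can
be overridden per species. The overrides exist because empirical orders
in real campaigns are frequently fractional (a one-step scheme standing
in for a wider network, e.g. a catalyst shuttling between states); the
simulator reproduces such behaviour without modelling the full
mechanism. Units are fixed: concentrations in mM, time in minutes, so a
step of total molecularity $n$ has $k$ in mM$^{1-n}$ min$^{-1}$.
Instrument schedules are specified in seconds only at the
`sample_schedule()` boundary, because sampling intervals are quoted in
seconds while rate constants are quoted per minute.

`simulate_network()` integrates the ODE system with `deSolve::ode`
(`lsoda`, rtol $10^{-8}$, atol $10^{-10}$). The stiffness-switching
solver is deliberate: screens that mix fast complexation with slow
consumption can be stiff. Concentrations are clipped at zero both inside
the rate evaluation (fractional powers of small negatives are undefined)
and in the output. `pfo_closed_form()` provides the independent
pseudo-first-order reference $A_0 e^{-k_2 B_0 t}$ used by the tests; the
test suite also checks the solver against the exact two-species
second-order solution and against fractional-order closed forms.

## The synthetic instrument

`render_spectrum()` maps one time point of a trace onto a spectrum:

* NMR: each peak is a Lorentzian of half-width-at-half-maximum $w$
  scaled to unit area, multiplied by `response × concentration`, so the
  noiseless integral is exactly proportional to concentration — the
  property that makes NMR calibration-free. The x-axis is stored in
  descending ppm.
* UV-Vis: Gaussian bands with peak height `response × concentration`
  (Beer–Lambert, absorbances additive), ascending nm.

Noise is additive Gaussian with standard deviation
`relative_sigma × max(signal)` plus a constant per-spectrum baseline
offset. The stream is seeded per spectrum (`seed + index`) on a private
RNG, so identical plans and seeds give byte-identical spectra after
serialization while leaving the caller's RNG untouched.

What the generator does *not* emulate matters for interpreting green
tests: there is no lineshape distortion (shimming, phasing), no
$T_1$-related integral bias, no temperature drift, no peak overlap
beyond Lorentzian tails, and no solvent background. Passing recovery
tests therefore demonstrate that the *analysis chain* is unbiased under
an idealized but noisy instrument — not that any real spectrometer
behaves this well.

The shipped chemistry presets carry placeholder spectral positions
(tosyl methyl singlets at 2.46/2.36 ppm, visible bands at 540/560 nm):
the underlying campaigns quote such values only in supporting material,
so the defaults are chosen to be plausible and are fully configurable
through `spectral_signature()` / YAML.

## Processing choices

* **Integration** is trapezoidal (`pracma::trapz`), not Simpson:
  instrument grids are arbitrary and trapezoids are exact for the
  piecewise-linear interpolant on any grid. Additivity over region
  splits holds exactly when the split point is a sample point.
* **Baseline.** The only correction offered is the straight line through
  the region's two endpoint intensities. It removes constant and linear
  backgrounds exactly. It is *off by default*: on the synthetic spectra
  the true baseline is zero, and for two nearby Lorentzians the endpoint
  chord sits on the neighbouring peak's tail, over-subtracts, and clips
  small product signals to zero early in a run — a nonlinearity that
  visibly biases initial rates. Real data with sloping baselines should
  enable it with regions whose endpoints sit in signal-free zones.
* **Conversion** is the product region's integral over the summed
  integrals of all related regions, with small negative areas clipped to
  zero first and the ratio clipped to $[0,1]$. Because both numerator
  and denominator are linear in the same response factor, the ratio is
  invariant to uniform rescaling — no calibration needed. Lorentzian
  tail cross-talk between adjacent regions produces a small affine
  distortion of conversion (an offset at 0 % and a symmetric deficit at
  100 %); it cancels entirely in rate *ratios* (orders, Hammett) and is
  kept below 0.02 in the round-trip tests by using well-separated
  regions there.

## Fitting choices

**Initial rates** are OLS slopes over an early window. The default
window is the first 15 points (a typical 15-minute acquisition) further
truncated to points below 20 % conversion. The truncation protects
linearity for fast runs: the OLS slope of an exponential over a window
$[0,T]$ underestimates the initial derivative by a factor of roughly
$1 - k_\mathrm{obs}T/2$, so capping the observed conversion caps that
bias at ~11 %.

**Pseudo-first-order rate constants** are *not* taken from the linear
initial-rate slope. Dividing a windowed linear slope by $A_0$ inherits
the curvature bias above, which compounds across an excess series: the
highest-excess run is the most curved, so the $k_\mathrm{obs}$ vs
$[B]_0$ regression is biased low by more than the individual fits. The
package instead fits $\ln[A]$ (or $\ln(1-x)$) against time
(`fit_pfo_kobs()`), which is exact for first-order decay and keeps the
$k_2$ estimator unbiased at any conversion reached by the design. The
plain linear fit remains available (`fit_initial_rate()`) and is the
method used for the Hammett and order pipelines, where the campaigns
compare *rates* under identical windows and the residual bias largely
cancels in ratios. The $k_\mathrm{obs}$ vs $[B]_0$ regression keeps a
free intercept: a non-zero intercept is a cheap diagnostic for a
background reaction consuming the limiting reagent.

**Orders** are slopes of $\log_{10}(\text{rate})$ vs
$\log_{10}(\text{conc})$; non-positive rates (possible under noise) are
dropped with a warning rather than silently clamped.

**VTNA.** The normalized time is the discretized integral

$$ t^\Sigma_i = \sum_{j \le i} \left( \frac{C_j + C_{j-1}}{2} \right)^{\!\alpha} (t_j - t_{j-1}), $$

the standard midpoint-concentration discretization. (Note this is the
midpoint raised to $\alpha$, not the mean of $C^\alpha$; the two differ
at second order in the step and the midpoint form is the conventional
one.) The $\alpha = 0$ identity — normalized time equals elapsed time —
is honoured exactly, not merely to rounding. The overlay score at each
$\alpha$ is the RMSD between every experiment's profile and the pooled
piecewise-linear mean profile interpolated on the union of normalized
time points within the shared range. This $O(N)$ pooled-reference score
is symmetric in the experiments and reproducible; it is one of several
defensible choices (pairwise curve distances, area-between-curves), and
the underlying platform literature does not pin one down. Ties are
broken toward smaller $\alpha$, and the default grid $-1$ to $3$ in
steps of $0.05$ covers inhibition through second order.

**Hammett.** $\rho$ is the OLS slope of $\log_{10}(k_X/k_\mathrm{ref})$
against tabulated $\sigma$ (log base 10 throughout — the field's
convention). The reference substituent enters the fit at
$(\sigma, \log\text{-ratio}) = (0, 0)$. The shipped table
(`hansch_sigma()`, mirrored in `inst/extdata/hansch_sigma.yaml`) holds
standard Hansch $\sigma_p/\sigma_m$ values and is fully overridable,
because any given campaign's substituent set is a configuration, not a
constant. The default 8-aniline set spans $\sigma$ from $-0.27$
(p-anisidine) to $0.37$ (m-chloroaniline).

## The endpoint monitor

The dynamic stop condition tests, after every acquisition, whether the
spread (max − min) of the `window` most recent conversions is at most
`threshold` — a while-loop with a data-driven exit. Both parameters are
mandatory: there is no universal plateau threshold, and recording them
is what makes a monitored run reproducible. The test runs on the
*derived conversion*, not on raw spectra vectors, because the decision
of interest is chemical; an L∞ mode on consecutive raw spectra is
available behind `mode = "spectrum_linf"` for uncalibrated use. A
plateau-terminated run can be frozen (`freeze_protocol()`) into a
fixed-duration protocol whose replay — same chemistry, fresh noise —
must reproduce the final conversion within the plateau threshold; this
bridges dynamic execution and static, analytics-free procedures.

## Generator defaults as study conditions

The presets encode one coherent set of study conditions, chosen once:

* `iedda_chemistry()`: $k_2 = 3.5\times10^{-5}$ mM$^{-1}$ min$^{-1}$,
  1.5 mM limiting reagent, 100/150/200 mM excess, 20 points every 82 s,
  1 % spectral noise — the printed design of the cycloaddition study.
* `tosylation_chemistry()`: $k_\mathrm{ref} = 10^{-3}$
  mM$^{-0.7}$ min$^{-1}$, i.e. $k_\mathrm{obs} \approx 0.025$ min$^{-1}$
  at 100 mM amine, matching a reaction that approaches completion in
  about two hours (the monitored-run timescale); amine order 0.7 (the
  campaign-average empirical order); $\rho = -0.98$ generating the
  substituent ladder; 5 mM tosyl chloride so the amine stays in excess
  across the 25–100 mM series.
* `complexation_chemistry()`: one effective termolecular step at
  $k = 0.005$ mM$^{-2}$ min$^{-1}$, giving an (1, 2, 2) mM mixture a
  ~3 h approach to completion on the 112 s sampling grid.

The recovery studies in `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R` use 50 replicates per estimate with 5 % rate
noise and 1 % spectral noise; the VTNA check is noiseless with a 0.1
grid step; the plateau-oracle property uses 1000 random traces and the
replay-equivalence property 5–8 random kinetics. These sizes make the
Monte-Carlo error of each mean a small fraction of the tolerance it is
compared against while keeping the whole suite at around a minute.

## Known limitations

* Overlapping peaks are not deconvolved and diagnostic regions are not
  discovered automatically; both are explicit non-goals, and region
  placement is the user's responsibility.
* The simulator's one-step networks with fractional orders reproduce
  observed rate laws, not mechanisms; campaign-level conclusions about
  *why* an order is fractional are outside its scope.
* The conversion observable saturates information near 0 and 1; the
  plateau detector therefore cannot distinguish "complete" from "stalled"
  — it reports that the signal stopped moving, nothing more.
* Estimator error bars are OLS standard errors conditional on the
  window; they do not propagate integration or calibration uncertainty.
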