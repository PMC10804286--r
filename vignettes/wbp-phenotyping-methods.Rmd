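---
title: "Methods: breath-by-breath phenotyping of rodent plethysmography polysomnography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: breath-by-breath phenotyping of rodent plethysmography polysomnography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wbpsleep)
```

# Scope

`wbpsleep` re-implements, as a tested pipeline, the breath-by-breath
respiratory and metabolic phenotyping used in rodent sleep studies that
combine whole-body plethysmography (WBP) with EEG/EMG polysomnography and
pulse oximetry: barometric tidal-volume calibration, breath segmentation
and inspiratory flow landmarks, sniff and inspiratory-flow-limitation
classification, apnea and oxygen-desaturation indices by sleep stage, the
hypercapnic ventilatory response (HCVR), open-circuit calorimetry
coupling, and exact nonparametric crossover statistics. Because the
recordings behind such studies are rarely deposited, the package ships a
synthetic-recording generator that emulates the statistical structure the
analysis assumes and carries full ground truth, so that every stage is
validated by construction rather than against irreproducible animal data.

# The barometric tidal-volume conversion

In a sealed WBP chamber a breath produces a pressure swing because
inspired air is warmed to body temperature and saturated with water
vapor. With a calibration injection of volume $V_K$ producing deflection
$P_K$, tidal volume follows

$$V(t) = \frac{P(t)}{P_K}\, V_K\, F, \qquad
F = \frac{T_B (P_B - P_{H_2O,T_C})}
         {T_B (P_B - P_{H_2O,T_C}) - T_C (P_B - P_{H_2O,T_B})},$$

with $T_B$, $T_C$ the body and chamber temperatures (kelvin), $P_B$
barometric pressure, $P_{H_2O,T_B}$ the saturated water-vapor pressure at
body temperature and $P_{H_2O,T_C}$ the chamber vapor pressure (relative
humidity x saturated value). Saturated vapor pressure uses the Antoine
equation with the standard water constants for 1-100 degC
($\log_{10} P = 8.07131 - 1730.63/(233.426 + T)$, $P$ in mm Hg, $T$ in
degC), which agrees with steam-table values to well under 1% over the
physiological range. The factor is validated against an independent
arithmetic evaluation of the same closed form to $10^{-12}$ relative on a
grid of conditions. When body and chamber approach the same temperature
with a saturated chamber the denominator vanishes and the method is
degenerate; this raises a dedicated error rather than returning a huge
factor. Note that *raising* body temperature *lowers* $F$ (the same
breath moves more pressure), which is the physically correct direction.

Airflow is the time derivative of the volume signal (second-order central
difference; optional zero-phase 20 Hz Butterworth low-pass, off by
default since murine breathing lives below ~10 Hz). Defaults mirror
common practice: chamber ~29 degC and humidified (RH 0.9 by default,
configurable), signals at 1,000 Hz.

# Breath segmentation and features

Positive flow is inspiration (invertible by configuration). Breaths are
delimited by signed zero crossings with a hysteresis band of
$\max(3\hat\sigma_n, 0.05\,A_{95})$, where $\hat\sigma_n$ is the robust
per-sample noise SD estimated from first differences
(`mad(diff(flow))/sqrt(2)`) and $A_{95}$ the 95th percentile of
$|flow|$. The MAD term adapts to noise; the 5% floor prevents residual
flow during obstructive apneas (or quantization ripple on noiseless
signals) from being segmented as breaths. Boundaries are refined to the
sample-level zero crossing, and edge breaths at the start/end of a
recording are kept when they contain a complete inspiration.

Per breath we compute Ti, Te, Ttot, tidal volume (trapezoidal integral of
inspiratory flow), maximal inspiratory flow `v_i_max`, the landmark flows
`v_imax1` (peak over the first half of inspiration), `v_i50` (flow at
mid-inspiration, linearly interpolated), `v_imax2` (peak over the second
half), mean inspiratory flow VT/Ti, and instantaneous rate and minute
ventilation. On a 2.5 Hz unit sinusoid at 1,000 Hz these match the closed
forms (150 breaths/min, VT $= 1/(2.5\pi) \approx 0.1273$ mL, mean
inspiratory flow $2/\pi$) to 0.1%.

Respiratory signals are analyzed from **all REM periods** and from NREM
sampled periodically: one 20-s stretch per 30-min block, taken from the
first NREM run of at least 20 s in the block ("first" placement; a
"centered" alternative is available). "First eligible run per block" is
our disambiguation of periodic sampling; the alternative placement exists
precisely because the prose rule underdetermines it.

# Sniffs and inspiratory flow limitation

Sniff-like breaths are excluded before plateau testing using the
inspiration-time Z-score rule with threshold 1.75. The published phrasing
("Z score lower than 1.75" for *short*-duration breaths) is internally
inconsistent — a short breath has a *negative* Z — so the package
implements $Z \le -1.75$ (the short side), with both the threshold and
the side configurable. The Z context is the analysis window, using the
robust center and spread (median/MAD); a degenerate spread yields no
sniffs, and fewer than 10 breaths yields no sniffs with a warning.

A non-sniff breath is inspiratory-flow-limited when (a) near-peak flow
(within the flatness tolerance of `v_i_max`) is first attained at or
before half of inspiration, (b) flow over the middle 50% of inspiration
is flat: trimmed range (5th-95th percentile) divided by `v_i_max` at most
$\tau = 0.10$, and optionally (c) effort keeps rising across the plateau
when an effort channel is present. Before shape testing the inspiration
is denoised with a ~Ti/10 running mean; the trimmed range (rather than
max - min) keeps the statistic robust to residual noise tails and to
smoothing blur at the plateau onset. A pure half-sine has mid-span
variation $1 - \sin(\pi/4) \approx 0.29$ (trimmed: ~0.27), comfortably
rejected at $\tau = 0.10$, while generator clips of severity 0.7 and
above fall well below $\tau$. Whether the original scoring used effort as
a hard criterion is unknown; we default `require_effort_rise = FALSE` and
expose it.

# Sleep staging

Staging is an automated rendering of the standard visual criteria on 5-s
epochs — wake: low-amplitude 10-20 Hz EEG with high EMG tone; NREM:
high-amplitude 2-5 Hz EEG with EMG well below wake; REM: low-amplitude
5-10 Hz EEG with EMG at or below NREM. Band powers come from the epoch
periodogram; EMG RMS is computed after a 30 Hz high-pass. Thresholds are
self-calibrated per recording: wake-like epochs are anchored by dominant
10-20 Hz power, the EMG wake/sleep threshold is the log-midpoint between
the median EMG of wake-like and other epochs (robust when wake is a
minority and the EMG histogram's deepest valley separates REM from NREM
rather than sleep from wake), and the NREM/REM amplitude split is the
geometric mean of the 20th/80th percentiles of sleep-epoch EEG RMS.
Ambiguous epochs inherit the previous stage. Automated staging is an
artifact addition — the original scoring was visual — so externally
scored hypnograms are first-class inputs everywhere and the rest of the
pipeline never depends on the stager.

# Apnea and desaturation scoring

Apneas are scored as a $\ge 90\%$ reduction in airflow lasting two or
more breath cycles or at least 0.7 s at the baseline rate. The printed
"or" is read as *either clause sufficing*
(`min(2 * 60/baseline_rr, 0.7)` s), with a `"both"` mode available — the
alternative reading that 0.7 s merely instantiates "two cycles" at the
observed rate. The airflow reference is the running median `v_i_max` of
the preceding 10 breaths (the source does not define the reference).
Candidate events are maximal runs where $|flow|$ stays at or below 10% of
that reference. Because a segmented breath's end extends to the next
inspiration onset, an apnea gap is "swallowed" by the preceding breath's
expiration; event boundaries are therefore snapped to the preceding
breath's expected expiratory end (its inspiratory end plus the median Te)
and to the next inspiration onset. This removes the naturally quiet
late-expiratory tail from the event and recovers injected event durations
to within ~50 ms. Indices are events per hour of stage time.

Desaturations are drops of at least 4% below a running baseline — the
90th percentile of SpO2 over the preceding 120 s, evaluated on a 10 Hz
decimated copy (desaturation kinetics are far slower than breathing; the
window and percentile are artifact choices, as the source does not define
"the baseline") — lasting at least two local breath cycles. The ODI
counts events beginning in sleep per hour of total sleep (NREM + REM);
wake-time dips are excluded by the definition's denominator.

# HCVR

Minute ventilation is averaged over wake breaths from 60 s after each gas
switch (a fixed transition exclusion per the plateau prescription;
adaptive change-point detection was deliberately not used) to the end of
the level window, and the HCVR is the least-squares slope of plateau VE
on inspired CO2 percentage (0-8%). With exactly two levels the slope is
computed as the exact difference quotient. Wakefulness is enforced via
the hypnogram.

# Calorimetry

Open-circuit rates use the Haldane transformation: with inflow fractions
$F^{in}$ and outflow fractions $F^{out}$,
$H = (1 - F^{in}_{O_2} - F^{in}_{CO_2})/(1 - F^{out}_{O_2} - F^{out}_{CO_2})$,
$VO_2 = \dot V (F^{in}_{O_2} - F^{out}_{O_2} H)$ and
$VCO_2 = \dot V (F^{out}_{CO_2} H - F^{in}_{CO_2})$; RER $= VCO_2/VO_2$
holds exactly on every 11-min bin by construction. Gas rates are reported
in mL/h and converted to mL/min only inside the VE/VO2 and VE/VCO2
coupling ratios, which are dimensionless on matched bins. The generator
inverts these equations in closed form ($H = 1 - a + b$ with
$a = VO_2/\dot V$, $b = VCO_2/\dot V$ per minute), so the noiseless round
trip is exact.

# Exact crossover statistics

Within-animal contrasts use the exact Wilcoxon matched-pairs signed-rank
test (zero deltas dropped, midranks for ties); between-group contrasts
use the exact Mann-Whitney test. Exact two-sided p-values
($\min(1, 2\min(\text{tails}))$, each tail including the observed value)
come from the full null distribution computed by integer dynamic
programming over doubled midranks — arithmetically identical to
enumerating all $2^n$ sign assignments or $\binom{N}{n_a}$ labelings,
including tied data, and feasible up to the documented exact limits
(n = 25 paired, N = 20 pooled). Beyond those, a normal approximation with
continuity and tie correction is used and flagged in the result. The test
suite checks the exact paths against brute-force enumeration oracles and,
on tie-free data, against `stats::wilcox.test`. Boxplot summaries use
linear-interpolation quartiles (`quantile` type 7 — a documented choice,
as no convention was stated) with Tukey 1.5 IQR whiskers.

# The synthetic-recording generator

The generator is first-class, tested code. One random stream is seeded
once per recording and the sub-generators draw in a fixed order
(hypnogram, breath train, apneas, SpO2, EEG/EMG, metabolic), so identical
configurations are bit-identical.

* **Hypnogram** — semi-Markov: gamma bout durations (shape 2) around
  per-stage means (defaults 120/160/60 s for W/NREM/REM), configurable
  transition weights, REM entered only from NREM by convention, 5-s
  epochs.
* **Breath train** — half-sine inspiration scaled to the target tidal
  volume, exponential-decay expiration returning volume to baseline
  exactly; defaults 150 breaths/min, VT 0.15 mL, Ti 40% of the cycle —
  resting values for an obese mouse. Cycle-length jitter is *bounded
  uniform* with SD `rate_cv * period` (default CV 0.1): breathing-rate
  variability is physiologically bounded, and a bounded distribution also
  means the sniff Z rule cannot be triggered by ordinary cycle variation
  (for U(-a, a), $|Z|_{\max} \approx 1.35 < 1.75$). Sniffs scale Ti by
  `ti_scale` (default 0.4). Flow-limited breaths (REM only by default, as
  flow limitation is uncommon in NREM) are hard-clipped at
  $A(1 - 0.35\,s)$ for severity $s$ — at $s = 1$ the entire middle half
  of inspiration sits on the plateau — without volume renormalization, so
  obstructed breaths lose volume as in real obstruction. The effort
  channel is the unclipped inspiratory drive, rising monotonically
  through inspiration ($\propto 1 - \cos$) and amplified by
  `effort_gain` (default 1.5) on flow-limited breaths. Additive white
  flow noise has SD `amplitude_noise_sd` (default 5%) of the nominal
  peak; the volume channel is defined as the running integral of the
  emitted flow, so the integral consistency is exact by construction.
* **Apneas** — Poisson counts per stage (defaults 0/2/20 per hour of
  W/NREM/REM, an obese-phenotype REM predominance), placed on uniformly
  chosen runs of whole breaths (durations ~N(1.2, 0.3) s, floor 0.8 s);
  flow is suppressed to 2% while effort is untouched; overlapping
  placements are re-drawn with bounded retries, then error. Suppressed
  breaths leave the truth table.
* **SpO2** — baseline 96% plus bounded smoothed noise (clamped at 3 SD so
  an event-free trace provably stays within 3 SD of baseline); each event
  drives a lagged (5 s) first-order dip (time constant 1.5 s) of depth
  ~N(6, 0.5)% held for 8 s; the paper gives no SpO2 kinetics, so the
  first-order response is a modeling choice.
* **EEG/EMG** — per bout, band-limited Gaussian noise in the stage band
  with stage-dependent RMS (NREM 3x amplitude) plus broadband background;
  EMG is >30 Hz noise with RMS ordered W > NREM > REM.
* **CO2 challenge** — minute ventilation is scaled toward
  $1 + g\,\%CO_2 / VE_{base}$ with a first-order transition
  ($\tau = 15$ s, so the post-60-s plateau is within 2% of asymptote);
  default gain 7.5 mL/min per %CO2.
* **Metabolic traces** — closed-form inversion of the Haldane equations
  at VO2 90 mL/h, RER 0.85 on the 11-min grid; Poisson activity stream
  (2 beam breaks/min).

What the generator does *not* emulate: movement and bias-flow artifacts,
electrode drift and transients, periodic-breathing oscillations, state
transitions within an epoch, SpO2 probe dropouts, and real EEG spectra
(1/f background, spindles). Passing tests therefore demonstrate that the
pipeline implements its stated rules correctly and recovers known truth
under realistic noise — not that it is robust to every artifact of real
recordings.

# Numerical choices and degenerate inputs

Half-open `[t_start, t_end)` intervals in seconds from recording start;
trapezoidal quadrature for volumes; linear interpolation for `v_i50`;
ties in staging resolved toward the previous epoch; flat-zero flow
segments to an empty breath list rather than an error; degenerate breaths
(VT <= 0) are flagged and never flow-limited; zero metabolic denominators
yield flagged missing values. Exactness claims (RER identity, two-point
HCVR slope, linearity of the pressure conversion) hold to floating-point
associativity, i.e. ~1e-12 relative.

Problem sizes in the tests and acceptance checks — a 1-h recording for
event scoring, 400-s recordings for classifier operating characteristics,
20 seeds for HCVR recovery, 500+ random instances for the exact-test
oracles — were chosen so the whole validation runs comfortably on one
CPU while leaving the statistical checks well-powered.

# Known limitations

* The stager is validated on generator data only; on real signals its
  self-calibration assumes a bimodal EMG and stage-typical spectra, and
  externally scored hypnograms should be preferred.
* The apnea boundary snap assumes breaths are detectable up to the event;
  heavily corrupted flow around an event biases durations.
* EDF import/export is not provided; the native container is JSON +
  delimited text. Proprietary acquisition formats must be converted
  upstream.
* Two-way ANOVA / mixed-effects modeling is out of scope by design; the
  pipeline emits tidy tables ready for standard fitting functions.
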