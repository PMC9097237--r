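---
title: "From balance log to K_leaf: the EFM processing chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From balance log to K_leaf: the EFM processing chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kleaf)
```

## The measurement and its model

In the evaporative flux method (EFM) an excised, transpiring leaf draws
water through its petiole from a reservoir standing on an analytical
balance. The reservoir's weight loss rate is the transpirational flow;
once that flow is steady, leaf hydraulic conductance is

$$K_\mathrm{leaf} = \frac{E}{0 - \Psi_\mathrm{final}}$$

with $E$ the steady area-normalized flow (mmol m^-2^ s^-1^), the
reservoir water at 0 MPa, and $\Psi_\mathrm{final}$ the leaf water
potential at the end of the run (MPa, negative). $K_\mathrm{leaf}$ is
finally rescaled to a 25 °C reference by the water-viscosity ratio
$\eta(T_\mathrm{leaf})/\eta(25)$, removing the purely physical effect of
temperature on flow.

Two facts drive the whole design of this package. First, $E$ is only
defined at steady state, and real flow traces frequently never get there:
they oscillate (stomatal oscillation), decline after a peak, or the run
ends too early. Deciding *whether* a trace is steady is therefore as much
part of the measurement as the flow itself. Second, because
$\Psi_\mathrm{final}$ is typically small in magnitude (above −0.5 MPa),
$K_\mathrm{leaf} \propto 1/|\Psi_\mathrm{final}|$ is steep there: at a
fixed $E$ of 8.7 mmol m^-2^ s^-1^, moving $\Psi_\mathrm{final}$ across
the commonly observed −0.17 to −0.45 MPa range changes
$K_\mathrm{leaf}$ by a factor of 0.45/0.17 ≈ 2.6. Small water-potential
errors produce large conductance errors, which is why the report format
conserves every input alongside the result.

## From weight to flow

`weight_to_flow()` differentiates the cumulative weight series with a
centered rolling OLS window (default 60 s, i.e. ~21 points at the usual
3-s logging interval; windows truncate asymmetrically at the edges so the
trace keeps its length). The 60 s default smooths balance jitter while
leaving 15-min-scale structure untouched. Background evaporation of the
reservoir — about 0.115 × 10^-3^ mmol s^-1^ for an uncovered cylinder,
near zero under wax + humid-chamber prevention — is a property of the
cylinder, not the leaf, so `correct_evaporation()` subtracts it *before*
`area_normalize()` divides by leaf area. Corrected flows below zero are
kept and flagged rather than clipped: they are evidence of a
miscalibrated blank, not noise to hide. With prevention in place the
blank default is 0 and the correction is the identity.

## Segmentation

Steadiness is judged on a piecewise-linear decomposition of flow versus
time. Each candidate segment $[i, j]$ is scored by the negative mean
residual variance of its OLS line fit, $-\mathrm{rss}/n$, and a
segmentation is scored by the sum of its segment scores minus a penalty
$P$ per breakpoint. `dp_segment()` maximizes this objective exactly by
dynamic programming over all segmentations with at least
`min_seg_points` (3) points per segment, using prefix sums so each
candidate segment is scored in constant time (O(n²) overall).
Ties are broken toward fewer segments, then toward a longer
final segment, so output is deterministic.

Numerical choices worth knowing:

* The default penalty is `0.05 * var(flow)`, user-overridable. Scaling by
  the global variance makes classification invariant to rescaling the
  flow. The factor 0.05 was chosen so that the initial rise splits off
  while an oscillating or declining stretch remains *one* long segment.
  That matters because the class-C rule below keys on the duration of the
  last segment: a penalty small enough to shred an oscillation into
  half-period segments would turn every oscillating trace into a
  "too-short last segment" verdict. (The variance scoring itself already
  resists gratuitous splits — each extra segment contributes another full
  residual-variance term — so the penalty's job is only to damp
  noise-driven breaks.)
* Segments shorter than 1 min are deemed invalid (a few outliers
  splitting a real segment) and dissolved by `merge_invalid_segments()`
  into whichever neighbor gives the smaller combined residual variance,
  repeatedly, with refitting.
* All fits use actual timestamps, not sample counts, so irregular
  sampling is handled; durations come from timestamps too.
* Prefix-sum fits are computed on centered series and residual sums are
  clamped at zero, keeping the scores exact to ~10^-9^ relative even on
  perfectly linear input.

## Steadiness classification

`classify_steadiness()` applies, in order:

1. **Class C** — the final segment lasts less than 15 min
   (`steady_min_duration_s = 900`): the plateau, if any, is too short.
2. Otherwise the slope of the trailing 15-min window (~300 points at 3-s
   sampling) is t-tested against zero. **Class D (steady)** if
   p > 0.001 (`slope_alpha`); the trailing window becomes the
   E-extraction window.
3. Otherwise the trace is non-steady with a direction: **class A**
   (oscillating) if the post-rise trajectory is non-monotone, **class B**
   (declining) if it is monotone.

Degenerate conventions in `slope_p_value()`: an exact nonzero-slope line
gives p = 0; a window of identical values gives p = 1.

Two refinements depart from the naive reading of these criteria, both for
statistical rather than cosmetic reasons:

* **Thinned slope test on derived flow.** Flow obtained from weight by
  *overlapping* rolling windows carries moving-average autocorrelation
  over the window width. A naive 300-point OLS t-test on such a series is
  badly anti-conservative on a true plateau: smoothing shrinks the
  estimated residual variance ~20-fold while barely changing the slope
  estimator's sampling variance, inflating the t statistic by a factor of
  about √20 ≈ 4.5, so even a generous significance threshold is crossed
  routinely; autocorrelation-robust standard errors help but remain
  unreliable this far into the tail at this sample size. The classifier
  therefore thins the window to one sample per smoothing window (15 effectively
  independent points for the defaults) before testing, which restores the
  nominal level exactly; the test-suite calibration check measures the
  false-positive rate at 0.001 on 10,000 windows. Directly recorded flow
  (no smoothing recorded on the trace) is tested on all ~300 points.
* **Sub-window slopes for A vs B.** With the default penalty an
  oscillating stretch is one segment, so "sign changes of segment slopes"
  cannot see the oscillation. Non-monotonicity is instead judged on OLS
  slopes of consecutive non-overlapping 2.5-min sub-windows
  (`steady_window_s / 6`) after the rise (first attainment of 90% of the
  fitted span), counting only slopes exceeding twice their standard error
  so plateau noise cannot fake an oscillation; ≥ 2 sign changes means
  class A.

## K_leaf and its normalization

`extract_E()` is the mean flow over the trailing steady window — robust,
and matching the operational "stable for > 15 min" definition — rather
than an extrapolated intercept. `compute_kleaf()` applies the ratio
formula and `normalize_to_25C()` multiplies by
$\eta(T_\mathrm{leaf})/\eta(25)$ using a Vogel-type pure-water
correlation, $\eta = \exp(-3.7188 + 578.919/(T_K - 137.546))$ mPa s
(coefficients as tabulated in Reid, Prausnitz & Poling, *The Properties
of Gases and Liquids*). Published pure-water correlations agree to well
under 0.5% over 15–40 °C, below EFM measurement error, so the choice of
correlation is immaterial; it is exposed as `water_viscosity()` for
inspection. `hydrostatic_pressure_kPa()` quantifies the ρgh pressure of
reservoir-to-leaf height offsets: 2 cm of water is 0.196 kPa, three
orders of magnitude below typical driving forces, which is why small
offsets are tolerable. (Note the unit: ρgh for 2 cm is 196 Pa; the
package reports kPa.)

## The synthetic generator

`simulate_flow()` draws traces from

$$\mathrm{flow}(t) = E\,(1 - e^{-t/\tau})\,(1 + a \sin(2\pi t/T_\mathrm{osc}))\,
  e^{-r\,\max(0,\,t - 5\tau)} + \varepsilon_t$$

with i.i.d. (optionally AR(1)) Gaussian noise, and labels each trace with
the class it *should* receive, derived analytically from the parameters:
declining traces (r > 0) are B; an oscillation whose noise-free
trailing-window slope is detectable by the t-test (expected |t| above the
α = 0.001 critical value, with the sinusoid's own lack-of-fit counted in
the residual variance) is A; a plateau reached by $t = \tau\ln 50$
(within 2%) with ≥ 15 min to spare is D; anything else is C. The peak for
the decline term sits at $5\tau$, where the rise is > 99% complete.
`flow_to_weight()` integrates flow (trapezoid rule) into a balance log so
the whole chain, including `weight_to_flow()`, can be tested; the
round-trip is exact for constant flow and accurate to < 1% of the plateau
away from the trace edges, where one-sided windows meet the rise's
curvature.

Defaults emulate rice under 1000 µmol m^-2^ s^-1^ PARa: plateau
E = 8.75 mmol m^-2^ s^-1^, ψ_final = −0.31 MPa, ~25 cm² leaves, 1-h runs
logged every 3 s, noise SD 0.175 (2% of plateau). Oscillation amplitude
and period have no published values; the illustrative defaults (15% of
plateau, 10–15 min periods) sit in the range reported for stomatal
oscillation. What the generator does **not** emulate: genuinely
autocorrelated biological flow fluctuation beyond AR(1), drifting
environments, balance artifacts (taring jumps, resolution quantization),
or any feedback between flow and leaf water status. Passing the simulated
checks therefore demonstrates the *algorithms* behave as specified, not
that every field trace will be classified the way an expert would.

## Validation problem sizes

The test suite validates the chain at sizes chosen to be decisive yet
quick: exhaustive-enumeration equivalence of the dynamic program on 200
random traces of ≤ 15 points; classification against ground truth on a
200-trace mix (100 steady, 40 declining, 30 oscillating, 30 truncated) at
2% noise; end-to-end K_leaf recovery from 50 simulated weight logs
(within 5% of truth); and t-test calibration on 10,000 white-noise
windows of 300 points. One caveat surfaced by this exercise: a trace must
either end a plateau short of 15 min *after a sharp rise* or simply end
early to be a reliable class C — when a slow smooth rise fills most of
the record, the optimal last segment absorbs the curved tail and the
trace is (correctly, by the stated criteria) judged B rather than C.
Borderline last-segment durations near 900 s are inherently coin flips.

## Limitations

* The steadiness taxonomy follows fixed thresholds (15 min, α = 0.001);
  no attempt is made to estimate *how* unsteady a class-A/B trace is.
* The blank-evaporation correction is a constant offset; temperature- or
  humidity-dependent evaporation during a run is out of scope.
* $\Psi_\mathrm{final}$ is an input here; pressure-chamber practice and
  equilibration protocols are the operator's responsibility.
* Per-leaf conductances are computed independently; treatment-level
  statistics (ANOVA, multiple comparisons) are left to standard tools.
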