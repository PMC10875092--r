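---
title: "Quantifying stomatal wrong-way responses to VPD steps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying stomatal wrong-way responses to VPD steps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6, fig.height = 4)
library(stomavpd)
```

## The measurement problem

When the vapor pressure deficit (VPD) around a leaf is stepped up — say by
dropping chamber relative humidity from 70% to 15% at constant 22 °C —
stomatal conductance ($g_{sw}$) does something initially counter-intuitive:
it transiently *rises* before closing down to a new steady state. This
"wrong-way response" (WWR) is hydropassive: neighboring epidermal cells lose
turgor faster than the guard cells, epidermal backpressure drops, and the
pore gapes open. Active processes then take over — turgor is restored in the
pavement cells, and guard cells lose osmolytes, driving closure. The net
result is a characteristic overshoot-then-relaxation trajectory whose shape
carries information about the signaling machinery of the genotype under
test.

stomavpd turns a per-minute $g_{sw}$ log around such a step into four
response statistics:

1. **WWR amplitude** — peak $g_{sw}$ after the step minus $g_{sw}$ at time
   zero (mol m⁻² s⁻¹);
2. **WWR duration** — how long the overshoot lasts (min), with a criterion
   that depends on where the new steady state sits relative to baseline;
3. **cumulative water loss during the WWR** — transpiration integrated over
   the usable part of the overshoot (mol m⁻²);
4. **steady-state VPD response** $\Delta g_{ss} = g_{t0} - g_{ss,post}$ —
   positive for net closure; a magnitude within the equality band marks a
   VPD-hyposensitive steady state.

A complication drives much of the design: gas-exchange systems compute
conductance from chamber mass balance, and an abrupt humidity setpoint
change transiently corrupts that computation while the chamber
re-equilibrates. Runs with rigid artificial leaves of known, constant pore
geometry show the corruption is confined to roughly the first three minutes
after the step, after which the reading returns to the pre-step level. The
pipeline therefore masks the half-open window $[0, \text{mask})$ minutes
(default 3) and no masked record ever contributes to any metric.

## Environmental arithmetic

Saturation vapor pressure uses the Tetens approximation
$e_{sat}(T) = 0.6108\,\exp\!\left(\frac{17.27\,T}{T + 237.3}\right)$ kPa,
the standard empirical form in leaf micrometeorology. Air-basis VPD is
$e_{sat}(T)(1 - RH/100)$; the leaf-to-air form replaces the saturation term
with $e_{sat}(T_{leaf})$. Chamber protocols conventionally print VPD at one
or two decimals; `report_vpd()` **truncates toward zero** rather than
rounding, because that is the convention under which the package's three
reference chamber conditions — 22 °C/15% → 2.2 kPa, 22 °C/80% → 0.52 kPa,
28 °C/35% → 2.45 kPa — are all reproduced simultaneously (rounding would
give 0.53 and 2.46). Full floating precision is kept internally; truncation
happens only at the reporting boundary. One caveat worth knowing: published
low-VPD figures for nominally identical conditions sometimes disagree at
the second decimal (an air-basis computation at 22 °C/70% gives ≈0.79 kPa,
while 0.65 or 0.75 may be quoted, plausibly reflecting a leaf-temperature
basis or transcription slips); none of those contested values is used as a
reference here.

```{r vpd}
report_vpd(vpd_air(air_state(22, 15)), 1)
report_vpd(vpd_air(air_state(22, 80)), 2)
report_vpd(vpd_air(air_state(28, 35)), 2)
```

## Steady-state detection and the four statistics

Plateaus are certified, not assumed: `detect_steady_state()` slides a
window of `plateau_window_min` (default 10 min) over one side of the step
and accepts a window when its least-squares slope magnitude is at most
`slope_tol` (default 0.001 mol m⁻² s⁻¹ min⁻¹) and its coefficient of
variation is at most `cv_tol` (default 5%). The *latest* qualifying window
wins, so slowly relaxing tails bias the level as little as possible; the
plateau level is the window mean. When no window qualifies the error
carries the best candidate's diagnostics, because "no steady state" is
usually a protocol problem (trace too short, leaf still drifting) the user
needs to see.

$g_{t0}$ is the pre-step plateau level — the mean of the qualifying
pre-window — not the single sample logged at $t=0$, which makes the
baseline robust to one noisy record while agreeing with the $t=0$ reading
exactly on steady pre-step traces.

The **equality band**, used everywhere "equal to baseline" must be made
operational, is $\max(2\%\ \text{of}\ g_{t0},\ 2\,SE_{pre})$ with
$SE_{pre}$ the pre-plateau standard error. The duration criterion is then a
trichotomy on the post-step plateau level:

* below $g_{t0} - \text{band}$: **return_to_baseline** — the first
  post-mask time $g_{sw}$ crosses $g_{t0}$ from above, linearly
  interpolated between the bracketing per-minute samples (interpolation is
  used *only* for crossing times, never for sums). If baseline is never
  re-attained before the trace ends, that is an error, not a guess.
* above $g_{t0} + \text{band}$: **reach_new_steady_state** — the first
  post-mask time the trace enters the band around the new level and stays
  inside it for at least `settle_persist_min` (default 3) consecutive
  minutes.
* within the band: **degenerate** — the first time the trace re-enters and
  stays within the band around $g_{t0}$, which is 0 for a trace that never
  left it (the artificial-leaf case); if no such re-entry resolves, the
  post plateau's window start is used. Exactly one of the three fires for
  any resolvable trace.

The amplitude search window runs from the mask edge to
$\min(20\ \text{min}, \text{first baseline crossing})$ — overshoot
durations in this assay class are on the order of 9–17 min, and capping the
search prevents late noise excursions after closure from masquerading as
the peak. Amplitudes are reported signed: when the true peak falls inside
the artifact mask the measured amplitude can be ≤ 0, and clipping it would
hide exactly the cases a reader should be warned about (they are flagged
`no_resolvable_overshoot` instead).

Cumulative water loss is a left Riemann sum: unmasked records with
$\text{mask} \le t < \text{duration}$ each contribute $E \cdot \Delta t$
with $\Delta t$ the native sampling interval in seconds, so a 10-min
duration with a 3-min mask integrates exactly 7 minutes of transpiration.
Gaps up to ~20% of the WWR window are tolerated (the sum simply uses the
records present); no values are ever interpolated into a sum.

## The synthetic trajectory generator

Real deposited traces are not available for this assay, so the package
ships a first-class generator whose structure mirrors the three-component
view of the VPD response. For $t \ge 0$:

$$g(t) = g_{new} + (g_0 - g_{new})\,e^{-t/\tau_{close}}
       + A\,\frac{t}{\tau_{rise}}\,e^{\,1 - t/\tau_{rise}}
       + h\,e^{-t/\tau_{art}}\,\mathbf{1}[t < 3] + \varepsilon(t)$$

with $\varepsilon \sim N(0, \sigma^2)$ i.i.d. The functional forms are the
package's own minimal construction — the conceptual model is qualitative —
chosen so each component has one interpretable parameter: the gamma-like
pulse is normalized to attain its maximum $A$ exactly at $t = \tau_{rise}$
(hydropassive overshoot), a single $\tau_{close}$ subsumes turgor
restoration and osmotic closure (the two overlap in time and are not
separately identifiable from $g_{sw}$ alone), and $g_0 - g_{new}$ is the
steady-state response. The artifact term is confined to $t < 3$ min by
construction, emulating what artificial-leaf controls show. Transpiration
is derived as $E = g_{sw} \cdot VPD / 101.3$ at fixed atmospheric pressure,
ignoring boundary-layer conductance: only relative and cumulative $E$
behavior is exercised downstream.

Default conditions follow the measurement protocol the package targets:
per-minute sampling, 15 min of pre-step record, 45 min post-step (60 in the
validation runs so slow kinetics settle), a 22 °C chamber stepped from 70%
to 15% RH. Archetype parameter sets express the qualitative response
classes seen across genotypes — `wildtype` (g₀ = 0.20, g_new = 0.12,
A = 0.05, τ_rise = 3, τ_close = 8), `hyposensitive_steady_state`
(g_new = g₀), `slow_kinetics` (τ_close = 25), `reduced_wwr` (A = 0.015),
`artificial_leaf` (constant true conductance) — calibration choices in the
plausible range of published response axes, **not** measured values for any
real genotype. The artificial-leaf protocol default (25 °C, 73.2% → 18% RH)
reproduces a ≈0.85 → 2.6 kPa VPD step under Tetens. Noise defaults to
sd 0.002 mol m⁻² s⁻¹, a realistic per-minute instrument scatter;
validation sweeps also use 0.005 to stress the estimators.

```{r sim, fig.alt = "Simulated wildtype conductance trace with masked artifact window"}
tr <- simulate_trace(trace_params(seed = 42))
m <- extract_wwr(tr)
tidy(m)[, c("amplitude", "duration_min", "cumulative_water_loss", "delta_gss")]
plot_wwr(tr, m)
```

What passing tests on these simulations do and do not show: they establish
that the extractor recovers the generative truth to within discretization
and sampling-theory error *under the model's assumptions* — additive
Gaussian noise, an artifact strictly confined to the mask window, a single
smooth overshoot, no drift. Real traces can violate all four (multiplicative
noise at high flow, artifacts outlasting 3 min on other instruments, double
overshoots, circadian drift), which is why the mask length and every
tolerance are configuration, not constants.

Two separability caveats are worth stating precisely. First, the measured
amplitude estimates the attainable maximum of the *composite* curve: the
closure component removes about
$(g_0 - g_{new})(1 - e^{-\tau_{rise}/\tau_{close}})$ from the pulse at its
peak, so the injected $A$ is recovered exactly only when the steady-state
response is absent or $\tau_{close} \gg \tau_{rise}$. Second, the pulse's
tail decays slowly, so a post-plateau taken at 35–45 min still carries a
small ($\sim 10^{-4}$) remnant; validation bounds account for both effects
analytically rather than pretending they are zero.

## Statistics and the cultivar screen

Genotype-vs-reference comparisons use the two-sample t-test, Welch's
unequal-variance form by default (pooled available): at n = 3–5 plants per
genotype, assuming equal variances buys little and risks much. Significance
is coded `*` p < 0.05, `**` p < 0.01, `***` p < 0.0001 — the `***`
cutpoint implemented exactly as printed in the caption convention this
mirrors, although 0.001 is the more common choice; the thresholds are
configurable. No multiple-testing correction is applied by default,
matching per-comparison reporting practice; Holm adjustment is available.

The porometer screen takes spot readings (nominally eight per plant, a few
plants per cultivar), aggregates **per plant first** so that n counts
plants, and computes the percent reduction
$100\,(g_{before} - g_{after})/g_{before}$ after a sustained high-VPD
exposure. A cultivar is `hyposensitive` iff its reduction is strictly less
than 75% — the boundary itself classifies as `sensitive`. Whether percent
change should be computed per plant and then averaged instead is a genuine
judgment call; percent change on the panel means is the default because the
before/after panel means are the quantities a porometer survey reports, and
computing per-plant percent changes from the raw readings for the
alternative remains a one-line `dplyr` summary.

## Numerical conventions, in one place

* Mask window half-open, $[0, \text{mask})$; the record at $t=\text{mask}$
  is the first usable one. Masking is idempotent and pre-step records are
  never masked.
* Times are re-based so the step is $t = 0$; all definitions are phrased
  relative to it.
* Crossing and settling times by linear interpolation between bracketing
  samples; cumulative sums from raw samples only, left-endpoint rule.
* Truncation (not rounding) at the VPD reporting boundary; full precision
  internally; metrics JSON serialized at 17 significant digits so
  write/read round-trips are bit-exact.
* Degenerate cases are labelled, not silently coerced: masked peak →
  flagged non-positive amplitude; duration ending inside the mask → zero
  water loss with a flag; constant trace → degenerate criterion with zero
  duration.
* Seeds: every stochastic path (trace noise, panel seed derivation) is
  reproducible from one integer; panel per-trace seeds are drawn
  deterministically from the panel seed.

Validation problem sizes (chosen to make sampling-theory bounds sharp while
keeping the suite quick): 100-seed artificial-leaf runs at noise sd 0.002;
200 replicates per archetype at noise sd 0.005 for recovery error; a 3×3×3
sweep of $(A, \tau_{rise}, \tau_{close})$ against a dense-grid (0.001 min)
brute-force oracle; 400 replicates for the noise-scaling check.

## Known limitations

* The three-component form is a phenomenological summary, not a hydraulic
  model: no epidermal water-relations PDE, no ABA dynamics, no
  pore-geometry diffusion. Parameters are descriptive timescales.
* Oscillatory post-step dynamics (seen in some monocots) violate the
  single-overshoot assumption; the extractor will report the first
  crossing/settling and flag nothing — inspect `plot_wwr()` output when
  oscillations are plausible.
* The equality band couples hyposensitivity classification to pre-step
  noise via $SE_{pre}$; very quiet traces get a band floored at 2% of
  baseline.
* `li6800_like` parsing targets the *shape* of vendor console logs
  (preamble, group header, names, units, data) rather than any exact
  firmware export, and binary vendor files are out of scope.
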