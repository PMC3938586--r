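---
title: "Calibrating populations of action-potential models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating populations of action-potential models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apopcal)
```

This vignette is the package's account of the science it implements: the
model, the measurement definitions, the calibration and ranking
procedures, and the choices made where the method leaves room for
interpretation. It states no numbers that the test suite and
`scripts/acceptance.R` do not themselves compute.

## The pipeline in one paragraph

Six conductance scaling factors — transient outward (to), rapid and slow
delayed rectifier K⁺ (Kr, Ks), inward rectifier K⁺ (K1), L-type Ca²⁺
(CaL) and Na⁺/K⁺ pump (NaK), each a dimensionless multiplier with 1.0 the
control model — span a full factorial grid (default five levels per axis:
0.70, 0.85, 1.00, 1.15, 1.30, i.e. 0, ±15%, ±30%; 5⁶ = 15,625 parameter
sets). Every set is paced to steady state at cycle lengths of 400, 600 and
1,000 ms, ten AP and Ca²⁺-transient biomarkers are measured on the final
beat, and the population is calibrated by keeping the sets whose APD₅₀
*and* APD₉₀ fall inside experimentally derived rabbit epicardial ranges at
each cycle length. Downstream, waveform goodness-of-fit (NRMSD) ranks
which biomarker combinations best identify the sets closest to control,
and clutter-based dimension reordering projects the 6-D grid into a 2-D
image whose optimal stack order reveals the relative importance of the
conductances.

## The bundled cell model

The package ships a phenomenological cell model, not a biophysical one:
a closed-form waveform generator whose biomarkers have known analytic
values, so that every pipeline stage — pacing, steady-state detection,
biomarker measurement, calibration, selection, stacking — is testable
against independent oracles. Detailed ODE models (the natural targets of
the pipeline) plug in through the cell-model contract documented in
`?toy_cell_model`: an `init()`/`advance()` pair that must be
deterministic, composable (advancing twice by *n*/2 equals advancing once
by *n*), resample solver output onto the uniform `dt` grid, and declare
its solver tolerances (the reference pacing protocol used relative and
absolute tolerances of 1e-7 and 1e-9).

The model's steady-state APD₉₀ is

$$\mathrm{APD}_{90}^{\infty}(s, \mathrm{CL}) =
  \left(A - B\,e^{-\mathrm{CL}/\tau_{\mathrm{CL}}}\right)
  \prod_{i} s_i^{c_i}$$

with $A = 230$ ms, $B = 150$ ms, $\tau_{\mathrm{CL}} = 600$ ms and signed
exponents $c_{\mathrm{CaL}} = +0.30$, $c_{\mathrm{Kr}} = -0.20$,
$c_{\mathrm{K1}} = -0.15$, $c_{\mathrm{Ks}} = -0.10$,
$c_{\mathrm{NaK}} = -0.10$, $c_{\mathrm{to}} = -0.05$. The signs encode
the physiology (raising a repolarising conductance shortens the AP;
raising the L-type Ca²⁺ conductance prolongs it) and the magnitudes set a
deliberate importance ordering that the dimension-reordering stage should
recover. APD₅₀ is a fixed fraction $r = 0.78$ of APD₉₀. Rate adaptation
is geometric: beat $n$ has
$\mathrm{APD}_{90}(n) = \mathrm{APD}_{90}^{\infty}(1 + \delta\rho^{n-1})$
with $\delta = 0.08$, $\rho = 0.90$, so consecutive-beat differences
shrink monotonically and the steady-state detector provably terminates.

Within a beat the membrane potential rises linearly from
$V_{\mathrm{rest}}$ to $V_{\mathrm{peak}} = +35$ mV over
$t_{\mathrm{up}} = 2$ ms, then follows a falling sigmoid whose midpoint is
APD₅₀($n$) and whose steepness is set so the 90% crossing lands at
APD₉₀($n$), minus a notch term proportional to $s_{\mathrm{to}}$ (gamma
shape, amplitude 6 mV, time constant 12 ms). The resting potential
shifts with the inward-rectifier and pump scalings,
$V_{\mathrm{rest}} = -85 - 3\ln s_{\mathrm{K1}} - \ln s_{\mathrm{NaK}}$
mV. The calcium transient is a double exponential (rise 15 ms, decay
0.35·APD₉₀∞) normalised so its peak equals the diastolic level plus an
amplitude $0.45\, s_{\mathrm{CaL}}\, s_{\mathrm{NaK}}^{-0.25}$ µM; the
diastolic level itself is $0.20\, s_{\mathrm{CaL}}^{0.5}\,
s_{\mathrm{NaK}}^{-0.3}$ µM. All constants are defaults of
`toy_constants()` and can be overridden individually, including from the
`toy_model:` block of a YAML run configuration.

The constants were chosen once so that the control parameter set lands
inside the physiological APD ranges at all three cycle lengths — the
calibration stage then has non-trivial pass/fail structure over the grid
— and are not tuned thereafter.

**What the generator does and does not emulate.** It reproduces the
features the pipeline's measurements depend on: an upstroke, a notch, a
plateau, sigmoidal repolarisation, a rising-and-decaying calcium
transient, monotone log-linear conductance dependence of the durations,
cycle-length dependence, and a geometric approach to steady state. It
does not reproduce ionic mechanisms: no reconstruction of individual
currents, no alternans or other complex rate dependence, no stochastic
gating, no drug or temperature effects, and no interaction terms between
conductances (the log-linear form is exactly additive in log-space).
Consequently, green tests demonstrate that the *pipeline machinery* is
correct under realistic waveform shapes; they say nothing about how any
biophysical model will calibrate. In particular the toy population
calibrates permissively (most of the grid passes), whereas detailed
models are known to calibrate much more sharply; sharper structure enters
here only through the grid presets.

## Pacing and steady state

`run_paced()` paces for 1,000 s (configurable `max_time`), then compares
the last two full beats: the cell is at steady state when every sample of
the final AP differs from the corresponding sample of the previous AP by
less than 5% of the final AP's amplitude (max − min of V_m). Choices
worth stating:

* The criterion is applied to **V_m only**; the calcium transient is not
  checked. This is the literal reading of "comparing corresponding data
  points from the last two APs".
* Beats are aligned at stimulus onset and compared on the uniform `dt`
  grid (default 1 ms). Where a model integrates adaptively, its adapter
  resamples before comparison.
* If the criterion fails at `max_time`, pacing extends in increments of
  100 beats up to twice `max_time`; a still-failing set is flagged
  `steady = FALSE` rather than erroring, and such records are carried in
  the sweep table but always fail calibration.
* An AP that does not repolarise within its cycle (APD₉₀(n) ≥ CL) is a
  *degenerate* parameter set: flagged per record, never an abort, so a
  sweep over the full grid always completes.

## Biomarker definitions and numerical choices

All derivatives are first-order forward differences on the uniform grid,
attributed to the left sample; the dV/dt_max tie-break is the earliest
time. Threshold crossings (APD₅₀/₉₀, CTD₅₀/₉₀) are located as the first
*downward* crossing after the relevant reference point (maximal upstroke
for voltage, maximal rate of rise for calcium) and linearly interpolated
between the bracketing samples — without interpolation every duration
would be quantised to `dt`. Durations run from the reference point to the
crossing. V_rest and diastolic Ca are the values at the first sample of
the beat window (immediately before the stimulus); for the monotone toy
waveform this equals the diastolic minimum, and adapters for models with
diastolic drift can override the convention.

The plateau potential deserves its own paragraph because the customary
verbal definition — the point after the activation spike at which dV/dt
reaches the smallest absolute value less than or equal to zero — is
ambiguous on sampled data. The package reads it as: among samples between
the upstroke and the steepest repolarisation point (the global minimum of
dV/dt), take the first with the smallest |dV/dt| among those with
dV/dt ≤ 0. Restricting the window excludes the fully repolarised tail,
where |dV/dt| → 0 would otherwise always win; on a notched AP the chosen
point is the notch recovery. A purely local-minimum rule was rejected
because discrete sampling can step over the local pattern entirely,
making the result depend on the sampling phase. If no candidate exists
(monotone repolarisation), the value falls back to V at 20 ms after the
upstroke and the record is flagged `v_plat_fallback`.

Undefined biomarkers (a threshold never reached, a non-recovering
transient) are `NA`, retained in the table, and fail calibration.

## Calibration

Bounds are **inclusive** ("within the range" includes its endpoints) and
a record passes only if steady, non-degenerate, and both APD₅₀ and APD₉₀
are defined and in range. Intersections across cycle lengths are exact
set intersections on the scale vectors, keyed by sorted CL tuples.

When a conductance window yields no physiological sets, the procedure is:
extend the APD ranges by ±10% (`extend_apd_ranges()`; the default scales
each bound, lower ×0.9 and upper ×1.1 — the alternative reading, widening
about the interval midpoint, is available via `about = "midpoint"`),
re-filter, and shift each conductance's five-level window along the trend
of the near-miss passers. `propose_expanded_grid()` renders "following
the underlying trend" concretely: per axis, the mean level-index offset
of the passers from the window centre, times a gain (default 2), rounded,
gives the number of 0.15-wide steps to translate the window. The
published expanded search window is also shipped verbatim as
`expanded_mahajan_grid()`, so the published search is reproducible
independently of this rule.

## Goodness-of-fit ranking

NRMSD between a candidate and the reference signal is the root mean
square of the pointwise differences divided by the reference's range,
making voltage and calcium scores dimensionless and addable. The
waveform-based selection ranks by combined V-plus-Ca NRMSD and keeps the
`target_count` (default 250) smallest, breaking cutoff ties by the
canonical scale-tuple order. The biomarker-based selection sweeps the
acceptable percentage difference θ upward from zero in steps of 0.1
percentage points (the sweep granularity is otherwise unspecified) and
keeps the θ whose match count is closest to the target, resolving ties
toward the smaller, stricter θ. Records with an undefined biomarker in
the combination never match. Percentage overlap between the two
selections uses the NRMSD-selected set as the denominator — NRMSD is the
stated gold standard — with `"a"`, `"union"` and `"mean"` denominators
available because the bare phrase "percentage overlap" does not fix one.
Which universe of parameter sets enters the selection (full grid versus
calibrated subset) is likewise left open by the phrase; the package
defaults to the full population and lets the caller pass any subset.

## Dimensional stacking and reordering

A stack order assigns the six conductances to six slots: (x, y) pairs at
low, medium and high nesting order. The pixel of a grid point has column
index i(x_high)·L² + i(x_mid)·L + i(x_low) over 0-based level indices
(rows likewise), row 0 at the bottom, so the all-minimum point is the
bottom-left pixel — a bijection between the 15,625 grid points and the
125×125 image, tested by round-trip. The clutter cost sums |difference|
over horizontally and vertically adjacent pixel pairs, each unordered
pair counted **once**; per-pixel 4-neighbour summation would double every
pair and order solutions identically, so the single-count convention is
chosen for reproducibility of the reported numbers. Pairs touching a
masked pixel (a grid point with no value, e.g. non-steady) contribute
zero rather than a penalty. Values are stacked raw, not normalised; cost
magnitudes are therefore comparable only within one biomarker.

Optimisation is exhaustive over all 720 slot assignments — tractable at
this size and free of any unstated search heuristic. Reversing all three
(x, y) pairs transposes the image and cannot change the cost, so minima
come in pairs; ties, including those pairs, resolve to the
lexicographically smallest slot tuple, making the reported order
canonical. Membership stacks (which CL subsets a point passes at) use a
fixed unoptimised order by convention so stacks of different biomarkers
remain directly comparable.

## Sweep execution, persistence, interfaces

Sweeps are keyed by the canonical grid enumeration — axes ordered to, Kr,
Ks, K1, CaL, NaK with the last axis fastest — so results are independent
of worker count and scheduling: the parallel path (forked workers via
`parallel::mclapply`) splits the grid into deterministic chunks and
reassembles them in order, and the serial and parallel biomarker tables
are byte-identical on disk. The sweep store is a directory of plain text:
the biomarker table as CSV with doubles written as `%.17g` (which
re-parses to the identical double, so save → load → save reproduces the
file exactly) and a JSON sidecar carrying the format version, cycle
lengths, `dt` and grid levels; loading a store with a different format
version is an explicit error. Run configurations round-trip through YAML.
A thin command-line wrapper (`inst/cli/apopcal`) exposes `sweep`,
`calibrate`, `fitrank`, `cbdr` and `report` over the same functions.

## Problem sizes used by the tests

The test suite and the acceptance script run the study-scale
configuration where it is the point — the full 15,625-set sweep at all
three cycle lengths for calibration and APD-recovery checks, and a full
single-CL sweep twice for the serial/parallel equivalence check — and
scale down where the property is size-independent: stack-order
optimisation is cross-checked against an independently written
brute-force enumeration on two- and three-level grids (64 and 729
points), where the oracle remains fast, and selection-logic fixtures use
50-point populations with hand-computable scores. At 1 ms sampling the
full three-CL sweep takes on the order of half a minute on one core.

## Known limitations

* The bundled model is phenomenological; conclusions about biophysical
  mechanisms require an external ODE model behind the contract.
* Dimensional stacking as implemented requires equal level counts per
  axis and exactly six axes; rectangular or higher-dimensional stacking
  is out of scope.
* NRMSD against noisy experimental recordings is not supported — the
  metric is known to be poorly suited to that use; the intended reference
  is always a simulated control trace.
* The steady-state rule inspects V_m only; a model with slow calcium
  accumulation could pass it while Ca²⁺ is still drifting.
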