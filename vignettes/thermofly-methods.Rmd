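---
title: "ThermoFly methods: models, conventions and design choices"
author: "ThermoFly authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ThermoFly methods: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ThermoFly)
```

ThermoFly analyzes three linked behavioral readouts of flies held at
controlled temperatures: per-minute locomotor counts from activity
monitors, sleep scored from those counts, and the spatial distribution of
flies on a thermal gradient. This vignette documents the models behind
each step, the parameters that matter, and the choices made where the
design was genuinely open.

## The activity container and its clock

An `ActivityExperiment` stores counts on a gapless one-minute grid (rows)
per fly (columns). Two clocks coexist: `minuteIndex` (linear time since
recording start) and `minuteOfDay` (0–1439, anchored to the recording
start clock). All daily aggregates are computed on `minuteOfDay`,
averaged over the recorded days. This makes the two standard splits exact
partitions even though both cross midnight in linear time:

* first/second half of the day: 02:00–14:00 vs 14:00–02:00, bracketing
  the morning and evening activity peaks respectively;
* daytime/nighttime: the lights-on window (default 08:00–20:00, a
  12-h/12-h LD cycle) vs its complement.

The invariant `totalDaily = firstHalf + secondHalf = dayTotal +
nightTotal` therefore holds exactly per fly, and the test suite asserts
it for every simulated fly.

The protocol defaults — drop 2 acclimation days, analyze 3 whole days
recorded at 1-min resolution — are encoded as the defaults of
`pipelineConfig()`, so an empty configuration reproduces the standard
design. No timezone or DST logic exists: recordings are
constant-condition incubator runs.

**Instrument-invalid minutes.** Monitor files may flag rows with a
hardware status code. Flagged minutes are retained in the container but
marked, and analysis excludes them: a beam-break count of zero cannot be
read as immobility when the hardware was in error. A recorded day with
more than 5% invalid minutes is dropped whole; the threshold is an
artifact decision (it only affects recordings with substantial hardware
trouble, which deserve manual review anyway). An optional dead-fly filter
(`filterDeadFlies()`) removes flies silent over their entire final day;
it is off by default because excluding moribund animals from activity
averages is a protocol decision, not a computation.

## Sleep scoring

Sleep is a maximal run of at least `minBout` consecutive zero-count valid
minutes; `minBout` defaults to 5, the melanogaster convention. Runs
touching the recording boundaries are scored if long enough (no censoring
correction). Bouts are detected on the undivided multi-day series; a bout
spanning midnight or a light transition is one event, while its minutes
are attributed to day or night individually. This preserves minute
conservation (sleep + wake minutes = 1440 per fly-day) and avoids
double-counting events. Consequently `nBouts` (bouts/day) can be
fractional — an uninterrupted 3-day sleep is 1/3 bout per day — and
`nBouts * meanBoutLength = totalSleep` holds on the undivided window.

`minBout` is exposed prominently because the 5-min rule was established
for a highly active species; for species whose awake counts are low, a
zero-count minute is weak evidence of immobility and scored sleep
inflates. The synthetic panel shows this directly: its least active
profiles accrue scored sleep beyond their configured sleep fraction,
which is a realistic property of the rule, not a bug in the scorer. The
scorer itself is verified exactly against an independent
exhaustive-window oracle on 1,000 random traces.

## The synthetic generator

Because raw recordings for multi-species comparisons are rarely
deposited, the generator produces data with precisely the structure the
analyses assume, so every stage can be tested against known truth.

Per fly, a two-state alternating renewal process gates an inhomogeneous
Poisson count process:

* **Bouts.** Wake bouts are geometric with support ≥ 1 min; sleep bouts
  are 5 min plus a geometric remainder, so their support respects the
  scoring rule and the configured mean is exact. Geometric (memoryless,
  minute-resolution) lengths are the simplest process consistent with
  run-length scoring; heavy-tailed bouts are deliberately out of scope.
  The initial state is drawn from the stationary wake probability
  `wake/(wake + sleep)`; the residual-length transient this ignores is
  negligible over three days and is absorbed by the Monte-Carlo
  tolerances in the tests.
* **Rate.** While awake the Poisson rate is `tpcScale(T) · gate(t) ·
  (baseline + morning(t) + evening(t))`, zero while asleep. The two
  peaks are circular Gaussians on `minuteOfDay` (wrapped at 1440 min, so
  a peak near midnight is well-defined), centered by default at 08:30
  and 19:30 — just after lights-on and before lights-off. `gate(t)` is 1
  in light and a species `nightAttenuation` factor in dark. `tpcScale`
  is a Gaussian thermal performance curve normalized to 1 at the
  species' optimum. Counts are Poisson; overdispersion is not modeled
  (no data to calibrate it against).
* **Gradient preference.** Each fly's latent temperature is uniform on
  14–32 °C with probability `uniformFraction` (the fly ignores the
  gradient), otherwise Normal(`prefTemp`, `prefSpread`) truncated to the
  field. The truncated-Normal/uniform mixture is the smallest family
  that reproduces both sharp preference peaks and flat or cold-piled
  distributions. Latent temperatures are inverted through the probe
  calibration to positions.

`expectedDailyActivity()` gives the closed-form expectation (rate
integral × stationary awake fraction) used as the independent oracle for
Monte-Carlo checks.

**The 11-species panel.** `makeSpeciesPanel()` fixes eleven named
profiles spanning the qualitative diversity reported for the classic
sequenced *Drosophila* species: a 10× range in baseline rate and in
configured expected daily activity at 23 °C (most active
melanogaster-like ≈ 1650 counts/day down to erecta-like ≈ 165); sleep
fraction strictly anti-ordered with activity; evening- vs
morning-dominant peak ratios; thermal optima from 19 to 27.5 °C with a
near-flat melanogaster curve (breadth 8 °C); and preferences from sharp
(spread 1.5 °C) through broad (4.5 °C) to cold-piled profiles with 30%
gradient-ignoring flies. Peak heights were calibrated once against the
closed-form expectation to realize the configured 10× activity fold; no
published within-species variance exists, so dispersion comes solely
from the Poisson/renewal process. What the generator does *not* emulate:
social or feeding effects, aging, developmental carry-over, nocturnal
consolidation of sleep (bout placement is homogeneous in time), and
overdispersed counts. Tests passing on this generator therefore validate
the computations and their contracts, not any biological claim about
real recordings.

## Thermal performance fitting

Performance is the per-temperature mean of per-fly total daily activity
(per-fly weighting is available, but temperature means are the primary
target since group sizes are usually balanced). Four models are fitted:

| model | parameters | form |
|---|---|---|
| quadratic | a, b, c | `a + bT + cT²`, solved exactly by linear least squares |
| gaussian | P_max, T_opt, σ | `P_max exp(−(T−T_opt)²/2σ²)` |
| briere2 | a, T_min, T_max, m | `a T (T−T_min)(T_max−T)^{1/m}` on [T_min, T_max], else 0 |
| weibull | a, T_opt, b, d | reparameterized Weibull with height `a` at `T_opt`, 0 where undefined |

Nonlinear models use bounded Levenberg–Marquardt with 25 seeded random
starts within the parameter bounds plus one moment-based start, the best
local optimum kept and polished; tight convergence tolerances (1e-15)
make noiseless data from any library model refittable to RSS < 1e-6 and
parameter error < 1e-3, which the tests assert. `T_opt` is closed-form
for the quadratic and otherwise located by a 0.01 °C grid over the
sampled range ± 5 °C; an optimum outside the sampled range is flagged
`extrapolated` rather than trusted. A species whose mean activity is flat
across temperatures is flagged `degenerate` — a real outcome for
thermally insensitive species, not an error. At least `nParams` distinct
temperatures are required (exact interpolation allowed); fewer is an
under-determined error, which also mirrors designs missing the hottest
condition.

Selection is by lowest AIC, `n ln(RSS/n) + 2(k+1)` with the error
variance counted as a parameter; exact ties break toward fewer
parameters, then the fixed model order. AIC rather than AICc is the
default to match the conventional criterion; AICc would be defensible at
n as small as 4–5 temperatures. A known limitation, quantified by the
acceptance script's model-selection rate: the weibull form can
approximate a Gaussian arbitrarily well, so with data truly generated by
the gaussian model, AIC's fixed +2 penalty lets a flexible 4-parameter
competitor win whenever its likelihood-ratio gain exceeds 2 — roughly a
fifth to a quarter of noisy replicates, independent of the noise scale.
Users comparing models of unequal flexibility should read the per-model
AIC table (`fitTpc()$fits`), not only the winner.

## Gradient assays

Probe calibrations (4 or 6 points along the axis) must be strictly
monotone in temperature; fly positions are linearly interpolated between
the two bracketing probes, and positions overshooting the span — photo
digitization jitter — are clamped to the end probe temperature up to 2%
of the span, beyond which the assay is rejected. Assays are treated as
one-dimensional; the transverse coordinate is ignored.

The nine ranges are `< 16 → "15"`, seven 2-°C ranges over 16–30, and
`> 30 → "31"`. Interior bins are half-open `[lo, hi)` with the last
closed at 30: 16.0 falls in 16–18, 18.0 in 18–20, and 30.0 in 28–30.
This convention is documented, not asserted as universal; boundary ties
are measure-zero for real digitized positions.

The preferred temperature is the per-assay median of individual fly
temperatures (mean of middle two for even n). The assay — not the fly —
is the replicate unit everywhere: aggregate distributions are mean ± SEM
across assays (aggregates refuse further aggregation), and group
contrasts (e.g. control vs antenna-ablated) are Mann–Whitney tests on
per-assay medians. Groups below 5 assays are flagged but still tested.
Whether preference boxplots should display assay medians or individual
flies is ambiguous in common practice; assay medians are primary here,
consistent with the replicate-unit choice.

## Nonparametric statistics

All tests are implemented from first principles with midranks and tie
corrections throughout; base R's `kruskal.test`, `wilcox.test` and
`cor.test` appear only as cross-checks in the test suite.

* **Kruskal–Wallis.** `H = 12/(N(N+1)) Σ nᵢ(R̄ᵢ − (N+1)/2)²` divided by
  the tie factor `1 − Σ(t³−t)/(N³−N)`; p from χ² with k−1 df, the
  standard identification under which H is reported as a χ² statistic.
  For tiny samples (N ≤ 10 with a group under 5) the p-value comes from
  full permutation enumeration instead. All values identical across
  groups yields H = 0, p = 1, flagged degenerate.
* **Dunn/Bonferroni.** `z = (R̄ᵢ − R̄ⱼ)/√((N(N+1)/12 −
  Σ(t³−t)/(12(N−1)))(1/nᵢ + 1/nⱼ))`, two-sided normal p, Bonferroni over
  all k(k−1)/2 pairs (`p_adj = min(1, m·p)`).
* **Mann–Whitney.** `U = min(U₁, U₂)`; exact p by full enumeration of
  the U distribution when `n₁+n₂ ≤ 20` without ties (identical samples
  give the maximal p of 1), otherwise normal approximation with tie and
  continuity corrections.
* **Spearman.** ρ is the Pearson correlation of midranks; p exact by
  permutation for n ≤ 8, else the t approximation. Zero rank variance is
  flagged undefined rather than returned as a number.

Two-sided tests are the default throughout; one-sided alternatives exist
but are non-standard for these designs. Null calibration (rejection rate
at α = 0.05 within [0.03, 0.07] over 2,000 simulated datasets for both
KW and MWU) is checked by the test suite and recomputed by the
acceptance script.

## Pipeline, configuration and determinism

`runActivityPipeline()` / `runTemprefPipeline()` /` runFullPipeline()`
orchestrate the full layout: summaries, profiles, bout tables, KW + Dunn
across temperatures per species, TPC fits, nine-range distributions,
preferred temperatures, ablation contrasts, and the
preferred-vs-optimal join. Configuration is a YAML file (a standard
key-value format with an installed, dependency-free parser) whose
defaults are the protocol's; unknown keys are errors. Every random draw
derives from the single config seed, and identical config + seed gives
byte-identical CSVs, across reruns and across the CLI
(`exec/thermofly`) versus direct library calls — both asserted by the
tests. Each run writes a JSON manifest embedding the full configuration,
seed and package version, sufficient to regenerate any table. Errors
propagate with their stage name (e.g. `stage drop_acclimation: …`).

## Problem sizes used by the tests

The suite simulates at sizes chosen to keep Monte-Carlo error well below
each asserted tolerance while remaining desk-scale: 100 flies for
bout-length and expectation recovery, 60 flies for the peak-asymmetry
property, 12 flies × 11 species for the panel correlation and fold
checks, 8 assays × 40 flies for preference recovery, 100 replicates for
the ablation power simulation, 50 replicates for noisy TPC recovery,
2,000 datasets for null calibration, and 1,000 random traces for the
sleep-scorer oracle. SEM with a single replicate is defined as 0 and
flagged — plots from n = 1 should not pretend to show dispersion.

## Known limitations

* The 5-min sleep rule inflates scored sleep for weakly active flies;
  compare `minBout` sensitivities before interpreting interspecific
  sleep differences.
* AIC model selection over models of unequal flexibility favors the
  flexible form on a sizable minority of noisy datasets (see above).
* The generator's sleep placement is time-homogeneous, so simulated
  sleep profiles lack the nocturnal consolidation of real flies; sleep
  *profiles* from the generator exercise the code path, not the
  biology.
* No circadian period estimation (free-run designs), arousal-threshold
  sleep metrics, or image processing: positions and counts arrive as
  numbers.
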