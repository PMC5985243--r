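---
title: "Model and methods of the AV cost-effectiveness microsimulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods of the AV cost-effectiveness microsimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avcea)
```

## The model

`avcea` is a decision-analytic Markov microsimulation in the tradition of
health-economic state-transition models. Each iteration simulates two
drivers of the same age, one per strategy, over `T = 100` annual timesteps.
A subject is always in one of five states: *driving*, *driving severely
injured*, *dead*, *out of the analytic horizon and healthy*, or *out of the
analytic horizon and severely injured*. The analytic horizon is the
vehicle's service life; after the vehicle leaves service the subject keeps
accruing (discounted) QALYs in the post-horizon states but no vehicle
costs. Death is absorbing; severe injury is permanent until death, which
matches the state space's lack of a recovery transition.

Within a timestep, the state occupied during that year accrues first — a
full year of state utility and, in the driving states, a full year of
recurring cost, both discounted at rate `r` with a start-of-year
convention (`t = 0` is undiscounted, no half-cycle correction). Events then
resolve in a fixed order:

1. **Crash** (driving states only, at most one per year): with the
   strategy's annual crash probability, a severity is drawn over
   property-damage-only (PDO), minor, severe, and fatal outcomes. Fatal
   crashes move the subject to *dead* and charge the fatal crash cost plus
   the funeral cost; severe crashes move to *driving severely injured*;
   PDO/minor crashes charge their cost and leave the state unchanged. The
   same car continues after a non-fatal crash (repair costs are inside the
   per-crash cost figures).
2. **Background mortality**: an annual death probability from the period
   lifetable at the subject's current age, applied to crash survivors. A
   lifetable death inside the analytic horizon also charges the funeral
   cost; post-horizon deaths do not.
3. **Vehicle expiration**: the car leaves service with the conditional
   annual probability from the vehicle lifetable at its age. The vehicle
   is not replaced; the subject moves to the corresponding post-horizon
   state.

The mortality table closes at `q(110) = 1` and driver ages start at 16 or
above, so all subjects are dead well before the model ends; all vehicles
have expired long before that.

Costs comprise the vehicle purchase (charged once at `t = 0`), annual
ownership, parking, productivity loss from piloting (HPV only — AV
occupants and taxi passengers lose no productive time), the taxi driver's
salary (human-piloted taxi only), per-crash costs by severity (the AV cost
column for AV strategies, reflecting the more expensive equipment at risk),
and the funeral. The societal perspective is taken throughout: the taxi
driver's salary is a cost regardless of who writes the cheque.

## Parameters

All monetary values are 2016 USD. The registry (`default_parameters()`)
holds each parameter's base value, plausible low/high bounds where a range
is published, and its sampling distribution (`triangular` with mode at the
base value, or `fixed`). Key constants: discount rate 0.03/yr; 14,133
annual vehicle-miles per driver; productivity parameter 0.3 (the fraction
of driving time that would otherwise be productive — the $1,657/yr base
productivity loss scales linearly in it); 3.4 parking spots per registered
car; willingness-to-pay threshold $140,000/QALY; 10,000 iterations over
100 timesteps.

Three parameters deserve comment because the model structure, not a
published table, fixes their roles:

* **Parking amortization (35 years, 0% real).** The parking cost of a
  non-taxi is the cost of one spot ($102,000) times the spots-per-car
  ratio (3.4); a taxi pays for a single spot ($30,000). A capital cost of
  this size cannot plausibly be charged at `t = 0` of a single vehicle's
  life, so it is annuitized. The 35-year straight-line horizon is a
  structural-lifetime figure for parking infrastructure, calibrated
  jointly with the vehicle lifespan so the simulated HPV lifetime cost
  reproduces the published total (see *Calibration*).
* **AV ownership premium ($2,000/yr, range 0–4,000).** Annual ownership
  of any car is $8,536. An AV additionally carries upkeep of its sensing
  and computing equipment. Scaling the whole ownership cost by the
  vehicle price ratio (5.5× for today's AV) would put AV ownership near
  $47,000/yr and the AV lifetime cost at roughly double the published
  total, so price-proportional scaling is structurally wrong: the
  published lifetime costs of the current AV and its 5-year price
  projection imply nearly identical recurring premiums despite a 3.2×
  price gap. The premium is therefore modeled as a fixed annual amount,
  identical for all AV strategies, with a wide sensitivity range.
* **Health-state utilities (healthy 0.85, severely injured 0.60).** The
  elicited EQ-5D-5L weights behind the analysis are not published; these
  defaults are conventional magnitudes for general-population health and
  serious permanent injury, and are exposed in the registry with
  sensitivity ranges (0.70–0.95 and 0.40–0.80).

## Synthetic cohort tables

The analysis needs three demographic inputs that are not cost/probability
parameters. All three are generated by code from compact specs,
deterministic given the spec, and shipped as versioned CSVs under
`inst/extdata/` (a test asserts bit-identical regeneration).

* **Driver ages**: piecewise-uniform over bands of 16–90 with band shares
  approximating the age structure of US licensed drivers (mean ≈ 47).
  Real licensing data can be substituted via an explicit weight vector.
* **Mortality**: Gompertz–Makeham, `h(x) = 5e-4 + 2.7e-5·exp(0.098·x)`,
  closed at `q(110) = 1`. This yields a life expectancy at birth of about
  77 years and 32.6 years at age 47 — a plausible recent US period table.
* **Vehicle lifespan**: discretized Weibull (shape 4) whose scale is
  solved so the mean service life is 17.5 years, with forced retirement
  at 35.

What the generator does *not* emulate: age-dependent crash risk, cohort
(improving) mortality, socio-economic heterogeneity, and any correlation
between driver age and vehicle age. Tests passing against these tables
show that the engine is a faithful implementation of the model, not that
the model matches any particular empirical cohort.

### Calibration

The published analysis reports its lifetime totals but not its lifetable,
vehicle-survival table, utility weights, or cost-spreading conventions, so
exact replication is impossible by construction; the package instead
calibrates the unpublished structural inputs once, jointly, to the
published totals, and freezes them as the defaults used everywhere:

* the Gompertz–Makeham parameters were chosen so that, with utility 0.85,
  the HPV arm's mean discounted QALYs land near the published 16.4;
* vehicle lifespan (17.5 y), parking amortization (35 y) and the AV
  ownership premium ($2,000/yr) were chosen so the four strategies with
  published point estimates land within a few percent of them
  simultaneously, and the AV/HPV cost ratio matches the published +49%.

At `n = 10,000`, seed 1, the defaults give HPV $292.5k (published $286.1k),
AV $438.6k ($425.8k), 5-year AV $311.4k ($303.5k), AV taxi $428.2k
($447.7k), human-piloted taxi $597.0k (inside its wide published interval),
HPV QALYs 16.42 (16.43), and an AV–HPV QALY gain of 0.080 (0.08).

## Random numbers

One master seed derives named sub-streams by hashing stream labels, so any
component can be regenerated independently. Within an iteration the two
arms share every draw of a strategy-independent process: the driver's age,
the background-mortality uniforms, and the vehicle-expiration uniforms
(both strategies assume the same vehicle lifespan distribution). Crash and
severity draws are per-strategy streams. This common-random-numbers design
is what makes the incremental estimates usable: the ≈0.08 QALY gain would
otherwise be buried under background-mortality noise (standard error
≈ 0.06 at 10,000 iterations with independent mortality streams, versus
≈ 0.002 with shared ones). `run_iteration(shared_streams = TRUE)` shares
*all* streams, under which identical strategies produce identical records.

The engine is vectorized across iterations (a 10,000-iteration,
five-strategy run takes on the order of a second); a scalar reference
engine with a full event log backs `run_iteration()`, and a test asserts
that both engines agree draw-for-draw.

## Sensitivity analyses

One-way analyses re-run the simulation with one parameter at its low and
high bound, same seed, and report both ICERs and the swing. The PSA samples
every ranged parameter from a triangular(low, base, high) distribution —
the sampled AV severity split is renormalized to a probability vector —
and runs a reduced inner simulation (default 1,000 iterations) per draw,
with one shared inner seed so parameter uncertainty is the only difference
between draws. The acceptability curve is the fraction of draws
cost-effective as a function of the threshold.

## Numerical choices and degenerate inputs

* Discounting: start-of-year, `1/(1+r)^t`; `r = 0` degenerates to no
  discounting (used by the lifetable oracle test).
* Severity splits are renormalized to sum exactly to 1; the published
  HPV split sums to 1.0001 as printed.
* Degenerate triangular ranges (`low == high`) are point masses;
  parameters without ranges are never varied.
* The Weibull discretization uses cumulative-hazard increments, which is
  numerically stable far beyond the distribution's scale.
* `compute_icer` never divides by a zero QALY difference — it returns an
  explicit `UNDEFINED` verdict — and classifies dominance before forming
  any ratio. The willingness-to-pay comparison is boundary-inclusive.
* The delta-V severity tool (`severity_from_delta_v`) maps KABCO risk
  curves (K→fatal, A→severe, B→minor, C/O→PDO) through an expectation
  over a discrete crash-speed distribution. The default exponential
  curves are calibrated so the default speed distribution (lognormal,
  mean 3.91 mph, CV 1) reproduces the AV severity split; they are a
  synthetic stand-in for published delta-V injury regressions and sit off
  the simulation's critical path, which consumes the published splits
  directly.

## Known limitations

* Crash probabilities are age- and exposure-invariant; annual mileage
  enters only through the annualized crash probabilities.
* The HPV crash probability reflects *reported* crashes; roughly half of
  minor HPV crashes go unreported, while the AV record contains every
  incident. An optional scenario multiplier
  (`unreported_crash_multiplier`, default 1 = off) scales the HPV crash
  probability to explore this asymmetry.
* The 5-year AV price is taken from the published projection directly;
  `moore_projection()` documents the halving structure but does not
  reproduce that figure exactly under any simple fixed-component choice.
* Taxi strategies treat the vehicle as serving one representative
  subject; fleet utilization, fares and profit flows are out of scope, as
  are congestion, transit displacement and land-use effects.
* Calibration targets published *means*; the simulated distributions'
  tails (and hence interval estimates) need not match the published
  intervals, which depend on unpublished heterogeneity.
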