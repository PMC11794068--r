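---
title: "A system-dynamics model of new-drug pricing premiums: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A system-dynamics model of new-drug pricing premiums: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdpricing)
```

## The model

Japan's premium system for innovative drugs awards price mark-ups when a new
drug demonstrates particular kinds of usefulness. `sdpricing` represents
that decision system as a stock-and-flow model with three kinds of
variables:

* **constants** — dimensionless criterion scores. Sixteen criteria carry a
  fixed score (e.g. *new mechanism* = 2, *evidence from RCT* = 2, most
  single-criterion scores = 1), and one shared **special-designation base**
  (= 5) anchors the rare-disease, small-market and children's-drug scores.
* **auxiliaries** — linear algebra recomputed every step. Each scored
  criterion appears as an auxiliary carrying its constant into the algebra;
  compound criteria add inline offsets (e.g. *new action part* =
  2 + *new mechanism*); four issue-level aggregates combine into the **value
  premium**; the special-designation scores feed **marketability premiums I
  and II** and the **pediatrics premium**; four criteria sum to the
  **SAKIGAKE premium**; and the five premiums combine into the evaluation
  flow with weights 1.8, 1.15, 1.05, 1.125, 1.15.
* **one stock** — *new drug pricing decision evaluation*, integrating the
  flow from 0.

Two first-order information delays (`DELAY1`) carry time lags: the
*significant improvement in efficacy* signal enters comparator validity with
time constant 0.5 years, and the SAKIGAKE premium enters each
special-designation score with time constant 5 years — early designation
takes years to propagate into rare/small-market/pediatric valuations, which
is the only dynamic feedback in the model.

The census is 17 constants, 33 auxiliaries and 1 stock (51 variables). The
printed source table lists one row per named quantity; we factor each
bare-score row into a `"<name> score"` constant plus a same-named auxiliary
(and the shared base 5 into one constant) to obtain that census — the
catalog (`japan_catalog()`) keeps the printed spellings alongside the model
identifiers. The split is a reconstruction: the source names the counts but
not the constant roster. For experiments that must perturb the three
special-designation bases independently, `japan_special_premium_model()`
splits the shared base into three per-row constants (19 constants); its
baseline behaviour is identical.

## Numerical scheme

Simulation is forward Euler with explicit delay state, the scheme that
desktop SD tools default to and the only one consistent with an
integer-year step. Each step at time *t*:

1. evaluate all auxiliaries in dependency order (topological order of the
   reference edges; delay and stock edges carry state and impose no
   ordering; ties broken by declaration order, so runs are bit-reproducible);
2. advance every delay output: `y <- y + (dt/τ)(u − y)` with the input `u`
   just evaluated;
3. advance every stock: `s <- s + dt · inflow`, the inflow sampled at the
   start of the step.

Values recorded at `t_start` are the initial state before any step; the
save grid always contains both endpoints. Any non-finite intermediate
aborts the run naming the variable and step. `sd_validate()` returns all
structural problems (duplicate names, unresolved references, algebraic
cycles, non-positive delay times, missing inflows) instead of raising on
the first.

### Delay initialisation

The source material never states delay initial conditions, so this is a
design choice. The default policy initialises a delay to **zero** when
`τ ≥ dt` and to **equilibrium** (its input's initial value) when `τ < dt`:

* Zero-initialising the 5-year delays reproduces the documented transient —
  special-designation premiums start at their base 5, below the SAKIGAKE
  premium's 8, and overtake it within the first decade as the designation
  effect builds over roughly five years.
* A sub-step delay (`τ = 0.5` at `dt = 1`) has Euler factor
  `|1 − dt/τ| = 1`: zero-initialised it would oscillate forever instead of
  converging. Starting it at equilibrium removes an artefact of the
  discretisation, not a feature of the model.

Both choices can be overridden per delay (`init_policy`, including an
explicit numeric start) or globally (`sd_simulate(..., init_policy =
"zero"/"equilibrium")`). Equilibrium initialisation of every delay makes the
whole model stationary: every auxiliary is constant and the stock exactly
linear, `E(t) = t · 106.425`.

### Closed-form asymptotics

With constant inputs every delay output tends to its input, so
`sd_asymptotics()` replaces delay terms by pass-through references and
solves the acyclic linear algebra once. This yields the premium asymptotes
(30, 13, 13, 13, 8) and the flow asymptote 106.425 independently of the
simulation loop, and `analytic_gain()` differentiates it by unit finite
difference — exact for a linear model — to provide the oracle against which
simulated sensitivity deltas are checked
(`delta = gain × (scale − 1) × base`).

## Experiments and their parameters

* **Baseline** (`run_baseline()`): 50 years at `dt = 1`, default delay
  initialisation — the source's stated simulation settings.
* **Stability test** (`stability_test()`): re-runs at `dt = 1, 0.5, 0.125`
  (successive halving) and compares the stock at save points shared with
  the coarsest run. Under equilibrium initialisation the flow is constant,
  so Euler is exact and deviations sit at floating-point rounding level
  (summing 400 eighth-steps rounds differently from 50 whole-steps;
  ~10⁻¹¹ absolute on a stock of ~5·10³). Under the default initialisation
  the transient's *integral* is step-size independent (the integrated
  deficit of a zero-started delay is exactly `input × τ` for any
  `dt < 2τ`), so end-of-horizon deviations stay below 0.1% even though the
  transient paths differ slightly.
* **OAT sensitivity** (`oat_sensitivity()`): one constant at a time is
  multiplied by `scale` (default 1.8, i.e. +80%, read as "increase by
  80%"; ×0.8 is equally runnable), the model re-initialised and re-run from
  `t_start`, and the flow-asymptote shift against baseline recorded.
  `rank_parameters()` orders descending; exact ties share a rank and are
  listed alphabetically. The impact metric is the asymptote shift
  (equivalently the late-horizon stock slope) with the final stock reported
  alongside; a perturbation-at-time-τ mode is deliberately out of scope.

## The fixture generator

`generate_fixture_model()` builds seeded random linear models (constants in
[0, 10], acyclic references to earlier-declared variables, delay times in
`[dt, 10·dt]`, one stock on a random auxiliary) for property tests:
write/read round-trips, superposition (scaling every constant input scales
every trajectory exactly), and stationarity of delay-free models. These
fixtures emulate the *structure* of scoring models — small, linear,
feed-forward algebra with a few delays — not real pricing data: they contain
no feedback through stocks, no nonlinearities and no noise, so passing
property tests demonstrates engine correctness on this model class, not
predictive validity on market data.

Test and acceptance runs use 50–100-year horizons at `dt ∈ {0.125, …, 1}`
(≤ 400 steps, 51 variables) and 100 fixtures per property — sizes chosen to
match the study's own horizons while keeping the whole suite fast.

## Known limitations

* The model is linear plus first-order delays; the source alludes to
  nonlinear settings but prints only linear forms, and we implement exactly
  what is printed rather than invent nonlinearities.
* Premium scores are dimensionless and are not converted to yen or
  percentage mark-ups; post-launch price revisions and competitive dynamics
  are out of scope.
* The 17-constant roster and the equilibrium-vs-zero delay defaults are
  reconstructions of under-specified aspects of the source; both are
  documented knobs rather than hidden assumptions.
* Only `DELAY1` and stock integration are provided — no higher-order
  delays, smoothing or lookup tables — and the JSON dialect is deliberately
  one-record-per-variable to ease a future converter from XMILE-style
  formats, which the package does not parse.
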