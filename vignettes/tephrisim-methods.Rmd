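---
title: "Methods: weather-driven demographic models of tropical fruit flies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weather-driven demographic models of tropical fruit flies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tephrisim)
```

## The model and its assumptions

`tephrisim` implements physiologically based demographic models (PBDMs) for
four tropical tephritid fruit flies. The core assumptions:

* **Physiological time.** Poikilotherm development is driven by degree-days
  (dd) above a stage-specific lower threshold `theta_L`. The daily increment
  is `dx(T) = (T - theta_L)/(1 + b^(T - theta_U))`: linear between the
  thresholds and collapsing to zero above the inflection `theta_U`. The
  forcing temperature is the daily mean, taken as `(tmax + tmin)/2` (the
  standard convention; the model is otherwise agnostic to how the mean is
  formed).
* **Distributed maturation times.** Each stage is a chain of `k` identical
  age compartments, so stage-transit times of a cohort are Erlang-distributed
  with mean `delta` and SD `delta/sqrt(k)` (`erlang_stats()`). `k` is 25 or
  40 for immature stages; the adult `k` equals the mean longevity in days at
  25 °C (a consistency the acceptance suite verifies for medfly and melon
  fly; the oriental fruit fly ships with its published `k = 71` even though
  the rule would give ~65).
* **Demand-driven reproduction.** Potential daily oviposition (demand `D`)
  is the fecundity-profile-weighted sum over adult age classes, scaled by a
  temperature scalar `phi_T`, a humidity scalar `phi_RH`, and the sex ratio
  0.5. Realized oviposition `S` passes demand through a ratio-dependent
  functional response with a constant host level `H = 500`, which both
  represents host limitation and bounds the model (populations equilibrate at
  a weather-limited level rather than growing without bound).
* **No dormancy.** None of the four species diapauses. Under adverse
  conditions (`phi_T * phi_RH <= 0.05`) adults are treated as quiescent:
  non-reproducing and longer-lived (see below).
* **No host-plant dynamics, no dispersal.** Flies reproduce as weather
  allows; the immigration/emigration components of the loss rate are not
  modelled (no data exist to parameterize them).

## Parameters that matter

Every species constant is shipped in `inst/extdata/species/<name>.json`,
one human-readable file per species, schema-validated on load and guarded by
frozen md5 checksums in the test suite. Per stage: `delta` (dd), `theta_L`,
`theta_U` (°C), decay base `b` (dimensionless), published rate coefficient
`a` (1/day/°C, `NA` where no stage-specific fit exists), and `erlang_k`.
Reproduction: fecundity scale `gamma` (eggs/female/day per day of age),
decay base `phi_base` (> 1), pre-oviposition age `x0` (days at 25 °C), the
`phi_T`/`phi_RH` functional forms, sex ratio `sr = 0.5`, host level
`H = 500`, search coefficient `alpha_coeff = 0.005` per dd, and the
reference temperature 25 °C. Mortality: per stage-group polynomial or
piecewise-exponential daily rates, clamped to [0, 1]. Polynomials are
evaluated with the digits exactly as published.

User-facing defaults: `n0 = 10` founding adults per cell (enough to escape
numerical extinction in favorable weather, small enough to show limitation);
elevation mask cutoff 2000 m; burn-in of exactly one calendar year excluded
from the multi-year statistics.

## Numerical choices

* **Rate normalization.** The published stage rate coefficients `a` are
  internally consistent with `1/delta` for melon fly, oriental fruit fly,
  and mexfly (within 10%; the suite audits this), but the medfly egg–larval
  fit (`a = 0.031`) is an egg-only fit inconsistent with the egg–larval
  `delta = 129` dd. The dynamics therefore integrate the normalized
  increment `dx(T) = (T - theta_L)/(1 + b^(T - theta_U))` — i.e. `a` is set
  to `1/delta` while preserving the fitted shape — which reproduces
  `delta = d(T) (T - theta_L)` exactly in the linear range for all species.
  The printed rate functions remain available verbatim through `dev_rate()`
  for audit.
* **Integrator.** Forward Euler on the delay chain with automatic
  sub-stepping. The per-substep flow ratio `k*dx/delta` is capped at 0.02:
  a pulse cohort pushed through the Euler scheme exits with
  negative-binomial timing whose SD is biased by `sqrt(1 - p)` relative to
  the exact Erlang SD, so a cap of 0.02 keeps the bias near 1% (a cap of
  0.5 — enough for stability and non-negativity — would bias the SD by
  ~29%). Mortality is applied within each sub-step as `mu/nsub`. Mass is
  conserved to floating-point accuracy with `mu = 0`, and no age class can
  go negative.
* **Daily ordering.** (1) compute the day's scalars from the weather;
  (2) advance egg–larva, then pupa, then adult, routing each stage's daily
  outflow into the next stage the same day; adults surviving to the end of
  class `k` exit as deaths at maximum age; (3) compute demand and realized
  oviposition from the post-advance adult structure and inject the eggs the
  **next** day. The injection lag is a convention (the source material does
  not state one); fixing it makes runs bit-reproducible.
* **Quiescent adults.** The parameter tables list a separate quiescent-adult
  `delta` but no transition rule. On days with `phi_T * phi_RH <= 0.05`
  adult aging is slowed by the factor `delta_adult / delta_quiescent`
  (medfly 772/1050, oriental 1050/1532; melon fly and mexfly publish equal
  deltas, so the rule is a no-op for them) and the quiescent stage-group
  mortality applies. The behaviour can be disabled
  (`initialize_population(..., quiescence = FALSE)`).
* **`phi_T` normalization.** The published bound is `0 < phi_T <= 1`, but
  the melon fly rational form peaks near 0.053. Every `phi_T` is therefore
  max-normalized over its admissible temperature range (the form's own
  thresholds for melon fly; the stage thresholds for the oriental cubic;
  window forms already peak at exactly 1) so its supremum is 1. For the
  oriental cubic this is a < 1% change; for melon fly it is the only
  reading under which the stated bound holds.
* **`phi_RH` forms.** The published medfly/mexfly quartic carries a leading
  "1 −" that would push values above 1.9 at RH = 50%, violating the stated
  bound; it is read as a typesetting artifact and dropped. The mexfly scalar
  is 1.36 × the medfly value (clamped at 1), following the statement that
  mexfly is 36% more desiccation resistant, rather than the near-duplicate
  printed coefficients.
* **Age conversion for fecundity.** The oviposition profile `f(x)` is
  defined on age in days at 25 °C, while adults age in dd. Class `i`'s
  midpoint age `(i - 0.5) * delta_adult / k` dd is converted by dividing by
  `25 - theta_L_adult` dd/day.
* **Functional-response limit.** `S` at `D = 0` is taken as its analytic
  limit 0, avoiding the 0/0 in `alpha*H/D`.
* **Annual summary statistics.** The multi-year SD/CV use the sample (n−1)
  estimator, matching the worked reference value (CV 0.471 for annual
  values 10 and 20); the first calendar year is always excluded as burn-in.
* **"Cumulative pupae per year"** is the cumulative daily *flux* of
  individuals entering the pupal stage, not the standing pupal stock: flux
  is independent of stage duration and matches "pupae produced per year".
* **Degenerate inputs.** Below-threshold days give `dx = 0` (mortality and
  arrivals still act); an empty population is absorbing; all scalar BDFs
  clamp to [0, 1] for any finite input; weather series are rejected on date
  gaps, reversed dates, or `tmin > tmax`, with row numbers.

## The synthetic weather generator

`synth_weather()` emulates the gross structure of daily station/reanalysis
forcing: a sinusoidal seasonal cycle in the daily mean temperature with
additive Gaussian noise (default SD 2 °C), a fixed diurnal range splitting
`tmax/tmin` around the mean, and a seasonal RH cycle (anti-phased with
temperature for the temperate and desert regimes) with noise, clamped to
[5, 100]%. The three stated regimes are tropical (mean 26 °C, amplitude
3 °C), temperate (12 °C, 10 °C), and desert (25 °C, 10 °C, RH mean 25%).
Years are 365 days; the warmest day falls near day 200 (northern
hemisphere). Values not fixed by the stated regimes (noise SDs, diurnal
ranges of 8/10/14 °C, RH means/amplitudes) were chosen once as
field-realistic and are documented here, not tuned.

What the generator does **not** emulate: autocorrelated synoptic weather
(day-to-day noise is independent), heat waves and cold snaps beyond what
Gaussian noise produces, interannual variability and trends, rainfall, and
the spatial correlation of real lattices. A green regime test therefore
establishes that the model separates climatically favorable from
unfavorable cells in the stated direction — not that it reproduces any
observed map. The headline continental maps of the source analysis require
gridded historical weather datasets that are out of scope here.

## Known limitations

* Parameter sets are the published point transcriptions; no uncertainty is
  propagated.
* The quiescence rule and the egg-injection lag are conventions chosen in
  the absence of a published specification (both documented above and
  switchable or harmless, respectively).
* The marginal regression is plain OLS: no spatial or robust standard
  errors, no model selection. Covariates are the user's choice; annual
  cold/heat mortality sums and degree-days are provided ready-made
  (`thermal_stress_covariates()`).
* Host-plant phenology, immigration/emigration, and time-varying `delta`
  are not modelled (no published parameterizations exist).

## A compact demonstration

```{r demo}
sp <- load_species("medfly")
erlang_stats(sp$stages$pupa$delta, sp$stages$pupa$erlang_k)
wx <- synth_weather("tropical", years = 2, seed = 1)
annual <- run_cell(wx, sp, n0 = 10)
annual
```
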