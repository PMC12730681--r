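---
title: "A molt-driven dynamic energy budget model for pond-cultured swimming crabs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A molt-driven dynamic energy budget model for pond-cultured swimming crabs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crabdeb)
```

## The problem

Swimming crabs (*Portunus trituberculatus*) grow in steps. The rigid
exoskeleton fixes external size between molts, so wet weight `Ww` is
piecewise constant and jumps at each molt, while organic mass accumulates
continuously. Energy allocation is biphasic as well: before the terminal
(puberty) molt almost everything goes into soma, after it the ovary grows
by an order of magnitude in weeks. Classical growth curves and standard
dynamic energy budget (DEB) formulations, which assume continuous size
change and a fixed allocation rule, miss both features. `crabdeb`
implements a DEB variant built around the molt cycle, for growth
prediction in pond aquaculture.

## State variables and fluxes

The individual carries a reserve `E` (J), structural weight `WG`
(g carbon), somatic wet weight `Ww` (g, constant between molts), a
reproduction buffer `ER` (J), an ovary `WO` (g), a molt stage (I–XI) and a
post-puberty flag. Carbon weight is `WC = WG + E/muE` — structure plus
reserve mass, the ovary deliberately excluded so the molting indicator
reflects somatic packing only.

Fluxes follow the standard weight-based DEB form, every rate scaled by a
single Arrhenius factor `c(T) = exp(TA/T_ref - TA/T)`:

- assimilation `pA = f * pAm * c * WG^(2/3)` — surface-area scaling on
  *structural* weight, which stays stable through the molt cycle, rather
  than on morphological size;
- mobilization
  `pC = [E] * (EG*(pAm/Em)*c*WG^(2/3) + pM*c*WG) / (EG + kappa*[E])` with
  reserve density `[E] = E/WG`;
- somatic maintenance `pS = pM * c * WG`;
- growth `pG = max(kappa*pC - pS, 0)` at cost `EG` per gram of structure;
- reproductive-channel flow `pR = (1 - kappa) * pC` into `ER`.

Because feeding in intensive ponds is near ad libitum, the functional
response is a constant scalar (`f = 0.9` by default), not a dynamic prey
field.

## The molting trigger

The internal indicator is `alpha = WC / Ww`. Between molts `WC` rises and
`alpha` climbs toward the stage-specific threshold `alpha_pre` (Table:
0.27, 0.44, 0.30, 0.30, 0.30, 0.26, 0.21, 0.19, 0.16, 0.15, 0.15 for
stages I–XI). At `alpha >= alpha_pre[stage]` (ties molt) the wet weight
jumps to `WC / alpha_post` with `alpha_post = 0.1`, so `alpha` resets to
`alpha_post` exactly and `WC` is continuous across the event. Each molt
therefore multiplies `Ww` by roughly `alpha_pre/alpha_post`, which is what
pins the staged weight trajectory: a stage-VIII crab of 34 g necessarily
passes near 65 g and 103 g at its next two molts. The stage-XI molt is the
puberty molt; molting then stops, but the simulation continues for ovarian
growth.

No exuvial carbon loss or molt energy cost is modelled: the alpha
bookkeeping conserves `WC` across molts, a documented simplification.

## Segmented kappa and the puberty switch

`kappa` is 1.0 for stages I–VII (no ovarian investment), 0.9 for stages
VIII–XI, and 0.2 after the puberty molt. Two design points deserve
mention:

- The adult value 0.2 applies only once the puberty molt has *completed*.
  Applying it already during the stage-XI intermolt would make the puberty
  molt unreachable: with `kappa = 0.2`, `kappa*pC` barely covers
  maintenance, `WC` all but stops growing, and `alpha` would need years to
  climb from 0.1 to the 0.15 threshold. The biphasic reading — 0.9 while
  molting, 0.2 after the terminal molt — is the only one consistent with
  rapid *post*-puberty ovarian growth and a puberty molt that actually
  happens.
- `kappa` switches instantaneously at the molt that creates the stage
  transition; there are no mid-intermolt allocation changes.

## The ovarian module

Ovarian conversion is demand-driven. Densities are carbon ratios relative
to structure: the reproductive reserve density `mER = (ER/muE)/WG` and the
reproductive material density `mG = (WO*cO)/WG` (`cO = 0.4` g carbon per g
ovary). The demand is

```
dWO/dt = nuG * c(T) * mER * max(mGm - mG, 0) * WG   [g/d]
```

priced at `EBO = 36,690 J/g` before and `EAO = 66,200 J/g` after the
puberty molt, and supply-limited by the buffer (`pO <= ER/dt`).

Basing the demand on the *reproductive* reserve density is a deliberate
choice. A demand driven by the somatic reserve density cannot be biphasic:
`[E]`, `WG` and `mG` barely change across the puberty molt, so no constant
coefficient pair can hold the pre-puberty ovary near 0.8 g and still
deliver tens of grams by day 180. With `mER` as the driver the buffer
itself is the switch — pre-puberty only 10% of `pC` feeds `ER`, so demand
stays small and energy accumulates; after the molt 80% of `pC` floods the
buffer and conversion accelerates on its own. The same mechanism makes the
gonad module feedback-free with respect to growth: the ovary drains only
`ER`, so molt timing and weight are identical across gonad parameter
values (exploited by the calibration).

`nuG` (d⁻¹) and `mGm` (g ovary carbon per g structure) have no measured
values; `calibrate_gonad()` fits them by grid search (coarse log grid plus
one refinement pass) minimizing the summed squared log-error of simulated
ovary mass at target days. The shipped defaults `nuG = 0.008`,
`mGm = 0.93` are the calibration against the published milestones (0.8 g
just before the puberty molt, 20 g at day 180) under the default seasonal
forcing. The Arrhenius factor is applied to the conversion rate for
consistency with every other rate in the model.

## Forcing and initial conditions

Temperature forcing is a daily series, linearly interpolated to the model
clock. Files are delimited text with `date,temp_C`; the synthetic profile
is an annual sinusoid `T = (Tmin+Tmax)/2 + (Tmax-Tmin)/2 *
cos(2*pi*(doy - day_of_peak)/365)`. The default emulates a Yellow Sea pond
season: 16–29 °C annual band, peak on day-of-year 227 (mid-August),
simulations starting May 1 — which places the May–October window in
roughly 21–29 °C. The warmer southern (Ningbo-like) band used for one
validation cohort is 18–31 °C, a choice of this package since no series is
printed. A (−2, 40) °C sanity band guards against unit mistakes. No
netCDF reader is included; gridded SST must be exported to CSV first.

Individuals enter the model freshly molted: `WC0 = alpha_post * Ww0`,
split `WG = beta * WC0` and `E = (1-beta) * WC0 * muE` with `beta = 0.79`,
empty buffer and ovary. The molt stage is inferred from `Ww0` via a
reference simulation: starting from a 0.02 g stage-I juvenile (a first
crab instar weighs ~20 mg; the value is not printed anywhere and is this
package's choice), the recorded post-molt weights define per-stage bands
with midpoint edges. Because the molt cascade is multiplicative, the
printed validation weights (34, 28.79, 12.88 g) land in the bands (VIII,
VIII, VII) that reproduce the published molt counts.

Two printed values are mutually inconsistent: `beta = 0.79` and
`muE = 18,750` imply an initial reserve density of 4984 J/g, above
`Em = 3860`. The initialization keeps the `beta` split; `Em` acts as a
soft cap only (assimilation is clamped to mobilization while
`[E] >= Em`), so the density relaxes below `Em` within days.

## Numerical scheme

Explicit forward Euler with `dt = 0.1 d` (forcing stays at daily
resolution; the finer step is for integrator accuracy). Order within a
step: flux evaluation, reserve/buffer update, maintenance shortfall
(drawn from `ER` first, then `E`; structure is never resorbed — an
unpayable deficit raises a sticky starvation flag instead of death),
structural growth, ovarian conversion, then the molt check and the clock.

A step that fires a molt is redone as two half-steps, recursively down to
`dt/16`, so the threshold crossing is localized well inside the step; the
reported fluxes are averaged over the sub-steps, which keeps the per-step
energy ledger exact (supply `pA*dt` equals the change in `E + ER` plus
growth, maintenance and ovary energy to ~1e-6 relative, which the tests
assert). Without this refinement the crossing overshoot compounds over the
11 molts of a full juvenile-to-adult run and halving `dt` still moved the
180-day weight by ~1.7%; with it the dt-halving change is ~0.3%. Negative
excursions of `E` from the explicit update are clamped at zero; they are
negligible in fed scenarios.

## Estimators

Each physiological experiment maps to one estimator on a plain data table:

- `estimate_arrhenius()` — per-size-group OLS of `ln(ROC)` on `1/T`; `TA`
  is the unweighted mean of the negated slopes (matching the averaging of
  the five published datasets), with the sample SD as dispersion.
- `estimate_assimilation()` — OLS of assimilated energy on `WG^(2/3)`,
  through the origin by default (the quantity is a ratio by definition; a
  free-intercept diagnostic is available).
- `estimate_starvation()` — plateau logic: after ~8 days the carbon weight
  equals structure; returns `beta`, `Em = (WC0-WG)*muE/WG` and
  `pM = oxycal * mean plateau ROC` (ROC input in mg O2 g⁻¹ h⁻¹, converted
  to g O2 g⁻¹ d⁻¹ internally).
- `estimate_alpha_post()` — through-origin slope of `WC` on `Ww` in
  freshly molted animals.
- `EG` has no estimator: the published derivation is under-specified, so
  it stays a fixed default (51,180 J/g).

All estimators are exact on noiseless tables from the bundled generators
and invariant under row permutation; `r²` is reported with every slope.

## Goodness of fit and sensitivity

`goodness_of_fit()` reports `R²` (squared Pearson correlation), the
Nash–Sutcliffe model efficiency `ME = 1 - SS_err/SS_obs` (1 = perfect,
0 = no better than the observed mean), Theil's `U` in the
bounded-denominator form `RMSE / (sqrt(mean(O²)) + sqrt(mean(P²)))`
(0 = ideal; the exact published variant is not stated, so the
`rmse_obs` denominator is available as an option), and RMSE, with a
`drop_first` switch to exclude the shared initial value.

`sensitivity_analysis()` perturbs one parameter at a time by ±10% and
scores the mean relative deviation of daily carbon weight,
`SI = 100 * mean(|WC+ - WC0| + |WC- - WC0|) / (2 * WC0)`, averaging the
two directions since the published procedure does not say how they were
combined. `WC` — not `Ww` — is the response variable. A structural note:
because post-molt weight is `alpha_pre/alpha_post` times pre-molt weight
regardless of rates, rate perturbations mostly shift molt *timing* rather
than terminal size, and once the run reaches its post-puberty plateau the
perturbed and reference trajectories reconverge. On the 180-day
juvenile-to-adult scenario this compression bounds the assimilation
indices near 16%, below the >20% published for a scenario whose exact
window is not specified; the qualitative ranking — assimilation
(`pAm`, `f`) above structure cost (`EG`), reserve capacity (`Em`) last —
is reproduced and asserted in the tests.

## Synthetic data: what it does and does not show

The generators (`gen_roc()`, `gen_starvation()`, `gen_feeding()`,
`gen_molt_pairs()`, `gen_observations()`) emulate the *designs* of the
supporting experiments — five size groups at five temperatures,
every-other-day starvation sampling, surface-scaled feeding, proportional
molt pairs, noisy trajectory sampling — with multiplicative lognormal
noise for strictly positive quantities (additive gaussian only for the
starvation weights). They are pure functions of their seed.

Passing recovery tests therefore shows the estimators invert their own
generating laws at realistic noise, not that the laws describe real crabs:
tank effects, protocol artifacts, individual variability in `alpha_pre`,
and feed-quality variation are all outside the noise model. Likewise the
seasonal sinusoid lacks synoptic weather excursions, so simulated molt
dates are smoother than pond reality.

## Problem sizes

The test suite and the acceptance script run desk-scale configurations
chosen as this package's defaults: cohort scenarios of 50–180 days at
`dt = 0.1`, an hourly brute-force cross-check over 30 days, gonad
calibration on a ~160-point grid (the growth run is shared across
candidates), and sensitivity over 4–7 parameters (two runs each). The
whole suite completes in well under a minute of compute.

## Known limitations

- Single females only; no mortality, stocking density, feed dynamics or
  water-quality feedback; males are not modelled (their gonadosomatic
  index is negligible).
- No exuviae or molt energy cost; no maturity maintenance in the
  reproductive channel.
- `alpha_pre` is deterministic per stage; real thresholds vary between
  individuals, which spreads molt timing in a cohort.
- The day-180 ovary mass under the default (cooler) forcing calibrates to
  ~16 g rather than the 20 g milestone: the simulated puberty molt falls
  near day 115, leaving too short a rapid-growth window. Under the warmer
  band the same calibration meets both milestones, so predictions of
  late-season ovary mass are sensitive to the forcing series used.
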