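---
title: "Methods: a desk-scale foresight model of agricultural investment and hunger"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a desk-scale foresight model of agricultural investment and hunger}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# What the package models

`agforesight` is a deliberately small, fully reproducible version of the
multi-model foresight systems used to project food security under
alternative investment and climate futures: a global partial-equilibrium
(PE) multi-market model of agriculture, coupled to a reduced-form
economy-wide income feedback, driven by SSP2-style population and GDP
trajectories, climate yield shocks, and an investment layer that converts
R&D spending into total factor productivity (TFP) through the perpetual
inventory method (PIM).  Three scenarios are compared to 2030:

* **NoCC** — constant 2005 climate, baseline productivity growth;
* **CC** — a severe high-emissions climate realization layered on the same
  baseline;
* **COMP** — CC plus a comprehensive investment package (international
  agricultural research, irrigation expansion, water-use efficiency, soil
  management, and infrastructure that narrows marketing margins), with all
  interventions starting after 2015.

The published analyses this emulates run on hundreds of countries, dozens
of commodities and gridded biophysical models with unpublished parameters;
their headline outputs are therefore not exactly reproducible at desk
scale.  The package instead (i) reproduces exactly the accounting
arithmetic of the published investment and macro tables, and (ii)
generates synthetic worlds calibrated to the published 2010 anchors so
that the *sign and ordering* of every cross-scenario comparison — hunger
COMP < NoCC < CC, prices COMP < NoCC < CC, incomes COMP > CC — and the
five-percent-threshold pattern emerge from the mechanics rather than being
asserted.

# The synthetic world generator

`build_world(seed)` creates the study conditions.  Its defaults are the
conditions of the analysis, not tuning knobs:

* **Geography.** Seven leaf regions — Northern, Western, Eastern, Central
  and Southern Africa, other-developing, developed (the default
  `n_subregions = 8` splits other-developing in two) — with reporting
  aggregates SSA, Africa, developing, world.  The "Africa and West Asia"
  rows of the cost tables are mapped to Northern Africa for costing, since
  West Asia cannot be carved out of the other-developing block at this
  resolution.
* **Macro drivers.** Population and GDP decade anchors are taken from the
  encoded SSP2 table and interpolated geometrically.  Leaf GDP is derived
  as income × population because the printed 1-dp GDP cells for the small
  African regions carry less relative precision than the income cells
  (e.g. Central Africa's printed 0.2 trillion against an implied 0.24).
* **Demand calibration.** 2010 per-capita calorie anchors (Northern ≈3040,
  Western ≈2573, Eastern ≈2134, Central ≈2054, Southern ≈3040
  kcal/person/day) are rescaled so the Africa aggregate is exactly 2500;
  the other-developing anchor then solves the developing aggregate of
  2700.  Calories are allocated over seven commodity groups by
  development-tier diet shares (±10 % seed jitter) and converted to
  quantities by group energy densities.
* **Base-year equilibrium by construction.** Supply is set equal to demand
  cell by cell up to a seeded trade jitter that is rebalanced so world
  production equals world consumption per commodity; supply-function
  intercepts are backed out at base prices.  The base year therefore
  clears to machine precision for any seed.
* **Elasticities.** Supply price elasticities U(0.22, 0.28); demand price
  elasticities −U(0.27, 0.33); income elasticities by group (0.18 cereals
  … 0.23 meats, ±0.01).  The published analysis does not report its
  elasticities; these stylized ranges were chosen once so that the
  no-climate-change 2030 price indices land inside the published +10–30 %
  band and per-capita calories grow to roughly the published 2030 levels
  (Africa ≈2700), and they are documented rather than estimated.
* **Productivity and shocks.** Intrinsic productivity multipliers are
  calibrated so each African region's production-weighted 2030 value is
  exactly 1.38 under NoCC and the developing aggregate is 1.32 (developed
  is fixed at 1.12, a stylized mature-agriculture rate).  CC shock
  endpoints are 0.93 for every African region; the other-developing and
  developed endpoints solve the developing (0.95) and world (0.94)
  production-weighted means.  Per-commodity dispersion (±3 points) is
  drawn once per seed and recentred so the regional weighted means hold
  exactly.  Shocks are 1 through 2014 and ramp linearly over 2015–2030:
  the published description gives only 2030 endpoints, and holding the
  base period at 1 keeps NoCC and CC runs identical before the
  intervention era, which the scenario contracts require.

# Market equilibrium

Supply and demand are constant-elasticity:

$$Q^s_{rc} = Q^s_{rc,0}\Big(\tfrac{P_c(1-m_{rc}/2)}{P_{c,0}(1-m_{rc,0}/2)}\Big)^{\varepsilon^s_{rc}} g_{rc}(t)\,\tau_{r}(t)\,s_{rc}(t), \qquad
Q^d_{rc} = Q^d_{rc,0}\Big(\tfrac{P_c(1+m_{rc}/2)}{P_{c,0}(1+m_{rc,0}/2)}\Big)^{\varepsilon^d_{rc}} \Big(\tfrac{y_r}{y_{r,0}}\Big)^{\varepsilon^y_{rc}} \tfrac{N_r}{N_{r,0}}$$

with a single world price per commodity (regions trade their residual
frictionlessly), intrinsic growth $g$, R&D TFP $\tau$, climate shock $s$,
and marketing margins $m$ split 50/50 between producer and consumer wedges
(the incidence is not published; the split is a documented choice).  Each
year the solver zeroes world excess demand with a damped Newton iteration
on log prices (analytic Jacobian, step halving, start at the previous
year's prices, relative clearing tolerance 10⁻⁹ against a 10⁻⁶ contract);
years are solved sequentially with no expectations.  Optional cross-price
terms are supported but default to zero.  Prices are homogeneous of
degree one in base prices, so only relative prices matter.

# Investment: PIM and inverse costing

Knowledge stocks follow $K_t=(1-\delta)K_{t-1}+\sum_l w_l I_{eff,t-l}$
with $I_{eff}$ adding a 0.2 spillover from every region's international-
centre (CGIAR) investment to the others.  Defaults: decay δ = 0.10/yr;
trapezoidal gestation lags over 10 years peaking at year 5 for the CGIAR
channel (basic research) and 6 years peaking at year 3 for national
systems (applied/developmental); TFP growth is η times stock growth.
None of δ, the lags or η are published; all are config-exposed.  Baseline
streams reproduce the published average annual levels (CGIAR growing
6.3 %/yr to 2030, national systems rising 50 % over 2010–2030).

The COMP productivity targets (a production-weighted +51 % for Africa by
2030 against 2010, region targets 1.47–1.56; +15 % TFP vs the CC baseline
for other-developing, a stylized choice since only the Africa aggregate is
published) are costed by inversion: a fixed additional-stream shape (zero
to 2014, 10 %/yr geometric ramp 2015–2030, unit mean) is scaled by
bisection until the PIM-implied 2030 TFP hits the target to 10⁻⁶.  The
per-region CGIAR stock elasticities are calibrated once so that streams at
the published additional averages (0.67 SSA / 0.01 NAWA / 0.07 other
developing, bn/yr) reach those targets — the published costs identify the
product of elasticity and stream, not each separately, so this is a
calibration, and the inverse machinery is independently verified by
round-trip tests at random scales.  Capital categories use unit costs
(USD/ha, per efficiency point, per composite infrastructure unit)
calibrated to the published cost tables, with capital installed in equal
tranches and 2 %/yr maintenance on the installed base; costing is linear
in increments and unit costs.

# Income feedback

The economy-wide model is replaced by the linear reduced form
$\Delta y_r = \kappa\, v_r\, \Delta q_r$, where $v_r$ is the region's food
value-added share of GDP (stylized values 0.08–0.32 for Africa, 0.10
other-developing, 0.015 developed) and $\Delta q_r$ is the realized
base-price-valued agricultural output deviation from the no-feedback NoCC
reference.  Using the realized output deviation (rather than the
exogenous TFP shifter alone) keeps the two-model loop a genuine fixed
point: incomes move demand, demand moves prices and output, output moves
incomes.  The loop contracts quickly (the implied loop gain is well below
one at the calibrated κ) and stops when relative income changes fall
below 10⁻⁸.  κ is calibrated once per world so the Africa income gain of
COMP over CC in 2030 equals the published ≈5 % anchor, then frozen; with
the feedback active the realized gain differs from 5 % only at second
order.  A small side effect worth knowing: in the two rich, low-
agriculture-share African regions the feedback's demand-driven price rise
can marginally outweigh the tiny income gain, so the published
"feedback lowers hunger" direction holds for the Africa aggregate and all
food-insecure regions, not literally per region.

# Hunger indicators

Equilibrium demand is converted to kcal/person/day and mapped to the share
at risk of hunger by a monotone piecewise log-linear curve in the ratio of
availability to a 2400 kcal/day reference requirement (configurable; the
1800 kcal minimum line is retained for plots only).  The cited
prevalence relation is not reproduced in the source, so the curve's form
is a documented choice with pluggable anchors; its interior anchors are
placed at the realized 2010 African calorie levels so the published 2010
shares (Africa 21 %, Eastern 35 %, Central 41 %) hold exactly, the
Northern/Southern 2010 share is fixed at 3 %, and the Western share solves
the Africa aggregate.  Beyond the anchor range the end segments
extrapolate, clipped to a 2 % floor — average-availability measures never
drive prevalence to zero.  People at risk are share × population;
aggregates always sum people, never average shares; the five-percent
threshold report is inclusive at the boundary.

# Numerical and design choices

* Newton damping halves the step until the residual falls; the fallback
  bracket search used in tests doubles as an independent oracle.
* Bisection brackets for the inverse costing expand geometrically and
  abort beyond 2²⁰×, reported as non-convergence.
* The 2010 base year is untouched by every scenario lever, so scenario
  runs are bit-identical before 2015 and COMP with all interventions
  zeroed reproduces CC exactly.
* Determinism: all randomness flows from the single world seed through a
  locally-scoped RNG; identical seeds give byte-identical serialized
  worlds.
* Problem sizes: the default world is 8 leaf regions × 7 commodity groups
  over 2010–2030; a three-scenario run with feedback converges in about
  five coupled iterations and takes on the order of a second, and the
  full test suite builds all its fixtures in code.

# What passing tests do and do not show

The generator emulates the statistical structure the analysis assumes —
market-clearing baselines, constant-elasticity responses, anchored
productivity and shock aggregates — not real data: there are no bilateral
trade flows, no stocks, no within-region heterogeneity, no weather
variability, and the hunger curve is a calibrated stand-in for an
unpublished relation.  Passing tests therefore demonstrate that the
mechanics reproduce the published accounting identities exactly and the
published qualitative comparative statics robustly across seeds; they do
not validate the magnitudes of hunger changes, which in the real system
depend on model details that are not public.  Known limitations beyond
scope: no malnutrition indicators, no dietary-quality dimension, no
endogenous response of national or private R&D to international spending,
and a single climate realization per scenario.
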