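# agforesight

A desk-scale foresight model of agricultural investment, climate change
and hunger in Africa, for food-policy and agricultural-economics analysts
who want the mechanics of the big multi-model projection systems —
partial-equilibrium commodity markets, R&D-investment-to-productivity
accounting, an economy-wide income feedback, and calorie-based hunger
indicators — in a package small enough to run, test and audit in seconds.

## The model in brief

A constant-elasticity multi-market core clears world commodity markets
annually: for each region *r* and commodity *c*,

    supply:  Qs = Qs0 * (Pprod/Pprod0)^eps_s * g(t) * tau(t) * s(t)
    demand:  Qd = Qd0 * (Pcons/Pcons0)^eps_d * (y/y0)^eps_y * (N/N0)

where `g` is intrinsic productivity growth, `tau` the TFP multiplier from
R&D investment, `s` a climate yield shock, and producer/consumer prices
differ from the world price by a marketing margin.  A damped Newton
iteration on log prices zeroes world excess demand each year.

R&D spending becomes productivity through the perpetual inventory method,

    K_t = (1 - delta) K_{t-1} + sum_l w_l I_eff(t - l),
    TFP growth = eta * (K_t / K_{t-1} - 1),

with gestation lags, knowledge decay and cross-region spillovers; the
mapping is inverted by bisection to cost productivity targets.  Real
incomes deviate from their baseline path in proportion to each region's
food value-added share times its agricultural output deviation
(`delta_y = kappa * va * delta_q`), iterated with the market model to a
fixed point.  Equilibrium food demand is converted to kcal/person/day and
mapped to the share of the population at risk of hunger through a
monotone calibrated prevalence curve, with a five-percent prevalence
threshold report.

Three scenarios are compared over 2010–2030: **NoCC** (constant climate),
**CC** (a severe climate realization: −7 % Africa / −5 % developing /
−6 % world yields by 2030) and **COMP** (CC plus a comprehensive
agricultural investment package starting in 2015).

## Worked example

```r
library(agforesight)

world <- build_world(seed = 1)        # seeded synthetic world, calibrated
runs  <- run_all_scenarios(world)     # NoCC, CC, COMP

print(runs$COMP)
#> Scenario run: COMP (world seed 1, 2010-2030)
#>   feedback iterations: 5
#>   Africa 2030: 2854 kcal/person/day, 10.3% at risk (159 million)
#>   food price index 2030 (2010 = 1): 1.00-1.08 across groups
#>   worst clearing residual: 2.35e-12

cmp <- compare_runs(runs$COMP, runs$CC)
cmp$hunger[cmp$hunger$region_id == "AFR" & cmp$hunger$year == 2030, ]
#>    region_id year delta_kcal delta_share delta_millions
#> 21       AFR 2030   209.1643 -0.05160484      -79.36824

threshold_report(runs$COMP$hunger[runs$COMP$hunger$region_id %in%
  c("NAF", "WAF", "EAF", "CAF", "SAF"), ], year = 2030)$meeting
#> [1] "NAF" "WAF" "SAF"
```

Reading the numbers: under the comprehensive investment package Africa
reaches about 2850 kcal/person/day by 2030 with 10.3 % of the population
(159 million people) at risk of hunger — 79 million fewer than under
climate change without the investments, with average calorie availability
about 209 kcal/person/day higher.  Northern, Western and Southern Africa
reach the five-percent prevalence target; Eastern and Central Africa stay
above ten percent.  Commodity prices that climate change pushes 23–31 %
above 2010 levels return to roughly 2010 levels.  `summary()`, `plot()`
and `residuals()` methods give regional detail, price/hunger panels and
market-clearing diagnostics; `export_run()` writes the long-format CSVs.

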