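test_that("calorie availability is the exact unit conversion", {
  # 0.365 Mt at 1000 kcal/kg feeding 1 million people: 1000 kcal/day each
  expect_equal(kcal_availability(0.365, 1000, 1), 1000, tolerance = 1e-12)
  # constructed fixture scaled to land exactly on 2500
  expect_equal(kcal_availability(0.9125, 1000, 1), 2500, tolerance = 1e-12)
  # doubling population halves availability
  expect_equal(kcal_availability(0.365, 1000, 2), 500, tolerance = 1e-12)
  expect_error(kcal_availability(1, 3000, 0), "population")
})

test_that("the prevalence curve reproduces the 2010 calibration anchors", {
  hc <- world_default$hunger_curve
  kc <- agforesight:::kcal_by_region(world_default,
                                     world_default$baselines$consumption)
  expect_equal(hunger_share(kc[["EAF"]], hc$requirement, hc), 0.35,
               tolerance = 1e-9)
  expect_equal(hunger_share(kc[["CAF"]], hc$requirement, hc), 0.41,
               tolerance = 1e-9)
  h2010 <- runs_default$NoCC$hunger
  afr <- h2010[h2010$region_id == "AFR" & h2010$year == 2010, ]
  expect_equal(afr$share_at_risk, 0.21, tolerance = 1e-6)
})

test_that("the prevalence curve is monotone, saturating, and invertible", {
  hc <- world_default$hunger_curve
  kcal <- seq(1200, 4200, by = 50)
  sh <- hunger_share(kcal, hc$requirement, hc)
  expect_true(all(diff(sh) <= 1e-15))
  expect_equal(hunger_share(10000, hc$requirement, hc), hc$floor)
  expect_lte(max(sh), 1)
  # inverse round trip on the interpolation range
  shares <- seq(min(hc$anchors$share) + 1e-6, max(hc$anchors$share) - 1e-6,
                length.out = 40)
  back <- hunger_share(hunger_share_inverse(shares, hc$requirement, hc),
                       hc$requirement, hc)
  expect_equal(back, shares, tolerance = 1e-10)
  bad <- hc
  bad$anchors$share <- rev(bad$anchors$share)
  expect_error(hunger_share(2500, hc$requirement, bad), "monotone")
})

test_that("millions at risk is share times population, in millions", {
  expect_identical(population_at_risk(0, 1538), 0)
  expect_equal(population_at_risk(0.10, 1538), 153.8, tolerance = 1e-12)
  expect_error(population_at_risk(1.2, 100), "share")
})

test_that("aggregates sum millions, never averaging shares", {
  h <- runs_default$CC$hunger
  for (yr in c(2010, 2030)) {
    ssa <- h[h$region_id == "SSA" & h$year == yr, ]
    parts <- h[h$region_id %in% c("WAF", "EAF", "CAF", "SAF") & h$year == yr, ]
    expect_equal(ssa$millions_at_risk, sum(parts$millions_at_risk),
                 tolerance = 1e-9)
    expect_equal(ssa$share_at_risk, ssa$millions_at_risk / ssa$population,
                 tolerance = 1e-12)
  }
  # share/number consistency everywhere
  expect_equal(h$millions_at_risk / h$population, h$share_at_risk,
               tolerance = 1e-12)
})

test_that("larger TFP never lowers calories or raises hunger (monotone chain)", {
  comp <- runs_default$COMP$hunger
  cc <- runs_default$CC$hunger
  m <- merge(comp, cc, by = c("region_id", "year"), suffixes = c("_comp", "_cc"))
  expect_true(all(m$kcal_pc_comp >= m$kcal_pc_cc - 1e-9))
  expect_true(all(m$share_at_risk_comp <= m$share_at_risk_cc + 1e-12))
})

test_that("the threshold report is inclusive at the boundary", {
  ind <- data.frame(region_id = c("A", "B", "C"), year = 2030,
                    scenario = "X", kcal_pc = c(3000, 2600, 2200),
                    share_at_risk = c(0.04, 0.05, 0.12),
                    millions_at_risk = c(4, 5, 12), population = 100)
  rep <- threshold_report(ind)
  expect_setequal(rep$meeting, c("A", "B"))      # 0.05 counts as meeting
  expect_identical(rep$not_meeting, "C")
  all_ok <- threshold_report(transform(ind, share_at_risk = 0.04))
  expect_identical(all_ok$n_meeting, 3L)
})
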