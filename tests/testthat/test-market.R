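test_that("supply and demand reduce to their closed forms", {
  w <- world_default
  r <- "WAF"; cc <- "cereals"; p0 <- w$baselines$price[[cc]]
  # calibration identity: base drivers return base quantities exactly
  expect_equal(supply_quantity(w, r, cc, 2010, p0),
               w$baselines$production[r, cc], tolerance = 1e-12)
  y0 <- average_income(w$macro[[r]], 2010)
  n0 <- w$macro[[r]]$population[1]
  expect_equal(demand_quantity(w, r, cc, 2010, p0, y0, n0),
               w$baselines$consumption[r, cc], tolerance = 1e-12)
  # elasticity 0.5: quadrupling the producer price doubles supply
  w$elasticities$supply_price[r, cc] <- 0.5
  expect_equal(supply_quantity(w, r, cc, 2010, 4 * p0) /
                 supply_quantity(w, r, cc, 2010, p0), 2, tolerance = 1e-12)
  # elasticity -0.5: quadrupling the consumer price halves demand
  w$elasticities$demand_price[r, cc] <- -0.5
  expect_equal(demand_quantity(w, r, cc, 2010, 4 * p0, y0, n0) /
                 demand_quantity(w, r, cc, 2010, p0, y0, n0), 0.5,
               tolerance = 1e-12)
  # population doubling doubles demand at fixed prices and income
  expect_equal(demand_quantity(w, r, cc, 2010, p0, y0, 2 * n0) /
                 demand_quantity(w, r, cc, 2010, p0, y0, n0), 2,
               tolerance = 1e-12)
  expect_error(supply_quantity(w, r, cc, 2010, -5), "price")
})

test_that("the 2030 climate shock cuts supply by the regional seven percent", {
  w <- world_default
  p0 <- w$baselines$price
  lv <- agforesight:::region_leaves(w, "AFR")
  s_no <- agforesight:::supply_all(
    w, p0, agforesight:::year_drivers(w, "NoCC", 2030, 1, 1, 1))
  s_cc <- agforesight:::supply_all(
    w, p0, agforesight:::year_drivers(w, "CC", 2030, 1, 1, 1))
  # at fixed prices the regional supply loss is the supply-weighted shock
  expect_equal(sum(s_cc[lv, ]) / sum(s_no[lv, ]),
               agforesight:::wmean(w$shock_end_2030[lv, ], s_no[lv, ]),
               tolerance = 1e-12)
  # which sits at the published seven-percent Africa loss (weights differ
  # slightly from base-production weights only through 2030 growth)
  expect_equal(sum(s_cc[lv, ]) / sum(s_no[lv, ]), 0.93, tolerance = 0.005)
})

test_that("one-market equilibrium matches the closed form and a grid oracle", {
  # unit elasticities, demand shifted x1.21 via population: P* = base x 1.1
  toy <- make_toy_world(eps_s = 1, eps_d = -1, pop_path = c(100, 121, 121))
  sol <- solve_year(toy, 2011)
  expect_equal(unname(sol$price[1] / toy$baselines$price[1]), 1.1,
               tolerance = 1e-9)
  # independent oracle: sign-change search on excess demand
  expect_equal(unname(sol$price[1]), oracle_clear_price(toy, 2011),
               tolerance = 1e-8)
  # no driver change: base prices are an exact fixed point
  sol0 <- solve_year(toy, 2010)
  expect_identical(unname(sol0$price[1]), toy$baselines$price[[1]])
})

test_that("solved years clear every market to the contracted tolerance", {
  for (run in runs_default) {
    expect_true(all(abs(run$solution$residual) < 1e-6))
    expect_true(all(run$solution$price > 0))
    # world production equals world consumption at the solution (no stocks)
    sup <- apply(run$solution$supply, c(1, 3), sum)
    dem <- apply(run$solution$demand, c(1, 3), sum)
    expect_equal(sup, dem, tolerance = 1e-6)
  }
})

test_that("prices are homogeneous: scaling base prices leaves quantities alone", {
  w <- world_default
  ref <- solve_year(w, 2020, drivers = list(climate = "CC"))
  w2 <- w
  w2$baselines$price <- w$baselines$price * 7
  scaled <- solve_year(w2, 2020, drivers = list(climate = "CC"))
  expect_equal(scaled$price / 7, ref$price, tolerance = 1e-9)
  expect_equal(scaled$supply, ref$supply, tolerance = 1e-9)
  expect_equal(scaled$demand, ref$demand, tolerance = 1e-9)
})

test_that("negative supply shocks raise equilibrium prices (random worlds)", {
  for (sd in 4:8) {
    w <- build_world(seed = sd, calibrate_feedback = FALSE)
    no <- solve_year(w, 2030, drivers = list(climate = "NoCC"))
    cc <- solve_year(w, 2030, drivers = list(climate = "CC"),
                     p_start = no$price)
    expect_true(all(cc$price > no$price))
  }
})

test_that("margin cuts lower consumer and raise producer prices at fixed world price", {
  w <- world_default
  r <- "EAF"; cc <- "cereals"; p <- w$baselines$price[[cc]]
  m0 <- w$baselines$margin[r, cc]
  m1 <- m0 * 0.8
  expect_lt(p * (1 + m1 / 2), p * (1 + m0 / 2))
  expect_gt(p * (1 - m1 / 2), p * (1 - m0 / 2))
  # and they move quantities the right way
  q0 <- supply_quantity(w, r, cc, 2010, p)
  q1 <- supply_quantity(w, r, cc, 2010, p, margin = m1)
  expect_gt(q1, q0)
  y0 <- average_income(w$macro[[r]], 2010); n0 <- w$macro[[r]]$population[1]
  d0 <- demand_quantity(w, r, cc, 2010, p, y0, n0)
  d1 <- demand_quantity(w, r, cc, 2010, p, y0, n0, margin = m1)
  expect_gt(d1, d0)
})

test_that("price indices are unity at base, raw ratios for single groups", {
  run <- runs_default$NoCC
  expect_equal(price_index(run, world_default, "all", 2010), 1, tolerance = 1e-12)
  # single-commodity group: index equals the raw price relative
  expect_equal(price_index(run, world_default, "meats", 2030),
               unname(run$solution$price["2030", "meats"] /
                        run$solution$price["2010", "meats"]),
               tolerance = 1e-12)
  expect_error(price_index(run, world_default, "spices", 2030), "empty")
})

test_that("constant-climate 2030 price indices sit in the calibrated band", {
  idx <- vapply(unique(world_default$commodities$group), function(g)
    price_index(runs_default$NoCC, world_default, g, 2030), numeric(1))
  expect_true(all(idx >= 1.10 & idx <= 1.30))
})
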