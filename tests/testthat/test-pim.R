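test_that("a single pulse with no decay raises the stock by one, permanently", {
  prm <- pim_params("applied", decay = 0, lag_years = 1, peak = 1,
                    elasticity = 0.2)
  v <- c(0, 0, 1, 0, 0, 0)
  st <- accumulate_stock(investment_stream(2011:2016, v), prm, K0 = 5)
  expect_equal(unname(st$K[, 1]), c(5, 5, 6, 6, 6, 6), tolerance = 1e-15)
})

test_that("constant investment converges to the I/delta steady state", {
  prm <- pim_params("basic", decay = 0.1, elasticity = 0.25)
  st <- accumulate_stock(investment_stream(1:500, rep(2, 500)), prm, K0 = 0)
  expect_equal(st$K[500, 1], 2 / 0.1, tolerance = 1e-9)
  # and the TFP multiplier of a steady-state stock converges back to flat
  st2 <- accumulate_stock(investment_stream(1:300, rep(2, 300)), prm)  # K0 = I/delta
  tfp <- tfp_growth(st2, prm)
  expect_equal(unname(tfp[300, 1] / tfp[299, 1]), 1, tolerance = 1e-9)
})

test_that("full mutual spillovers make stocks independent of who invests", {
  sig <- matrix(1, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  prm <- pim_params("basic", decay = 0.1, elasticity = 0.25,
                    spillover_matrix = sig)
  left <- investment_stream(1:40, cbind(A = rep(3, 40), B = rep(0, 40)),
                            c("A", "B"))
  right <- investment_stream(1:40, cbind(A = rep(0, 40), B = rep(3, 40)),
                             c("A", "B"))
  expect_equal(accumulate_stock(left, prm)$K, accumulate_stock(right, prm)$K,
               tolerance = 1e-12)
})

test_that("TFP growth follows the stock elasticity exactly", {
  prm <- pim_params("basic", decay = 0, lag_years = 1, peak = 1, elasticity = 1)
  # constant stock: multiplier identically one
  st <- structure(list(years = 1:5, regions = "A",
                       K = matrix(4, 5, 1, dimnames = list(1:5, "A")), K0 = 4),
                  class = "ag_stock")
  expect_equal(unname(tfp_growth(st, prm)[, 1]), rep(1, 5))
  # unit elasticity, stock doubling once: multiplier doubles
  st$K[3:5, 1] <- 8
  expect_equal(unname(tfp_growth(st, prm)[, 1]), c(1, 1, 2, 2, 2))
  st$K[1, 1] <- 0
  expect_error(tfp_growth(st, prm), "zero knowledge stock")
})

test_that("larger investment streams never yield smaller stocks or TFP", {
  set.seed(42)
  prm <- pim_params("basic", decay = 0.08, elasticity = 0.3)
  for (k in 1:10) {
    base <- runif(30, 0, 5)
    extra <- base + runif(30, 0, 2)
    k1 <- accumulate_stock(investment_stream(1:30, base), prm, K0 = 1)
    k2 <- accumulate_stock(investment_stream(1:30, extra), prm, K0 = 1)
    expect_true(all(k2$K >= k1$K - 1e-12))
    expect_true(all(tfp_growth(k2, prm) >= tfp_growth(k1, prm) - 1e-12))
  }
})

test_that("inverse costing recovers a stream's scale (round trip)", {
  prm <- pim_params("basic", decay = 0.1, elasticity = 0.25)
  yrs <- 2010:2030
  base <- investment_stream(yrs, 0.5 * 1.05^(yrs - 2010))
  prof_v <- ifelse(yrs < 2015, 0, 1.1^(yrs - 2015))
  profile <- investment_stream(yrs, prof_v / mean(prof_v[yrs >= 2015]))
  for (true_scale in c(0.4, 1.7, 6)) {
    total <- agforesight:::stream_add(base,
                                      agforesight:::stream_scale(profile, true_scale))
    target <- tfp_growth(accumulate_stock(total, prm), prm)[length(yrs), 1]
    rec <- required_investment(target, base, prm, profile)
    expect_equal(attr(rec, "scale"), true_scale, tolerance = 1e-6)
  }
  # identity: target equal to the baseline needs zero additional investment
  t0 <- tfp_growth(accumulate_stock(base, prm), prm)[length(yrs), 1]
  expect_identical(attr(required_investment(t0, base, prm, profile), "scale"), 0)
  expect_error(required_investment(t0 * 0.9, base, prm, profile), "below the baseline")
})

test_that("calibrated inverse costing reproduces the published R&D averages", {
  pkg <- agforesight:::comp_rnd_package(world_default)
  expect_equal(unname(pkg$avg_additional["SSA"]), 0.67, tolerance = 1e-4)
  expect_equal(unname(sum(pkg$avg_additional)), 0.74, tolerance = 0.016)
  # additional streams are zero before the intervention start
  for (ad in pkg$additional)
    expect_true(all(ad$values[as.character(2010:2014), ] == 0))
  # TFP uplift paths reach the regional targets at 2030
  tg <- agforesight:::comp_uplift_targets(world_default)
  expect_equal(unname(pkg$tau["2030", "WAF"]), unname(tg$leaf["WAF"]),
               tolerance = 1e-4)
})

test_that("baseline R&D streams reproduce the published average levels", {
  base <- agforesight:::baseline_rnd_streams(world_default)
  expect_equal(unname(colMeans(base$cgiar$values)),
               c(0.68, 0.06, 0.41), tolerance = 1e-9)
  expect_equal(unname(colMeans(base$nars$values)),
               c(0.85, 1.12, 3.38), tolerance = 1e-9)
  # national-systems stream grows by the printed ~50 % over 2010-2030
  expect_equal(unname(base$nars$values["2030", ] / base$nars$values["2010", ]),
               rep(1.5, 3), tolerance = 1e-9)
})

test_that("capital costing is linear, zero at zero, and hits the cost tables", {
  uc <- world_default$unit_costs
  tg <- agforesight:::capital_targets(uc, "comp")
  s1 <- cost_capital(tg, uc, phase = "comp")
  # zero increments cost nothing
  tg0 <- tg; tg0$increment <- 0
  expect_true(all(cost_capital(tg0, uc, phase = "comp")$value == 0))
  # doubling every unit cost doubles the stream exactly
  uc2 <- uc; uc2$unit_cost <- uc2$unit_cost * 2
  s2 <- cost_capital(tg, uc2, phase = "comp")
  expect_equal(s2$value, 2 * s1$value, tolerance = 1e-12)
  # additivity over a sum of target tables
  tgh <- tg; tgh$increment <- tgh$increment / 3
  sh <- cost_capital(tgh, uc, phase = "comp")
  expect_equal(sh$value * 3, s1$value, tolerance = 1e-12)
  # published additional-cost cells (Africa & West Asia row = SSA + NAWA)
  sm <- capital_cost_summary(s1)
  cell <- function(cat) sum(sm$avg_annual[sm$category == cat &
                                            sm$region %in% c("SSA", "NAWA")])
  expect_equal(cell("irrigation_expansion"), 3.59, tolerance = 0.005)
  expect_equal(cell("water_use_efficiency"), 1.02, tolerance = 0.005)
  expect_equal(cell("soil_water_mgmt"), 3.04, tolerance = 0.005)
  expect_error(cost_capital(data.frame(region = "SSA", category = "dams",
                                       increment = 1), uc), "unit cost")
})

test_that("parameter constructors enforce the documented ranges", {
  expect_error(pim_params(decay = 0.5), "decay")
  expect_error(pim_params(elasticity = 0), "elasticity")
  expect_error(pim_params(lag_weights = c(0.5, 0.4)), "sum to 1")
  expect_error(investment_stream(1:3, c(1, -1, 1)), "non-negative")
  expect_error(investment_stream(1:3, c(1, 1, 1), institution = "capital",
                                 category = "R&D"), "channels")
  w <- pim_params("basic")$lag_weights
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_identical(which.max(w), 5L)     # basic research peaks at lag year 5
})
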