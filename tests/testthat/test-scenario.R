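test_that("scenario specifications enforce the intervention conventions", {
  expect_error(scenario_spec("NoCC", rnd_uplift = TRUE), "intervention")
  expect_error(scenario_spec("CC", margin_reduction = 0.2), "intervention")
  sp <- scenario_spec("COMP")
  expect_true(sp$rnd_uplift)
  expect_identical(sp$climate, "CC")
  expect_identical(sp$start_year, 2015L)
})

test_that("constant-climate and climate-change runs coincide through 2014", {
  pre <- as.character(2010:2014)
  expect_equal(runs_default$NoCC$solution$price[pre, ],
               runs_default$CC$solution$price[pre, ], tolerance = 1e-9)
  h_no <- runs_default$NoCC$hunger
  h_cc <- runs_default$CC$hunger
  sel <- h_no$year <= 2014
  expect_equal(h_no$millions_at_risk[sel], h_cc$millions_at_risk[sel],
               tolerance = 1e-6)
})

test_that("a null-intervention comprehensive run reproduces climate change exactly", {
  null_comp <- run_scenario(world_default,
                            scenario_spec("COMP", rnd_uplift = FALSE,
                                          capital = FALSE, margin_reduction = 0))
  expect_identical(null_comp$solution$price, runs_default$CC$solution$price)
  expect_identical(null_comp$solution$demand, runs_default$CC$solution$demand)
})

test_that("runs are deterministic end to end", {
  again <- run_scenario(world_default, "COMP")
  expect_identical(again$solution$price, runs_default$COMP$solution$price)
  expect_identical(again$hunger, runs_default$COMP$hunger)
})

test_that("cross-scenario deltas are antisymmetric and vanish on self-comparison", {
  d0 <- compare_runs(runs_default$CC, runs_default$CC)
  expect_true(all(d0$income$delta_income == 0))
  expect_true(all(d0$hunger$delta_millions == 0))
  ab <- compare_runs(runs_default$COMP, runs_default$CC)
  ba <- compare_runs(runs_default$CC, runs_default$COMP)
  expect_equal(ab$income$delta_income, -ba$income$delta_income, tolerance = 1e-12)
  expect_equal(ab$price, -ba$price, tolerance = 1e-12)
  # the comprehensive package reduces Africa hunger relative to climate change
  afr30 <- ab$hunger[ab$hunger$region_id == "AFR" & ab$hunger$year == 2030, ]
  expect_lt(afr30$delta_millions, 0)
  w2 <- build_world(seed = 2, calibrate_feedback = FALSE)
  expect_error(compare_runs(runs_default$CC, run_scenario(w2, "CC")),
               "different worlds")
})

test_that("the published-table report passes and is stable across calls", {
  rep1 <- check_paper_tables(world_default)
  rep2 <- check_paper_tables(world_default)
  expect_true(all(rep1$pass))
  expect_identical(rep1, rep2)
  expect_gt(nrow(rep1), 100)
})

test_that("result bundles expose methods without re-solving", {
  run <- runs_default$COMP
  expect_output(print(run), "COMP")
  expect_output(summary(run), "Price indices")
  res <- residuals(run)
  expect_true(all(abs(res) < 1e-6))
  tmp <- tempfile()
  files <- export_run(run, tmp)
  expect_true(all(file.exists(files)))
  sol <- utils::read.csv(files["solution"])
  expect_setequal(names(sol), c("region", "commodity", "year", "price",
                                "supply", "demand", "net_trade"))
  # net trade balances at the world level
  nt <- tapply(sol$net_trade, interaction(sol$year, sol$commodity), sum)
  expect_true(all(abs(nt) < 1e-4))
  unlink(tmp, recursive = TRUE)
})

test_that("configuration files drive world construction", {
  skip_if_not_installed("yaml")
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c("world:", "  seed: 11", "  n_subregions: 7", "feedback:",
               "  kappa: 0.5"), cfg)
  w <- world_from_config(read_config(cfg))
  expect_identical(w$seed, 11L)
  expect_identical(length(w$geography$region_id[w$geography$is_leaf]), 7L)
  expect_identical(w$feedback$kappa, 0.5)
})
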