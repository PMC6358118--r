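test_that("compounding is exact and validates its domain", {
  expect_equal(project_series(1, 0.10, 2), c(1, 1.1, 1.21), tolerance = 1e-15)
  expect_equal(project_series(5, 0, 10), rep(5, 11))
  # regional GDP anchor: 2.8 trillion at 5.2 %/yr over 20 years lands near 7.7
  expect_equal(project_series(2.8, 0.052, 20)[21], 7.7, tolerance = 0.01)
  expect_error(project_series(-1, 0.05, 5), "base_value")
  expect_error(project_series(1, -1.5, 5), "growth rate")
})

test_that("average income reproduces the published per-capita cells", {
  t2 <- load_paper_fixtures()$table2
  wld <- macro_trajectory("WLD", c(2010, 2020, 2030),
                          t2[t2$region == "World", c("pop_2010", "pop_2020", "pop_2030")] |> unlist(),
                          t2[t2$region == "World", c("gdp_2010", "gdp_2020", "gdp_2030")] |> unlist())
  expect_equal(round(average_income(wld, 2010), 1), 9.8)
  afr <- macro_trajectory("AFR", c(2010, 2020, 2030),
                          c(1032, 1279, 1538), c(2.8, 4.5, 7.7))
  expect_equal(round(average_income(afr, 2030), 1), 5.0)
  # identity: gdp = population x k (consistent units) gives exactly k
  tj <- macro_trajectory("X", c(2010, 2020), c(100, 120), c(100 * 0.004, 120 * 0.004))
  expect_equal(average_income(tj, 2010), 4, tolerance = 1e-12)
  expect_error(average_income(tj, 2035), "outside")
})

test_that("income identity holds for every region and year of a built world", {
  for (m in world_default$macro) {
    expect_equal(average_income(m, m$year) * m$population / 1000, m$gdp,
                 tolerance = 1e-12)
  }
})

test_that("aggregation sums levels, recomputes income and is associative", {
  trajs <- world_default$macro
  ssa_leaves <- c("WAF", "EAF", "CAF", "SAF")
  ssa <- aggregate_regions(trajs[ssa_leaves], "SSA", ssa_leaves)
  expect_equal(ssa$population,
               Reduce(`+`, lapply(trajs[ssa_leaves], `[[`, "population")))
  # one-shot Africa equals Africa built from the SSA intermediate
  afr1 <- aggregate_regions(trajs[c("NAF", ssa_leaves)], "AFR")
  afr2 <- aggregate_regions(list(trajs$NAF, ssa), "AFR")
  expect_equal(afr1$population, afr2$population, tolerance = 1e-12)
  expect_equal(afr1$gdp, afr2$gdp, tolerance = 1e-12)
  # single-child aggregate is the child
  one <- aggregate_regions(trajs["NAF"], "X")
  expect_equal(one$gdp, trajs$NAF$gdp)
  expect_error(aggregate_regions(trajs[ssa_leaves], "AFR",
                                 children = c("NAF", ssa_leaves)), "NAF")
})

test_that("aggregate income lies between child incomes (random trajectories)", {
  set.seed(99)
  for (k in 1:20) {
    t1 <- macro_trajectory("A", c(2010, 2020, 2030), runif(3, 50, 500), runif(3, 0.1, 5))
    t2 <- macro_trajectory("B", c(2010, 2020, 2030), runif(3, 50, 500), runif(3, 0.1, 5))
    ag <- aggregate_regions(list(t1, t2), "AB")
    for (yr in c(2010, 2025, 2030)) {
      incs <- c(average_income(t1, yr), average_income(t2, yr))
      expect_gte(average_income(ag, yr), min(incs) - 1e-12)
      expect_lte(average_income(ag, yr), max(incs) + 1e-12)
    }
  }
})

test_that("published income cells reproduce at propagated printed precision", {
  t2 <- load_paper_fixtures()$table2
  for (i in seq_len(nrow(t2))) for (yr in c(2010, 2020, 2030)) {
    pop <- t2[i, paste0("pop_", yr)]
    computed <- t2[i, paste0("gdp_", yr)] / pop * 1000
    printed <- t2[i, paste0("income_", yr)]
    expect_lt(abs(computed - printed), 0.05 + 1000 * 0.05 / pop,
              label = paste("income cell", t2$region[i], yr))
  }
})
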