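# Shared fixtures, built once per test run.

world_default <- build_world(seed = 1)
runs_default <- run_all_scenarios(world_default)

# hand-built minimal world for closed-form market checks: one or more
# regions/commodities, unit elasticities, no margins, flat productivity
make_toy_world <- function(n_regions = 1, n_commodities = 1,
                           eps_s = 1, eps_d = -1, eps_y = 0,
                           prod = 100, price = 100, pop_path = NULL,
                           years = 2010:2012) {
  leaves <- paste0("R", seq_len(n_regions))
  cid <- paste0("C", seq_len(n_commodities))
  mat <- function(x) matrix(x, n_regions, n_commodities,
                            dimnames = list(leaves, cid))
  macro <- lapply(leaves, function(r) {
    pop <- if (is.null(pop_path)) rep(100, length(years)) else pop_path
    structure(data.frame(region_id = r, year = years, population = pop,
                         gdp = pop / 100),
              class = c("ag_macro", "data.frame"))
  })
  names(macro) <- leaves
  geography <- data.frame(
    region_id = c(leaves, "WLD"), name = c(leaves, "World"),
    parent = c(rep("WLD", n_regions), NA), is_leaf = c(rep(TRUE, n_regions), FALSE),
    stringsAsFactors = FALSE)
  structure(list(
    seed = 0L, base_year = 2010L, horizon = max(years), years = years,
    geography = geography,
    commodities = data.frame(commodity_id = cid, group = cid,
                             kcal_per_kg = 3000, base_price = price,
                             stringsAsFactors = FALSE),
    macro = macro,
    baselines = list(production = mat(prod), consumption = mat(prod),
                     price = stats::setNames(rep(price, n_commodities), cid),
                     margin = mat(0)),
    elasticities = list(supply_price = mat(eps_s), demand_price = mat(eps_d),
                        demand_income = mat(eps_y), demand_cross = NULL),
    intrinsic_2030 = mat(1), shock_end_2030 = mat(1),
    kcal_anchor = stats::setNames(rep(2500, n_regions), leaves),
    food_va_share = stats::setNames(rep(0.2, n_regions), leaves),
    hunger_curve = list(anchors = data.frame(ratio = c(0.7, 1.0, 1.3),
                                             share = c(0.5, 0.2, 0.05)),
                        floor = 0.02, requirement = 2400),
    feedback = list(kappa = 0, tol = 1e-8, max_iter = 50L)
  ), class = "ag_world")
}

# brute-force market-clearing oracle: grid + bisection on a single commodity's
# excess demand, independent of the Newton solver
oracle_clear_price <- function(world, year, climate = "NoCC",
                               lo = 1e-3, hi = 1e3) {
  stopifnot(ncol(world$baselines$margin) == 1)
  cid <- world$commodities$commodity_id
  excess <- function(p) {
    leaves <- rownames(world$baselines$production)
    iyr <- match(year, world$years)
    d <- s <- 0
    for (r in leaves) {
      pop <- world$macro[[r]]$population[iyr]
      inc <- average_income(world$macro[[r]], year)
      s <- s + supply_quantity(world, r, cid, year, p, climate)
      d <- d + demand_quantity(world, r, cid, year, p, inc, pop)
    }
    d - s
  }
  p0 <- world$baselines$price[[1]]
  grid <- p0 * exp(seq(log(lo), log(hi), length.out = 2000))
  ex <- vapply(grid, excess, numeric(1))
  i <- which(diff(sign(ex)) != 0)[1]
  stats::uniroot(excess, c(grid[i], grid[i + 1]), tol = 1e-12)$root
}
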