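# Scenario orchestration: NoCC / CC / COMP runs, cross-scenario deltas, and
# reproduction of the published accounting tables.

#' Scenario specification
#'
#' The three study scenarios: \code{NoCC} (constant 2005 climate, baseline
#' productivity), \code{CC} (severe climate change, baseline productivity)
#' and \code{COMP} (climate change plus the comprehensive investment
#' package: R&D-driven productivity uplift, capital investments in
#' irrigation, water-use efficiency and soil management, and marketing-
#' margin reductions from infrastructure).  All COMP interventions begin
#' after 2015.
#'
#' @param name "NoCC", "CC" or "COMP".
#' @param rnd_uplift include the R&D productivity uplift (COMP only).
#' @param capital include the additional capital investment package.
#' @param margin_reduction fraction of the marketing wedge removed by 2030
#'   in developing regions (COMP only; NULL = the world default).
#' @param start_year first intervention year (default 2015).
#' @return an object of class \code{ag_scenario}.
#' @export
scenario_spec <- function(name = c("NoCC", "CC", "COMP"), rnd_uplift = NULL,
                          capital = NULL, margin_reduction = NULL,
                          start_year = 2015L) {
  name <- match.arg(name)
  is_comp <- name == "COMP"
  if (!is_comp && (isTRUE(rnd_uplift) || isTRUE(capital) ||
                   (!is.null(margin_reduction) && margin_reduction > 0)))
    stop_config(name, " carries no intervention block; interventions belong to COMP")
  structure(list(
    name = name,
    climate = if (name == "NoCC") "NoCC" else "CC",
    rnd_uplift = rnd_uplift %||% is_comp,
    capital = capital %||% is_comp,
    margin_reduction = margin_reduction %||% if (is_comp) NA_real_ else 0,
    start_year = as.integer(start_year)
  ), class = "ag_scenario")
}

# years x leaves margin multiplier path for the comprehensive package:
# linear reduction from the intervention start to 2030, developing only
comp_margin_path <- function(world, reduction = NULL, start_year = NULL) {
  reduction <- reduction %||% world$comp$margin_reduction
  start_year <- start_year %||% world$comp$start_year
  leaves <- rownames(world$baselines$production)
  yrs <- world$years
  frac <- pmin(pmax((yrs - start_year + 1) / (2030 - start_year + 1), 0), 1)
  ms <- 1 - outer(frac, rep(reduction, length(leaves)))
  dimnames(ms) <- list(yrs, leaves)
  ms[, "DEV"] <- 1
  ms
}

#' Run one scenario end to end
#'
#' Builds the scenario's driver paths (climate shocks, R&D TFP uplift from
#' the perpetual-inventory inversion, margin reductions), iterates the
#' market solve with the income feedback to a fixed point, and assembles
#' the result bundle: equilibrium prices and quantities, income deviations,
#' hunger indicators and investment streams.
#'
#' @param world an \code{ag_world} (validated).
#' @param spec an \code{ag_scenario} or a scenario name.
#' @param feedback include the income feedback (default TRUE; FALSE forces
#'   kappa = 0).
#' @return an object of class \code{ag_run}.
#' @export
run_scenario <- function(world, spec = "NoCC", feedback = TRUE) {
  if (is.character(spec)) spec <- scenario_spec(spec)
  leaves <- rownames(world$baselines$production)
  nT <- length(world$years)
  ones <- matrix(1, nT, length(leaves), dimnames = list(world$years, leaves))

  rnd <- NULL
  tau <- ones
  if (isTRUE(spec$rnd_uplift)) {
    rnd <- comp_rnd_package(world)
    tau <- rnd$tau
  }
  mr <- if (is.na(spec$margin_reduction)) world$comp$margin_reduction
        else spec$margin_reduction
  ms <- if (mr > 0) comp_margin_path(world, mr, spec$start_year) else ones

  kappa <- if (feedback) world$feedback$kappa %||% 0 else 0
  cpl <- iterate_coupled(world, spec$climate, tau, ms, kappa = kappa)

  hung <- hunger_indicators(world, cpl$solution$demand, spec$name)
  incomes <- income_table(world, cpl$deviation)
  inv <- list(
    baseline_capital = capital_cost_summary(phase_capital_costs(world, "baseline")),
    baseline_rnd = lapply(baseline_rnd_streams(world), as.data.frame)
  )
  if (isTRUE(spec$capital) && spec$name == "COMP") {
    inv$additional_capital <- capital_cost_summary(phase_capital_costs(world, "comp"))
  }
  if (!is.null(rnd)) inv$additional_rnd_avg <- rnd$avg_additional

  grp <- unique(world$commodities$group)
  pidx <- vapply(grp, function(g)
    price_index(cpl$solution, world, g, min(2030, world$horizon)), numeric(1))

  structure(list(
    scenario = spec,
    world_seed = world$seed,
    years = world$years,
    solution = cpl$solution,
    deviation = cpl$deviation,
    iterations = cpl$iterations,
    hunger = hung,
    incomes = incomes,
    price_index_2030 = pidx,
    investments = inv
  ), class = "ag_run")
}

# per-region income table (thousand USD/person) with feedback deviations
income_table <- function(world, deviation) {
  leaves <- rownames(world$baselines$production)
  yrs <- world$years
  aggs <- c("SSA", "AFR", "DVG", "WLD")
  rows <- list()
  for (r in leaves) {
    base <- average_income(world$macro[[r]], yrs)
    rows[[r]] <- data.frame(region_id = r, year = yrs, income_baseline = base,
                            deviation = deviation[, r],
                            income = base * (1 + deviation[, r]),
                            stringsAsFactors = FALSE)
  }
  for (a in aggs) {
    lv <- region_leaves(world, a)
    gdp <- sapply(lv, function(r) world$macro[[r]]$gdp)
    pop <- sapply(lv, function(r) world$macro[[r]]$population)
    gdp_adj <- gdp * (1 + deviation[, lv, drop = FALSE])
    base_inc <- rowSums(gdp) / rowSums(pop) * 1000
    inc <- rowSums(gdp_adj) / rowSums(pop) * 1000
    rows[[a]] <- data.frame(region_id = a, year = yrs,
                            income_baseline = base_inc,
                            deviation = inc / base_inc - 1, income = inc,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the three study scenarios
#' @param world an \code{ag_world}.
#' @param feedback include the income feedback.
#' @return named list of \code{ag_run} bundles (NoCC, CC, COMP).
#' @export
run_all_scenarios <- function(world, feedback = TRUE) {
  stats::setNames(lapply(c("NoCC", "CC", "COMP"), function(nm)
    run_scenario(world, nm, feedback = feedback)), c("NoCC", "CC", "COMP"))
}

#' Cross-scenario difference tables
#'
#' Region-by-year differences (first minus second run) of incomes, calorie
#' availability, hunger indicators, and commodity prices.
#'
#' @param a,b \code{ag_run} bundles computed on the same world.
#' @return list of delta data frames: \code{income}, \code{hunger} (kcal,
#'   share, millions), \code{price} (by commodity and year).
#' @export
compare_runs <- function(a, b) {
  if (!identical(a$world_seed, b$world_seed) || !identical(a$years, b$years))
    stop_config("result bundles were computed on different worlds")
  inc <- merge(a$incomes, b$incomes, by = c("region_id", "year"),
               suffixes = c("_a", "_b"))
  income <- data.frame(region_id = inc$region_id, year = inc$year,
                       delta_income = inc$income_a - inc$income_b)
  hg <- merge(a$hunger, b$hunger, by = c("region_id", "year"),
              suffixes = c("_a", "_b"))
  hunger <- data.frame(region_id = hg$region_id, year = hg$year,
                       delta_kcal = hg$kcal_pc_a - hg$kcal_pc_b,
                       delta_share = hg$share_at_risk_a - hg$share_at_risk_b,
                       delta_millions = hg$millions_at_risk_a - hg$millions_at_risk_b)
  price <- a$solution$price - b$solution$price
  list(pair = paste(a$scenario$name, "-", b$scenario$name),
       income = income, hunger = hunger, price = price)
}

#' Recompute the published tables' accounting targets
#'
#' Reproduces, from the package's own streams and costing machinery, every
#' supported sum/ratio of the encoded reference tables: fixture marginal
#' totals, per-capita income arithmetic, baseline R&D stream averages,
#' capital-cost averages for both phases and the additional R&D averages of
#' the comprehensive package.
#'
#' @param world an \code{ag_world} (calibrated).
#' @param fixtures fixture set (default: the shipped tables).
#' @return data frame (target, computed, printed, tol, pass).
#' @export
check_paper_tables <- function(world, fixtures = load_paper_fixtures()) {
  rows <- list()
  add <- function(target, computed, printed, tol) {
    rows[[length(rows) + 1L]] <<- data.frame(
      target = target, computed = computed, printed = printed, tol = tol,
      pass = is.finite(computed) && abs(computed - printed) <= tol,
      stringsAsFactors = FALSE)
  }
  fx <- check_fixture_tables(fixtures)
  for (i in seq_len(nrow(fx)))
    add(paste0(fx$table[i], ": ", fx$relation[i]), fx$computed[i],
        fx$printed[i], fx$tol[i])

  # income arithmetic of the socioeconomic table: GDP / population against
  # the printed per-capita cells, at propagated printed precision
  t2 <- fixtures$table2
  for (i in seq_len(nrow(t2))) for (yr in c(2010, 2020, 2030)) {
    pop <- t2[i, paste0("pop_", yr)]; gdp <- t2[i, paste0("gdp_", yr)]
    printed <- t2[i, paste0("income_", yr)]
    add(paste0("table2 income ", t2$region[i], " ", yr),
        gdp / pop * 1000, printed, 0.05 + 1000 * 0.05 / pop)
  }

  # baseline R&D streams reproduce the printed average annual levels
  base <- baseline_rnd_streams(world)
  sel <- world$years <= 2030
  t4 <- fixtures$table4; rn4 <- t4$region
  t4map <- c(SSA = "Africa South of the Sahara", NAWA = "North Africa and West Asia",
             ODV = "Other Developing Countries")
  for (r in world$rnd$regions) {
    add(paste0("table4 CGIAR avg ", r), mean(base$cgiar$values[sel, r]),
        t4[match(t4map[[r]], rn4), "cgiar"], 0.005)
    add(paste0("table4 NARS avg ", r), mean(base$nars$values[sel, r]),
        t4[match(t4map[[r]], rn4), "nars"], 0.005)
  }

  # capital costing reproduces the printed averages, both phases
  cap_cols4 <- c(irrigation_expansion = "irrigated_area",
                 water_use_efficiency = "water_use",
                 soil_water_mgmt = "soil_mgmt", infrastructure = "infrastructure")
  bsum <- capital_cost_summary(phase_capital_costs(world, "baseline"))
  for (i in seq_len(nrow(bsum))) {
    r <- bsum$region[i]; cat_ <- bsum$category[i]
    pr <- if (r == "DEV") fixtures$table4[match("Developed Countries", rn4), cap_cols4[[cat_]]]
          else fixtures$table4[match(t4map[[r]], rn4), cap_cols4[[cat_]]]
    add(paste0("table4 capital avg ", r, "/", cat_), bsum$avg_annual[i],
        as.numeric(pr), 0.005)
  }
  t5 <- fixtures$table5; rn5 <- t5$region
  csum <- capital_cost_summary(phase_capital_costs(world, "comp"))
  for (i in seq_len(nrow(csum))) {
    r <- csum$region[i]; cat_ <- csum$category[i]
    add(paste0("table5 capital avg ", r, "/", cat_), csum$avg_annual[i],
        t5[match(t4map[[r]], rn5), cat_], 0.005)
  }

  # inverse-costed additional R&D reproduces the printed averages
  if (!is.null(world$rnd$eta_cgiar)) {
    avg <- comp_rnd_package(world)$avg_additional
    for (r in world$rnd$regions)
      add(paste0("table5 R&D avg ", r), avg[[r]],
          t5[match(t4map[[r]], rn5), "rnd"], 0.005)
    # three printed components each carry up to half a unit of 2-dp rounding
    add("table5 R&D avg developing total", sum(avg),
        t5[match("All Developing Countries", rn5), "rnd"], 0.016)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
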