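#' Compound a level forward at a constant annual growth rate
#'
#' @param base_value starting level (must be positive).
#' @param cagr annual growth rate as a fraction (0.052 = 5.2 %/yr).
#' @param years number of years to project beyond the base.
#' @return numeric vector of length \code{years + 1}: the base value followed
#'   by exactly compounded levels \code{base * (1 + cagr)^t}.
#' @examples
#' project_series(2.8, 0.052, 20)[21]  # ~7.7
#' @export
project_series <- function(base_value, cagr, years) {
  if (!is.finite(base_value) || base_value <= 0) stop_domain("base_value must be > 0")
  if (years < 0) stop_domain("years must be >= 0")
  if (cagr <= -1) stop_domain("growth rate must exceed -100 %/yr")
  base_value * (1 + cagr)^(0:years)
}

# geometric interpolation through decade anchors (levels at anchor years)
interp_geometric <- function(anchor_years, anchor_values, years) {
  stopifnot(length(anchor_years) == length(anchor_values), all(anchor_values > 0))
  logv <- stats::approx(anchor_years, log(anchor_values), xout = years,
                        rule = 2)$y
  # extend beyond last anchor at the final inter-anchor growth rate
  n <- length(anchor_years)
  last_rate <- (log(anchor_values[n]) - log(anchor_values[n - 1])) /
    (anchor_years[n] - anchor_years[n - 1])
  beyond <- years > anchor_years[n]
  logv[beyond] <- log(anchor_values[n]) + last_rate * (years[beyond] - anchor_years[n])
  exp(logv)
}

#' Construct a population/GDP trajectory for one region
#'
#' Decade anchor levels are interpolated geometrically (constant growth rate
#' within each decade); the path is extended beyond the final anchor at the
#' last decade's growth rate.
#'
#' @param region_id region code.
#' @param anchor_years calendar years of the printed anchors.
#' @param population population anchors, millions.
#' @param gdp GDP anchors, trillion constant-2005 USD.
#' @param years years the trajectory should cover (default 2010..2030).
#' @return an \code{ag_macro} object: data frame with year, population, gdp.
#' @export
macro_trajectory <- function(region_id, anchor_years, population, gdp,
                             years = 2010:2030) {
  if (any(population <= 0) || any(gdp <= 0)) stop_domain("population and gdp must be > 0")
  structure(
    data.frame(
      region_id = region_id, year = years,
      population = interp_geometric(anchor_years, population, years),
      gdp = interp_geometric(anchor_years, gdp, years)
    ),
    class = c("ag_macro", "data.frame")
  )
}

#' Average annual income along a trajectory
#'
#' GDP (trillion USD) divided by population (million persons), expressed in
#' thousand USD per person - the unit of the published socioeconomic table.
#'
#' @param traj an \code{ag_macro} trajectory.
#' @param year calendar year (vectorised).
#' @return thousand USD per person.
#' @export
average_income <- function(traj, year) {
  i <- match(year, traj$year)
  if (anyNA(i)) stop_domain("year ", paste(year[is.na(i)], collapse = ", "),
                            " outside trajectory")
  pop <- traj$population[i]
  if (any(pop == 0)) stop_domain("population is zero")
  traj$gdp[i] / pop * 1000
}

#' Aggregate child-region trajectories into a parent region
#'
#' Population and GDP are summed across children year by year; income of the
#' aggregate is always recomputed from the summed GDP and population, never
#' averaged across children.
#'
#' @param trajs list of \code{ag_macro} trajectories (the children).
#' @param aggregate region code for the result.
#' @param children optional character vector naming the required children;
#'   aggregation fails loudly if one is absent.
#' @return an \code{ag_macro} trajectory for the aggregate.
#' @export
aggregate_regions <- function(trajs, aggregate, children = NULL) {
  ids <- vapply(trajs, function(t) t$region_id[1], character(1))
  if (!is.null(children)) {
    miss <- setdiff(children, ids)
    if (length(miss)) stop_domain("missing child region(s) for ", aggregate, ": ",
                                  paste(miss, collapse = ", "))
    trajs <- trajs[match(children, ids)]
  }
  yrs <- trajs[[1]]$year
  for (t in trajs[-1]) {
    if (!identical(t$year, yrs)) stop_domain("child trajectories cover different years")
  }
  pop <- Reduce(`+`, lapply(trajs, `[[`, "population"))
  gdp <- Reduce(`+`, lapply(trajs, `[[`, "gdp"))
  structure(
    data.frame(region_id = aggregate, year = yrs, population = pop, gdp = gdp),
    class = c("ag_macro", "data.frame")
  )
}

# Build the leaf-region trajectories from the encoded socioeconomic table.
# Leaf GDP anchors are derived as income x population / 1000: the printed
# per-capita income cells carry more relative precision than the 1-dp GDP
# cells for the small African regions (see methods vignette).
build_macro_trajectories <- function(table2, leaves, years = 2010:2030) {
  rn <- table2$region
  rowmap <- c(NAF = "Northern Africa", WAF = "Western Africa",
              EAF = "Eastern Africa", CAF = "Central Africa",
              SAF = "Southern Africa", ODV = "Other Developing Countries",
              DEV = "Developed Countries")
  out <- list()
  for (lf in leaves) {
    src <- sub("_[0-9]+$", "", lf)      # split leaves (e.g. ODV_1) share anchors
    i <- match(rowmap[[src]], rn)
    pop <- as.numeric(table2[i, c("pop_2010", "pop_2020", "pop_2030")])
    inc <- as.numeric(table2[i, c("income_2010", "income_2020", "income_2030")])
    gdp <- inc * pop / 1000
    out[[lf]] <- macro_trajectory(lf, c(2010, 2020, 2030), pop, gdp, years)
  }
  out
}
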