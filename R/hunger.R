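# Calorie availability and hunger-prevalence indicators.
#
# Equilibrium food demand is converted to dietary energy supply per person
# and mapped to the share of the population at risk of hunger through a
# monotone-decreasing piecewise log-linear curve in the ratio of
# availability to a 2400 kcal/day reference requirement.  The curve's
# interior anchors are calibrated at build time so the published 2010
# shares are reproduced; its functional form is pluggable (see the methods
# vignette for what is and is not identified by the published numbers).

#' Kilocalorie availability per person per day
#'
#' @param demand food demand by commodity, Mt/yr.
#' @param kcal_per_kg energy density by commodity, kcal/kg.
#' @param population millions of persons (> 0).
#' @return kcal per person per day.
#' @export
kcal_availability <- function(demand, kcal_per_kg, population) {
  if (population <= 0) stop_domain("population must be > 0")
  sum(demand * kcal_per_kg) * 1e9 / (population * 1e6 * 365)
}

#' Share of the population at risk of hunger
#'
#' Piecewise log-linear interpolation through the calibrated anchor pairs
#' (availability/requirement ratio, share), clipped to [floor, 1].
#'
#' @param kcal_pc kcal per person per day (> 0); vectorised.
#' @param requirement reference requirement, kcal/day.
#' @param params hunger-curve parameters: list with \code{anchors} (data
#'   frame: ratio, share), \code{floor}.
#' @return share at risk, fraction in [floor, 1].
#' @export
hunger_share <- function(kcal_pc, requirement = 2400, params) {
  if (any(kcal_pc <= 0)) stop_domain("kcal_pc must be > 0")
  a <- params$anchors
  if (any(diff(a$ratio) <= 0) || any(diff(a$share) >= 0))
    stop_config("hunger-curve anchors must be strictly monotone ",
                "(increasing ratio, decreasing share)")
  ratio <- kcal_pc / requirement
  ls <- stats::approx(a$ratio, log(a$share), xout = ratio, rule = 2)$y
  # extrapolate the end segments' slopes outside the anchor range, so the
  # curve keeps falling to its floor at high availability (and rising
  # toward 1 at very low availability)
  n <- nrow(a)
  low <- ratio < a$ratio[1]
  if (any(low)) {
    sl <- (log(a$share[2]) - log(a$share[1])) / (a$ratio[2] - a$ratio[1])
    ls[low] <- log(a$share[1]) + sl * (ratio[low] - a$ratio[1])
  }
  high <- ratio > a$ratio[n]
  if (any(high)) {
    sh <- (log(a$share[n]) - log(a$share[n - 1])) / (a$ratio[n] - a$ratio[n - 1])
    ls[high] <- log(a$share[n]) + sh * (ratio[high] - a$ratio[n])
  }
  pmin(pmax(exp(ls), params$floor), 1)
}

#' Invert the hunger curve on its interpolation range
#' @param share share at risk, within the anchor range.
#' @param requirement reference requirement, kcal/day.
#' @param params hunger-curve parameters.
#' @return kcal per person per day giving that share.
#' @export
hunger_share_inverse <- function(share, requirement = 2400, params) {
  a <- params$anchors
  if (any(share > max(a$share) | share < min(a$share)))
    stop_domain("share outside the interpolation range")
  ratio <- stats::approx(log(a$share), a$ratio, xout = log(share))$y
  ratio * requirement
}

#' Millions of people at risk of hunger
#' @param share share at risk, in [0, 1].
#' @param population millions.
#' @return millions at risk.
#' @export
population_at_risk <- function(share, population) {
  if (any(share < 0 | share > 1)) stop_domain("share must lie in [0, 1]")
  share * population
}

#' Regions meeting a hunger-prevalence threshold
#'
#' @param indicators hunger-indicator data frame (region_id, year, scenario,
#'   kcal_pc, share_at_risk, millions_at_risk, population).
#' @param threshold prevalence threshold (default 0.05, the prudential
#'   five-percent target); the comparison is inclusive: a share exactly at
#'   the threshold counts as meeting it.
#' @param year report year (default: latest in the table).
#' @return list: \code{meeting} and \code{not_meeting} region vectors,
#'   counts, the year, and the filtered indicator rows.
#' @export
threshold_report <- function(indicators, threshold = 0.05, year = NULL) {
  year <- year %||% max(indicators$year)
  sub <- indicators[indicators$year == year, ]
  ok <- sub$share_at_risk <= threshold
  list(year = year, threshold = threshold,
       meeting = sub$region_id[ok], not_meeting = sub$region_id[!ok],
       n_meeting = sum(ok), n_not_meeting = sum(!ok), rows = sub)
}

# hunger indicators for every leaf and reporting aggregate of a solved run.
# Aggregates sum calories and millions over their leaves (never averaging
# shares), and recompute the share as millions / population.
hunger_indicators <- function(world, demand, scenario,
                              aggregates = c("SSA", "AFR", "DVG", "WLD")) {
  yrs <- world$years
  leaves <- dimnames(demand)[[2]]
  kpk <- world$commodities$kcal_per_kg
  hc <- world$hunger_curve
  rows <- list()
  pop <- vapply(leaves, function(r) world$macro[[r]]$population, numeric(length(yrs)))
  for (i in seq_along(yrs)) {
    kc <- vapply(leaves, function(r)
      kcal_availability(demand[i, r, ], kpk, pop[i, r]), numeric(1))
    sh <- hunger_share(kc, hc$requirement, hc)
    mill <- population_at_risk(sh, pop[i, ])
    rows[[i]] <- data.frame(region_id = leaves, year = yrs[i],
                            scenario = scenario, kcal_pc = kc,
                            share_at_risk = sh, millions_at_risk = mill,
                            population = pop[i, ], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  for (agg in aggregates) {
    lv <- region_leaves(world, agg)
    sub <- out[out$region_id %in% lv, ]
    by_year <- split(sub, sub$year)
    agg_rows <- do.call(rbind, lapply(by_year, function(s) {
      popa <- sum(s$population)
      milla <- sum(s$millions_at_risk)
      data.frame(region_id = agg, year = s$year[1], scenario = scenario,
                 kcal_pc = sum(s$kcal_pc * s$population) / popa,
                 share_at_risk = milla / popa, millions_at_risk = milla,
                 population = popa, stringsAsFactors = FALSE)
    }))
    out <- rbind(out, agg_rows)
  }
  rownames(out) <- NULL
  out
}
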