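# Climate yield shocks and intrinsic productivity paths.
#
# Two climates are represented: NoCC (constant 2005 climate, multiplier 1
# everywhere) and CC (a severe high-emissions realization whose biophysical
# yield shock reaches -7 % for Africa, -5 % for the developing average and
# -6 % for the world average by 2030).  Shocks are 1 through the base
# period (2010-2014) and phase in linearly from 2015 to the 2030 endpoint,
# so the NoCC and CC scenarios coincide before 2015; per-commodity
# dispersion around each regional endpoint is drawn once per world seed and
# recentred so the production-weighted regional mean matches the endpoint
# exactly.  Beyond 2030 the shock is held at its endpoint.

CLIMATE_SCENARIOS <- c("NoCC", "CC")

# leaves x commodities shock matrix for one year
shock_matrix <- function(world, climate, year) {
  if (!climate %in% CLIMATE_SCENARIOS)
    stop_config("unknown climate scenario: ", climate)
  m <- world$shock_end_2030
  onset <- 2015
  if (climate == "NoCC" || year < onset) {
    m[] <- 1
    return(m)
  }
  frac <- min((year - onset + 1) / (2030 - onset + 1), 1)
  1 + frac * (m - 1)
}

# leaves x commodities intrinsic productivity multiplier for one year
# (geometric path through the calibrated 2030 multiplier)
intrinsic_matrix <- function(world, year) {
  world$intrinsic_2030^((year - world$base_year) / (2030 - world$base_year))
}

#' Climate yield-shock multiplier
#'
#' Multiplicative yield shock for a region, commodity and year under a given
#' climate scenario.  \code{NoCC} returns exactly 1; \code{CC} interpolates
#' linearly between 1 in 2010 and the region's calibrated 2030 endpoint.
#' Aggregate regions return the production-weighted mean over their leaves;
#' \code{commodity = NULL} gives the production-weighted regional mean.
#'
#' @param world an \code{ag_world}.
#' @param scenario \code{"NoCC"} or \code{"CC"}.
#' @param region region code (leaf or aggregate).
#' @param commodity commodity code, or NULL for the regional mean.
#' @param year calendar year within the projection window.
#' @return shock multiplier (unitless).
#' @export
shock_at <- function(world, scenario, region, commodity = NULL, year) {
  if (year < world$base_year || year > world$horizon)
    stop_domain("year ", year, " outside projection window")
  m <- shock_matrix(world, scenario, year)
  leaves <- region_leaves(world, region)
  w <- world$baselines$production[leaves, , drop = FALSE]
  if (is.null(commodity)) return(wmean(m[leaves, , drop = FALSE], w))
  wmean(m[leaves, commodity], w[, commodity])
}

#' Cumulative intrinsic productivity path
#'
#' The baseline (no additional investment) productivity multiplier path from
#' compounded intrinsic yield growth, calibrated so the 2030
#' production-weighted values reproduce the no-climate-change anchors
#' (Africa 1.38, developing 1.32).
#'
#' @inheritParams shock_at
#' @param region region code (leaf or aggregate).
#' @param commodity commodity code or NULL for the production-weighted mean.
#' @return named numeric path over the projection years (2010 = 1).
#' @export
baseline_productivity_path <- function(world, region, commodity = NULL) {
  leaves <- region_leaves(world, region)
  w <- world$baselines$production[leaves, , drop = FALSE]
  vapply(world$years, function(y) {
    m <- intrinsic_matrix(world, y)
    if (is.null(commodity)) wmean(m[leaves, , drop = FALSE], w)
    else wmean(m[leaves, commodity], w[, commodity])
  }, numeric(1)) |> stats::setNames(world$years)
}

#' Export shock paths as a long table
#' @param world an \code{ag_world}.
#' @param scenario \code{"NoCC"} or \code{"CC"}.
#' @return data frame (region, commodity, year, multiplier).
#' @export
shock_table <- function(world, scenario) {
  leaves <- rownames(world$baselines$production)
  cid <- world$commodities$commodity_id
  out <- expand.grid(region = leaves, commodity = cid, year = world$years,
                     stringsAsFactors = FALSE)
  out$multiplier <- vapply(seq_len(nrow(out)), function(i)
    shock_matrix(world, scenario, out$year[i])[out$region[i], out$commodity[i]],
    numeric(1))
  out
}
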