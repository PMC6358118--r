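# Unit-cost capital costing of irrigation expansion, water-use efficiency,
# soil-water management and infrastructure.
#
# Capital is installed in equal physical tranches over the intervention
# window; the annual stream is the installation cost plus maintenance on the
# capital installed so far: value_k = C/Y + mf * C * k/Y for year k of Y,
# with C = increment x unit cost.

#' Cost capital investment targets with unit costs
#'
#' @param targets data frame with columns \code{region}, \code{category} and
#'   \code{increment} (physical units: Mha for area-based categories,
#'   efficiency points for water-use efficiency, composite units for
#'   infrastructure); increments must be non-negative.
#' @param unit_costs data frame with columns \code{region}, \code{category},
#'   \code{unit_cost} (billion USD per physical unit),
#'   \code{maintenance_frac}, \code{start_year}, \code{end_year}; the shipped
#'   calibration table is \code{load_paper_fixtures()$capital_costing}.
#' @param phase which unit-cost rows to use when the table carries a
#'   \code{phase} column ("baseline" or "comp").
#' @return data frame (region, category, year, value) of annual investment,
#'   billion 2005 USD, of class \code{ag_capital_stream}.
#' @export
cost_capital <- function(targets, unit_costs, phase = NULL) {
  if (any(targets$increment < 0)) stop_domain("increments must be non-negative")
  if (!is.null(phase) && "phase" %in% names(unit_costs))
    unit_costs <- unit_costs[unit_costs$phase == phase, ]
  out <- vector("list", nrow(targets))
  for (i in seq_len(nrow(targets))) {
    tg <- targets[i, ]
    uc <- unit_costs[unit_costs$region == tg$region &
                       unit_costs$category == tg$category, ]
    if (nrow(uc) != 1)
      stop_config("no unit cost configured for ", tg$region, "/", tg$category)
    Y <- uc$end_year - uc$start_year + 1L
    C <- tg$increment * uc$unit_cost
    k <- seq_len(Y)
    out[[i]] <- data.frame(region = tg$region, category = tg$category,
                           year = uc$start_year + k - 1L,
                           value = C / Y + uc$maintenance_frac * C * k / Y,
                           stringsAsFactors = FALSE)
  }
  structure(do.call(rbind, out), class = c("ag_capital_stream", "data.frame"))
}

#' Average annual cost by region and category
#' @param stream an \code{ag_capital_stream} from \code{\link{cost_capital}}.
#' @return data frame (region, category, avg_annual) in billion USD/yr.
#' @export
capital_cost_summary <- function(stream) {
  agg <- stats::aggregate(value ~ region + category, data = stream, FUN = mean)
  names(agg)[3] <- "avg_annual"
  agg
}

# physical capital targets of the comprehensive scenario (and the baseline),
# taken from the shipped calibration table
capital_targets <- function(unit_costs, phase) {
  uc <- unit_costs[unit_costs$phase == phase, ]
  data.frame(region = uc$region, category = uc$category,
             increment = uc$increment, stringsAsFactors = FALSE)
}

# annual capital streams for a phase, summarised as region x category means
phase_capital_costs <- function(world, phase) {
  uc <- world$unit_costs
  cost_capital(capital_targets(uc, phase), uc, phase = phase)
}
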