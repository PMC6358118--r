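# Partial-equilibrium multi-market core.
#
# Constant-elasticity supply and demand with marketing margins (split 50/50
# between a producer and a consumer wedge) and a single world price per
# commodity; regions trade their supply-demand residual frictionlessly.
# Each year the world price vector is solved so world excess demand is zero
# for every commodity: a damped Newton iteration on log prices with an
# analytic Jacobian, initialized at the previous year's prices, with step
# halving on residual increases.  Years are solved sequentially (recursive
# dynamics, no expectations).

# scenario driver bundle for one year
year_drivers <- function(world, climate, year, tau, margin_scale,
                         income_mult) {
  list(
    intr = intrinsic_matrix(world, year),
    shock = shock_matrix(world, climate, year),
    tau = tau,                 # leaves-length TFP multiplier (R&D uplift)
    margin = world$baselines$margin * margin_scale,
    income_mult = income_mult  # leaves-length multiplier on baseline income
  )
}

#' Regional supply at a candidate world price
#'
#' \eqn{Q^s = Q^s_{base} (P_{prod}/P_{prod,base})^{\epsilon_s} g(t) \tau s}:
#' the constant-elasticity producer-price response scaled by intrinsic
#' productivity growth, the R&D TFP multiplier and the climate shock.
#'
#' @param world an \code{ag_world}.
#' @param region leaf region code.
#' @param commodity commodity code.
#' @param year calendar year.
#' @param price world price, USD/t (must be > 0).
#' @param climate "NoCC" or "CC".
#' @param tau R&D TFP multiplier (default 1).
#' @param margin optional margin override (fraction of the wedge).
#' @return supply, Mt.
#' @export
supply_quantity <- function(world, region, commodity, year, price,
                            climate = "NoCC", tau = 1, margin = NULL) {
  if (any(price <= 0)) stop_domain("price must be > 0")
  bl <- world$baselines
  m0 <- bl$margin[region, commodity]
  m <- margin %||% m0
  pp0 <- bl$price[[commodity]] * (1 - m0 / 2)
  pp <- price * (1 - m / 2)
  g <- intrinsic_matrix(world, year)[region, commodity]
  s <- shock_matrix(world, climate, year)[region, commodity]
  bl$production[region, commodity] *
    (pp / pp0)^world$elasticities$supply_price[region, commodity] * g * tau * s
}

#' Regional demand at a candidate world price
#'
#' \eqn{Q^d = Q^d_{base} (P_{cons}/P_{cons,base})^{\epsilon_d}
#' (y/y_{base})^{\epsilon_y} (N/N_{base})} with an optional cross-price
#' product term.
#'
#' @inheritParams supply_quantity
#' @param income_pc per-capita income, thousand USD (baseline-year units).
#' @param population millions.
#' @return demand, Mt.
#' @export
demand_quantity <- function(world, region, commodity, year, price,
                            income_pc, population, margin = NULL) {
  if (any(price <= 0) || income_pc <= 0 || population <= 0)
    stop_domain("price, income and population must be > 0")
  bl <- world$baselines
  m0 <- bl$margin[region, commodity]
  m <- margin %||% m0
  pc0 <- bl$price[[commodity]] * (1 + m0 / 2)
  pc <- price * (1 + m / 2)
  y0 <- average_income(world$macro[[region]], world$base_year)
  n0 <- world$macro[[region]]$population[1]
  bl$consumption[region, commodity] *
    (pc / pc0)^world$elasticities$demand_price[region, commodity] *
    (income_pc / y0)^world$elasticities$demand_income[region, commodity] *
    (population / n0)
}

# vectorised supply/demand matrices for the solver (leaves x commodities)
supply_all <- function(world, price, dr) {
  bl <- world$baselines
  pp0 <- outer(rep(1, nrow(bl$margin)), bl$price) * (1 - bl$margin / 2)
  pp <- outer(rep(1, nrow(bl$margin)), price) * (1 - dr$margin / 2)
  bl$production * (pp / pp0)^world$elasticities$supply_price *
    dr$intr * dr$shock * dr$tau
}

demand_all <- function(world, price, dr, pop_mult, inc_ratio) {
  bl <- world$baselines
  pc0 <- outer(rep(1, nrow(bl$margin)), bl$price) * (1 + bl$margin / 2)
  pc <- outer(rep(1, nrow(bl$margin)), price) * (1 + dr$margin / 2)
  q <- bl$consumption * (pc / pc0)^world$elasticities$demand_price *
    (inc_ratio * dr$income_mult)^world$elasticities$demand_income * pop_mult
  cr <- world$elasticities$demand_cross
  if (!is.null(cr)) {
    lnrel <- log(price / bl$price)
    q <- q * exp(matrix(lnrel, nrow(q), ncol(q), byrow = TRUE) %*% t(cr))
  }
  q
}

#' Solve one year's market-clearing world prices
#'
#' Damped Newton iteration on log prices zeroing world excess demand per
#' commodity; deterministic given the drivers.
#'
#' @param world an \code{ag_world}.
#' @param year calendar year.
#' @param drivers list from the scenario layer: climate, tau (leaf TFP
#'   multipliers), margin_scale, income_mult (leaf income multipliers).
#' @param p_start starting prices (default: baseline).
#' @param tol relative clearing tolerance (default 1e-9).
#' @param max_iter Newton iteration cap.
#' @return list: price vector, supply and demand matrices, residuals.
#' @export
solve_year <- function(world, year, drivers = list(), p_start = NULL,
                       tol = 1e-9, max_iter = 200L) {
  climate <- drivers$climate %||% "NoCC"
  leaves <- rownames(world$baselines$production)
  tau <- drivers$tau %||% stats::setNames(rep(1, length(leaves)), leaves)
  margin_scale <- drivers$margin_scale %||% 1
  income_mult <- drivers$income_mult %||% stats::setNames(rep(1, length(leaves)), leaves)
  dr <- year_drivers(world, climate, year, tau, margin_scale, income_mult)
  dr$tau <- matrix(tau[leaves], length(leaves), ncol(world$baselines$margin))

  iyr <- match(year, world$years)
  pop_mult <- vapply(leaves, function(r)
    world$macro[[r]]$population[iyr] / world$macro[[r]]$population[1], numeric(1))
  inc_ratio <- vapply(leaves, function(r)
    average_income(world$macro[[r]], year) /
      average_income(world$macro[[r]], world$base_year), numeric(1))

  p <- p_start %||% world$baselines$price
  es <- world$elasticities$supply_price
  ed <- world$elasticities$demand_price
  resid <- function(S, D) (colSums(D) - colSums(S)) / colSums(S)
  S <- supply_all(world, p, dr); D <- demand_all(world, p, dr, pop_mult, inc_ratio)
  r <- resid(S, D)
  for (it in seq_len(max_iter)) {
    if (max(abs(r)) < tol) break
    E <- colSums(D) - colSums(S)
    J <- diag(colSums(D * ed) - colSums(S * es), length(p))
    cr <- world$elasticities$demand_cross
    if (!is.null(cr)) J <- J + colSums(D) * cr  # dD_c/dlnp_k = D_c cr[c,k]
    step <- -solve(J, E)
    lambda <- 1
    repeat {
      p_new <- p * exp(lambda * step)
      S2 <- supply_all(world, p_new, dr)
      D2 <- demand_all(world, p_new, dr, pop_mult, inc_ratio)
      r2 <- resid(S2, D2)
      if (max(abs(r2)) < max(abs(r)) || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    p <- p_new; S <- S2; D <- D2; r <- r2
  }
  if (max(abs(r)) >= 1e-6)
    stop_solver("market solver failed to clear year ", year,
                "; worst commodity ", names(p)[which.max(abs(r))],
                " residual ", signif(max(abs(r)), 3))
  list(year = year, price = p, supply = S, demand = D, residual = r,
       iterations = it)
}

# solve all years sequentially for a scenario driver set
solve_horizon <- function(world, climate, tau_path, margin_scale_path,
                          income_mult, tol = 1e-9) {
  yrs <- world$years
  leaves <- rownames(world$baselines$production)
  cid <- names(world$baselines$price)
  nT <- length(yrs)
  price <- matrix(NA_real_, nT, length(cid), dimnames = list(yrs, cid))
  supply <- array(NA_real_, c(nT, length(leaves), length(cid)),
                  dimnames = list(yrs, leaves, cid))
  demand <- supply
  residual <- price
  p_prev <- world$baselines$price
  for (i in seq_len(nT)) {
    sol <- solve_year(world, yrs[i],
                      drivers = list(climate = climate,
                                     tau = tau_path[i, ],
                                     margin_scale = margin_scale_path[i],
                                     income_mult = income_mult[i, ]),
                      p_start = p_prev, tol = tol)
    price[i, ] <- sol$price
    supply[i, , ] <- sol$supply
    demand[i, , ] <- sol$demand
    residual[i, ] <- sol$residual
    p_prev <- sol$price
  }
  list(price = price, supply = supply, demand = demand, residual = residual)
}

#' Commodity-group price index
#'
#' Base-year-consumption-weighted mean of within-group price relatives
#' (base year = 1).
#'
#' @param solution a solved scenario (an \code{ag_run} or the raw solution
#'   list with a \code{price} matrix).
#' @param world the world the solution was computed on.
#' @param group commodity group name, or "all" for the full food index.
#' @param year report year.
#' @param base_year index base (default: the world's base year).
#' @return index value (base = 1).
#' @export
price_index <- function(solution, world, group = "all", year,
                        base_year = world$base_year) {
  price <- if (!is.null(solution$solution)) solution$solution$price else solution$price
  sel <- if (identical(group, "all")) rep(TRUE, nrow(world$commodities))
         else world$commodities$group == group
  if (!any(sel)) stop_domain("empty commodity group: ", group)
  cid <- world$commodities$commodity_id[sel]
  w <- colSums(world$baselines$consumption[, cid, drop = FALSE]) *
    world$baselines$price[cid]
  rel <- price[as.character(year), cid] / price[as.character(base_year), cid]
  sum(rel * w) / sum(w)
}
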