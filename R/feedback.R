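# Reduced-form economy-wide income feedback.
#
# The full economy-wide model is replaced by a linear reduced form: a
# region's real-income deviation from its baseline trajectory is
# proportional to its food value-added share times its agricultural
# productivity-driven output deviation, delta_y = kappa * va * tfp_delta.
# The market model and the income update are iterated to a fixed point,
# mirroring the two-model loop of the full framework: incomes shift food
# demand, demand moves prices and realized output, and output deviations
# feed back into incomes.  The pass-through kappa is calibrated once per
# world against the published Africa income gain of the comprehensive
# scenario (about +5 % vs the climate-change baseline in 2030) and then
# frozen.

#' Income deviation implied by a productivity deviation
#'
#' Linear reduced form \code{delta_y = kappa * va_share * tfp_delta}.
#'
#' @param tfp_delta fractional productivity(-driven output) deviation from
#'   baseline, by region (vectorised).
#' @param va_share food value-added share of GDP, in [0, 1].
#' @param kappa pass-through coefficient (> 0).
#' @return fractional per-capita income deviation(s).
#' @export
income_deviation <- function(tfp_delta, va_share, kappa) {
  if (any(va_share < 0 | va_share > 1)) stop_domain("va_share must lie in [0, 1]")
  if (kappa < 0) stop_domain("kappa must be non-negative")
  kappa * va_share * tfp_delta
}

# real agricultural output valued at base prices, years x leaves
output_index <- function(world, supply) {
  p0 <- world$baselines$price
  apply(supply, c(1, 2), function(q) sum(q * p0))
}

#' Iterate the market model and the income feedback to a fixed point
#'
#' Alternates a full market solve with the income update until the maximum
#' relative income change falls below \code{tol}.  With \code{kappa = 0} the
#' loop converges in one iteration to the pure partial-equilibrium solution.
#'
#' @param world an \code{ag_world}.
#' @param climate "NoCC" or "CC".
#' @param tau_path years x leaves TFP multiplier matrix (R&D uplift).
#' @param margin_scale_path years x leaves multiplier on baseline margins.
#' @param kappa pass-through (default: the world's calibrated value).
#' @param max_iter iteration cap (default 50).
#' @param tol convergence tolerance on relative income change (default 1e-8).
#' @param reference optional precomputed no-feedback reference output index
#'   (years x leaves); default: the no-climate-change no-feedback run.
#' @return list: \code{solution} (price/supply/demand/residual),
#'   \code{deviation} (years x leaves income deviations),
#'   \code{iterations}, \code{reference_output}.
#' @export
iterate_coupled <- function(world, climate = "NoCC", tau_path = NULL,
                            margin_scale_path = NULL, kappa = NULL,
                            max_iter = NULL, tol = NULL, reference = NULL) {
  leaves <- rownames(world$baselines$production)
  nT <- length(world$years)
  tau_path <- tau_path %||% matrix(1, nT, length(leaves),
                                   dimnames = list(world$years, leaves))
  margin_scale_path <- margin_scale_path %||% tau_path * 0 + 1
  kappa <- kappa %||% world$feedback$kappa %||% 0
  max_iter <- max_iter %||% world$feedback$max_iter
  tol <- tol %||% world$feedback$tol
  ones <- matrix(1, nT, length(leaves), dimnames = list(world$years, leaves))

  if (is.null(reference)) {
    ref_sol <- solve_horizon(world, "NoCC", ones, ones, ones)
    reference <- output_index(world, ref_sol$supply)
  }
  va <- world$food_va_share[leaves]
  delta <- ones * 0
  sol <- NULL
  prev_delta <- delta
  changes <- numeric(0)
  for (it in seq_len(max_iter)) {
    sol <- solve_horizon(world, climate, tau_path, margin_scale_path,
                         1 + delta)
    gap <- output_index(world, sol$supply) / reference - 1
    new_delta <- sweep(gap, 2, va, function(g, v) income_deviation(g, v, kappa))
    change <- max(abs((1 + new_delta) / (1 + delta) - 1))
    changes <- c(changes, change)
    prev_delta <- delta
    delta <- new_delta
    if (change < tol) break
  }
  if (change >= tol)
    stop_solver("income feedback failed to converge after ", max_iter,
                " iterations (last change ", signif(change, 3),
                "; last two iterate ranges [",
                paste(signif(range(prev_delta), 4), collapse = ", "), "] vs [",
                paste(signif(range(delta), 4), collapse = ", "), "])")
  list(solution = sol, deviation = delta, iterations = it,
       change_trace = changes, reference_output = reference)
}

# Calibrate kappa once on a world: run the climate-change and comprehensive
# scenarios without feedback and choose kappa so the GDP-weighted Africa
# income deviation gap in 2030 equals the +5 % anchor.
calibrate_kappa <- function(world, anchor = 0.05) {
  leaves <- rownames(world$baselines$production)
  nT <- length(world$years)
  ones <- matrix(1, nT, length(leaves), dimnames = list(world$years, leaves))
  ref <- output_index(world, solve_horizon(world, "NoCC", ones, ones, ones)$supply)
  cc <- output_index(world, solve_horizon(world, "CC", ones, ones, ones)$supply)
  comp_tau <- comp_rnd_package(world)$tau
  ms <- comp_margin_path(world)
  comp <- output_index(world,
                       solve_horizon(world, "CC", comp_tau, ms, ones)$supply)
  iy <- match(min(2030, world$horizon), world$years)
  afr <- region_leaves(world, "AFR")
  gdp_w <- vapply(afr, function(r) world$macro[[r]]$gdp[iy], numeric(1))
  gap <- (comp[iy, afr] / ref[iy, afr]) - (cc[iy, afr] / ref[iy, afr])
  sens <- sum(gdp_w * world$food_va_share[afr] * gap) / sum(gdp_w)
  if (sens <= 0) stop_config("cannot calibrate kappa: non-positive output gap")
  anchor / sens
}
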