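# Perpetual-inventory knowledge stocks, TFP growth, inverse costing of
# productivity targets, and unit-cost capital costing.
#
# Knowledge accumulates as K_t = (1 - delta) K_{t-1} + sum_l w_l I_eff,t-l,
# where the effective investment I_eff adds spillover-weighted foreign
# investment, and annual TFP growth is eta * (K_t/K_{t-1} - 1).  Research
# types differ in gestation: longer, later-peaking lags for basic research,
# shorter for applied/developmental work.  The decay captures obsolescence
# ("creative destruction") of the stock.

#' Perpetual-inventory parameters
#'
#' @param research_type one of "basic", "applied", "developmental".
#' @param decay annual obsolescence rate delta, in [0, 0.3] (0 is permitted
#'   for closed-form checks; a strictly positive decay is the substantive
#'   configuration).
#' @param lag_years length of the gestation window L.
#' @param peak lag year (1-based) at which the trapezoidal weights peak.
#' @param elasticity stock elasticity eta: percent TFP growth per percent
#'   growth of the knowledge stock; must be > 0.
#' @param lag_weights optional explicit weights (overrides the trapezoid);
#'   must be non-negative and sum to 1.
#' @param spillover_matrix optional square matrix sigma with rows = source
#'   region, columns = receiving region, unit diagonal, entries in [0, 1].
#' @return an object of class \code{ag_pim_params}.
#' @export
pim_params <- function(research_type = c("basic", "applied", "developmental"),
                       decay = 0.10, lag_years = 10L, peak = 5L,
                       elasticity = 0.25, lag_weights = NULL,
                       spillover_matrix = NULL) {
  research_type <- match.arg(research_type)
  if (decay < 0 || decay > 0.3) stop_domain("decay must lie in [0, 0.3]")
  if (elasticity <= 0) stop_domain("stock elasticity must be > 0")
  if (is.null(lag_weights)) {
    l <- seq_len(lag_years)
    lag_weights <- pmin(l / peak, (lag_years + 1 - l) / (lag_years + 1 - peak))
    lag_weights <- lag_weights / sum(lag_weights)
  }
  if (any(lag_weights < 0) || abs(sum(lag_weights) - 1) > 1e-12)
    stop_domain("lag weights must be non-negative and sum to 1")
  if (!is.null(spillover_matrix)) {
    if (any(diag(spillover_matrix) != 1) ||
        any(spillover_matrix < 0 | spillover_matrix > 1))
      stop_domain("spillover matrix needs unit diagonal and entries in [0, 1]")
  }
  structure(list(research_type = research_type, decay = decay,
                 lag_weights = lag_weights, elasticity = elasticity,
                 spillover_matrix = spillover_matrix),
            class = "ag_pim_params")
}

# rebuild from deserialized fields without re-deriving weights
pim_params_raw <- function(research_type, decay, lag_weights, elasticity,
                           spillover_matrix = NULL, ...) {
  pim_params(research_type, decay, lag_years = length(lag_weights),
             elasticity = elasticity, lag_weights = as.numeric(lag_weights),
             spillover_matrix = spillover_matrix)
}

#' Annual investment stream
#'
#' @param years calendar years covered.
#' @param values numeric vector (one region) or years x regions matrix of
#'   annual investment, billion constant-2005 USD; must be non-negative.
#' @param regions region codes (columns).
#' @param institution "CGIAR", "NARS" or "capital".
#' @param category investment category; "R&D" is restricted to the CGIAR and
#'   NARS channels.
#' @return an object of class \code{ag_stream}.
#' @export
investment_stream <- function(years, values, regions = "ALL",
                              institution = c("CGIAR", "NARS", "capital"),
                              category = "R&D") {
  institution <- match.arg(institution)
  if (category == "R&D" && !institution %in% c("CGIAR", "NARS"))
    stop_domain("R&D streams must come through the CGIAR or NARS channels")
  if (!is.matrix(values)) values <- matrix(values, ncol = length(regions))
  if (nrow(values) != length(years)) stop_domain("values must have one row per year")
  if (any(values < 0)) stop_domain("investment amounts must be non-negative")
  dimnames(values) <- list(years, regions)
  structure(list(years = as.integer(years), regions = regions, values = values,
                 institution = institution, category = category),
            class = "ag_stream")
}

#' @export
print.ag_stream <- function(x, ...) {
  cat(sprintf("Investment stream [%s/%s]: %d-%d, regions %s, mean %.3f bn/yr\n",
              x$institution, x$category, min(x$years), max(x$years),
              paste(x$regions, collapse = ","), mean(x$values)))
  invisible(x)
}

#' @export
as.data.frame.ag_stream <- function(x, ...) {
  data.frame(region = rep(x$regions, each = length(x$years)),
             institution = x$institution, category = x$category,
             year = rep(x$years, length(x$regions)),
             value = as.numeric(x$values), stringsAsFactors = FALSE)
}

# add two streams over the union of years (absent years = 0)
stream_add <- function(a, b) {
  yrs <- sort(union(a$years, b$years))
  stopifnot(identical(a$regions, b$regions))
  v <- matrix(0, length(yrs), length(a$regions), dimnames = list(yrs, a$regions))
  v[as.character(a$years), ] <- v[as.character(a$years), ] + a$values
  v[as.character(b$years), ] <- v[as.character(b$years), ] + b$values
  investment_stream(yrs, v, a$regions, a$institution, a$category)
}

stream_scale <- function(a, s) {
  investment_stream(a$years, a$values * s, a$regions, a$institution, a$category)
}

#' Accumulate an investment stream into a knowledge stock
#'
#' Perpetual-inventory recursion with gestation lags and spillovers:
#' \deqn{K_t = (1-\delta) K_{t-1} + \sum_l w_l I_{eff,t-l}}
#' where \eqn{I_{eff,r} = I_r + \sum_{r' \ne r} \sigma_{r' \to r} I_{r'}}.
#' Years before the stream's first year are padded with its first-year level
#' (a steady pre-period), and the default initial stock is the steady state
#' of that pre-period level, \eqn{I_{eff,1}/\delta}.
#'
#' @param stream an \code{ag_stream}.
#' @param params an \code{ag_pim_params}.
#' @param K0 initial stock per region (billion USD-equivalent); must be
#'   non-negative.  Default: pre-period steady state (0 when decay = 0).
#' @return an object of class \code{ag_stock} with the stock path \code{K}
#'   (years x regions) and the initial level.
#' @export
accumulate_stock <- function(stream, params, K0 = NULL) {
  v <- stream$values
  sig <- params$spillover_matrix
  ieff <- if (is.null(sig)) v else v %*% sig[stream$regions, stream$regions]
  w <- params$lag_weights
  L <- length(w)
  d <- params$decay
  if (is.null(K0)) K0 <- if (d > 0) ieff[1, ] / d else rep(0, ncol(ieff))
  K0 <- rep_len(K0, ncol(ieff))
  if (any(K0 < 0)) stop_domain("initial stock K0 must be non-negative")
  nT <- nrow(ieff)
  pad <- matrix(rep(ieff[1, ], each = L), L, ncol(ieff))
  ip <- rbind(pad, ieff)                       # row L + t is year t
  K <- matrix(0, nT, ncol(ieff), dimnames = dimnames(v))
  prev <- K0
  for (t in seq_len(nT)) {
    inflow <- colSums(w * ip[L + t - (seq_len(L) - 1L), , drop = FALSE])
    prev <- (1 - d) * prev + inflow
    K[t, ] <- prev
  }
  structure(list(years = stream$years, regions = stream$regions, K = K, K0 = K0),
            class = "ag_stock")
}

#' TFP multiplier path implied by a knowledge stock
#'
#' Annual TFP growth is \eqn{g_t = \eta (K_t/K_{t-1} - 1)}; the returned
#' path is the cumulative product of \eqn{1 + g_t} (first year relative to
#' the initial stock).
#'
#' @param stock an \code{ag_stock}.
#' @param params an \code{ag_pim_params} (supplies eta).
#' @return years x regions matrix of cumulative TFP multipliers.
#' @export
tfp_growth <- function(stock, params) {
  K <- stock$K
  Kprev <- rbind(stock$K0, K[-nrow(K), , drop = FALSE])
  if (any(K <= 0) || any(Kprev <= 0))
    stop_domain("zero knowledge stock with non-zero elasticity")
  g <- params$elasticity * (K / Kprev - 1)
  apply(1 + g, 2, cumprod) |> matrix(nrow(K), ncol(K), dimnames = dimnames(K))
}

#' Invert the investment-to-productivity mapping
#'
#' Finds the additional investment stream (a fixed temporal profile scaled
#' by a single factor, solved by bisection with geometric bracket expansion)
#' whose accumulated stock and TFP growth reach a target end-year TFP
#' multiplier on top of a baseline stream.
#'
#' @param target_tfp target cumulative TFP multiplier at \code{target_year}
#'   (total, i.e. including the baseline stream's own growth); must be at
#'   least the baseline's multiplier.
#' @param base_stream baseline \code{ag_stream} (may span several regions).
#' @param params \code{ag_pim_params}.
#' @param profile \code{ag_stream} giving the shape of the additional
#'   investment (zero outside the intervention window); scaled by the
#'   returned factor.
#' @param region region whose TFP multiplier is matched (default: first).
#' @param target_year year at which the target is matched (default: last).
#' @param tol relative tolerance on the matched multiplier (default 1e-6).
#' @return the scaled additional \code{ag_stream}, with attributes
#'   \code{scale} and \code{achieved}.
#' @export
required_investment <- function(target_tfp, base_stream, params, profile,
                                region = base_stream$regions[1],
                                target_year = max(base_stream$years),
                                tol = 1e-6) {
  iy <- match(target_year, base_stream$years)
  tfp_at <- function(scale) {
    total <- stream_add(base_stream, stream_scale(profile, scale))
    tfp_growth(accumulate_stock(total, params), params)[iy, region]
  }
  base_val <- tfp_at(0)
  if (target_tfp < base_val * (1 - tol))
    stop_domain("target TFP ", signif(target_tfp, 6), " is below the baseline ",
                signif(base_val, 6), ": additional investment cannot be negative")
  if (abs(target_tfp - base_val) <= tol * base_val)
    return(structure(stream_scale(profile, 0), scale = 0, achieved = base_val))
  hi <- 1
  while (tfp_at(hi) < target_tfp) {
    hi <- hi * 2
    if (hi > 2^20)
      stop_solver("no bracket for the required investment scale within 2^20x")
  }
  root <- stats::uniroot(function(s) tfp_at(s) - target_tfp, c(0, hi),
                         tol = tol * max(1, hi) * 1e-6)
  out <- stream_scale(profile, root$root)
  structure(out, scale = root$root, achieved = tfp_at(root$root))
}

# --- package-level R&D configuration -------------------------------------

# baseline CGIAR / NARS streams for the three investment regions
baseline_rnd_streams <- function(world) {
  rd <- world$rnd
  yrs <- world$years
  t <- yrs - world$base_year
  cg_g <- ifelse(yrs <= 2030, rd$cgiar_growth, rd$cgiar_growth_post2030)
  cg_mult <- cumprod(c(1, 1 + cg_g[-length(cg_g)]))
  cgiar <- outer(cg_mult, rd$cgiar_base_2010)
  nars <- outer((1 + rd$nars_growth)^t, rd$nars_base_2010)
  list(
    cgiar = investment_stream(yrs, cgiar, rd$regions, "CGIAR", "R&D"),
    nars = investment_stream(yrs, nars, rd$regions, "NARS", "R&D")
  )
}

# additional-investment profile: zero before the intervention start, then a
# geometric ramp, normalized to unit mean over the intervention window so
# the bisection scale is directly the average annual amount (bn USD/yr)
comp_rnd_profile <- function(world, region) {
  yrs <- world$years
  start <- world$comp$start_year
  g <- world$rnd$comp_profile_growth
  shape <- ifelse(yrs < start, 0, (1 + g)^(yrs - start))
  shape <- shape / mean(shape[yrs >= start & yrs <= 2030])
  v <- matrix(0, length(yrs), length(world$rnd$regions),
              dimnames = list(yrs, world$rnd$regions))
  v[, region] <- shape
  investment_stream(yrs, v, world$rnd$regions, "CGIAR", "R&D")
}

rnd_spillover_matrix <- function(world) {
  rg <- world$rnd$regions
  sig <- matrix(world$rnd$spillover, length(rg), length(rg),
                dimnames = list(rg, rg))
  diag(sig) <- 1
  sig
}

cgiar_params <- function(world) {
  p <- world$rnd$params_cgiar
  p$spillover_matrix <- rnd_spillover_matrix(world)
  p
}

# COMP end-year TFP uplift (multiplier vs the climate-change baseline) for a
# set of leaves, production-weighted
comp_uplift_targets <- function(world) {
  prod <- world$baselines$production
  upl_leaf <- function(r) {
    tot <- if (r %in% AFRICA_LEAVES) world$comp$africa_target[[r]] else NA_real_
    base <- wmean(world$intrinsic_2030[r, ], prod[r, ]) *
      wmean(world$shock_end_2030[r, ], prod[r, ])
    if (is.na(tot)) world$comp$odv_uplift else tot / base
  }
  leaves <- rownames(prod)
  u <- vapply(leaves, upl_leaf, numeric(1))
  u["DEV"] <- 1
  ssa <- region_leaves(world, "SSA")
  odv <- setdiff(region_leaves(world, "DVG"), region_leaves(world, "AFR"))
  agg <- c(
    SSA = wmean(u[ssa], rowSums(prod[ssa, , drop = FALSE])),
    NAWA = u[["NAF"]],
    ODV = wmean(u[odv], rowSums(prod[odv, , drop = FALSE]))
  )
  list(leaf = u, invest_region = agg)
}

# map investment regions to the model leaves they cover
invest_region_leaves <- function(world, ir) {
  switch(ir,
         SSA = region_leaves(world, "SSA"),
         NAWA = "NAF",
         ODV = setdiff(region_leaves(world, "DVG"), region_leaves(world, "AFR")),
         stop_config("unknown investment region: ", ir))
}

# Calibrate the per-region CGIAR stock elasticities so that additional
# streams at the published average annual levels reach the COMP productivity
# uplift targets (the inverse-costing calibration).  Stocks are computed
# once (they do not depend on eta); each region's elasticity then solves a
# one-dimensional root problem.
calibrate_rnd_elasticities <- function(world) {
  rd <- world$rnd
  base <- baseline_rnd_streams(world)$cgiar
  prm <- cgiar_params(world)
  add <- Reduce(stream_add, lapply(rd$regions, function(r)
    stream_scale(comp_rnd_profile(world, r), rd$table5_rnd[[r]])))
  st_base <- accumulate_stock(base, prm)
  st_tot <- accumulate_stock(stream_add(base, add), prm)
  iy <- match(min(2030, world$horizon), world$years)
  targets <- comp_uplift_targets(world)$invest_region
  eta <- vapply(rd$regions, function(r) {
    gb <- st_base$K[, r] / rbind(st_base$K0, st_base$K)[seq_along(world$years), r] - 1
    gt <- st_tot$K[, r] / rbind(st_tot$K0, st_tot$K)[seq_along(world$years), r] - 1
    f <- function(e) prod(1 + e * gt[1:iy]) / prod(1 + e * gb[1:iy]) - targets[[r]]
    stats::uniroot(f, c(1e-6, 200), tol = 1e-12)$root
  }, numeric(1))
  stats::setNames(eta, rd$regions)
}

# COMP R&D: invert each region's uplift target into an additional CGIAR
# stream (others held at their calibrated levels), and return the leaf-level
# TFP multiplier paths.
comp_rnd_package <- function(world) {
  rd <- world$rnd
  if (is.null(rd$eta_cgiar))
    stop_config("R&D elasticities not calibrated; build the world with calibrate_feedback = TRUE")
  base <- baseline_rnd_streams(world)$cgiar
  sig <- rnd_spillover_matrix(world)
  targets <- comp_uplift_targets(world)
  iy <- match(min(2030, world$horizon), world$years)
  adds <- list(); taus <- list()
  for (r in rd$regions) {
    others <- setdiff(rd$regions, r)
    base_r <- Reduce(stream_add, c(list(base), lapply(others, function(o)
      stream_scale(comp_rnd_profile(world, o), rd$table5_rnd[[o]]))))
    prm <- world$rnd$params_cgiar
    prm$elasticity <- rd$eta_cgiar[[r]]
    prm$spillover_matrix <- sig
    # target total multiplier: pure-baseline level x the region's uplift
    tgt <- tfp_growth(accumulate_stock(base, prm), prm)[iy, r] *
      targets$invest_region[[r]]
    adds[[r]] <- required_investment(tgt, base_r, prm, comp_rnd_profile(world, r),
                                     region = r, target_year = world$years[iy])
  }
  # region-level TFP uplift paths: all additional streams together (incl.
  # spillovers) relative to the pure baseline, under each region's elasticity
  total <- Reduce(stream_add, c(list(base), adds))
  for (r in rd$regions) {
    prm <- world$rnd$params_cgiar
    prm$elasticity <- rd$eta_cgiar[[r]]
    prm$spillover_matrix <- sig
    taus[[r]] <- tfp_growth(accumulate_stock(total, prm), prm)[, r] /
      tfp_growth(accumulate_stock(base, prm), prm)[, r]
  }
  leaves <- rownames(world$baselines$production)
  tau <- matrix(1, length(world$years), length(leaves),
                dimnames = list(world$years, leaves))
  for (r in rd$regions) {
    u_R <- targets$invest_region[[r]]
    for (lf in invest_region_leaves(world, r)) {
      u_leaf <- targets$leaf[[lf]]
      expo <- if (abs(log(u_R)) > 1e-12) log(u_leaf) / log(u_R) else 0
      tau[, lf] <- taus[[r]]^expo
    }
  }
  avg_add <- vapply(rd$regions, function(r) {
    sel <- world$years >= world$comp$start_year & world$years <= 2030
    mean(adds[[r]]$values[sel, r])
  }, numeric(1))
  list(tau = tau, additional = adds, avg_additional = avg_add)
}
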