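# Synthetic world construction.
#
# The generator produces a small multi-region, multi-commodity world whose
# 2010 base year is itself a market equilibrium and whose anchors match the
# published 2010 levels: Africa 2500 kcal/person/day (developing 2700,
# Eastern/Central Africa around 2100), 2010 hunger shares of 21 % for Africa
# (35 % Eastern, 41 % Central), no-climate-change productivity growth of
# +38 % in Africa and +32 % across developing countries by 2030, and 2030
# climate yield shocks of -7 % (Africa), -5 % (developing), -6 % (world).
# Calibration order: per-capita calorie anchors fix demand levels, supply is
# set equal to demand commodity by commodity, and supply-function intercepts
# are backed out, which guarantees base-year clearing by construction.

COMMODITY_GROUPS <- c("cereals", "roots_tubers", "meats", "pulses",
                      "oils", "sugar", "fruits_veg")
KCAL_PER_KG <- c(cereals = 3300, roots_tubers = 1000, meats = 2000,
                 pulses = 3400, oils = 8000, sugar = 3600, fruits_veg = 500)
BASE_PRICE <- c(cereals = 220, roots_tubers = 150, meats = 2500,
                pulses = 600, oils = 900, sugar = 350, fruits_veg = 550)
INCOME_ELAST <- c(cereals = 0.19, roots_tubers = 0.18, meats = 0.23,
                  pulses = 0.18, oils = 0.21, sugar = 0.19, fruits_veg = 0.22)
DIET_SHARES <- list(
  africa_low = c(cereals = 0.50, roots_tubers = 0.14, meats = 0.04,
                 pulses = 0.07, oils = 0.11, sugar = 0.06, fruits_veg = 0.08),
  africa_mid = c(cereals = 0.45, roots_tubers = 0.06, meats = 0.08,
                 pulses = 0.05, oils = 0.15, sugar = 0.10, fruits_veg = 0.11),
  odv        = c(cereals = 0.45, roots_tubers = 0.06, meats = 0.09,
                 pulses = 0.05, oils = 0.15, sugar = 0.09, fruits_veg = 0.11),
  dev        = c(cereals = 0.30, roots_tubers = 0.05, meats = 0.15,
                 pulses = 0.04, oils = 0.19, sugar = 0.12, fruits_veg = 0.15)
)
# 2010 per-capita calorie anchors (kcal/person/day) for the African leaves,
# rescaled at build time so the Africa aggregate is exactly 2500.
KCAL_ANCHOR_AFRICA <- c(NAF = 3050, WAF = 2581, EAF = 2140, CAF = 2060, SAF = 3050)
VA_SHARE <- c(NAF = 0.12, WAF = 0.28, EAF = 0.32, CAF = 0.30, SAF = 0.08,
              ODV = 0.10, DEV = 0.015)
AFRICA_LEAVES <- c("NAF", "WAF", "EAF", "CAF", "SAF")
# COMP per-region 2030 crop-productivity targets (multiplier on 2010), before
# rescaling the African set to a production-weighted 1.51
COMP_TARGET_AFRICA <- c(NAF = 1.47, WAF = 1.56, EAF = 1.50, CAF = 1.53, SAF = 1.47)

#' Generate a synthetic world configuration
#'
#' Builds a seeded world whose statistical structure matches the assumptions
#' of the foresight analysis: a region hierarchy (five African sub-regions,
#' other-developing, developed, with sub-Saharan/African/developing/world
#' aggregates), constant-elasticity supply and demand calibrated so 2010
#' clears every market, published 2010 calorie anchors, intrinsic
#' productivity paths hitting the no-climate-change 2030 anchors, climate
#' shock endpoints, marketing margins, a perpetual-inventory R&D
#' configuration and capital unit costs.  Identical seeds give bit-identical
#' worlds (compare \code{\link{world_to_json}} output).
#'
#' @param seed integer RNG seed.
#' @param n_subregions number of leaf model regions, at least 7: the five
#'   African sub-regions, at least one other-developing region and the
#'   developed aggregate.  Values above 7 subdivide the other-developing
#'   block.  Default 8.
#' @param n_commodities number of commodity markets, at least 4; 7 covers the
#'   full set of reporting groups (cereals, roots and tubers, meats, pulses,
#'   oils, sugar, fruits and vegetables); larger values subdivide groups.
#' @param horizon final projection year (default 2030).
#' @param calibrate_feedback logical; calibrate the income-feedback
#'   pass-through (and the R&D stock elasticities it depends on) at build
#'   time.  Default TRUE; FALSE skips the extra equilibrium runs.
#' @return an object of class \code{ag_world}.
#' @export
build_world <- function(seed = 1L, n_subregions = 8L, n_commodities = 7L,
                        horizon = 2030L, calibrate_feedback = TRUE) {
  if (n_subregions < 5)
    stop_config("n_subregions must be at least 5 (the five African sub-regions)")
  if (n_subregions < 7)
    stop_config("n_subregions = ", n_subregions, " cannot host the required ",
                "regions: five African sub-regions plus other-developing and ",
                "developed aggregates need at least 7")
  if (n_commodities < 4) stop_config("n_commodities must be at least 4")
  horizon <- as.integer(horizon)
  if (horizon < 2015 || horizon > 2050) stop_config("horizon must lie in 2015..2050")

  world <- with_seed(seed, {
    n_odv <- n_subregions - 6L
    odv_leaves <- if (n_odv == 1L) "ODV" else paste0("ODV_", seq_len(n_odv))
    leaves <- c(AFRICA_LEAVES, odv_leaves, "DEV")

    commodities <- make_commodities(n_commodities)
    cid <- commodities$commodity_id
    geography <- make_geography(odv_leaves)

    fixtures <- load_paper_fixtures()
    years <- 2010:horizon
    macro <- build_macro_trajectories(fixtures$table2, leaves, years)
    if (n_odv > 1L) {
      sh <- stats::runif(n_odv, 0.5, 1.5); sh <- sh / sum(sh)
      for (k in seq_len(n_odv)) {
        macro[[odv_leaves[k]]]$population <- macro[[odv_leaves[k]]]$population * sh[k]
        macro[[odv_leaves[k]]]$gdp <- macro[[odv_leaves[k]]]$gdp * sh[k]
        macro[[odv_leaves[k]]]$region_id <- odv_leaves[k]
      }
    }
    pop0 <- vapply(macro, function(m) m$population[1], numeric(1))

    # calorie anchors: Africa leaves rescaled so the aggregate is exactly
    # 2500; the other-developing anchor solves the developing 2700 anchor
    afr_anchor <- KCAL_ANCHOR_AFRICA *
      (2500 * sum(pop0[AFRICA_LEAVES]) / sum(pop0[AFRICA_LEAVES] * KCAL_ANCHOR_AFRICA))
    pop_afr <- sum(pop0[AFRICA_LEAVES])
    pop_odv <- sum(pop0[odv_leaves])
    odv_anchor <- (2700 * (pop_afr + pop_odv) -
                     sum(pop0[AFRICA_LEAVES] * afr_anchor)) / pop_odv
    if (!is.finite(odv_anchor) || odv_anchor < 800)
      stop_config("infeasible calorie anchor set: other-developing anchor ",
                  round(odv_anchor), " kcal/person/day is unreachable with ",
                  "positive quantities (region ODV)")
    kcal_anchor <- c(afr_anchor, stats::setNames(rep(odv_anchor, n_odv), odv_leaves),
                     DEV = 3400)

    # demand levels from the calorie anchors and regional diet shares
    tier <- c(NAF = "africa_mid", WAF = "africa_low", EAF = "africa_low",
              CAF = "africa_low", SAF = "africa_mid",
              stats::setNames(rep("odv", n_odv), odv_leaves), DEV = "dev")
    nr <- length(leaves); nc <- length(cid)
    cons <- matrix(0, nr, nc, dimnames = list(leaves, cid))
    for (r in leaves) {
      share_g <- DIET_SHARES[[tier[[r]]]][commodities$group]
      share <- share_g / ave(share_g, commodities$group, FUN = length)
      share <- share * stats::runif(nc, 0.9, 1.1)
      share <- share / sum(share)
      kcal_total <- kcal_anchor[[r]] * pop0[[r]] * 1e6 * 365       # kcal/yr
      cons[r, ] <- kcal_total * share / (commodities$kcal_per_kg * 1e9)  # Mt
    }
    # production: jittered around consumption, then rebalanced so every
    # world market clears in the base year
    prod <- cons * exp(stats::runif(nr * nc, -0.2, 0.2))
    prod <- sweep(prod, 2, colSums(cons) / colSums(prod), `*`)

    price0 <- commodities$base_price
    names(price0) <- cid
    margin <- matrix(stats::runif(nr * nc, 0.08, 0.14), nr, nc,
                     dimnames = list(leaves, cid))
    margin[AFRICA_LEAVES, ] <- stats::runif(5 * nc, 0.30, 0.42)
    margin[odv_leaves, ] <- stats::runif(n_odv * nc, 0.15, 0.25)

    eps_s <- matrix(stats::runif(nr * nc, 0.22, 0.28), nr, nc,
                    dimnames = list(leaves, cid))
    eps_d <- matrix(-stats::runif(nr * nc, 0.27, 0.33), nr, nc,
                    dimnames = list(leaves, cid))
    eps_y <- matrix(rep(INCOME_ELAST[commodities$group], each = nr) +
                      stats::runif(nr * nc, -0.01, 0.01), nr, nc,
                    dimnames = list(leaves, cid))

    # intrinsic (no-climate-change) productivity multipliers at 2030:
    # each African leaf production-weighted to 1.38; other-developing solved
    # so the developing aggregate is 1.32; developed fixed at 1.12
    intrinsic <- matrix(1, nr, nc, dimnames = list(leaves, cid))
    disp <- matrix(1 + stats::runif(nr * nc, -0.015, 0.015), nr, nc)
    p_afr <- sum(prod[AFRICA_LEAVES, ]); p_odv <- sum(prod[odv_leaves, ])
    p_dev <- sum(prod["DEV", ]); p_dvg <- p_afr + p_odv
    m_odv <- (1.32 * p_dvg - 1.38 * p_afr) / p_odv
    target_m <- c(stats::setNames(rep(1.38, 5), AFRICA_LEAVES),
                  stats::setNames(rep(m_odv, n_odv), odv_leaves), DEV = 1.12)
    for (r in leaves)
      intrinsic[r, ] <- renorm_to_target(disp[leaves == r, ], prod[r, ], target_m[[r]])

    # climate-change 2030 shock endpoints: Africa 0.93; other-developing from
    # the developing average 0.95; developed from the world average 0.94
    s_odv <- (0.95 * p_dvg - 0.93 * p_afr) / p_odv
    s_dev <- (0.94 * (p_dvg + p_dev) - 0.95 * p_dvg) / p_dev
    end_r <- c(stats::setNames(rep(0.93, 5), AFRICA_LEAVES),
               stats::setNames(rep(s_odv, n_odv), odv_leaves), DEV = s_dev)
    if (any(end_r <= 0.5 | end_r > 1.1))
      stop_config("derived climate shock endpoint outside (0.5, 1.1]: ",
                  paste(sprintf("%s=%.3f", names(end_r), end_r), collapse = ", "))
    shock_end <- matrix(0, nr, nc, dimnames = list(leaves, cid))
    sdisp <- matrix(stats::runif(nr * nc, -0.03, 0.03), nr, nc)
    for (r in leaves) {
      i <- which(leaves == r)
      dev_c <- sdisp[i, ] - wmean(sdisp[i, ], prod[r, ])
      shock_end[r, ] <- pmin(end_r[[r]] + dev_c, 1.1)
    }

    va <- VA_SHARE[c(AFRICA_LEAVES, rep("ODV", n_odv), "DEV")] *
      stats::runif(nr, 0.95, 1.05)
    names(va) <- leaves

    hunger <- make_hunger_curve(afr_anchor, pop0[AFRICA_LEAVES])

    comp_afr <- COMP_TARGET_AFRICA *
      (1.51 * sum(prod[AFRICA_LEAVES, ]) /
         sum(rowSums(prod[AFRICA_LEAVES, ]) * COMP_TARGET_AFRICA))
    comp <- list(
      africa_target = comp_afr,        # 2030 productivity multiplier vs 2010
      odv_uplift = 1.15,               # 2030 R&D TFP multiplier vs CC baseline
      margin_reduction = 0.15,         # fraction of the wedge removed by 2030
      start_year = 2015L
    )

    list(
      seed = as.integer(seed), base_year = 2010L, horizon = horizon,
      years = years,
      geography = geography, commodities = commodities,
      macro = macro,
      baselines = list(production = prod, consumption = cons,
                       price = price0, margin = margin),
      elasticities = list(supply_price = eps_s, demand_price = eps_d,
                          demand_income = eps_y, demand_cross = NULL),
      intrinsic_2030 = intrinsic,
      shock_end_2030 = shock_end,
      kcal_anchor = kcal_anchor,
      food_va_share = va,
      hunger_curve = hunger,
      rnd = rnd_defaults(),
      unit_costs = fixtures$capital_costing,
      comp = comp,
      feedback = list(kappa = NULL, tol = 1e-8, max_iter = 50L)
    )
  })
  world <- structure(world, class = "ag_world")
  if (calibrate_feedback) {
    world$rnd$eta_cgiar <- calibrate_rnd_elasticities(world)
    world$feedback$kappa <- calibrate_kappa(world)
  }
  world
}

make_commodities <- function(n_commodities) {
  k <- ceiling(n_commodities / length(COMMODITY_GROUPS))
  grp <- rep(COMMODITY_GROUPS, k)[seq_len(n_commodities)]
  id <- if (n_commodities <= length(COMMODITY_GROUPS)) grp else
    paste0(grp, "_", stats::ave(seq_along(grp), grp, FUN = seq_along))
  data.frame(commodity_id = id, group = grp,
             kcal_per_kg = unname(KCAL_PER_KG[grp]),
             base_price = unname(BASE_PRICE[grp]),
             stringsAsFactors = FALSE)
}

make_geography <- function(odv_leaves) {
  leaf <- function(id, nm, parent) data.frame(
    region_id = id, name = nm, parent = parent, is_leaf = TRUE,
    stringsAsFactors = FALSE)
  agg <- function(id, nm, parent) data.frame(
    region_id = id, name = nm, parent = parent, is_leaf = FALSE,
    stringsAsFactors = FALSE)
  odv_parent <- if (length(odv_leaves) > 1L) "ODV" else "DVG"
  rows <- rbind(
    leaf("NAF", "Northern Africa", "AFR"),
    leaf("WAF", "Western Africa", "SSA"),
    leaf("EAF", "Eastern Africa", "SSA"),
    leaf("CAF", "Central Africa", "SSA"),
    leaf("SAF", "Southern Africa", "SSA"),
    do.call(rbind, lapply(seq_along(odv_leaves), function(k)
      leaf(odv_leaves[k], paste("Other developing", k), odv_parent))),
    leaf("DEV", "Developed countries", "WLD"),
    agg("SSA", "Africa South of the Sahara", "AFR"),
    agg("AFR", "Africa", "DVG"),
    if (length(odv_leaves) > 1L) agg("ODV", "Other developing countries", "DVG"),
    agg("DVG", "Developing countries", "WLD"),
    agg("WLD", "World", NA_character_)
  )
  rownames(rows) <- NULL
  rows
}

# region codes of the leaves under an aggregate (identity for a leaf)
region_leaves <- function(world, region) {
  g <- world$geography
  if (region %in% g$region_id[g$is_leaf]) return(region)
  kids <- g$region_id[!is.na(g$parent) & g$parent == region]
  if (!length(kids)) stop_domain("unknown region: ", region)
  unlist(lapply(kids, region_leaves, world = world))
}

# Hunger-prevalence curve: piecewise log-linear in the ratio of per-capita
# calorie availability to the 2400 kcal/day reference requirement.  Interior
# anchors are placed at the realized 2010 African calorie levels so the
# printed 2010 shares (Central 41 %, Eastern 35 %, Africa aggregate 21 %)
# are reproduced exactly; the Northern/Southern 2010 share is fixed at 3 %
# and the Western share solves the Africa aggregate.
make_hunger_curve <- function(afr_anchor, pop_afr, requirement = 2400,
                              floor_share = 0.02) {
  h_ns <- 0.03
  w <- (0.21 * sum(pop_afr) - 0.35 * pop_afr[["EAF"]] - 0.41 * pop_afr[["CAF"]] -
          h_ns * (pop_afr[["NAF"]] + pop_afr[["SAF"]])) / pop_afr[["WAF"]]
  anchors <- data.frame(
    ratio = c(0.55, 0.70, afr_anchor[["CAF"]] / requirement,
              afr_anchor[["EAF"]] / requirement,
              afr_anchor[["WAF"]] / requirement,
              afr_anchor[["NAF"]] / requirement, 1.42),
    share = c(0.85, 0.62, 0.41, 0.35, w, h_ns, 0.022)
  )
  list(anchors = anchors, floor = floor_share, requirement = requirement)
}

# Perpetual-inventory configuration.  Research-type defaults: the
# international-centre (CGIAR) channel behaves like longer-gestation basic
# research (10-year trapezoidal lag peaking at year 5, elasticity 0.25), the
# national-systems channel like applied/developmental research (6-year lag
# peaking at year 3, elasticity 0.15); knowledge decays at 10 %/yr; a 0.2
# spillover runs from international-centre investment to every developing
# region.  Baseline streams reproduce the published average annual levels:
# CGIAR grows at 6.3 %/yr to 2030 (4.1 %/yr beyond), national systems at the
# rate implied by the printed 50 % increase over 2010-2030.
rnd_defaults <- function() {
  avg_factor <- function(g, years = 21L) sum((1 + g)^(0:(years - 1))) / years
  cg_g <- 0.063; na_g <- 1.5^(1 / 20) - 1
  cg_avg <- c(SSA = 0.68, NAWA = 0.06, ODV = 0.41)
  na_avg <- c(SSA = 0.85, NAWA = 1.12, ODV = 3.38)
  list(
    regions = c("SSA", "NAWA", "ODV"),
    cgiar_base_2010 = cg_avg / avg_factor(cg_g),
    cgiar_growth = cg_g, cgiar_growth_post2030 = 0.041,
    nars_base_2010 = na_avg / avg_factor(na_g),
    nars_growth = na_g,
    params_cgiar = pim_params("basic", decay = 0.10, lag_years = 10L,
                              peak = 5L, elasticity = 0.25),
    params_nars = pim_params("applied", decay = 0.10, lag_years = 6L,
                             peak = 3L, elasticity = 0.15),
    spillover = 0.2,
    comp_profile_growth = 0.10,   # geometric ramp of the additional stream
    table5_rnd = c(SSA = 0.67, NAWA = 0.01, ODV = 0.07),
    eta_cgiar = NULL              # per-region calibrated elasticities
  )
}

#' Validate a world configuration
#'
#' Checks every structural invariant of the configuration: positive
#' quantities and prices, margins in [0, 0.9), elasticity sign and range
#' restrictions, base-year market clearing, the calorie anchors (within 5 %),
#' an acyclic region hierarchy with leaves reaching a single top aggregate,
#' food value-added shares in (0, 0.8), positive energy densities and a
#' monotone hunger curve.  Validation reports; it never raises.
#'
#' @param world an \code{ag_world}.
#' @return data frame of violations (zero rows if the world is valid), of
#'   class \code{ag_validation}.
#' @export
validate_world <- function(world) {
  v <- list()
  note <- function(component, where, message)
    data.frame(component = component, where = where, message = message,
               stringsAsFactors = FALSE)
  bl <- world$baselines
  bad_cell <- function(mat, test, comp, msg) {
    idx <- which(test(mat), arr.ind = TRUE)
    if (!nrow(idx)) return(NULL)
    do.call(rbind, lapply(seq_len(nrow(idx)), function(k)
      note(comp, paste0(rownames(mat)[idx[k, 1]], "/", colnames(mat)[idx[k, 2]]), msg)))
  }
  v$p1 <- bad_cell(bl$production, function(m) !(m > 0), "baselines", "non-positive production")
  v$p2 <- bad_cell(bl$consumption, function(m) !(m > 0), "baselines", "non-positive consumption")
  if (any(!(bl$price > 0)))
    v$p3 <- note("baselines", paste(names(bl$price)[!(bl$price > 0)], collapse = ","),
                 "non-positive price")
  v$p4 <- bad_cell(bl$margin, function(m) m < 0 | m >= 0.9, "baselines",
                   "margin outside [0, 0.9)")
  el <- world$elasticities
  v$e1 <- bad_cell(el$supply_price, function(m) m < 0, "elasticities", "negative supply elasticity")
  v$e2 <- bad_cell(el$demand_price, function(m) !(m < 0) | abs(m) > 2, "elasticities",
                   "demand price elasticity not in [-2, 0)")
  v$e3 <- bad_cell(el$demand_income, function(m) m < -0.5 | m > 1.5, "elasticities",
                   "income elasticity outside [-0.5, 1.5]")
  # base-year clearing
  rel <- abs(colSums(bl$production) - colSums(bl$consumption)) / colSums(bl$production)
  if (any(rel >= 1e-10))
    v$c1 <- note("clearing", paste(names(rel)[rel >= 1e-10], collapse = ","),
                 "base year does not clear")
  # calorie anchors within 5 %
  k2010 <- kcal_by_region(world, bl$consumption)
  for (r in names(world$kcal_anchor)) {
    if (abs(k2010[[r]] / world$kcal_anchor[[r]] - 1) > 0.05)
      v[[paste0("k", r)]] <- note("kcal", r, "2010 calorie level misses anchor by >5 %")
  }
  # geography is a forest whose leaves reach a single top aggregate
  g <- world$geography
  tops <- g$region_id[is.na(g$parent)]
  for (lf in g$region_id[g$is_leaf]) {
    seen <- character(); cur <- lf; ok <- TRUE
    while (!is.na(cur)) {
      if (cur %in% seen) { ok <- FALSE; break }
      seen <- c(seen, cur)
      cur <- g$parent[match(cur, g$region_id)]
    }
    if (!ok || !(seen[length(seen)] %in% tops))
      v[[paste0("g", lf)]] <- note("geography", lf, "leaf has no unique path to a top aggregate")
  }
  va <- world$food_va_share
  if (any(va <= 0 | va >= 0.8))
    v$va <- note("food_va_share", paste(names(va)[va <= 0 | va >= 0.8], collapse = ","),
                 "food value-added share outside (0, 0.8)")
  if (any(!(world$commodities$kcal_per_kg > 0)))
    v$kk <- note("commodities", "kcal_per_kg", "non-positive energy density")
  hs <- world$hunger_curve$anchors
  if (any(diff(hs$ratio) <= 0) || any(diff(hs$share) >= 0))
    v$hc <- note("hunger_curve", "anchors", "anchors not strictly monotone")
  out <- do.call(rbind, Filter(Negate(is.null), v))
  if (is.null(out)) out <- note("", "", "")[0, ]
  rownames(out) <- NULL
  structure(out, class = c("ag_validation", "data.frame"))
}

#' @export
print.ag_validation <- function(x, ...) {
  if (!nrow(x)) cat("world configuration valid: no violations\n")
  else {
    cat(nrow(x), "invariant violation(s):\n")
    print.data.frame(x, ...)
  }
  invisible(x)
}

# per-region kcal/person/day implied by a consumption matrix (2010 population)
kcal_by_region <- function(world, cons) {
  pop0 <- vapply(world$macro, function(m) m$population[1], numeric(1))
  leaves <- rownames(cons)
  k <- (cons %*% world$commodities$kcal_per_kg) * 1e9 / (pop0[leaves] * 1e6 * 365)
  stats::setNames(as.numeric(k), leaves)
}

#' Serialize a world configuration to JSON
#'
#' Full-precision canonical serialization; two worlds built from the same
#' seed produce byte-identical strings.
#'
#' @param world an \code{ag_world}.
#' @param path optional file to write to.
#' @return the JSON string, invisibly when written to a file.
#' @export
world_to_json <- function(world, path = NULL) {
  strip <- function(x) {
    if (is.data.frame(x)) return(x)
    if (is.list(x)) return(lapply(unclass(x), strip))
    if (is.atomic(x) && !is.matrix(x) && !is.null(names(x))) return(as.list(x))
    x
  }
  js <- jsonlite::toJSON(strip(world), digits = NA, auto_unbox = TRUE,
                         dataframe = "columns", null = "null", na = "null")
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' Restore a world configuration from JSON
#' @param json a JSON string or path to a file written by
#'   \code{\link{world_to_json}}.
#' @return an \code{ag_world}.
#' @export
world_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyMatrix = TRUE)
  for (nm in c("geography", "commodities", "unit_costs"))
    x[[nm]] <- as.data.frame(x[[nm]], stringsAsFactors = FALSE)
  x$hunger_curve$anchors <- as.data.frame(x$hunger_curve$anchors)
  leaves <- x$geography$region_id[x$geography$is_leaf]
  cid <- x$commodities$commodity_id
  fixm <- function(m) { m <- as.matrix(m); dimnames(m) <- list(leaves, cid); m }
  x$baselines$production <- fixm(x$baselines$production)
  x$baselines$consumption <- fixm(x$baselines$consumption)
  x$baselines$margin <- fixm(x$baselines$margin)
  x$baselines$price <- stats::setNames(as.numeric(x$baselines$price), cid)
  for (nm in c("supply_price", "demand_price", "demand_income"))
    x$elasticities[[nm]] <- fixm(x$elasticities[[nm]])
  x$intrinsic_2030 <- fixm(x$intrinsic_2030)
  x$shock_end_2030 <- fixm(x$shock_end_2030)
  x$kcal_anchor <- unlist(x$kcal_anchor)
  x$food_va_share <- unlist(x$food_va_share)
  x$macro <- lapply(x$macro, function(m) structure(as.data.frame(m),
                                                   class = c("ag_macro", "data.frame")))
  for (nm in c("cgiar_base_2010", "nars_base_2010", "table5_rnd", "eta_cgiar"))
    if (!is.null(x$rnd[[nm]])) x$rnd[[nm]] <- unlist(x$rnd[[nm]])
  for (p in c("params_cgiar", "params_nars"))
    x$rnd[[p]] <- do.call(pim_params_raw, x$rnd[[p]])
  x$comp$africa_target <- unlist(x$comp$africa_target)
  x$years <- as.integer(x$years)
  structure(x, class = "ag_world")
}

#' @export
print.ag_world <- function(x, ...) {
  leaves <- x$geography$region_id[x$geography$is_leaf]
  cat("Synthetic world configuration (seed ", x$seed, ")\n", sep = "")
  cat("  regions:     ", length(leaves), " leaves (",
      paste(leaves, collapse = ", "), ")\n", sep = "")
  cat("  commodities: ", nrow(x$commodities), " (",
      paste(x$commodities$commodity_id, collapse = ", "), ")\n", sep = "")
  cat("  years:       ", x$base_year, "-", x$horizon, "\n", sep = "")
  k <- kcal_by_region(x, x$baselines$consumption)
  pop0 <- vapply(x$macro, function(m) m$population[1], numeric(1))
  afr <- region_leaves(x, "AFR")
  cat(sprintf("  2010 kcal/person/day: Africa %.0f, developing %.0f\n",
              sum(k[afr] * pop0[afr]) / sum(pop0[afr]),
              {dv <- region_leaves(x, "DVG"); sum(k[dv] * pop0[dv]) / sum(pop0[dv])}))
  cat(sprintf("  feedback pass-through kappa: %s\n",
              if (is.null(x$feedback$kappa)) "uncalibrated" else
                format(x$feedback$kappa, digits = 4)))
  invisible(x)
}

#' @export
summary.ag_world <- function(object, ...) {
  print(object)
  cat("\nValidation:\n")
  print(validate_world(object))
  invisible(object)
}
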