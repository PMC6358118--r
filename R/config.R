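# Hierarchical run configuration.
#
# A small YAML file selects the world resolution, climate, solver and
# feedback settings, e.g.:
#
#   world: {seed: 1, n_subregions: 8, n_commodities: 7, horizon: 2030}
#   climate: CC
#   feedback: {kappa: null, tol: 1.0e-8, max_iter: 50}
#   pim: {decay: 0.10, eta_cgiar: 0.25, eta_nars: 0.15, spillover: 0.2}

#' Read a run configuration file
#' @param path YAML configuration file.
#' @return nested list of settings.
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop_config("reading configuration files requires the 'yaml' package")
  if (!file.exists(path)) stop_config("configuration file not found: ", path)
  yaml::read_yaml(path)
}

#' Build a world from a configuration list
#' @param config list from \code{\link{read_config}} (or constructed).
#' @return an \code{ag_world} with any pim/feedback overrides applied.
#' @export
world_from_config <- function(config) {
  wc <- config$world %||% list()
  world <- build_world(seed = wc$seed %||% 1L,
                       n_subregions = wc$n_subregions %||% 8L,
                       n_commodities = wc$n_commodities %||% 7L,
                       horizon = wc$horizon %||% 2030L,
                       calibrate_feedback = FALSE)
  pm <- config$pim
  if (!is.null(pm)) {
    if (!is.null(pm$decay)) {
      world$rnd$params_cgiar$decay <- pm$decay
      world$rnd$params_nars$decay <- pm$decay
    }
    if (!is.null(pm$spillover)) world$rnd$spillover <- pm$spillover
  }
  fb <- config$feedback
  if (!is.null(fb)) {
    if (!is.null(fb$tol)) world$feedback$tol <- fb$tol
    if (!is.null(fb$max_iter)) world$feedback$max_iter <- as.integer(fb$max_iter)
  }
  world$rnd$eta_cgiar <- calibrate_rnd_elasticities(world)
  world$feedback$kappa <- fb$kappa %||% calibrate_kappa(world)
  world
}
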