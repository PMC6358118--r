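# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code with a locally-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("ag_config_error", "error")))
}

stop_domain <- function(...) {
  stop(errorCondition(paste0(...), class = c("ag_domain_error", "error")))
}

stop_solver <- function(...) {
  stop(errorCondition(paste0(...), class = c("ag_solver_error", "error")))
}

# production-weighted mean over a region x commodity block
wmean <- function(x, w) sum(x * w) / sum(w)

# scale multiplicative deviations so the weighted mean hits `target` exactly:
# returns target * dev / wmean(dev, w)
renorm_to_target <- function(dev, w, target) {
  target * dev / wmean(dev, w)
}
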