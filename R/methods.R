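# S3 methods for result bundles.

#' @export
print.ag_run <- function(x, ...) {
  nm <- x$scenario$name
  yr <- min(2030, max(x$years))
  h <- x$hunger[x$hunger$region_id == "AFR" & x$hunger$year == yr, ]
  cat("Scenario run:", nm, sprintf("(world seed %d, %d-%d)\n",
                                   x$world_seed, min(x$years), max(x$years)))
  cat(sprintf("  feedback iterations: %d\n", x$iterations))
  cat(sprintf("  Africa %d: %.0f kcal/person/day, %.1f%% at risk (%.0f million)\n",
              yr, h$kcal_pc, 100 * h$share_at_risk, h$millions_at_risk))
  cat(sprintf("  food price index %d (2010 = 1): %.2f-%.2f across groups\n",
              yr, min(x$price_index_2030), max(x$price_index_2030)))
  cat(sprintf("  worst clearing residual: %.2e\n", max(abs(x$solution$residual))))
  invisible(x)
}

#' @export
summary.ag_run <- function(object, ...) {
  print(object)
  yr <- min(2030, max(object$years))
  cat("\nHunger indicators,", yr, "\n")
  print(object$hunger[object$hunger$year == yr,
                      c("region_id", "kcal_pc", "share_at_risk", "millions_at_risk")],
        row.names = FALSE, digits = 3)
  cat("\nPrice indices by commodity group (2010 = 1):\n")
  print(round(object$price_index_2030, 3))
  invisible(object)
}

#' Market-clearing residuals of a solved run
#' @param object an \code{ag_run}.
#' @param ... unused.
#' @return years x commodities matrix of relative clearing residuals.
#' @export
residuals.ag_run <- function(object, ...) object$solution$residual

#' Plot a scenario run
#'
#' Two base-graphics panels: commodity-group price indices at the horizon
#' and the hunger-share trajectories of the African regions.
#'
#' @param x an \code{ag_run}.
#' @param ... passed to \code{barplot}.
#' @export
plot.ag_run <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(7, 4, 3, 1))
  on.exit(graphics::par(op))
  graphics::barplot(x$price_index_2030, las = 2,
                    ylab = "price index (2010 = 1)",
                    main = paste(x$scenario$name, "prices"), ...)
  graphics::abline(h = 1, lty = 2)
  hr <- x$hunger[x$hunger$region_id %in% c("NAF", "WAF", "EAF", "CAF", "SAF"), ]
  rg <- unique(hr$region_id)
  graphics::matplot(unique(hr$year),
                    100 * sapply(rg, function(r) hr$share_at_risk[hr$region_id == r]),
                    type = "l", lty = 1, lwd = 2, xlab = "year",
                    ylab = "share at risk of hunger (%)",
                    main = paste(x$scenario$name, "hunger"))
  graphics::abline(h = 5, lty = 3)
  graphics::legend("topright", legend = rg, col = seq_along(rg), lty = 1,
                   lwd = 2, cex = 0.8, bty = "n")
  invisible(x)
}

#' Export a solved run as long-format tables
#' @param x an \code{ag_run}.
#' @param dir directory to write CSV files to (created if needed).
#' @return invisibly, the list of written file paths.
#' @export
export_run <- function(x, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  yrs <- x$years
  sup <- x$solution$supply
  long <- do.call(rbind, lapply(seq_along(yrs), function(i) {
    g <- expand.grid(region = dimnames(sup)[[2]], commodity = dimnames(sup)[[3]],
                     stringsAsFactors = FALSE)
    g$year <- yrs[i]
    g$price <- x$solution$price[i, g$commodity]
    g$supply <- sup[i, , ][cbind(g$region, g$commodity)]
    g$demand <- x$solution$demand[i, , ][cbind(g$region, g$commodity)]
    g$net_trade <- g$supply - g$demand
    g
  }))
  files <- c(
    solution = file.path(dir, paste0(x$scenario$name, "_solution.csv")),
    hunger = file.path(dir, paste0(x$scenario$name, "_hunger.csv")),
    incomes = file.path(dir, paste0(x$scenario$name, "_incomes.csv"))
  )
  utils::write.csv(long, files["solution"], row.names = FALSE)
  utils::write.csv(x$hunger, files["hunger"], row.names = FALSE)
  utils::write.csv(x$incomes, files["incomes"], row.names = FALSE)
  invisible(files)
}
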