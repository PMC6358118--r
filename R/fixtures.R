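#' Load the printed reference tables shipped with the package
#'
#' Reads the hand-encoded CSV versions of the published investment, macro,
#' resource-target and cost tables.  Empty cells encoded as \code{"-"} (used
#' where the source prints an en-dash, e.g. developed-country development
#' flows) load as \code{NA}, never as zero, and are skipped when sums are
#' recomputed.
#'
#' @param path directory containing the fixture CSV files; defaults to the
#'   copies installed with the package.
#' @return an object of class \code{ag_fixtures}: a named list of data frames
#'   (\code{table1}, \code{table2}, \code{table3}, \code{table4},
#'   \code{table5}, \code{capital_costing}).
#' @export
load_paper_fixtures <- function(path = system.file("extdata", package = "agforesight")) {
  if (!nzchar(path) || !dir.exists(path)) {
    stop_config("fixture directory not found: ", path)
  }
  files <- c(
    table1 = "table1_current_investment.csv",
    table2 = "table2_ssp2_macro.csv",
    table3 = "table3_resource_targets.csv",
    table4 = "table4_baseline_costs.csv",
    table5 = "table5_comp_costs.csv",
    capital_costing = "capital_costing_synthetic.csv"
  )
  fx <- lapply(names(files), function(nm) {
    f <- file.path(path, files[[nm]])
    if (!file.exists(f)) stop_config("missing fixture file: ", f)
    read_fixture_csv(f)
  })
  names(fx) <- names(files)
  structure(fx, class = "ag_fixtures")
}

# CSV reader with the missing-cell convention and row-numbered parse errors.
read_fixture_csv <- function(file) {
  tab <- utils::read.csv(file, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character", strip.white = TRUE)
  if (ncol(tab) < 2) stop_config("malformed fixture ", basename(file), ": fewer than 2 columns")
  for (j in seq_len(ncol(tab))[-1]) {
    col <- tab[[j]]
    col[col %in% c("-", "–", "")] <- NA_character_
    num <- suppressWarnings(as.numeric(col))
    bad <- which(!is.na(col) & is.na(num))
    if (!length(bad)) {                      # clean numeric column
      tab[[j]] <- num
    } else if (any(!is.na(num))) {           # numeric column with bad cells
      stop_config("malformed fixture ", basename(file), ": cannot parse '",
                  col[bad[1]], "' in column '", names(tab)[j],
                  "', data row ", bad[1])
    } else {
      tab[[j]] <- col                        # label column, keep as text
    }
  }
  tab
}

#' @export
print.ag_fixtures <- function(x, ...) {
  cat("Reference-table fixtures:\n")
  for (nm in names(x)) {
    cat(sprintf("  %-16s %3d rows x %d cols\n", nm, nrow(x[[nm]]), ncol(x[[nm]])))
  }
  invisible(x)
}

# Accounting relations between printed marginal totals and their components.
# Each relation: the total row/column must equal the sum of component rows
# within half a unit of the table's printed precision (integers for the
# current-investment table, 1 dp with 2-dp cells for the cost tables, so the
# tolerances are 1.5 and 0.055).  Relations are restricted to sums the
# printed tables actually support.
fixture_relations <- function() {
  t1cols <- c("private_2010_2012", "government_2010_2012", "dev_flows_2013_2014",
              "oda_climate_2013_2014", "climate_funds_2013_2014")
  rel <- list()
  add <- function(rel, table, total_row, part_rows, cols, tol) {
    for (cl in cols) {
      rel[[length(rel) + 1L]] <- list(table = table, total_row = total_row,
                                      part_rows = part_rows, col = cl, tol = tol)
    }
    rel
  }
  rel <- add(rel, "table1", "Africa", c("Northern Africa", "South of the Sahara"), t1cols, 1.5)
  rel <- add(rel, "table1", "South of the Sahara",
             c("Eastern Africa", "Central Africa", "Southern Africa", "Western Africa"),
             t1cols[1:2], 1.5)
  rel <- add(rel, "table1", "Developing Countries", c("Africa", "Other developing"), t1cols, 1.5)
  rel <- add(rel, "table1", "World", c("Developing Countries", "Developed Countries"), t1cols, 1.5)

  t4cols <- c("cgiar", "nars", "irrigated_area", "water_use", "soil_mgmt", "infrastructure")
  rel <- add(rel, "table4", "Africa and West Asia",
             c("Africa South of the Sahara", "North Africa and West Asia"),
             c(t4cols, "total"), 0.055)
  rel <- add(rel, "table4", "All Developing Countries",
             c("Africa and West Asia", "Other Developing Countries"),
             c(t4cols, "total"), 0.055)
  rel <- add(rel, "table4", "World",
             c("All Developing Countries", "Developed Countries"),
             c(t4cols, "total"), 0.055)

  t5cols <- c("rnd", "irrigation_expansion", "water_use_efficiency",
              "soil_water_mgmt", "infrastructure")
  rel <- add(rel, "table5", "Africa and West Asia",
             c("Africa South of the Sahara", "North Africa and West Asia"),
             c(t5cols, "total"), 0.055)
  rel <- add(rel, "table5", "All Developing Countries",
             c("Africa and West Asia", "Other Developing Countries"),
             c(t5cols, "total"), 0.055)

  # within-row totals of the cost tables (components sum to printed total)
  for (rg in c("Africa South of the Sahara", "North Africa and West Asia",
               "Africa and West Asia", "Other Developing Countries",
               "All Developing Countries", "Developed Countries", "World")) {
    rel[[length(rel) + 1L]] <- list(table = "table4", total_row = rg,
                                    part_rows = NULL, col = t4cols, tol = 0.055,
                                    row_total_col = "total")
  }
  for (rg in c("Africa South of the Sahara", "North Africa and West Asia",
               "Africa and West Asia", "Other Developing Countries",
               "All Developing Countries")) {
    rel[[length(rel) + 1L]] <- list(table = "table5", total_row = rg,
                                    part_rows = NULL, col = t5cols, tol = 0.055,
                                    row_total_col = "total")
  }
  rel
}

#' Check the accounting identities of the printed tables
#'
#' Recomputes every supported marginal total of the encoded reference tables
#' from its components and compares against the printed value at the table's
#' printed rounding.  Missing cells are skipped, not treated as zero.
#'
#' @param fixtures an \code{ag_fixtures} object from
#'   \code{\link{load_paper_fixtures}}.
#' @return data frame with one row per checked relation: table, description,
#'   computed sum, printed value, tolerance and a logical \code{pass}.
#' @export
check_fixture_tables <- function(fixtures = load_paper_fixtures()) {
  rels <- fixture_relations()
  out <- lapply(rels, function(r) {
    tab <- fixtures[[r$table]]
    rn <- tab[[1]]
    if (!is.null(r$part_rows)) {            # column relation: sum of rows
      printed <- tab[match(r$total_row, rn), r$col]
      parts <- tab[match(r$part_rows, rn), r$col]
      comp <- if (all(is.na(parts))) NA_real_ else sum(parts, na.rm = TRUE)
      desc <- paste0(r$col, ": ", r$total_row, " = ", paste(r$part_rows, collapse = " + "))
    } else {                                 # row relation: components sum to total col
      printed <- tab[match(r$total_row, rn), r$row_total_col]
      comp <- sum(unlist(tab[match(r$total_row, rn), r$col]), na.rm = TRUE)
      desc <- paste0(r$total_row, ": row components = printed total")
    }
    printed <- as.numeric(printed)
    pass <- if (is.na(printed) && is.na(comp)) TRUE
            else if (is.na(printed) || is.na(comp)) FALSE
            else abs(comp - printed) <= r$tol
    data.frame(table = r$table, relation = desc, computed = comp,
               printed = printed, tol = r$tol, pass = pass,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
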