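#' @importFrom rlang .data
NULL

# schema-violation conditions carry the offending table/row/column
stop_schema <- function(msg, table = NULL, row = NULL, column = NULL) {
  loc <- c(
    if (!is.null(table)) sprintf("table '%s'", table),
    if (!is.null(row)) sprintf("row %s", row),
    if (!is.null(column)) sprintf("column '%s'", column)
  )
  if (length(loc)) msg <- sprintf("%s (%s)", msg, paste(loc, collapse = ", "))
  rlang::abort(msg, class = "nutriflow_schema_error")
}

# Input/output table schemas. `units` marks columns converted to canonical
# units at the read boundary (using the sibling `unit` column); `check`
# validates each numeric column row-wise.
table_schemas <- list(
  commodities = list(
    columns = c("commodity_id", "name", "primary_food_group", "year",
                "production_kt", "food_supply_kt", "losses_kt"),
    numeric = c("year", "production_kt", "food_supply_kt", "losses_kt"),
    bounds = list(production_kt = c(0, Inf), food_supply_kt = c(0, Inf),
                  losses_kt = c(0, Inf))
  ),
  food_types = list(
    columns = c("food_type_id", "commodity_id", "share", "processing_yield",
                "inedible_fraction"),
    numeric = c("share", "processing_yield", "inedible_fraction"),
    bounds = list(share = c(0, 1), processing_yield = c(1e-12, 10),
                  inedible_fraction = c(0, 1))
  ),
  composition = list(
    columns = c("food_type_id", "nutrient", "amount", "unit"),
    numeric = "amount",
    bounds = list(amount = c(0, Inf)),
    unit_convert = "amount"
  ),
  bioavailability = list(
    columns = c("food_type_id", "nutrient", "coefficient"),
    numeric = "coefficient",
    bounds = list(coefficient = c(0, 1))
  ),
  waste = list(
    columns = c("region_id", "food_group", "fraction", "region_weight"),
    numeric = c("fraction", "region_weight"),
    bounds = list(fraction = c(0, 0.5), region_weight = c(0, Inf))
  ),
  demographics = list(
    columns = c("age_band", "sex", "population"),
    numeric = "population",
    bounds = list(population = c(0, Inf))
  ),
  nrv = list(
    columns = c("age_band", "sex", "nutrient", "amount", "unit"),
    numeric = "amount",
    bounds = list(amount = c(0, Inf)),
    unit_convert = "amount"
  ),
  availability = list(
    columns = c("food_type_id", "commodity_id", "nutrient", "available",
                "bioavailable", "per_capita_daily"),
    numeric = c("available", "bioavailable", "per_capita_daily"),
    bounds = list(available = c(0, Inf), bioavailable = c(0, Inf),
                  per_capita_daily = c(0, Inf))
  ),
  targets = list(
    columns = c("nutrient", "global_requirement", "per_capita_target",
                "adequacy_ratio", "undersupplied"),
    numeric = c("global_requirement", "per_capita_target", "adequacy_ratio"),
    bounds = list(global_requirement = c(0, Inf),
                  per_capita_target = c(0, Inf))
  ),
  contribution_report = list(
    columns = c("nutrient", "total_bioavailable", "contribution",
                "percent_contribution", "contribution_rank", "density",
                "density_rank"),
    numeric = c("total_bioavailable", "contribution", "percent_contribution",
                "contribution_rank", "density", "density_rank"),
    bounds = list()
  )
)

#' Read a typed input or output table
#'
#' Reads a CSV file against one of the declared table schemas, validating
#' the header, coercing declared numeric columns, checking per-column
#' bounds, and converting unit-bearing amount columns (composition, nutrient
#' reference values) to each nutrient's canonical unit at the boundary.
#' All downstream computation is unit-free.
#'
#' @param path Path to a CSV file (comma-separated, UTF-8, `.` decimal,
#'   mandatory header).
#' @param schema One of `"commodities"`, `"food_types"`, `"composition"`,
#'   `"bioavailability"`, `"waste"`, `"demographics"`, `"nrv"`,
#'   `"availability"`, `"targets"`, `"contribution_report"`.
#' @return A validated tibble; unit-converted tables gain a `unit` column
#'   holding the canonical unit.
#' @export
read_table <- function(path, schema) {
  sch <- table_schemas[[schema]]
  if (is.null(sch)) stop_schema(sprintf("unknown schema '%s'", schema))
  if (!file.exists(path)) stop_schema(sprintf("file not found: %s", path))
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  validate_table(tibble::as_tibble(raw), schema, coerce = TRUE)
}

# shared validator for freshly read (character) and in-memory tables
validate_table <- function(tab, schema, coerce = FALSE) {
  sch <- table_schemas[[schema]]
  missing <- setdiff(sch$columns, names(tab))
  if (length(missing)) {
    stop_schema(sprintf("missing column(s): %s", paste(missing, collapse = ", ")),
                table = schema)
  }
  tab <- tab[sch$columns]
  for (col in sch$numeric) {
    vals <- tab[[col]]
    if (coerce) {
      num <- suppressWarnings(as.numeric(vals))
      bad <- which(is.na(num) & !is.na(vals) & trimws(vals) != "")
      if (length(bad)) {
        stop_schema(sprintf("non-numeric value '%s'", vals[bad[1]]),
                    table = schema, row = bad[1], column = col)
      }
      vals <- num
    }
    if (!is.numeric(vals)) {
      stop_schema("column is not numeric", table = schema, column = col)
    }
    bad <- which(is.na(vals))
    if (length(bad)) {
      stop_schema("missing value", table = schema, row = bad[1], column = col)
    }
    b <- sch$bounds[[col]]
    if (!is.null(b)) {
      bad <- which(vals < b[1] | vals > b[2])
      if (length(bad)) {
        stop_schema(sprintf("value %g outside [%g, %g]", vals[bad[1]], b[1], b[2]),
                    table = schema, row = bad[1], column = col)
      }
    }
    tab[[col]] <- vals
  }
  if (schema == "targets" && is.character(tab$undersupplied)) {
    tab$undersupplied <- as.logical(tab$undersupplied)
  }
  if (!is.null(sch$unit_convert)) {
    col <- sch$unit_convert
    bad_nut <- which(!(tab$nutrient %in% nutriflow_nutrients$nutrient))
    if (length(bad_nut)) {
      stop_schema(sprintf("unknown nutrient '%s'", tab$nutrient[bad_nut[1]]),
                  table = schema, row = bad_nut[1], column = "nutrient")
    }
    tab[[col]] <- convert_units(tab[[col]], tab$unit, tab$nutrient)
    tab$unit <- nutrient_unit(tab$nutrient)
  }
  extra_checks(tab, schema)
  tab
}

# cross-row invariants that a per-cell bound cannot express
extra_checks <- function(tab, schema) {
  if (schema == "commodities") {
    by_c <- split(tab$year, tab$commodity_id)
    for (id in names(by_c)) {
      if (anyDuplicated(by_c[[id]]) || is.unsorted(by_c[[id]], strictly = TRUE)) {
        stop_schema(sprintf("years for commodity '%s' must be strictly increasing", id),
                    table = schema, column = "year")
      }
    }
  }
  if (schema == "food_types") {
    sums <- tapply(tab$share, tab$commodity_id, sum)
    bad <- names(sums)[abs(sums - 1) > 1e-9]
    if (length(bad)) {
      stop_schema(sprintf("shares under commodity '%s' sum to %.12g, not 1",
                          bad[1], sums[[bad[1]]]),
                  table = schema, column = "share")
    }
  }
  if (schema == "bioavailability") {
    flagged <- nutrient_ids(bioavailable_only = TRUE)
    bad <- which(!(tab$nutrient %in% flagged))
    if (length(bad)) {
      stop_schema(sprintf("coefficient given for non-adjusted nutrient '%s'",
                          tab$nutrient[bad[1]]),
                  table = schema, row = bad[1], column = "nutrient")
    }
  }
  if (schema == "waste") {
    w <- tapply(tab$region_weight, tab$region_id, mean)
    if (abs(sum(w) - 1) > 1e-9) {
      stop_schema(sprintf("region weights sum to %.12g, not 1", sum(w)),
                  table = schema, column = "region_weight")
    }
  }
  if (schema == "demographics") {
    if (anyDuplicated(tab[c("age_band", "sex")])) {
      stop_schema("duplicate (age_band, sex) pair", table = schema)
    }
  }
  invisible(tab)
}

#' Write a table in its schema's CSV layout
#'
#' Columns are reordered to the schema's declared order and written at full
#' precision (up to 15 significant digits) so that a write/read round trip
#' reproduces values exactly. Output is deterministic: the same table always
#' produces a byte-identical file.
#'
#' @param tab A tibble conforming to the schema.
#' @param path Output CSV path.
#' @param schema Schema id as in [read_table()].
#' @return Invisibly, the written path.
#' @export
write_table <- function(tab, path, schema) {
  sch <- table_schemas[[schema]]
  if (is.null(sch)) stop_schema(sprintf("unknown schema '%s'", schema))
  tab <- validate_table(tibble::as_tibble(tab)[sch$columns], schema)
  out <- tab
  for (col in sch$numeric) {
    out[[col]] <- formatC(out[[col]], format = "g", digits = 15)
  }
  lines <- c(
    paste(sch$columns, collapse = ","),
    do.call(paste, c(unname(as.list(out)), sep = ","))
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a complete food-system input bundle from a directory
#'
#' Expects the seven input CSVs (`commodities.csv`, `food_types.csv`,
#' `composition.csv`, `bioavailability.csv`, `waste.csv`,
#' `demographics.csv`, `nrv.csv`) in `dir`, each validated against its
#' schema, and checks cross-table consistency: every food type's parent
#' commodity exists, composition covers every food type for all 29
#' nutrients, and nutrient reference values cover every demographic group.
#'
#' @param dir Directory containing the seven input CSVs.
#' @return A `food_system` object (a named list of validated tibbles).
#' @export
read_food_system <- function(dir) {
  parts <- c("commodities", "food_types", "composition", "bioavailability",
             "waste", "demographics", "nrv")
  tabs <- lapply(parts, function(p) {
    read_table(file.path(dir, paste0(p, ".csv")), p)
  })
  names(tabs) <- parts
  food_system(tabs)
}

#' Assemble and validate a food system from in-memory tables
#'
#' @param tables Named list with elements `commodities`, `food_types`,
#'   `composition`, `bioavailability`, `waste`, `demographics`, `nrv`.
#' @return A validated `food_system` object.
#' @export
food_system <- function(tables) {
  parts <- c("commodities", "food_types", "composition", "bioavailability",
             "waste", "demographics", "nrv")
  missing <- setdiff(parts, names(tables))
  if (length(missing)) {
    stop_schema(sprintf("food system is missing table(s): %s",
                        paste(missing, collapse = ", ")))
  }
  tables <- lapply(parts, function(p) validate_table(tables[[p]], p))
  names(tables) <- parts
  orphan <- setdiff(tables$food_types$commodity_id,
                    tables$commodities$commodity_id)
  if (length(orphan)) {
    stop_schema(sprintf("food type parent commodity '%s' not in commodities",
                        orphan[1]), table = "food_types")
  }
  need <- expand.grid(food_type_id = unique(tables$food_types$food_type_id),
                      nutrient = nutriflow_nutrients$nutrient,
                      stringsAsFactors = FALSE)
  have <- paste(tables$composition$food_type_id, tables$composition$nutrient)
  gap <- which(!(paste(need$food_type_id, need$nutrient) %in% have))
  if (length(gap)) {
    stop_schema(sprintf("composition missing for food type '%s', nutrient '%s'",
                        need$food_type_id[gap[1]], need$nutrient[gap[1]]),
                table = "composition")
  }
  structure(tables, class = "food_system")
}

#' @export
print.food_system <- function(x, ...) {
  cat("<food_system>\n")
  cat(sprintf("  %d commodities, %d food types, %d regions, %d demographic groups\n",
              length(unique(x$commodities$commodity_id)),
              nrow(x$food_types),
              length(unique(x$waste$region_id)),
              nrow(x$demographics)))
  yr <- range(x$commodities$year)
  cat(sprintf("  years %d-%d; population %.4g\n", yr[1], yr[2],
              sum(x$demographics$population)))
  invisible(x)
}

#' Write a food system's seven input tables to a directory
#'
#' @param system A `food_system` object.
#' @param dir Output directory (created if absent).
#' @return Invisibly, `dir`.
#' @export
write_food_system <- function(system, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (p in names(table_schemas)[1:7]) {
    if (!is.null(system[[p]])) {
      write_table(system[[p]], file.path(dir, paste0(p, ".csv")), p)
    }
  }
  invisible(dir)
}

# bioavailability lookup: coefficient for (food_type, nutrient), default 1
# for absent pairs; identically 1 for non-adjusted nutrients
bioavailability_coefficient <- function(bioavailability, food_type_id, nutrient) {
  flagged <- nutrient %in% nutrient_ids(bioavailable_only = TRUE)
  key <- paste(food_type_id, nutrient)
  idx <- match(key, paste(bioavailability$food_type_id, bioavailability$nutrient))
  coef <- ifelse(is.na(idx), 1, bioavailability$coefficient[idx])
  ifelse(flagged, coef, 1)
}

#' Write a contribution report CSV
#'
#' Output columns follow the `contribution_report` schema at full numeric
#' precision; [read_report()] of the written file reproduces the report.
#' Nutrients with an undefined percentage (zero total availability) carry
#' `NA` in the percent and rank columns.
#'
#' @param report A contribution report tibble from [contribution_report()].
#' @param path Output CSV path.
#' @return Invisibly, the path.
#' @export
write_report <- function(report, path) {
  out <- report
  num <- table_schemas$contribution_report$numeric
  for (col in num) {
    out[[col]] <- ifelse(is.na(out[[col]]), "NA",
                         formatC(out[[col]], format = "g", digits = 15))
  }
  lines <- c(paste(names(out), collapse = ","),
             do.call(paste, c(unname(as.list(out)), sep = ",")))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a contribution report CSV written by [write_report()]
#'
#' @param path Path to the report CSV.
#' @return The report tibble.
#' @export
read_report <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         fileEncoding = "UTF-8")
  tab <- tibble::as_tibble(raw)
  for (col in table_schemas$contribution_report$numeric) {
    tab[[col]] <- suppressWarnings(as.numeric(tab[[col]]))
  }
  tab
}

#' Map an FAO-style food balance sheet extract to the commodities schema
#'
#' A documented converter stub for long-format balance-sheet extracts with
#' columns `Item Code`, `Item`, `Element`, `Year`, `Value` (thousand
#' tonnes), where `Element` is one of `"Production"`, `"Food"` or
#' `"Losses"`. The food-group mapping must be supplied because balance
#' sheets do not carry one. This converter has not been exercised against
#' live FAO downloads; it documents the intended mapping only.
#'
#' @param fbs A data frame in the long FAO export layout described above.
#' @param group_map Named character vector mapping `Item` to one of the 15
#'   primary food groups.
#' @return A tibble in the `commodities` schema.
#' @export
fao_fbs_to_commodities <- function(fbs, group_map) {
  element_col <- c(Production = "production_kt", Food = "food_supply_kt",
                   Losses = "losses_kt")
  fbs <- fbs[fbs$Element %in% names(element_col), ]
  wide <- tidyr::pivot_wider(
    tibble::tibble(
      commodity_id = as.character(fbs[["Item Code"]]),
      name = fbs$Item,
      year = as.integer(fbs$Year),
      quantity = element_col[fbs$Element],
      value = as.numeric(fbs$Value)
    ),
    names_from = "quantity", values_from = "value", values_fill = 0
  )
  wide$primary_food_group <- unname(group_map[wide$name])
  validate_table(wide[table_schemas$commodities$columns], "commodities")
}
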