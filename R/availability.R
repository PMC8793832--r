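# kt -> g; all commodity masses are kilotonnes per year
GRAMS_PER_KT <- 1e9

# population-weighted mean in-home waste fraction per food group
group_waste_fraction <- function(waste, food_group) {
  idx <- waste$food_group == food_group
  if (!any(idx)) {
    stop_schema(sprintf("food group '%s' absent from waste table", food_group),
                table = "waste")
  }
  sum(waste$region_weight[idx] * waste$fraction[idx]) /
    sum(waste$region_weight[idx])
}

#' Edible mass reaching consumption, per food type
#'
#' The commodity's baseline food supply is split among its food types by
#' share, scaled by the processing yield, stripped of the inedible fraction,
#' and reduced by the in-home waste fraction for the commodity's food group
#' (the region-population-weighted mean; applied globally this is
#' algebraically identical to applying regional fractions before
#' aggregating, for a fixed group):
#' \deqn{M = S \times share \times yield \times (1 - inedible) \times (1 - \bar w)}
#'
#' @param baseline A `baseline` tibble from [fit_baseline()].
#' @param food_types The food-type subdivision table.
#' @param waste The regional waste table.
#' @param waste_override Optional fraction in \[0, 1\] replacing the weighted
#'   mean in-home waste fraction for every food group (scenario use).
#' @return Tibble with columns `food_type_id`, `commodity_id`,
#'   `primary_food_group`, `edible_kt` (kt/yr) and `home_waste_kt`, the
#'   edible mass discarded in-home (used by waste-share analytics).
#' @export
edible_mass <- function(baseline, food_types, waste, waste_override = NULL) {
  ft <- dplyr::inner_join(
    food_types,
    baseline[c("commodity_id", "primary_food_group", "food_supply_kt")],
    by = "commodity_id"
  )
  wbar <- vapply(ft$primary_food_group, function(g) {
    if (!is.null(waste_override)) waste_override
    else group_waste_fraction(waste, g)
  }, numeric(1), USE.NAMES = FALSE)
  pre_waste <- ft$food_supply_kt * ft$share * ft$processing_yield *
    (1 - ft$inedible_fraction)
  tibble::tibble(
    food_type_id = ft$food_type_id,
    commodity_id = ft$commodity_id,
    primary_food_group = ft$primary_food_group,
    edible_kt = pre_waste * (1 - wbar),
    home_waste_kt = pre_waste * wbar
  )
}

#' Convert edible food-type masses into nutrient availability
#'
#' Composition is stored per 100 g edible mass in each nutrient's canonical
#' unit, so the annual available quantity is
#' `edible_kt * 1e9 / 100 * amount` in canonical units per year.
#'
#' @param masses Tibble from [edible_mass()].
#' @param composition Composition table in canonical units.
#' @return Tibble with columns `food_type_id`, `commodity_id`, `nutrient`,
#'   `available` (canonical unit per year), one row per food type and each
#'   of the 29 nutrients.
#' @export
mass_to_nutrients <- function(masses, composition) {
  comp <- dplyr::inner_join(
    composition[c("food_type_id", "nutrient", "amount")],
    masses[c("food_type_id", "commodity_id", "edible_kt")],
    by = "food_type_id"
  )
  if (nrow(comp) != nrow(masses) * nrow(nutriflow_nutrients)) {
    missing <- setdiff(masses$food_type_id, composition$food_type_id)
    if (length(missing)) {
      stop_schema(sprintf("no composition rows for food type '%s'", missing[1]),
                  table = "composition")
    }
  }
  tibble::tibble(
    food_type_id = comp$food_type_id,
    commodity_id = comp$commodity_id,
    nutrient = comp$nutrient,
    available = comp$edible_kt * GRAMS_PER_KT / 100 * comp$amount
  )
}

#' Apply bioavailability coefficients
#'
#' Multiplies the available quantity of protein and the seven indispensable
#' amino acids by each food type's bioavailability coefficient (default 1
#' where no coefficient is given); all other nutrients pass through with a
#' coefficient of exactly 1.
#'
#' @param avail Tibble from [mass_to_nutrients()].
#' @param bioavailability Coefficient table.
#' @return `avail` with an added `bioavailable` column.
#' @export
apply_bioavailability <- function(avail, bioavailability) {
  coef <- bioavailability_coefficient(bioavailability, avail$food_type_id,
                                      avail$nutrient)
  avail$bioavailable <- avail$available * coef
  avail
}

#' Per-capita daily nutrient availability
#'
#' @param avail Tibble with a `bioavailable` column.
#' @param population Total population (persons, > 0).
#' @return `avail` with an added `per_capita_daily` column
#'   (canonical unit per person per day; annual quantity / population / 365).
#' @export
per_capita_daily <- function(avail, population) {
  if (!isTRUE(population > 0)) {
    stop_schema("population must be a single positive number")
  }
  avail$per_capita_daily <- avail$bioavailable / population / 365
  avail
}

#' Run the availability chain for a food system
#'
#' Convenience wrapper chaining [fit_baseline()] (unless a pre-computed
#' baseline is supplied), [edible_mass()], [mass_to_nutrients()],
#' [apply_bioavailability()] and [per_capita_daily()].
#'
#' @param system A `food_system` object.
#' @param target_year Baseline target year; defaults to the last data year.
#' @param window Fitting window in years (default 20).
#' @param method Baseline method, `"trend"` or `"last_value"`.
#' @param baseline Optional pre-computed baseline (e.g. after a scenario).
#' @param waste_override Optional global in-home waste fraction override.
#' @return An `availability` object: list with `values` (per food type ×
#'   nutrient: `available`, `bioavailable`, `per_capita_daily`), `masses`
#'   (per food type edible mass), `baseline`, and `population`.
#' @export
compute_availability <- function(system, target_year = NULL, window = 20,
                                 method = "trend", baseline = NULL,
                                 waste_override = NULL) {
  if (is.null(baseline)) {
    if (is.null(target_year)) target_year <- max(system$commodities$year)
    baseline <- fit_baseline(system$commodities, target_year, window, method)
  }
  masses <- edible_mass(baseline, system$food_types, system$waste,
                        waste_override)
  values <- mass_to_nutrients(masses, system$composition)
  values <- apply_bioavailability(values, system$bioavailability)
  population <- sum(system$demographics$population)
  values <- per_capita_daily(values, population)
  structure(list(values = values, masses = masses, baseline = baseline,
                 population = population),
            class = "availability")
}

#' @export
print.availability <- function(x, ...) {
  cat("<availability>\n")
  cat(sprintf("  %d food types x %d nutrients; population %.4g\n",
              nrow(x$masses), length(unique(x$values$nutrient)),
              x$population))
  tot <- sum(x$masses$edible_kt)
  cat(sprintf("  total edible mass %.6g kt/yr (%.1f g/person/day)\n", tot,
              tot * GRAMS_PER_KT / x$population / 365))
  invisible(x)
}

# per-nutrient totals over an optional commodity subset
nutrient_totals <- function(avail, commodities = NULL, field = "bioavailable") {
  v <- avail$values
  if (!is.null(commodities)) v <- v[v$commodity_id %in% commodities, ]
  out <- tapply(v[[field]], v$nutrient, sum, default = 0)
  full <- stats::setNames(numeric(nrow(nutriflow_nutrients)),
                          nutriflow_nutrients$nutrient)
  full[names(out)] <- out
  full
}
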