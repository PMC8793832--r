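#' The 29 modelled nutrients
#'
#' Registry of the nutrients tracked by the model: five macronutrients,
#' seventeen vitamins and minerals, and seven indispensable amino acids
#' (cystine is conventionally reported with methionine as the sulfur amino
#' acids and is included here). Each nutrient has a fixed canonical unit in
#' which all internal computation is carried out: grams for macronutrients
#' and amino acids, kcal for energy, milligrams for most minerals and
#' vitamins, and micrograms for folate, vitamin A, vitamin B12 and selenium.
#' Bioavailability coefficients apply only to protein and the seven amino
#' acids; for every other nutrient the coefficient is identically 1.
#'
#' @return A tibble with one row per nutrient and columns `nutrient`,
#'   `unit` (canonical unit), `class` (`"macronutrient"`, `"micronutrient"`
#'   or `"amino_acid"`), and `bioavailability_adjusted` (logical, `TRUE`
#'   for exactly protein and the seven amino acids).
#' @export
#' @examples
#' nutrients()
nutrients <- function() {
  nutriflow_nutrients
}

# built once at load; canonical units are a fixed design constant
nutriflow_nutrients <- local({
  macro <- c("carbohydrates", "energy", "fat", "fiber", "protein")
  micro <- c("calcium", "copper", "folate", "iron", "magnesium",
             "phosphorus", "potassium", "selenium", "vitamin_a",
             "vitamin_b1", "vitamin_b2", "vitamin_b5", "vitamin_b6",
             "vitamin_b12", "vitamin_c", "vitamin_e", "zinc")
  aa <- c("cystine", "histidine", "leucine", "lysine", "methionine",
          "threonine", "tryptophan")
  unit <- c(
    carbohydrates = "g", energy = "kcal", fat = "g", fiber = "g",
    protein = "g",
    calcium = "mg", copper = "mg", folate = "ug", iron = "mg",
    magnesium = "mg", phosphorus = "mg", potassium = "mg",
    selenium = "ug", vitamin_a = "ug", vitamin_b1 = "mg",
    vitamin_b2 = "mg", vitamin_b5 = "mg", vitamin_b6 = "mg",
    vitamin_b12 = "ug", vitamin_c = "mg", vitamin_e = "mg", zinc = "mg",
    cystine = "g", histidine = "g", leucine = "g", lysine = "g",
    methionine = "g", threonine = "g", tryptophan = "g"
  )
  ids <- c(macro, micro, aa)
  tibble::tibble(
    nutrient = ids,
    unit = unname(unit[ids]),
    class = rep(c("macronutrient", "micronutrient", "amino_acid"),
                c(length(macro), length(micro), length(aa))),
    bioavailability_adjusted = ids %in% c("protein", aa)
  )
})

#' Nutrient identifiers
#'
#' @param bioavailable_only If `TRUE`, return only protein and the seven
#'   indispensable amino acids (the nutrients whose supply is adjusted by a
#'   bioavailability coefficient).
#' @return Character vector of nutrient ids.
#' @export
nutrient_ids <- function(bioavailable_only = FALSE) {
  tab <- nutriflow_nutrients
  if (bioavailable_only) tab$nutrient[tab$bioavailability_adjusted]
  else tab$nutrient
}

# canonical unit for one nutrient
nutrient_unit <- function(nutrient) {
  tab <- nutriflow_nutrients
  idx <- match(nutrient, tab$nutrient)
  if (anyNA(idx)) {
    stop_schema(sprintf("unknown nutrient '%s'",
                        paste(nutrient[is.na(idx)], collapse = ", ")))
  }
  tab$unit[idx]
}

#' Convert an amount to a nutrient's canonical unit
#'
#' Mass units (g, mg, ug) interconvert by powers of 1000; energy accepts
#' kcal or kJ (1 kcal = 4.184 kJ). Mixing mass and energy units raises a
#' schema-violation error.
#'
#' @param amount Numeric vector of amounts.
#' @param unit Character vector of input units, recycled against `amount`.
#' @param nutrient Character vector of nutrient ids, recycled likewise.
#' @return Amounts expressed in each nutrient's canonical unit.
#' @export
#' @examples
#' convert_units(500, "ug", "calcium")   # 0.5 mg
#' convert_units(1, "kcal", "energy")    # 1
convert_units <- function(amount, unit, nutrient) {
  mass_in_g <- c(g = 1, mg = 1e-3, ug = 1e-6, mcg = 1e-6)
  energy_in_kcal <- c(kcal = 1, kj = 1 / 4.184)
  unit <- tolower(gsub("µ", "u", unit))
  canon <- nutrient_unit(nutrient)
  factor_for <- function(u, cu) {
    if (u %in% names(mass_in_g) && cu %in% names(mass_in_g)) {
      mass_in_g[[u]] / mass_in_g[[cu]]
    } else if (u %in% names(energy_in_kcal) && cu %in% names(energy_in_kcal)) {
      energy_in_kcal[[u]] / energy_in_kcal[[cu]]
    } else {
      stop_schema(sprintf("cannot convert unit '%s' to canonical '%s'", u, cu))
    }
  }
  amount * mapply(factor_for, unit, canon, USE.NAMES = FALSE)
}
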