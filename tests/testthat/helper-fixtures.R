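# Hand-built miniature food systems with arithmetic simple enough to check
# by hand. Constant time series make the fitted baseline equal the constants.

constant_series <- function(id, name, group, production, supply, losses,
                            years = 2009:2018) {
  tibble::tibble(commodity_id = id, name = name, primary_food_group = group,
                 year = years, production_kt = production,
                 food_supply_kt = supply, losses_kt = losses)
}

# composition rows for one food type: zero everywhere except `values`
composition_for <- function(food_type_id, values = c()) {
  nuts <- nutrients()$nutrient
  amount <- stats::setNames(rep(0, length(nuts)), nuts)
  amount[names(values)] <- values
  tibble::tibble(food_type_id = food_type_id, nutrient = nuts,
                 amount = unname(amount), unit = nutrients()$unit)
}

uniform_nrv <- function(demographics, amount = 1) {
  nuts <- nutrients()$nutrient
  dplyr::bind_rows(lapply(seq_len(nrow(demographics)), function(g) {
    tibble::tibble(age_band = demographics$age_band[g],
                   sex = demographics$sex[g],
                   nutrient = nuts, amount = amount,
                   unit = nutrients()$unit)
  }))
}

# two commodities (cereal + milk-like dairy), three food types, one region
# with zero waste by default; populations 1000 + 500
tiny_system <- function(waste_fraction = 0, milk_supply = 400,
                        nrv_amount = 1) {
  commodities <- dplyr::bind_rows(
    constant_series("c_a", "cereal", "cereals", 1000, 800, 100),
    constant_series("milk", "milk-like", "dairy", 500, milk_supply, 35)
  )
  food_types <- tibble::tibble(
    food_type_id = c("a_ft1", "a_ft2", "milk_ft1"),
    commodity_id = c("c_a", "c_a", "milk"),
    share = c(0.6, 0.4, 1),
    processing_yield = c(1, 0.9, 1),
    inedible_fraction = c(0, 0.1, 0)
  )
  composition <- dplyr::bind_rows(
    composition_for("a_ft1", c(energy = 350, protein = 10, fiber = 12,
                               carbohydrates = 70, iron = 3, calcium = 30,
                               lysine = 0.3)),
    composition_for("a_ft2", c(energy = 360, protein = 12, fiber = 10,
                               carbohydrates = 72, iron = 4, calcium = 25,
                               lysine = 0.35)),
    composition_for("milk_ft1", c(energy = 61, protein = 3.15, fat = 3.25,
                                  carbohydrates = 4.8, calcium = 113,
                                  lysine = 0.25, methionine = 0.08,
                                  cystine = 0.03, leucine = 0.27,
                                  threonine = 0.14, tryptophan = 0.04,
                                  histidine = 0.075, vitamin_b2 = 0.169))
  )
  bio <- milk_bioavailability()
  bioavailability <- tibble::tibble(
    food_type_id = "milk_ft1", nutrient = names(bio),
    coefficient = unname(bio)
  )
  waste <- tibble::tibble(
    region_id = "r1",
    food_group = c("cereals", "dairy"),
    fraction = waste_fraction, region_weight = 1
  )
  demographics <- tibble::tibble(
    age_band = c("adult", "child"), sex = c("all", "all"),
    population = c(1000, 500)
  )
  food_system(list(
    commodities = commodities, food_types = food_types,
    composition = composition, bioavailability = bioavailability,
    waste = waste, demographics = demographics,
    nrv = uniform_nrv(demographics, nrv_amount)
  ))
}

rel_err <- function(a, b) {
  abs(a - b) / pmax(abs(b), .Machine$double.xmin)
}
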