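# The 15 primary food groups a scenario can address; dairy is one of them.
primary_food_groups <- function() {
  c("cereals", "dairy", "eggs", "fish", "fruits", "meat", "nuts_seeds",
    "oils", "pulses", "spices", "starchy_roots", "stimulants", "sugar",
    "vegetables", "alcohol")
}

# per-100 g composition of the milk-like commodity (whole-milk-shaped
# synthetic values in canonical units; fiber exactly 0)
milk_composition <- function() {
  c(carbohydrates = 4.8, energy = 61, fat = 3.25, fiber = 0, protein = 3.15,
    calcium = 113, copper = 0.025, folate = 5, iron = 0.03, magnesium = 10,
    phosphorus = 84, potassium = 132, selenium = 3.7, vitamin_a = 46,
    vitamin_b1 = 0.046, vitamin_b2 = 0.169, vitamin_b5 = 0.373,
    vitamin_b6 = 0.036, vitamin_b12 = 0.45, vitamin_c = 0, vitamin_e = 0.07,
    zinc = 0.37, cystine = 0.03, histidine = 0.075, leucine = 0.27,
    lysine = 0.25, methionine = 0.08, threonine = 0.14, tryptophan = 0.04)
}

#' Bioavailability coefficients of milk protein and indispensable amino acids
#'
#' The coefficient set carried by the milk-like commodity in synthetic
#' fixtures: protein 0.95, tryptophan 0.98, threonine 0.97, leucine 1,
#' lysine 0.98, methionine 0.92, cystine 0.94, histidine 1. All are above
#' 0.9; the sulfur amino acids (methionine, cystine) carry the lowest
#' values.
#'
#' @return Named numeric vector of eight coefficients.
#' @export
milk_bioavailability <- function() {
  c(protein = 0.95, tryptophan = 0.98, threonine = 0.97, leucine = 1,
    lysine = 0.98, methionine = 0.92, cystine = 0.94, histidine = 1)
}

# plausible per-100 g composition ranges for generic synthetic food types
composition_ranges <- function() {
  rng <- list(
    carbohydrates = c(0, 80), energy = c(20, 600), fat = c(0, 40),
    fiber = c(0, 15), protein = c(0, 30),
    calcium = c(0, 300), copper = c(0, 2), folate = c(0, 300),
    iron = c(0, 10), magnesium = c(0, 250), phosphorus = c(0, 400),
    potassium = c(0, 1500), selenium = c(0, 50), vitamin_a = c(0, 500),
    vitamin_b1 = c(0, 1), vitamin_b2 = c(0, 1.5), vitamin_b5 = c(0, 5),
    vitamin_b6 = c(0, 1), vitamin_b12 = c(0, 5), vitamin_c = c(0, 60),
    vitamin_e = c(0, 10), zinc = c(0, 8)
  )
  for (aa in c("cystine", "histidine", "leucine", "lysine", "methionine",
               "threonine", "tryptophan")) {
    rng[[aa]] <- c(0, 2.5)
  }
  rng
}

# per-person-per-day reference-value midpoints (canonical units) used to
# draw synthetic NRVs; placeholders with realistic magnitudes, not agency
# values
nrv_midpoints <- function() {
  c(carbohydrates = 260, energy = 2200, fat = 70, fiber = 27, protein = 52,
    calcium = 1000, copper = 1.2, folate = 330, iron = 12, magnesium = 330,
    phosphorus = 600, potassium = 3400, selenium = 65, vitamin_a = 700,
    vitamin_b1 = 1.1, vitamin_b2 = 1.3, vitamin_b5 = 5, vitamin_b6 = 1.5,
    vitamin_b12 = 4, vitamin_c = 95, vitamin_e = 12, zinc = 9,
    cystine = 1.1, histidine = 0.9, leucine = 3.4, lysine = 2.7,
    methionine = 0.9, threonine = 1.3, tryptophan = 0.35)
}

#' Configuration for the synthetic food-system generator
#'
#' Defaults emulate the scale and conditions of the global balance-sheet
#' data the model is built for: 98 commodities subdivided into roughly 315
#' food types (1 to 6 per commodity), 20-year annual series ending in 2018,
#' a milk-like dairy commodity carrying the canonical bioavailability
#' coefficients, and regional in-home dairy waste fractions between 0.1%
#' and 15%.
#'
#' @param n_commodities Number of commodities (>= 1; one is the milk-like
#'   commodity when `include_milk_like`).
#' @param food_types_per_commodity Inclusive range (length-2 integer) of
#'   food types per commodity.
#' @param n_years Length of each annual series (default 20).
#' @param n_regions Number of waste regions.
#' @param seed Integer seed; equal configurations generate identical
#'   bundles.
#' @param include_milk_like Include the milk-like dairy commodity.
#' @param noise_sd Relative s.d. of multiplicative Gaussian noise around
#'   each linear trend (0 gives exactly linear series).
#' @param trend_range Range of per-year slope, as a fraction of each
#'   commodity's base level.
#' @param end_year Final calendar year of the series.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_commodities = 98,
                             food_types_per_commodity = c(1, 6),
                             n_years = 20, n_regions = 4, seed = 1,
                             include_milk_like = TRUE, noise_sd = 0.02,
                             trend_range = c(-0.02, 0.05),
                             end_year = 2018) {
  stopifnot(n_commodities >= 1, n_years >= 2, n_regions >= 1,
            noise_sd >= 0, length(food_types_per_commodity) == 2,
            food_types_per_commodity[1] >= 1,
            diff(food_types_per_commodity) >= 0,
            length(trend_range) == 2)
  structure(list(n_commodities = n_commodities,
                 food_types_per_commodity = food_types_per_commodity,
                 n_years = n_years, n_regions = n_regions,
                 seed = as.integer(seed),
                 include_milk_like = isTRUE(include_milk_like),
                 noise_sd = noise_sd, trend_range = trend_range,
                 end_year = end_year),
            class = "generator_config")
}

#' Generate a synthetic food system with known ground truth
#'
#' Emits all seven input tables of a complete food system. Every commodity
#' time series is a linear trend plus multiplicative Gaussian noise
#' (truncated at zero so masses stay non-negative); food-type shares under
#' each commodity sum to one exactly; generated tables pass the full input
#' validation. The returned `truth` element holds the expected baseline,
#' edible masses, availabilities, targets and milk analytics computed by
#' [oracle_outputs()], a deliberately naive straight-line implementation
#' sharing no code with the engine. Equal configurations yield identical
#' bundles.
#'
#' @param config A [generator_config()].
#' @return List with `system` (a `food_system`), `truth` (ground-truth
#'   list) and `config`.
#' @export
generate_system <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  groups <- primary_food_groups()
  n <- config$n_commodities
  ids <- sprintf("c%03d", seq_len(n))
  names_ <- sprintf("synthetic food %03d", seq_len(n))
  grp <- sample(setdiff(groups, "dairy"), n, replace = TRUE)
  milk_id <- NULL
  if (config$include_milk_like) {
    milk_id <- "milk"
    ids[1] <- milk_id
    names_[1] <- "milk-like commodity"
    grp[1] <- "dairy"
  }
  years <- seq(config$end_year - config$n_years + 1, config$end_year)

  # annual series: linear trend in each balance quantity + truncated noise
  commodity_rows <- vector("list", n)
  for (i in seq_len(n)) {
    base <- stats::runif(1, 100, 5000)
    slope <- stats::runif(1, config$trend_range[1], config$trend_range[2]) * base
    supply_frac <- stats::runif(1, 0.5, 0.85)
    loss_frac <- stats::runif(1, 0.02, 0.12)
    prod_trend <- base + slope * (years - years[1])
    noise <- function(m) {
      pmax(m * (1 + stats::rnorm(length(m), 0, config$noise_sd)), 0)
    }
    commodity_rows[[i]] <- tibble::tibble(
      commodity_id = ids[i], name = names_[i], primary_food_group = grp[i],
      year = years,
      production_kt = noise(prod_trend),
      food_supply_kt = noise(prod_trend * supply_frac),
      losses_kt = noise(prod_trend * loss_frac)
    )
  }
  commodities <- dplyr::bind_rows(commodity_rows)

  # food types: shares normalised to sum exactly to 1
  ft_rows <- vector("list", n)
  for (i in seq_len(n)) {
    k <- sample(seq(config$food_types_per_commodity[1],
                    config$food_types_per_commodity[2]), 1)
    raw <- stats::runif(k, 0.2, 1)
    share <- raw / sum(raw)
    share[k] <- 1 - sum(share[-k])
    is_milk <- identical(ids[i], milk_id)
    ft_rows[[i]] <- tibble::tibble(
      food_type_id = sprintf("%s_ft%d", ids[i], seq_len(k)),
      commodity_id = ids[i],
      share = share,
      processing_yield = if (is_milk) stats::runif(k, 0.9, 1.1)
                         else stats::runif(k, 0.5, 1.2),
      inedible_fraction = if (is_milk) rep(0, k) else stats::runif(k, 0, 0.4)
    )
  }
  food_types <- dplyr::bind_rows(ft_rows)

  # composition: generic ranges; milk food types use the milk profile with
  # mild per-food-type variation, fiber held at exactly 0
  rng <- composition_ranges()
  nuts <- nutriflow_nutrients$nutrient
  milk_comp <- milk_composition()
  comp_rows <- vector("list", nrow(food_types))
  for (j in seq_len(nrow(food_types))) {
    ftid <- food_types$food_type_id[j]
    if (identical(food_types$commodity_id[j], milk_id)) {
      amount <- milk_comp[nuts] * stats::runif(length(nuts), 0.95, 1.05)
      amount[nuts == "fiber"] <- 0
    } else {
      amount <- vapply(nuts, function(nm) {
        stats::runif(1, rng[[nm]][1], rng[[nm]][2])
      }, numeric(1))
    }
    comp_rows[[j]] <- tibble::tibble(
      food_type_id = ftid, nutrient = nuts, amount = unname(amount),
      unit = nutrient_unit(nuts)
    )
  }
  composition <- dplyr::bind_rows(comp_rows)

  # bioavailability: milk gets the canonical eight coefficients exactly;
  # other food types draw protein/amino-acid coefficients in [0.5, 1]
  flagged <- nutrient_ids(bioavailable_only = TRUE)
  milk_coef <- milk_bioavailability()
  bio_rows <- vector("list", nrow(food_types))
  for (j in seq_len(nrow(food_types))) {
    ftid <- food_types$food_type_id[j]
    coef <- if (identical(food_types$commodity_id[j], milk_id)) {
      unname(milk_coef[flagged])
    } else {
      stats::runif(length(flagged), 0.5, 1)
    }
    bio_rows[[j]] <- tibble::tibble(food_type_id = ftid, nutrient = flagged,
                                    coefficient = coef)
  }
  bioavailability <- dplyr::bind_rows(bio_rows)

  # regional waste: weights sum exactly to 1; dairy fractions in the
  # canonical 0.1-15% band
  regions <- sprintf("r%d", seq_len(config$n_regions))
  raw_w <- stats::runif(config$n_regions, 0.5, 1)
  w <- raw_w / sum(raw_w)
  w[config$n_regions] <- 1 - sum(w[-config$n_regions])
  waste_rows <- vector("list", config$n_regions)
  for (r in seq_len(config$n_regions)) {
    frac <- stats::runif(length(groups), 0, 0.3)
    frac[groups == "dairy"] <- stats::runif(1, 0.001, 0.15)
    waste_rows[[r]] <- tibble::tibble(region_id = regions[r],
                                      food_group = groups,
                                      fraction = frac, region_weight = w[r])
  }
  waste <- dplyr::bind_rows(waste_rows)

  # demographics: fixed small set of age bands x two sexes
  bands <- c("0-14", "15-34", "35-64", "65+")
  demographics <- tibble::tibble(
    age_band = rep(bands, each = 2),
    sex = rep(c("F", "M"), length(bands)),
    population = stats::runif(2 * length(bands), 2e8, 1e9)
  )

  # NRVs: uniform draws around realistic midpoints; placeholders, not
  # agency reference values
  mids <- nrv_midpoints()
  nrv_rows <- vector("list", nrow(demographics))
  for (g in seq_len(nrow(demographics))) {
    nrv_rows[[g]] <- tibble::tibble(
      age_band = demographics$age_band[g], sex = demographics$sex[g],
      nutrient = nuts,
      amount = unname(mids[nuts]) * stats::runif(length(nuts), 0.7, 1.3),
      unit = nutrient_unit(nuts)
    )
  }
  nrv <- dplyr::bind_rows(nrv_rows)

  system <- food_system(list(
    commodities = commodities, food_types = food_types,
    composition = composition, bioavailability = bioavailability,
    waste = waste, demographics = demographics, nrv = nrv
  ))
  truth <- oracle_outputs(system, target_year = config$end_year,
                          window = config$n_years,
                          foods = if (config$include_milk_like) milk_id)
  list(system = system, truth = truth, config = config)
}

#' Packaged milk fixture
#'
#' A small deterministic synthetic system containing a milk-like dairy
#' commodity whose bioavailability coefficients are exactly
#' [milk_bioavailability()], whose fiber composition is 0, and whose
#' regional in-home waste fractions lie in \[0.001, 0.15\], alongside a
#' handful of generic commodities for contribution context.
#'
#' @param seed Integer seed (default 101).
#' @param n_commodities Number of commodities including milk (default 6).
#' @return As [generate_system()]: list with `system`, `truth`, `config`.
#' @export
generate_milk_fixture <- function(seed = 101, n_commodities = 6) {
  generate_system(generator_config(
    n_commodities = n_commodities, food_types_per_commodity = c(1, 3),
    n_years = 20, n_regions = 4, seed = seed, include_milk_like = TRUE,
    noise_sd = 0.02
  ))
}

#' Serialize a ground-truth object to JSON
#'
#' @param truth Ground-truth list from [generate_system()].
#' @param path Output JSON path.
#' @return Invisibly, the path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
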