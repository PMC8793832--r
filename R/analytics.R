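# competition ranking: ties share the best rank, following ranks skipped
competition_rank <- function(values) {
  vapply(values, function(v) 1 + sum(values > v), numeric(1))
}

#' Percent of global availability contributed by a set of commodities
#'
#' @param avail An `availability` object.
#' @param foods Character vector of commodity ids.
#' @param nutrient A nutrient id.
#' @return Percentage in \[0, 100\], or `NA` with a warning when total
#'   availability of the nutrient is zero (no food contributes it).
#' @export
contribution_percent <- function(avail, foods, nutrient) {
  tot <- nutrient_totals(avail)[[nutrient]]
  if (tot <= 0) {
    warning(sprintf("total availability of %s is zero; percent undefined",
                    nutrient), call. = FALSE)
    return(NA_real_)
  }
  part <- nutrient_totals(avail, commodities = foods)[[nutrient]]
  100 * part / tot
}

#' Rank commodities by contribution to a nutrient
#'
#' Commodities are ordered by descending bioavailable contribution, ties
#' broken by ascending commodity id; ranks are competition ranks
#' (1, 2, 2, 4). Food types are aggregated to their parent commodity before
#' ranking.
#'
#' @param avail An `availability` object.
#' @param nutrient A nutrient id.
#' @return Tibble with columns `commodity_id`, `contribution`
#'   (canonical unit/yr, bioavailable) and `rank`, ordered best-first.
#' @export
rank_contributors <- function(avail, nutrient) {
  v <- avail$values[avail$values$nutrient == nutrient, ]
  contrib <- tapply(v$bioavailable, v$commodity_id, sum, default = 0)
  out <- tibble::tibble(commodity_id = names(contrib),
                        contribution = unname(contrib))
  out <- out[order(-out$contribution, out$commodity_id), ]
  out$rank <- competition_rank(out$contribution)
  out
}

#' Commodity-level nutrient density (per 100 g edible mass)
#'
#' A commodity's density is the edible-mass-weighted mean of its food
#' types' per-100 g content. Density uses mass after removal of inedible
#' fractions but before in-home waste: content per 100 g refers to food as
#' available, not as eaten. With `method = "representative"` the food type
#' carrying the largest edible mass stands for the commodity instead.
#' Zero-mass commodities are excluded with a warning.
#'
#' @param composition Composition table in canonical units.
#' @param food_types Food-type subdivision table.
#' @param masses Edible masses from [edible_mass()].
#' @param nutrient A nutrient id.
#' @param method `"weighted"` (default) or `"representative"`.
#' @return Tibble with columns `commodity_id`, `density` (canonical unit
#'   per 100 g) and `rank` (competition rank), ordered best-first.
#' @export
density_rank <- function(composition, food_types, masses, nutrient,
                         method = c("weighted", "representative")) {
  method <- match.arg(method)
  pre_waste <- masses$edible_kt + masses$home_waste_kt
  comp <- composition[composition$nutrient == nutrient, ]
  amount <- comp$amount[match(masses$food_type_id, comp$food_type_id)]
  dens <- vapply(split(seq_len(nrow(masses)), masses$commodity_id),
                 function(i) {
    w <- pre_waste[i]
    if (sum(w) <= 0) return(NA_real_)
    if (method == "representative") amount[i][which.max(w)]
    else sum(w * amount[i]) / sum(w)
  }, numeric(1))
  if (anyNA(dens)) {
    warning(sprintf("%d zero-mass commodity(ies) excluded from density ranking",
                    sum(is.na(dens))), call. = FALSE)
  }
  out <- tibble::tibble(commodity_id = names(dens), density = unname(dens))
  out <- out[!is.na(out$density), ]
  out <- out[order(-out$density, out$commodity_id), ]
  out$rank <- competition_rank(out$density)
  out
}

#' Share of production wasted between farm gate and consumption
#'
#' Total waste is supply-chain losses (from the balance sheet) plus in-home
#' waste mass (edible available mass times the group's weighted mean waste
#' fraction, summed over the commodity's food types), expressed as a
#' percentage of production at baseline values.
#'
#' @param baseline A `baseline` tibble.
#' @param food_types Food-type subdivision table.
#' @param waste Regional waste table.
#' @param commodity A commodity id.
#' @return Percentage of production wasted.
#' @export
waste_share <- function(baseline, food_types, waste, commodity) {
  b <- baseline[baseline$commodity_id == commodity, ]
  if (nrow(b) == 0) stop_schema(sprintf("unknown commodity '%s'", commodity))
  if (b$production_kt <= 0) {
    stop_schema(sprintf("commodity '%s' has zero production", commodity))
  }
  masses <- edible_mass(b, food_types[food_types$commodity_id == commodity, ],
                        waste)
  100 * (b$losses_kt + sum(masses$home_waste_kt)) / b$production_kt
}

#' Per-capita daily edible mass for a commodity set
#'
#' @param masses Edible masses from [edible_mass()].
#' @param foods Character vector of commodity ids (`NULL` for all).
#' @param population Total population.
#' @return Grams per person per day.
#' @export
per_capita_mass <- function(masses, foods = NULL, population) {
  if (!isTRUE(population > 0)) stop_schema("population must be positive")
  if (!is.null(foods)) masses <- masses[masses$commodity_id %in% foods, ]
  sum(masses$edible_kt) * GRAMS_PER_KT / population / 365
}

#' Digestible indispensable amino acid score (DIAAS)
#'
#' For each indispensable amino acid the digestibility-adjusted content per
#' gram of protein is compared with a reference pattern; the score is the
#' minimum of these ratios and the amino acid attaining it is the limiting
#' one. Scores above 1 indicate an excellent protein source, above 0.75 a
#' good one. The reference pattern is an input because the recommended
#' pattern differs by age group.
#'
#' @param aa_profile Named numeric vector: mg of each amino acid per g
#'   protein of the food.
#' @param digestibility Named numeric vector of true ileal digestibility
#'   fractions in \[0, 1\], matching `aa_profile` names.
#' @param reference_pattern Named numeric vector: mg per g protein required
#'   by the reference; strictly positive.
#' @return List with `score` (the minimum ratio) and `limiting` (the amino
#'   acid(s) attaining it).
#' @export
#' @examples
#' ref <- c(lysine = 48, leucine = 61, methionine = 23)
#' diaas(aa_profile = c(lysine = 78, leucine = 95, methionine = 22),
#'       digestibility = c(lysine = 0.98, leucine = 1, methionine = 0.92),
#'       reference_pattern = ref)
diaas <- function(aa_profile, digestibility, reference_pattern) {
  aas <- names(aa_profile)
  if (is.null(aas) || !all(aas %in% names(reference_pattern)) ||
      !all(aas %in% names(digestibility))) {
    stop_schema("aa_profile, digestibility and reference_pattern must share names")
  }
  ref <- reference_pattern[aas]
  if (any(ref <= 0)) stop_schema("reference pattern must be strictly positive")
  ratio <- digestibility[aas] * aa_profile[aas] / ref
  score <- min(ratio)
  list(score = unname(score),
       limiting = aas[abs(ratio - score) < 1e-12])
}

#' Full contribution report for a commodity set
#'
#' The machine-readable analogue of a contribution table: for each of the
#' 29 nutrients, the total bioavailable availability, the focal commodity
#' set's absolute and percent contribution, its contribution rank among
#' all commodities, its nutrient density per 100 g, and its density rank.
#' Nutrients the whole system does not supply carry `NA` percent and ranks
#' (rendered as "No contribution" in the human-readable table).
#'
#' @param avail An `availability` object.
#' @param system The `food_system` the availability was computed from.
#' @param foods Character vector of commodity ids the report is about
#'   (ranks are computed for the first listed commodity when several are
#'   given; contributions aggregate the whole set).
#' @param density_method Passed to [density_rank()].
#' @return A tibble in the `contribution_report` schema.
#' @export
contribution_report <- function(avail, system, foods,
                                density_method = "weighted") {
  nuts <- nutriflow_nutrients$nutrient
  focal <- foods[1]
  rows <- lapply(nuts, function(n) {
    tot <- nutrient_totals(avail)[[n]]
    part <- nutrient_totals(avail, commodities = foods)[[n]]
    if (tot > 0) {
      pct <- 100 * part / tot
      cr <- rank_contributors(avail, n)
      crank <- cr$rank[match(focal, cr$commodity_id)]
      dr <- suppressWarnings(
        density_rank(system$composition, system$food_types, avail$masses, n,
                     method = density_method)
      )
      drank <- dr$rank[match(focal, dr$commodity_id)]
      dens <- dr$density[match(focal, dr$commodity_id)]
      if (part <= 0) {
        pct <- 0
      }
    } else {
      pct <- NA_real_; crank <- NA_real_; drank <- NA_real_; dens <- NA_real_
    }
    tibble::tibble(nutrient = n, total_bioavailable = tot,
                   contribution = part, percent_contribution = pct,
                   contribution_rank = as.numeric(crank),
                   density = as.numeric(dens),
                   density_rank = as.numeric(drank))
  })
  dplyr::bind_rows(rows)
}
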