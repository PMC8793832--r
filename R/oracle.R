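#' Independent ground-truth oracle for a food system
#'
#' Recomputes every pipeline quantity with deliberately naive, explicit
#' loops and hand-written least squares (normal equations), sharing no
#' helper code with the engine, so that it can serve as an independent
#' check of the availability, requirements and analytics computations. The
#' engine and this oracle must agree to 1e-9 relative on every quantity.
#'
#' @param system A `food_system`.
#' @param target_year Baseline target year.
#' @param window Number of most recent years used in the fit.
#' @param foods Optional focal commodity id (or vector); when given, the
#'   result carries that set's percent contributions, contribution and
#'   density ranks, per-capita mass and waste share.
#' @return A nested ground-truth list (see details in source).
#' @export
oracle_outputs <- function(system, target_year, window = 20, foods = NULL) {
  nuts <- c("carbohydrates", "energy", "fat", "fiber", "protein",
            "calcium", "copper", "folate", "iron", "magnesium",
            "phosphorus", "potassium", "selenium", "vitamin_a",
            "vitamin_b1", "vitamin_b2", "vitamin_b5", "vitamin_b6",
            "vitamin_b12", "vitamin_c", "vitamin_e", "zinc",
            "cystine", "histidine", "leucine", "lysine", "methionine",
            "threonine", "tryptophan")
  flagged <- c("protein", "cystine", "histidine", "leucine", "lysine",
               "methionine", "threonine", "tryptophan")

  com <- as.data.frame(system$commodities)
  ids <- sort(unique(com$commodity_id))

  # ordinary least squares by the normal equations, evaluated at the
  # target year; negative predictions clamp to zero
  ols_at <- function(x, y, at) {
    n <- length(x)
    sx <- 0; sy <- 0; sxx <- 0; sxy <- 0
    for (i in seq_len(n)) {
      sx <- sx + x[i]; sy <- sy + y[i]
      sxx <- sxx + x[i] * x[i]; sxy <- sxy + x[i] * y[i]
    }
    slope <- (n * sxy - sx * sy) / (n * sxx - sx * sx)
    intercept <- (sy - slope * sx) / n
    val <- intercept + slope * at
    if (val < 0) 0 else val
  }

  baseline <- list()
  group_of <- character(0)
  for (id in ids) {
    sub <- com[com$commodity_id == id, ]
    sub <- sub[order(sub$year), ]
    if (nrow(sub) > window) sub <- sub[(nrow(sub) - window + 1):nrow(sub), ]
    baseline[[id]] <- list(
      production_kt = ols_at(sub$year, sub$production_kt, target_year),
      food_supply_kt = ols_at(sub$year, sub$food_supply_kt, target_year),
      losses_kt = ols_at(sub$year, sub$losses_kt, target_year)
    )
    group_of[id] <- sub$primary_food_group[1]
  }

  # region-weighted mean in-home waste fraction per food group
  wt <- as.data.frame(system$waste)
  wbar <- list()
  for (g in unique(wt$food_group)) {
    num <- 0; den <- 0
    for (i in seq_len(nrow(wt))) {
      if (wt$food_group[i] == g) {
        num <- num + wt$region_weight[i] * wt$fraction[i]
        den <- den + wt$region_weight[i]
      }
    }
    wbar[[g]] <- num / den
  }

  ft <- as.data.frame(system$food_types)
  edible <- numeric(nrow(ft)); home_waste <- numeric(nrow(ft))
  names(edible) <- ft$food_type_id; names(home_waste) <- ft$food_type_id
  for (i in seq_len(nrow(ft))) {
    cid <- ft$commodity_id[i]
    pre <- baseline[[cid]]$food_supply_kt * ft$share[i] *
      ft$processing_yield[i] * (1 - ft$inedible_fraction[i])
    w <- wbar[[group_of[cid]]]
    edible[i] <- pre * (1 - w)
    home_waste[i] <- pre * w
  }

  comp <- as.data.frame(system$composition)
  comp_key <- paste(comp$food_type_id, comp$nutrient)
  bio <- as.data.frame(system$bioavailability)
  bio_key <- paste(bio$food_type_id, bio$nutrient)

  population <- 0
  dem <- as.data.frame(system$demographics)
  for (i in seq_len(nrow(dem))) population <- population + dem$population[i]

  available <- matrix(0, nrow(ft), length(nuts),
                      dimnames = list(ft$food_type_id, nuts))
  bioavailable <- available
  per_capita <- available
  for (i in seq_len(nrow(ft))) {
    for (j in seq_along(nuts)) {
      key <- paste(ft$food_type_id[i], nuts[j])
      amt <- comp$amount[match(key, comp_key)]
      av <- edible[i] * 1e9 / 100 * amt
      coef <- 1
      if (nuts[j] %in% flagged) {
        hit <- match(key, bio_key)
        if (!is.na(hit)) coef <- bio$coefficient[hit]
      }
      available[i, j] <- av
      bioavailable[i, j] <- av * coef
      per_capita[i, j] <- av * coef / population / 365
    }
  }

  nrv <- as.data.frame(system$nrv)
  nrv_key <- paste(nrv$age_band, nrv$sex, nrv$nutrient)
  targets <- list()
  for (j in seq_along(nuts)) {
    req <- 0
    for (g in seq_len(nrow(dem))) {
      key <- paste(dem$age_band[g], dem$sex[g], nuts[j])
      req <- req + dem$population[g] * nrv$amount[match(key, nrv_key)]
    }
    target <- req / population
    supply <- 0
    for (i in seq_len(nrow(ft))) supply <- supply + per_capita[i, j]
    targets[[nuts[j]]] <- list(
      global_requirement = req, per_capita_target = target,
      adequacy_ratio = if (target > 0) supply / target else Inf
    )
  }

  # commodity-level bioavailable totals per nutrient
  by_commodity <- matrix(0, length(ids), length(nuts),
                         dimnames = list(ids, nuts))
  for (i in seq_len(nrow(ft))) {
    for (j in seq_along(nuts)) {
      by_commodity[ft$commodity_id[i], j] <-
        by_commodity[ft$commodity_id[i], j] + bioavailable[i, j]
    }
  }
  totals <- numeric(length(nuts)); names(totals) <- nuts
  for (j in seq_along(nuts)) {
    for (id in ids) totals[j] <- totals[j] + by_commodity[id, j]
  }

  out <- list(
    target_year = target_year, window = window, population = population,
    baseline = baseline,
    edible_kt = as.list(edible), home_waste_kt = as.list(home_waste),
    available = available, bioavailable = bioavailable,
    per_capita = per_capita, totals = as.list(totals), targets = targets,
    by_commodity = by_commodity
  )

  if (!is.null(foods)) {
    focal <- foods[1]
    percent <- list(); crank <- list(); density <- list(); drank <- list()
    # commodity densities: pre-waste-mass-weighted mean of food-type content
    dens_mat <- matrix(NA_real_, length(ids), length(nuts),
                       dimnames = list(ids, nuts))
    for (id in ids) {
      rows <- which(ft$commodity_id == id)
      wsum <- 0
      for (i in rows) wsum <- wsum + edible[i] + home_waste[i]
      if (wsum > 0) {
        for (j in seq_along(nuts)) {
          acc <- 0
          for (i in rows) {
            amt <- comp$amount[match(paste(ft$food_type_id[i], nuts[j]),
                                     comp_key)]
            acc <- acc + (edible[i] + home_waste[i]) * amt
          }
          dens_mat[id, j] <- acc / wsum
        }
      }
    }
    for (j in seq_along(nuts)) {
      n <- nuts[j]
      part <- 0
      for (id in foods) part <- part + by_commodity[id, j]
      if (totals[j] > 0) {
        percent[[n]] <- 100 * part / totals[j]
        r <- 1
        for (id in ids) {
          if (by_commodity[id, j] > by_commodity[focal, j]) r <- r + 1
        }
        crank[[n]] <- r
        density[[n]] <- dens_mat[focal, j]
        r <- 1
        for (id in ids) {
          if (!is.na(dens_mat[id, j]) &&
              dens_mat[id, j] > dens_mat[focal, j]) r <- r + 1
        }
        drank[[n]] <- r
      } else {
        percent[[n]] <- NA; crank[[n]] <- NA
        density[[n]] <- dens_mat[focal, j]; drank[[n]] <- NA
      }
    }
    mass <- 0
    for (i in seq_len(nrow(ft))) {
      if (ft$commodity_id[i] %in% foods) mass <- mass + edible[i]
    }
    hw <- 0
    for (i in seq_len(nrow(ft))) {
      if (ft$commodity_id[i] == focal) hw <- hw + home_waste[i]
    }
    out$focal <- list(
      foods = foods,
      percent = percent, contribution_rank = crank,
      density = density, density_rank = drank,
      per_capita_mass_g = mass * 1e9 / population / 365,
      waste_share_pct = 100 * (baseline[[focal]]$losses_kt + hw) /
        baseline[[focal]]$production_kt
    )
  }
  out
}
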