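#' Define a production/waste scenario
#'
#' A scenario operates at the level of the 15 primary food groups: each
#' group may be given either a production `multiplier` (scale factor >= 0)
#' or an absolute production `value` in kt/yr, from which the scale factor
#' is the ratio to the baseline group production. All of a group's
#' commodities are scaled uniformly; the scenario never changes
#' composition, bioavailability coefficients, reference values or
#' demographics. Optional overrides replace the supply-chain-loss fraction
#' (losses as a share of production) and/or the global in-home waste
#' fraction.
#'
#' @param groups Named list, one element per food group, each a list with
#'   either `multiplier` or `value` (kt/yr).
#' @param loss_fraction Optional override in \[0, 1\]: supply-chain losses
#'   become this fraction of production, and food supply absorbs the
#'   difference.
#' @param in_home_waste Optional override in \[0, 1\] replacing the weighted
#'   mean in-home waste fraction for all food groups.
#' @param label Free-text scenario label.
#' @return A `scenario` object.
#' @export
#' @examples
#' scenario(groups = list(dairy = list(multiplier = 2)), label = "double dairy")
scenario <- function(groups = list(), loss_fraction = NULL,
                     in_home_waste = NULL, label = "") {
  for (g in names(groups)) {
    spec <- groups[[g]]
    has_mult <- !is.null(spec$multiplier)
    has_val <- !is.null(spec$value)
    if (has_mult == has_val) {
      stop_schema(sprintf("group '%s': give exactly one of multiplier or value", g))
    }
    x <- if (has_mult) spec$multiplier else spec$value
    if (!is.numeric(x) || length(x) != 1 || x < 0) {
      stop_schema(sprintf("group '%s': multiplier/value must be a single number >= 0", g))
    }
  }
  for (ov in list(loss_fraction = loss_fraction, in_home_waste = in_home_waste)) {
    if (!is.null(ov) && (!is.numeric(ov) || ov < 0 || ov > 1)) {
      stop_schema("waste overrides must lie in [0, 1]")
    }
  }
  structure(list(groups = groups, loss_fraction = loss_fraction,
                 in_home_waste = in_home_waste, label = label),
            class = "scenario")
}

#' Read a scenario from a YAML or JSON file
#'
#' Expected layout:
#' \preformatted{label: double dairy
#' groups:
#'   dairy: {multiplier: 2.0}
#'   cereals: {value: 950000}
#' waste:
#'   loss_fraction: 0.05
#'   in_home: 0.05}
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` scenario file.
#' @return A `scenario` object.
#' @export
read_scenario <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  scenario(groups = if (is.null(raw$groups)) list() else raw$groups,
           loss_fraction = raw$waste$loss_fraction,
           in_home_waste = raw$waste$in_home,
           label = if (is.null(raw$label)) "" else raw$label)
}

#' Apply a scenario to a baseline
#'
#' Each named group's scale factor (multiplier, or absolute value divided
#' by the group's baseline production) multiplies the production, food
#' supply and losses of every commodity in the group; unnamed groups are
#' unchanged, so downstream results change in exact proportion. A loss
#' override then resets losses to the given fraction of (scaled)
#' production, moving the difference into food supply (clamped at zero).
#'
#' @param baseline A `baseline` tibble.
#' @param scn A `scenario` object.
#' @return A new `baseline` tibble with the scenario applied; the in-home
#'   waste override, if any, is carried in attribute `waste_override` for
#'   [compute_availability()].
#' @export
apply_scenario <- function(baseline, scn) {
  stopifnot(inherits(scn, "scenario"))
  out <- baseline
  for (g in names(scn$groups)) {
    idx <- out$primary_food_group == g
    if (!any(idx)) stop_schema(sprintf("unknown food group '%s'", g))
    spec <- scn$groups[[g]]
    k <- if (!is.null(spec$multiplier)) {
      spec$multiplier
    } else {
      base_prod <- sum(out$production_kt[idx])
      if (base_prod <= 0) {
        stop_schema(sprintf(
          "group '%s' has zero baseline production; use a multiplier", g))
      }
      spec$value / base_prod
    }
    for (q in c("production_kt", "food_supply_kt", "losses_kt")) {
      out[[q]][idx] <- out[[q]][idx] * k
    }
  }
  if (!is.null(scn$loss_fraction)) {
    new_losses <- scn$loss_fraction * out$production_kt
    out$food_supply_kt <- pmax(out$food_supply_kt + out$losses_kt - new_losses, 0)
    out$losses_kt <- new_losses
  }
  attr(out, "waste_override") <- scn$in_home_waste
  out
}

#' Production scale needed to close a nutrient gap
#'
#' Solves, in closed form, for the factor `k` by which one food group's
#' production must be scaled so that the global per-capita bioavailable
#' supply of a nutrient meets its target:
#' \deqn{k = (T - S_{others}) / S_{group}}
#' where `T` is the per-capita target and `S` the per-capita supplies. The
#' solution is verified by re-running the adequacy computation at `k`.
#'
#' @param system A `food_system`.
#' @param avail The baseline `availability` for `system`.
#' @param targets Targets from [compute_targets()].
#' @param group A primary food group.
#' @param nutrient A nutrient id.
#' @return List with `k` (the multiplier; `Inf` if the group contributes
#'   nothing and others fall short), `no_deficit` (`TRUE` with `k <= 1`
#'   when adequacy is already >= 1) and `adequacy_at_k` (re-evaluated
#'   ratio).
#' @export
solve_required_scale <- function(system, avail, targets, group, nutrient) {
  t_row <- targets[targets$nutrient == nutrient, ]
  target <- t_row$per_capita_target
  group_commodities <- unique(
    avail$baseline$commodity_id[avail$baseline$primary_food_group == group])
  if (!length(group_commodities)) {
    stop_schema(sprintf("unknown food group '%s'", group))
  }
  supply_all <- nutrient_totals(avail, field = "per_capita_daily")[[nutrient]]
  supply_group <- nutrient_totals(avail, commodities = group_commodities,
                                  field = "per_capita_daily")[[nutrient]]
  if (supply_group <= 0) {
    stop_schema(sprintf("group '%s' contributes nothing to %s", group, nutrient))
  }
  supply_others <- supply_all - supply_group
  k <- (target - supply_others) / supply_group
  no_deficit <- supply_all >= target
  scn <- scenario(groups = stats::setNames(list(list(multiplier = max(k, 0))),
                                           group))
  scaled <- apply_scenario(avail$baseline, scn)
  avail_k <- compute_availability(system, baseline = scaled)
  adequacy_k <- adequacy(avail_k, targets)
  list(k = k, no_deficit = no_deficit,
       adequacy_at_k = adequacy_k$adequacy_ratio[adequacy_k$nutrient == nutrient])
}
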