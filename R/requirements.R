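#' Global daily requirement for a nutrient
#'
#' Couples demographic counts with nutrient reference values:
#' \deqn{R_n = \sum_g pop_g \times nrv_{g,n}}
#'
#' @param demographics Demographic table (`age_band`, `sex`, `population`).
#' @param nrv Nutrient reference values in canonical units
#'   (`age_band`, `sex`, `nutrient`, `amount`).
#' @param nutrient Nutrient id (or vector of ids).
#' @return Named numeric vector of global requirements (canonical unit/day).
#' @export
global_requirement <- function(demographics, nrv, nutrient) {
  vapply(nutrient, function(n) {
    sub <- nrv[nrv$nutrient == n, ]
    idx <- match(paste(demographics$age_band, demographics$sex),
                 paste(sub$age_band, sub$sex))
    if (anyNA(idx)) {
      g <- which(is.na(idx))[1]
      stop_schema(sprintf("no reference value for group (%s, %s), nutrient '%s'",
                          demographics$age_band[g], demographics$sex[g], n),
                  table = "nrv")
    }
    sum(demographics$population * sub$amount[idx])
  }, numeric(1))
}

#' Per-capita daily target intake
#'
#' @param requirement Global daily requirement(s) from [global_requirement()].
#' @param demographics Demographic table; its total population divides the
#'   requirement.
#' @return Target intake per person per day, same shape as `requirement`.
#' @export
per_capita_target <- function(requirement, demographics) {
  pop <- sum(demographics$population)
  if (!isTRUE(pop > 0)) stop_schema("total population must be positive")
  requirement / pop
}

#' Global targets for all 29 nutrients
#'
#' @param demographics Demographic table.
#' @param nrv Nutrient reference value table in canonical units.
#' @return Tibble with columns `nutrient`, `global_requirement`
#'   (canonical unit/day) and `per_capita_target`
#'   (canonical unit/person/day).
#' @export
compute_targets <- function(demographics, nrv) {
  nuts <- nutriflow_nutrients$nutrient
  req <- global_requirement(demographics, nrv, nuts)
  tibble::tibble(
    nutrient = nuts,
    global_requirement = unname(req),
    per_capita_target = unname(per_capita_target(req, demographics))
  )
}

#' Adequacy of supply against target intakes
#'
#' The adequacy ratio is total per-capita bioavailable supply divided by
#' the per-capita target; nutrients with ratio below 1 are flagged
#' undersupplied. A zero target is reported as `Inf` (trivially adequate).
#'
#' @param avail An `availability` object from [compute_availability()].
#' @param targets Tibble from [compute_targets()].
#' @return `targets` with added columns `supply` (per-capita daily
#'   bioavailable), `adequacy_ratio`, and `undersupplied` (logical).
#' @export
adequacy <- function(avail, targets) {
  supply <- nutrient_totals(avail, field = "per_capita_daily")
  out <- targets
  out$supply <- unname(supply[out$nutrient])
  out$adequacy_ratio <- ifelse(out$per_capita_target > 0,
                               out$supply / out$per_capita_target, Inf)
  out$undersupplied <- out$adequacy_ratio < 1
  out
}
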