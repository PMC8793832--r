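#' Fit the baseline food system from commodity time series
#'
#' Each commodity's production, food supply and supply-chain losses are
#' represented at the target year by an ordinary least-squares linear trend
#' fitted to the most recent `window` annual observations (default 20) and
#' evaluated at `target_year`. A trend over the full window is the only
#' reading of the series that uses every observation; the alternative,
#' carrying forward the most recent observation, is available as
#' `method = "last_value"`. Negative fitted values (possible for steeply
#' declining series extrapolated forward) are clamped to zero with a
#' warning.
#'
#' @param commodities A `commodities` tibble (one row per commodity-year).
#' @param target_year Calendar year the baseline represents.
#' @param window Number of most recent years used in the fit (default 20).
#' @param method `"trend"` (least-squares line evaluated at `target_year`)
#'   or `"last_value"` (most recent observation carried forward).
#' @return A `baseline` tibble with one row per commodity and columns
#'   `commodity_id`, `name`, `primary_food_group`, `production_kt`,
#'   `food_supply_kt`, `losses_kt`; attributes `target_year` and `window`.
#' @export
#' @examples
#' series <- tibble::tibble(
#'   commodity_id = "c1", name = "wheat", primary_food_group = "cereals",
#'   year = 1999:2018, production_kt = 2 * (1999:2018 - 1999),
#'   food_supply_kt = 1.5 * (1999:2018 - 1999),
#'   losses_kt = 0.1 * (1999:2018 - 1999)
#' )
#' fit_baseline(series, target_year = 2018)
fit_baseline <- function(commodities, target_year, window = 20,
                         method = c("trend", "last_value")) {
  method <- match.arg(method)
  quantities <- c("production_kt", "food_supply_kt", "losses_kt")
  fit_one <- function(sub) {
    sub <- sub[order(sub$year), ]
    sub <- utils::tail(sub, window)
    if (method == "trend" && nrow(sub) < 2) {
      stop_schema(sprintf("commodity '%s': need >= 2 years in window, have %d",
                          sub$commodity_id[1], nrow(sub)),
                  table = "commodities")
    }
    est <- vapply(quantities, function(q) {
      if (method == "last_value") return(sub[[q]][nrow(sub)])
      fit <- stats::lm(y ~ year, data = data.frame(year = sub$year, y = sub[[q]]))
      unname(stats::predict(fit, newdata = data.frame(year = target_year)))
    }, numeric(1))
    tibble::tibble(
      commodity_id = sub$commodity_id[1], name = sub$name[1],
      primary_food_group = sub$primary_food_group[1],
      production_kt = est[["production_kt"]],
      food_supply_kt = est[["food_supply_kt"]],
      losses_kt = est[["losses_kt"]]
    )
  }
  out <- dplyr::bind_rows(lapply(split(commodities, commodities$commodity_id),
                                 fit_one))
  out <- out[order(out$commodity_id), ]
  neg <- c(out$production_kt, out$food_supply_kt, out$losses_kt) < 0
  if (any(neg)) {
    warning(sprintf("%d negative fitted baseline value(s) clamped to 0",
                    sum(neg)), call. = FALSE)
    for (q in quantities) out[[q]] <- pmax(out[[q]], 0)
  }
  structure(out, target_year = target_year, window = window,
            baseline_method = method, class = c("baseline", class(out)))
}
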