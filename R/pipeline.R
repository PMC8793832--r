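#' Run the full availability pipeline end to end
#'
#' Executes baseline fitting, commodity subdivision, waste deduction,
#' composition conversion, bioavailability adjustment, per-capita scaling,
#' target computation, adequacy, and the contribution report, optionally
#' under a scenario, and (if `output_dir` is given) writes
#' `availability.csv`, `targets.csv`, `contribution_report.csv` and a
#' `run_manifest.json` with a hash of the configuration. Identical inputs
#' and configuration produce byte-identical outputs.
#'
#' @param system A `food_system`, or a directory containing the seven input
#'   CSVs.
#' @param target_year Baseline target year; defaults to the last data year.
#' @param window Fitting window in years (default 20).
#' @param baseline_method `"trend"` or `"last_value"`.
#' @param scn Optional [scenario()] object or path to a scenario YAML/JSON.
#' @param report_foods Commodity id(s) the contribution report focuses on;
#'   defaults to `"milk"` when present, else the first commodity.
#' @param output_dir Optional directory to write outputs into.
#' @return List with `availability`, `targets` (with adequacy columns),
#'   `report`, `baseline`, and `population`.
#' @export
run_pipeline <- function(system, target_year = NULL, window = 20,
                         baseline_method = "trend", scn = NULL,
                         report_foods = NULL, output_dir = NULL) {
  if (is.character(system)) system <- read_food_system(system)
  if (is.character(scn)) scn <- read_scenario(scn)
  if (is.null(target_year)) target_year <- max(system$commodities$year)

  baseline <- fit_baseline(system$commodities, target_year, window,
                           baseline_method)
  waste_override <- NULL
  if (!is.null(scn)) {
    baseline <- apply_scenario(baseline, scn)
    waste_override <- attr(baseline, "waste_override")
  }
  avail <- compute_availability(system, baseline = baseline,
                                waste_override = waste_override)
  targets <- adequacy(avail, compute_targets(system$demographics, system$nrv))

  if (is.null(report_foods)) {
    cand <- unique(system$commodities$commodity_id)
    report_foods <- if ("milk" %in% cand) "milk" else sort(cand)[1]
  }
  report <- contribution_report(avail, system, report_foods)

  result <- list(availability = avail, targets = targets, report = report,
                 baseline = baseline, population = avail$population)

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_table(avail$values, file.path(output_dir, "availability.csv"),
                "availability")
    write_table(
      targets[c("nutrient", "global_requirement", "per_capita_target",
                "adequacy_ratio", "undersupplied")],
      file.path(output_dir, "targets.csv"), "targets")
    write_report(report, file.path(output_dir, "contribution_report.csv"))
    manifest <- list(
      target_year = target_year, window = window,
      baseline_method = baseline_method,
      scenario = if (is.null(scn)) NULL else scn[c("groups", "label")],
      report_foods = report_foods,
      config_hash = rlang::hash(list(target_year, window, baseline_method,
                                     scn, report_foods))
    )
    jsonlite::write_json(manifest, file.path(output_dir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}

# ordinal strings: 1st, 2nd, 3rd, 4th, ..., 11th-13th are all "th"
ordinal <- function(n) {
  suffix <- function(k) {
    if (k %% 100 %in% 11:13) return("th")
    switch(as.character(k %% 10), "1" = "st", "2" = "nd", "3" = "rd", "th")
  }
  vapply(n, function(k) paste0(k, suffix(k)), character(1))
}

# half-up rounding for printed integer percents
round_half_up <- function(x) floor(x + 0.5)

#' Render a contribution report as a human-readable text table
#'
#' Rows are grouped into macronutrients, micronutrients and indispensable
#' amino acids; percentages print as half-up-rounded integers and ranks as
#' ordinals ("3rd"); nutrients the system does not supply print
#' "No contribution" in both rank columns.
#'
#' @param report Tibble from [contribution_report()].
#' @param food Label for the focal food in the header.
#' @return Character vector of table lines (also printed invisibly via
#'   `cat` when `print = TRUE`).
#' @param print Print the lines to the console.
#' @export
render_table1 <- function(report, food = "milk", print = FALSE) {
  tab <- nutriflow_nutrients
  classes <- c(macronutrient = "Macronutrients",
               micronutrient = "Micronutrients",
               amino_acid = "Indispensable amino acids (bioavailability included)")
  header <- sprintf("Contribution of %s to global nutrient availability", food)
  widths <- c(18, 12, 20, 20)
  fmt_row <- function(cells) {
    paste(mapply(function(s, w) formatC(s, width = -w), cells, widths),
          collapse = "  ")
  }
  lines <- c(header,
             fmt_row(c("Nutrient", "% of global", "Contribution rank",
                       "Density rank")))
  for (cl in names(classes)) {
    lines <- c(lines, paste0("-- ", classes[[cl]]))
    for (n in tab$nutrient[tab$class == cl]) {
      r <- report[report$nutrient == n, ]
      if (is.na(r$percent_contribution) ||
          (r$contribution == 0 && r$percent_contribution == 0)) {
        pct <- if (is.na(r$percent_contribution)) "No contribution" else "0"
        cr <- "No contribution"
        dr <- "No contribution"
      } else {
        pct <- sprintf("%d", round_half_up(r$percent_contribution))
        cr <- ordinal(r$contribution_rank)
        dr <- ordinal(r$density_rank)
      }
      lines <- c(lines, fmt_row(c(n, pct, cr, dr)))
    }
  }
  if (print) cat(lines, sep = "\n")
  invisible(lines)
}
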