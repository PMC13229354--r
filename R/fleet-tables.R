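#' Published reference summaries of the Portuguese multi-gear coastal fleet
#'
#' Two small reference tables for the 2014-2023 study period of the
#' Portuguese multi-gear coastal fleet (roughly 150 electronically logged
#' vessels), shipped with the package:
#'
#' * `fleet_gear_summary()`: per main gear, the number of potential metiers
#'   and of vessels, trips and valid hauls. Gear totals sum to the fleet's
#'   197,081 valid hauls and 307 potential metiers (vessels and trips do
#'   not sum — vessels use several gears and trips hold several hauls).
#' * `fleet_metier_summary()`: the 37 leading metiers with haul counts,
#'   selectivity detail, dominant season/area/depth/sediment and their
#'   validation status (literature / onboard / interview / unvalidated).
#'
#' They serve as the reference input for the selection-accounting checks
#' and as a worked example of the reporting format.
#'
#' @return A tibble.
#' @export
fleet_gear_summary <- function() {
  readr::read_csv(system.file("extdata", "fleet_gear_summary.csv",
                              package = "metierid", mustWork = TRUE),
                  show_col_types = FALSE, progress = FALSE)
}

#' @rdname fleet_gear_summary
#' @export
fleet_metier_summary <- function() {
  readr::read_csv(system.file("extdata", "fleet_metier_summary.csv",
                              package = "metierid", mustWork = TRUE),
                  show_col_types = FALSE, progress = FALSE)
}

#' Fleet-level totals from a per-gear summary table
#'
#' The ranking/accounting step that reconciles per-gear tables with fleet
#' totals: potential metiers and hauls are additive across gears.
#'
#' @param gear_summary a tibble like [fleet_gear_summary()].
#' @return List with `total_metiers` and `total_hauls`.
#' @export
gear_summary_totals <- function(gear_summary) {
  list(total_metiers = sum(gear_summary$n_metiers),
       total_hauls = sum(gear_summary$n_hauls))
}
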