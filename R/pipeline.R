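#' Run the metier-identification pipeline end to end
#'
#' Convenience wrapper chaining quality control ([run_qc()]), annotation
#' ([annotate_hauls()]), value-based target attribution and metier keying
#' ([assign_metiers()]), ranking ([rank_metiers()]) and rank-frequency
#' selection ([select_metiers()]). The per-metier statistical
#' characterization is a separate step ([characterize_metiers()],
#' [summary_report()]) because it is usually run only on the selected
#' metiers.
#'
#' @param hauls,catches,sales logbook and sales data ([read_logbook()],
#'   [read_sales()] or [generate_records()]).
#' @param env list with `depth` and `sediment` [env_grid()]s.
#' @param area_cfg an [area_config()].
#' @param weight_tolerance,mainland_ports passed to [run_qc()].
#' @param alias optional species alias table for [assign_metiers()].
#' @param validation optional validation table for [select_metiers()].
#' @param max_rank passed to [detect_cutoff()].
#' @param n_years study-period length; defaults to the span of years
#'   observed in the valid hauls.
#' @return List: `qc` (the [run_qc()] result), `annotated` (valid hauls
#'   with annotation and metier assignment), `ranked`, `selection`.
#' @export
identify_metiers <- function(hauls, catches, sales, env,
                             area_cfg = area_config(),
                             weight_tolerance = 1, mainland_ports = NULL,
                             alias = NULL, validation = NULL,
                             max_rank = 20, n_years = NULL) {
  qc <- run_qc(hauls, catches, sales, env$depth,
               mainland_ports = mainland_ports,
               weight_tolerance = weight_tolerance)
  assigned <- assign_metiers(qc$valid_hauls, qc$valid_catches, sales,
                             alias = alias)
  annotated <- annotate_hauls(assigned, env$depth, env$sediment, area_cfg)
  ranked <- rank_metiers(annotated)
  if (is.null(n_years)) {
    yrs <- as.integer(format(annotated$set_time, "%Y"))
    n_years <- max(yrs) - min(yrs) + 1L
  }
  selection <- select_metiers(ranked, validation = validation,
                              max_rank = max_rank, n_years = n_years)
  list(qc = qc, annotated = annotated, ranked = ranked,
       selection = selection)
}
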