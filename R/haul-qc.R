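#' Quality-control rule identifiers
#'
#' The seven exclusion rules applied to haul records, in report order:
#' hauls outside FAO subarea 27.9; depths beyond 2000 m (outside the
#' fleet's operating range); trips not departing from and returning to a
#' mainland port; miscellaneous (non-main) gear; zero catches; landing
#' price unavailable; and abnormally high reported weights relative to the
#' trip's sold weight.
#'
#' @return Character vector of rule names.
#' @export
qc_rules <- function() {
  c("outside_subarea", "depth_gt_2000", "non_mainland_trip", "misc_gear",
    "zero_catch", "missing_price", "inflated_weight")
}

#' Run the haul exclusion rules and produce an auditable report
#'
#' Every rule is evaluated for every haul (no short-circuiting), so the
#' report lists all violated rules per haul even though a haul is removed
#' only once. Rule semantics:
#' * `outside_subarea`: `fao_subarea != "27.9"`.
#' * `depth_gt_2000`: bathymetry at the haul midpoint exceeds 2000 m.
#'   Midpoints on nodata or outside the grid are *not* removed by this rule
#'   (depth cannot be asserted).
#' * `non_mainland_trip`: the trip's departure or return port is not on the
#'   mainland.
#' * `misc_gear`: gear code outside [main_gear_codes()].
#' * `zero_catch`: empty catch list.
#' * `missing_price`: a caught species has no price in the trip's sales
#'   note.
#' * `inflated_weight`: for some species, the summed logbook weight over
#'   the trip's hauls exceeds `weight_tolerance` times the sold weight;
#'   all hauls of the trip containing that species are flagged.
#'
#' @param hauls,catches tibbles as produced by [read_logbook()] or
#'   [generate_records()].
#' @param sales list with `notes` and `lines` as produced by [read_sales()]
#'   or [generate_records()].
#' @param depth_grid bathymetry [env_grid()].
#' @param mainland_ports optional character set of mainland port codes;
#'   when `NULL` the `dep_mainland` / `ret_mainland` flags carried by the
#'   sales notes are used.
#' @param weight_tolerance factor >= 1 applied to the sold weight before a
#'   logbook weight counts as abnormally high.
#' @return List with `valid_hauls`, `valid_catches` and `report` (class
#'   `qc_report`): input/removed counts, per-rule violation counts, the
#'   removed fraction, the same accounting restricted to hauls already
#'   inside subarea 27.9, and the per-haul violation table.
#' @export
run_qc <- function(hauls, catches, sales, depth_grid,
                   mainland_ports = NULL, weight_tolerance = 1) {
  stopifnot(weight_tolerance >= 1)
  notes <- sales$notes
  orphans <- setdiff(unique(hauls$trip_id), notes$trip_id)
  if (length(orphans)) {
    stop("haul(s) reference trip(s) without a sales note: ",
         paste(utils::head(orphans, 10), collapse = ", "), call. = FALSE)
  }

  viol <- list()
  note_rule <- function(ids, rule) {
    if (length(ids)) {
      viol[[rule]] <<- tibble::tibble(haul_id = ids, rule = rule)
    }
  }

  note_rule(hauls$haul_id[hauls$fao_subarea != "27.9"], "outside_subarea")

  mid <- midpoint(hauls)
  d <- sample_grid(depth_grid, mid$mid_lon, mid$mid_lat)
  note_rule(hauls$haul_id[d$status == "ok" & !is.na(d$value) &
                            d$value > 2000], "depth_gt_2000")

  if (is.null(mainland_ports)) {
    bad_trip <- notes$trip_id[!notes$dep_mainland | !notes$ret_mainland]
  } else {
    bad_trip <- notes$trip_id[!(notes$departure_port %in% mainland_ports) |
                                !(notes$return_port %in% mainland_ports)]
  }
  note_rule(hauls$haul_id[hauls$trip_id %in% bad_trip], "non_mainland_trip")

  note_rule(hauls$haul_id[!hauls$gear_code %in% main_gear_codes()],
            "misc_gear")

  has_catch <- hauls$haul_id %in%
    catches$haul_id[!is.na(catches$weight_kg) & catches$weight_kg > 0]
  note_rule(hauls$haul_id[!has_catch], "zero_catch")

  cat_trip <- dplyr::left_join(
    catches, hauls[, c("haul_id", "trip_id")], by = "haul_id")
  priced <- dplyr::left_join(
    cat_trip, sales$lines[, c("trip_id", "species", "sold_weight_kg")],
    by = c("trip_id", "species"))
  note_rule(unique(priced$haul_id[is.na(priced$sold_weight_kg)]),
            "missing_price")

  trip_sum <- dplyr::summarise(
    priced, logbook_kg = sum(.data$weight_kg),
    sold_kg = .data$sold_weight_kg[1],
    .by = c("trip_id", "species"))
  over <- trip_sum[!is.na(trip_sum$sold_kg) &
                     trip_sum$logbook_kg >
                       weight_tolerance * trip_sum$sold_kg, ]
  flagged <- dplyr::semi_join(priced, over, by = c("trip_id", "species"))
  note_rule(unique(flagged$haul_id), "inflated_weight")

  violations <- dplyr::bind_rows(viol)
  if (!nrow(violations)) {
    violations <- tibble::tibble(haul_id = character(), rule = character())
  }
  removed_ids <- unique(violations$haul_id)
  valid <- !(hauls$haul_id %in% removed_ids)

  in_sub <- hauls$fao_subarea == "27.9"
  removed_in_sub <- sum(!valid & in_sub)
  rule_counts <- vapply(qc_rules(), function(r) {
    sum(violations$rule == r)
  }, integer(1))

  report <- structure(list(
    n_input = nrow(hauls),
    rule_counts = rule_counts,
    n_removed = length(removed_ids),
    removed_fraction = length(removed_ids) / nrow(hauls),
    n_input_in_subarea = sum(in_sub),
    n_removed_in_subarea = removed_in_sub,
    removed_fraction_in_subarea =
      if (sum(in_sub)) removed_in_sub / sum(in_sub) else NA_real_,
    weight_tolerance = weight_tolerance,
    violations = dplyr::arrange(violations, .data$haul_id, .data$rule)
  ), class = "qc_report")

  list(valid_hauls = hauls[valid, ],
       valid_catches = catches[catches$haul_id %in% hauls$haul_id[valid], ],
       report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d hauls in, %d removed (%.2f%%)\n",
              x$n_input, x$n_removed, 100 * x$removed_fraction))
  for (r in names(x$rule_counts)) {
    cat(sprintf("  %-18s %d\n", r, x$rule_counts[[r]]))
  }
  cat(sprintf("  within subarea 27.9: %d in, %d removed (%.2f%%)\n",
              x$n_input_in_subarea, x$n_removed_in_subarea,
              100 * x$removed_fraction_in_subarea))
  invisible(x)
}
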