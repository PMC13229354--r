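#' Rank potential metiers within each gear by haul count
#'
#' @param assigned hauls with a `metier` column ([assign_metiers()]).
#' @return Tibble (gear_code, metier, n_hauls, n_vessels, n_trips, rank)
#'   sorted within gear by descending haul count, ties by descending vessel
#'   count then label.
#' @export
rank_metiers <- function(assigned) {
  tab <- dplyr::summarise(
    assigned,
    n_hauls = dplyr::n(),
    n_vessels = dplyr::n_distinct(.data$vessel_id),
    n_trips = dplyr::n_distinct(.data$trip_id),
    .by = c("gear_code", "metier"))
  tab <- dplyr::arrange(tab, .data$gear_code, dplyr::desc(.data$n_hauls),
                        dplyr::desc(.data$n_vessels), .data$metier)
  dplyr::mutate(tab, rank = dplyr::row_number(), .by = "gear_code")
}

#' Rank-frequency cutoff: maximum distance to the chord
#'
#' A reproducible replacement for choosing the cutoff by eye on the
#' rank-frequency bar graph. The ranked counts are truncated to the first
#' `max_rank` ranks, both axes are min-max normalized, and the knee is the
#' rank with the greatest perpendicular distance to the chord joining the
#' first and last points of the truncated curve. Ties take the larger rank.
#' Degenerate cases: a flat curve (all counts equal) keeps everything; a
#' single metier keeps it (every gear retains at least one metier).
#'
#' @param counts numeric vector of haul counts, sorted descending.
#' @param max_rank ranks beyond this are ignored when locating the knee.
#' @return The rank index `k`; ranks `1..k` are kept.
#' @export
detect_cutoff <- function(counts, max_rank = 20) {
  n <- length(counts)
  if (n == 0) stop("no metiers to rank", call. = FALSE)
  if (n == 1) return(1L)
  if (any(diff(counts) > 0)) {
    stop("`counts` must be sorted in descending order", call. = FALSE)
  }
  r <- min(n, max_rank)
  c_r <- counts[seq_len(r)]
  if (c_r[1] == c_r[r]) return(n)  # flat curve: no knee, keep all
  x <- (seq_len(r) - 1) / (r - 1)
  y <- (c_r - c_r[r]) / (c_r[1] - c_r[r])
  # perpendicular distance to the chord from (0, 1) to (1, 0)
  d <- abs(x + y - 1) / sqrt(2)
  k <- max(which(d > max(d) - 1e-12))  # ties resolved to the larger rank
  as.integer(k)
}

#' Selection accounting for the excluded metiers
#'
#' Given the fleet totals and the haul counts of the selected metiers,
#' computes what the exclusion amounts to: how many potential metiers were
#' left out, the share of valid hauls they carry, and their mean number of
#' hauls per metier per year.
#'
#' @param total_hauls total number of valid hauls.
#' @param total_metiers total number of potential metiers.
#' @param selected_counts haul counts of the selected metiers.
#' @param n_years number of years in the study period.
#' @return List: `n_selected`, `n_excluded`, `excluded_hauls`,
#'   `excluded_share` (fraction), `excluded_share_pct` (rounded integer
#'   percent), `mean_excluded_per_metier_year`.
#' @export
selection_accounting <- function(total_hauls, total_metiers,
                                 selected_counts, n_years) {
  n_sel <- length(selected_counts)
  n_exc <- total_metiers - n_sel
  exc_hauls <- total_hauls - sum(selected_counts)
  stopifnot(n_exc >= 0, exc_hauls >= 0)
  list(
    n_selected = n_sel,
    n_excluded = n_exc,
    excluded_hauls = exc_hauls,
    excluded_share = exc_hauls / total_hauls,
    excluded_share_pct = round(100 * exc_hauls / total_hauls),
    mean_excluded_per_metier_year =
      if (n_exc > 0) exc_hauls / (n_exc * n_years) else 0
  )
}

#' Select the important metiers per gear and report the exclusion
#'
#' Applies [detect_cutoff()] within each gear of a [rank_metiers()] table
#' and merges an optional external validation table (validation is user
#' input — literature, on-board observation, interviews — never computed).
#'
#' @param ranked a [rank_metiers()] table.
#' @param validation optional tibble (`metier`, `status`, `source`) with
#'   `status` in literature/onboard/interview/unvalidated. Unknown metiers
#'   in it raise a warning.
#' @param max_rank passed to [detect_cutoff()].
#' @param n_years study-period length for the exclusion accounting.
#' @return List of class `metier_selection`: `table` (ranked table with
#'   `selected` flag and validation columns) and `summary`
#'   ([selection_accounting()] output plus per-gear cutoffs).
#' @export
select_metiers <- function(ranked, validation = NULL, max_rank = 20,
                           n_years = 10) {
  cut <- ranked |>
    dplyr::summarise(k = detect_cutoff(.data$n_hauls, max_rank),
                     .by = "gear_code")
  tab <- dplyr::left_join(ranked, cut, by = "gear_code")
  tab$selected <- tab$rank <= tab$k
  tab$k <- NULL
  tab$status <- NA_character_
  tab$source <- NA_character_
  if (!is.null(validation)) {
    unknown <- setdiff(validation$metier, tab$metier)
    if (length(unknown)) {
      warning("validation table mentions unknown metier(s): ",
              paste(utils::head(unknown, 5), collapse = ", "))
    }
    i <- match(tab$metier, validation$metier)
    tab$status <- validation$status[i]
    if ("source" %in% names(validation)) {
      tab$source <- validation$source[i]
    }
  }
  acc <- selection_accounting(
    total_hauls = sum(tab$n_hauls),
    total_metiers = nrow(tab),
    selected_counts = tab$n_hauls[tab$selected],
    n_years = n_years)
  acc$cutoffs <- stats::setNames(cut$k, cut$gear_code)
  acc$n_validated <- sum(tab$selected & !is.na(tab$status) &
                           tab$status != "unvalidated")
  structure(list(table = tab, summary = acc), class = "metier_selection")
}

#' @export
print.metier_selection <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<metier_selection> %d of %d potential metiers selected\n",
    s$n_selected, s$n_selected + s$n_excluded))
  cat(sprintf(
    "  excluded: %d metiers, %d hauls (%d%% of hauls, %.1f hauls/metier/year)\n",
    s$n_excluded, s$excluded_hauls, s$excluded_share_pct,
    s$mean_excluded_per_metier_year))
  cat("  per-gear cutoffs: ",
      paste(names(s$cutoffs), s$cutoffs, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
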