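#' Value a haul's catch at the trip's average prices
#'
#' Value of a species is its logbook weight times the trip-level average
#' price; the haul value is the sum. Every caught species must be priced
#' (guaranteed after quality control).
#'
#' @param catch tibble with `species` and `weight_kg` for one haul.
#' @param price_map named numeric vector of EUR/kg prices, or a tibble with
#'   `species` and `price`.
#' @return List with `values` (named numeric, EUR per species) and
#'   `haul_value`.
#' @export
value_catch <- function(catch, price_map) {
  if (is.data.frame(price_map)) {
    price_map <- stats::setNames(price_map$price, price_map$species)
  }
  p <- price_map[catch$species]
  if (any(is.na(p))) {
    stop("unpriced species in catch: ",
         paste(unique(catch$species[is.na(p)]), collapse = ", "),
         call. = FALSE)
  }
  v <- stats::setNames(as.numeric(catch$weight_kg * p), catch$species)
  list(values = v, haul_value = sum(v))
}

#' Pick the target species of a haul: the most valuable species caught
#'
#' Deterministic tie-breaking: equal values are resolved by the greater
#' catch weight, remaining ties lexicographically by species code.
#'
#' @param values named numeric vector of per-species values (EUR).
#' @param weights optional named numeric vector of catch weights used for
#'   the first tie-break.
#' @return The target species code.
#' @export
assign_target <- function(values, weights = NULL) {
  if (!length(values)) stop("empty value map", call. = FALSE)
  sp <- names(values)
  w <- if (is.null(weights)) rep(0, length(values)) else
    as.numeric(weights[sp])
  ord <- order(-values, -w, sp)
  sp[ord[1]]
}

#' Render and parse metier labels
#'
#' A metier label is `GEAR_SPECIES_DESCRIPTOR`: the FAO gear code, the
#' target species code, and a selectivity descriptor — the mesh-size bin
#' (mm) for dredges/traps/nets, the hook-number bin for longlines, or
#' `"0"` when no detail was recorded. `bins` optionally maps a numeric
#' detail into a labelled bin per gear code (a data frame with `lo`, `hi`,
#' `label`); without bins the descriptor is the detail value itself.
#'
#' @param gear_code one of [main_gear_codes()].
#' @param gear_detail numeric mesh size or hook number, NA when absent.
#' @param target target species code.
#' @param bins optional named list: gear code -> data.frame(lo, hi, label).
#' @return `label_metier()`: the rendered label string. `parse_metier_label()`:
#'   a list with `gear_code`, `target`, `descriptor`.
#' @export
label_metier <- function(gear_code, gear_detail, target, bins = NULL) {
  if (!gear_code %in% main_gear_codes()) {
    stop("not a main gear: ", gear_code, call. = FALSE)
  }
  descriptor <- "0"
  if (!is.na(gear_detail)) {
    if (gear_detail <= 0) stop("gear detail must be positive", call. = FALSE)
    descriptor <- format(gear_detail, trim = TRUE)
    if (!is.null(bins) && !is.null(bins[[gear_code]])) {
      b <- bins[[gear_code]]
      hit <- which(b$lo <= gear_detail & gear_detail <= b$hi)
      if (length(hit)) descriptor <- b$label[hit[1]]
    }
  }
  paste(gear_code, target, descriptor, sep = "_")
}

#' @rdname label_metier
#' @param label a rendered metier label.
#' @export
parse_metier_label <- function(label) {
  parts <- stringr::str_split_fixed(label, stringr::fixed("_"), 3)
  if (any(parts[, 3] == "")) stop("malformed metier label", call. = FALSE)
  list(gear_code = parts[, 1], target = parts[, 2], descriptor = parts[, 3])
}

#' Attribute value, target species and potential metier to every haul
#'
#' Vectorized over all valid hauls: per-species values at the trip's
#' average prices, the target species (argmax value with the documented
#' tie-breaks), and the potential-metier key `GEAR_TARGET`. A potential
#' metier is keyed on gear x target species only; the selectivity
#' descriptor is attached at reporting time from the modal gear detail of
#' the metier's hauls. An optional alias table (`species`, `group`)
#' collapses species into family-level groups before the metier key is
#' formed (e.g. soles, skates).
#'
#' @param hauls,catches valid hauls and catches (post [run_qc()]).
#' @param sales sales list with a `lines` tibble (for [trip_prices()]).
#' @param alias optional tibble (`species`, `group`).
#' @return `hauls` with `target_species`, `haul_value` and `metier` added.
#' @export
assign_metiers <- function(hauls, catches, sales, alias = NULL) {
  prices <- trip_prices(sales$lines)
  val <- dplyr::left_join(catches, hauls[, c("haul_id", "trip_id")],
                          by = "haul_id")
  val <- dplyr::left_join(val, prices, by = c("trip_id", "species"))
  if (any(is.na(val$price))) {
    stop("unpriced species reached assignment (QC contract breach): ",
         paste(utils::head(unique(val$species[is.na(val$price)]), 5),
               collapse = ", "), call. = FALSE)
  }
  val$value <- val$weight_kg * val$price
  best <- val |>
    dplyr::arrange(dplyr::desc(.data$value), dplyr::desc(.data$weight_kg),
                   .data$species) |>
    dplyr::summarise(target_species = .data$species[1],
                     haul_value = sum(.data$value),
                     .by = "haul_id")
  out <- dplyr::left_join(hauls, best, by = "haul_id")
  if (!is.null(alias)) {
    grp <- stats::setNames(alias$group, alias$species)
    hit <- out$target_species %in% names(grp)
    out$target_species[hit] <- grp[out$target_species[hit]]
  }
  dplyr::mutate(out, metier = paste(.data$gear_code, .data$target_species,
                                    sep = "_"))
}
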