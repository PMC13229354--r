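#' Main gear codes of the multi-gear coastal fleet
#'
#' FAO gear codes for the six main gears: bivalve dredges (DRB), pots and
#' traps (FPO), set gillnets (GNS), trammel nets (GTR), drifting longlines
#' (LLD) and set/bottom longlines (LLS). Any other code is treated as
#' miscellaneous gear and excluded during quality control.
#'
#' @return Character vector of the six codes.
#' @export
main_gear_codes <- function() c("DRB", "FPO", "GNS", "GTR", "LLD", "LLS")

#' Which selectivity detail a gear family carries
#'
#' Dredges, traps and nets are described by mesh size (mm); longlines by
#' hook number.
#'
#' @param gear_code character vector of FAO gear codes.
#' @return `"mesh"`, `"hook"` or NA for non-main gears.
#' @export
gear_detail_kind <- function(gear_code) {
  dplyr::case_when(
    gear_code %in% c("DRB", "FPO", "GNS", "GTR") ~ "mesh",
    gear_code %in% c("LLD", "LLS") ~ "hook",
    TRUE ~ NA_character_
  )
}

#' Schema configuration for delimited logbook / sales-note files
#'
#' The raw exports are delimited text; the dialect (delimiter, decimal mark,
#' timestamp format) and the mapping from canonical column names to the
#' file's column names are configurable here.
#'
#' @param delim field delimiter.
#' @param decimal_mark decimal mark used in numeric fields.
#' @param time_format strptime format for timestamps (logbooks).
#' @param date_format strptime format for dates (sales notes).
#' @param col_map named character vector mapping canonical names to the
#'   column names found in the file; defaults to the identity mapping.
#' @return A list of class `table_schema`.
#' @export
table_schema <- function(delim = ",", decimal_mark = ".",
                         time_format = "%Y-%m-%d %H:%M:%S",
                         date_format = "%Y-%m-%d", col_map = NULL) {
  structure(list(delim = delim, decimal_mark = decimal_mark,
                 time_format = time_format, date_format = date_format,
                 col_map = col_map),
            class = "table_schema")
}

logbook_columns <- function() {
  c("haul_id", "trip_id", "vessel_id", "gear_code", "gear_detail",
    "set_time", "haul_time", "set_lat", "set_lon", "haul_lat", "haul_lon",
    "fao_subarea", "species", "weight_kg")
}

sales_columns <- function() {
  c("trip_id", "vessel_id", "landing_date", "departure_port", "dep_mainland",
    "return_port", "ret_mainland", "species", "sold_weight_kg", "sold_value")
}

read_raw_table <- function(path, schema, mandatory, optional = character()) {
  raw <- readr::read_delim(
    path, delim = schema$delim, col_types = readr::cols(.default = "c"),
    locale = readr::locale(decimal_mark = schema$decimal_mark),
    progress = FALSE, show_col_types = FALSE
  )
  if (!is.null(schema$col_map)) {
    have <- schema$col_map[schema$col_map %in% names(raw)]
    raw <- dplyr::rename(raw, !!!rlang::set_names(have, names(have)))
  }
  missing <- setdiff(mandatory, names(raw))
  if (length(missing)) {
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (col in setdiff(optional, names(raw))) raw[[col]] <- NA_character_
  raw
}

num_or_na <- function(x, decimal_mark = ".") {
  if (decimal_mark != ".") x <- gsub(decimal_mark, ".", x, fixed = TRUE)
  suppressWarnings(as.numeric(x))
}

#' Read a haul-level electronic logbook
#'
#' One row per haul-and-species in long format; a haul with an empty
#' `species` field and no other rows is kept as zero-catch evidence (empty
#' catch list). Malformed rows are returned as explicit error records with
#' their file line number — never silently dropped. `line` is the physical
#' line in the file (header = line 1).
#'
#' @param path path to the delimited file.
#' @param schema a [table_schema()].
#' @return A list with `hauls` (one row per haul, first-appearance order),
#'   `catches` (haul_id, species, weight_kg) and `errors`
#'   (line, field, reason).
#' @export
read_logbook <- function(path, schema = table_schema()) {
  raw <- read_raw_table(path, schema,
                        mandatory = setdiff(logbook_columns(), "gear_detail"),
                        optional = "gear_detail")
  n <- nrow(raw)
  line <- seq_len(n) + 1L
  err <- list()
  bad <- rep(FALSE, n)
  flag <- function(cond, field, reason) {
    cond <- cond & !is.na(cond)
    if (any(cond)) {
      err[[length(err) + 1L]] <<- tibble::tibble(
        line = line[cond], field = field, reason = reason)
      bad <<- bad | cond
    }
  }

  set_lat <- num_or_na(raw$set_lat, schema$decimal_mark)
  set_lon <- num_or_na(raw$set_lon, schema$decimal_mark)
  haul_lat <- num_or_na(raw$haul_lat, schema$decimal_mark)
  haul_lon <- num_or_na(raw$haul_lon, schema$decimal_mark)
  for (nm in c("set_lat", "set_lon", "haul_lat", "haul_lon")) {
    v <- get(nm)
    flag(is.na(v) & !is.na(raw[[nm]]) & raw[[nm]] != "", nm,
         "unparsable coordinate")
    flag(!is.na(v) & (abs(v) > if (grepl("lat", nm)) 90 else 180), nm,
         "coordinate out of range")
    flag(is.na(raw[[nm]]) | raw[[nm]] == "", nm, "missing coordinate")
  }
  set_time <- as.POSIXct(raw$set_time, format = schema$time_format, tz = "UTC")
  haul_time <- as.POSIXct(raw$haul_time, format = schema$time_format, tz = "UTC")
  flag(is.na(set_time), "set_time", "unparsable timestamp")
  flag(is.na(haul_time), "haul_time", "unparsable timestamp")
  flag(!is.na(set_time) & !is.na(haul_time) & haul_time < set_time,
       "haul_time", "haul before set")

  species <- ifelse(is.na(raw$species), "", raw$species)
  weight <- num_or_na(raw$weight_kg, schema$decimal_mark)
  flag(species != "" & (is.na(weight) | weight <= 0), "weight_kg",
       "catch weight must be a positive number")
  detail <- num_or_na(raw$gear_detail, schema$decimal_mark)
  flag(!is.na(raw$gear_detail) & raw$gear_detail != "" & is.na(detail),
       "gear_detail", "unparsable gear detail")
  flag(!is.na(detail) & detail <= 0, "gear_detail",
       "gear detail must be positive")

  ok <- !bad
  parsed <- tibble::tibble(
    haul_id = raw$haul_id, trip_id = raw$trip_id, vessel_id = raw$vessel_id,
    gear_code = raw$gear_code, gear_detail = detail,
    detail_kind = gear_detail_kind(raw$gear_code),
    set_time = set_time, haul_time = haul_time,
    set_lat = set_lat, set_lon = set_lon,
    haul_lat = haul_lat, haul_lon = haul_lon,
    fao_subarea = raw$fao_subarea, species = species, weight_kg = weight
  )[ok, ]

  hauls <- dplyr::distinct(dplyr::select(parsed, -"species", -"weight_kg"))
  dup <- hauls$haul_id[duplicated(hauls$haul_id)]
  if (length(dup)) {
    sel <- parsed$haul_id %in% dup
    err[[length(err) + 1L]] <- tibble::tibble(
      line = line[ok][sel], field = "haul_id",
      reason = "inconsistent haul-level fields across rows of one haul")
    parsed <- parsed[!sel, ]
    hauls <- hauls[!hauls$haul_id %in% dup, ]
  }
  catches <- parsed[parsed$species != "",
                    c("haul_id", "species", "weight_kg")]
  errors <- if (length(err)) {
    dplyr::arrange(dplyr::bind_rows(err), .data$line)
  } else {
    tibble::tibble(line = integer(), field = character(), reason = character())
  }
  list(hauls = hauls, catches = catches, errors = errors)
}

#' Write a haul-level logbook in the long CSV dialect
#'
#' Inverse of [read_logbook()]: one row per catch line, haul-level fields
#' repeated; zero-catch hauls are written as a single row with an empty
#' species field.
#'
#' @param hauls,catches tibbles as returned by [read_logbook()].
#' @param path output path.
#' @param schema a [table_schema()].
#' @return `path`, invisibly.
#' @export
write_logbook <- function(hauls, catches, path, schema = table_schema()) {
  long <- dplyr::left_join(hauls, catches, by = "haul_id")
  long$species[is.na(long$species)] <- ""
  long$weight_kg[long$species == ""] <- NA_real_
  out <- dplyr::mutate(
    long,
    set_time = format(.data$set_time, schema$time_format, tz = "UTC"),
    haul_time = format(.data$haul_time, schema$time_format, tz = "UTC")
  )
  out <- out[, logbook_columns()]
  readr::write_delim(out, path, delim = schema$delim, na = "")
  invisible(path)
}

#' Read trip-level sales notes
#'
#' One row per species sold per trip. Duplicate species lines within a trip
#' are summed (weight and value) before the average price is computed, so a
#' species has exactly one price per trip. A row with an empty species field
#' is a placeholder carrying trip metadata for a note with no sold lines
#' (it survives a write/read round trip so quality control can still see
#' the trip). Rows with zero sold weight but positive value have an
#' undefined price and are reported as errors.
#'
#' @param path path to the delimited file.
#' @param schema a [table_schema()].
#' @return A list with `notes` (one row per trip), `lines` (trip_id,
#'   species, sold_weight_kg, sold_value, price) and `errors`.
#' @export
read_sales <- function(path, schema = table_schema()) {
  raw <- read_raw_table(path, schema, mandatory = sales_columns())
  n <- nrow(raw)
  line <- seq_len(n) + 1L
  err <- list()
  bad <- rep(FALSE, n)
  flag <- function(cond, field, reason) {
    cond <- cond & !is.na(cond)
    if (any(cond)) {
      err[[length(err) + 1L]] <<- tibble::tibble(
        line = line[cond], field = field, reason = reason)
      bad <<- bad | cond
    }
  }
  species <- ifelse(is.na(raw$species), "", raw$species)
  w <- num_or_na(raw$sold_weight_kg, schema$decimal_mark)
  v <- num_or_na(raw$sold_value, schema$decimal_mark)
  date <- as.Date(raw$landing_date, format = schema$date_format)
  flag(is.na(date), "landing_date", "unparsable date")
  flag(species != "" & (is.na(w) | w <= 0), "sold_weight_kg",
       "sold weight must be positive (undefined price otherwise)")
  flag(species != "" & (is.na(v) | v < 0), "sold_value",
       "sold value must be non-negative")

  ok <- !bad
  parsed <- tibble::tibble(
    trip_id = raw$trip_id, vessel_id = raw$vessel_id, landing_date = date,
    departure_port = raw$departure_port,
    dep_mainland = toupper(raw$dep_mainland) %in% c("TRUE", "T", "1", "YES"),
    return_port = raw$return_port,
    ret_mainland = toupper(raw$ret_mainland) %in% c("TRUE", "T", "1", "YES"),
    species = species, sold_weight_kg = w, sold_value = v
  )[ok, ]

  notes <- dplyr::distinct(
    dplyr::select(parsed, -"species", -"sold_weight_kg", -"sold_value"))
  notes <- notes[!duplicated(notes$trip_id), ]
  lines <- parsed[parsed$species != "", ] |>
    dplyr::summarise(
      sold_weight_kg = sum(.data$sold_weight_kg),
      sold_value = sum(.data$sold_value),
      .by = c("trip_id", "species")
    ) |>
    dplyr::mutate(price = .data$sold_value / .data$sold_weight_kg)
  errors <- if (length(err)) {
    dplyr::arrange(dplyr::bind_rows(err), .data$line)
  } else {
    tibble::tibble(line = integer(), field = character(), reason = character())
  }
  list(notes = notes, lines = lines, errors = errors)
}

#' Write sales notes in the long CSV dialect
#'
#' Inverse of [read_sales()]; notes without sold lines are written as a
#' placeholder row with an empty species field.
#'
#' @param notes,lines tibbles as returned by [read_sales()] (a `price`
#'   column, if present, is dropped — it is derived).
#' @param path output path.
#' @param schema a [table_schema()].
#' @return `path`, invisibly.
#' @export
write_sales <- function(notes, lines, path, schema = table_schema()) {
  lines <- lines[, c("trip_id", "species", "sold_weight_kg", "sold_value")]
  long <- dplyr::left_join(notes, lines, by = "trip_id")
  long$species[is.na(long$species)] <- ""
  out <- dplyr::mutate(
    long, landing_date = format(.data$landing_date, schema$date_format))
  out <- out[, sales_columns()]
  readr::write_delim(out, path, delim = schema$delim, na = "")
  invisible(path)
}

#' Per-trip average price map
#'
#' @param sales_lines the `lines` tibble from [read_sales()] or
#'   [generate_records()].
#' @return Tibble (trip_id, species, price) with one price per species per
#'   trip.
#' @export
trip_prices <- function(sales_lines) {
  dplyr::select(sales_lines, "trip_id", "species", "price")
}
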