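#' Fishing-area configuration for the Portuguese continental coast
#'
#' The coastline is split into four areas: northwest (NW), center west (CW),
#' southwest (SW) and south (S). NW and CW are separated at the latitude of
#' the Nazare Canyon, CW and SW just south of Sesimbra (Setubal Canyon), and
#' SW and S at the Cape St. Vincent corner where the west coast turns into
#' the south coast. The published landmarks are encoded as three
#' configurable coordinates; every analysis output should record the
#' configuration used.
#'
#' @param nw_cw_lat latitude separating NW from CW (Nazare Canyon).
#' @param cw_sw_lat latitude separating CW from SW (Setubal Canyon).
#' @param sw_s_lon longitude of the west/south coast corner (Cape
#'   St. Vincent); points east of it below `cw_sw_lat` are in the south.
#' @return A list of class `area_config`.
#' @export
area_config <- function(nw_cw_lat = 39.6, cw_sw_lat = 38.4, sw_s_lon = -8.99) {
  stopifnot(nw_cw_lat > cw_sw_lat)
  structure(list(nw_cw_lat = nw_cw_lat, cw_sw_lat = cw_sw_lat,
                 sw_s_lon = sw_s_lon),
            class = "area_config")
}

#' Area levels in coastline order
#' @return `c("NW", "CW", "SW", "S")`
#' @export
area_levels <- function() c("NW", "CW", "SW", "S")

#' Assign points to fishing areas
#'
#' Ordered rule: latitude at or above the Nazare split is NW; at or above
#' the Setubal split is CW; below that, points west of the Cape St. Vincent
#' corner are SW and the remainder S. Every point in the bounding box gets
#' exactly one area.
#'
#' @param lon,lat numeric vectors, decimal degrees.
#' @param config an [area_config()].
#' @return Character vector of area codes.
#' @export
assign_area <- function(lon, lat, config = area_config()) {
  dplyr::case_when(
    lat >= config$nw_cw_lat ~ "NW",
    lat >= config$cw_sw_lat ~ "CW",
    lon <= config$sw_s_lon ~ "SW",
    TRUE ~ "S"
  )
}

#' Haul midpoint between setting and hauling positions
#'
#' Arithmetic mean of the set and haul coordinate pairs. When the hauling
#' pair is missing the setting pair is used and the row is flagged
#' (`midpoint_fallback`); hauls with neither pair raise an error.
#'
#' @param hauls a hauls tibble (needs `set_lon`, `set_lat`, `haul_lon`,
#'   `haul_lat`).
#' @return `hauls` with `mid_lon`, `mid_lat` and `midpoint_fallback` added.
#' @export
midpoint <- function(hauls) {
  set_ok <- !is.na(hauls$set_lon) & !is.na(hauls$set_lat)
  haul_ok <- !is.na(hauls$haul_lon) & !is.na(hauls$haul_lat)
  if (any(!set_ok & !haul_ok)) {
    stop("haul(s) without any coordinate pair: ",
         paste(utils::head(hauls$haul_id[!set_ok & !haul_ok], 5),
               collapse = ", "),
         call. = FALSE)
  }
  fallback <- xor(set_ok, haul_ok)
  lon1 <- ifelse(set_ok, hauls$set_lon, hauls$haul_lon)
  lat1 <- ifelse(set_ok, hauls$set_lat, hauls$haul_lat)
  lon2 <- ifelse(haul_ok, hauls$haul_lon, hauls$set_lon)
  lat2 <- ifelse(haul_ok, hauls$haul_lat, hauls$set_lat)
  dplyr::mutate(hauls,
                mid_lon = (lon1 + lon2) / 2,
                mid_lat = (lat1 + lat2) / 2,
                midpoint_fallback = fallback)
}

#' Season levels (calendar quarters)
#' @return `c("Winter", "Spring", "Summer", "Autumn")`
#' @export
season_levels <- function() c("Winter", "Spring", "Summer", "Autumn")

#' Map a timestamp to its season
#'
#' Winter: Jan-Mar, Spring: Apr-Jun, Summer: Jul-Sep, Autumn: Oct-Dec.
#' The gear *setting* time defines the season of a haul.
#'
#' @param time POSIXct or Date vector.
#' @return Character vector of seasons.
#' @export
season_of <- function(time) {
  m <- as.integer(format(time, "%m"))
  season_levels()[(m - 1L) %/% 3L + 1L]
}

#' Depth-stratum levels
#' @return `c("Shallow", "Medium", "Deep")`
#' @export
depth_levels <- function() c("Shallow", "Medium", "Deep")

#' Map a depth to its stratum
#'
#' Shallow: below 200 m; Medium: 200-500 m (closed interval, so both
#' boundaries fall in Medium); Deep: above 500 m.
#'
#' @param depth_m non-negative depth in meters, positive down; NA allowed
#'   (returns NA).
#' @return Character vector of strata.
#' @export
depth_stratum <- function(depth_m) {
  if (any(depth_m < 0, na.rm = TRUE)) {
    stop("negative depth", call. = FALSE)
  }
  dplyr::case_when(
    is.na(depth_m) ~ NA_character_,
    depth_m < 200 ~ "Shallow",
    depth_m <= 500 ~ "Medium",
    TRUE ~ "Deep"
  )
}

#' Annotate valid hauls with midpoint, year, season, area, depth and sediment
#'
#' Pure derivation from the haul record and the two environmental grids.
#' Sediment nodata becomes the explicit `"Unknown"` class and the haul is
#' kept; a midpoint outside the grids leaves depth/sediment NA and sets
#' `area_flagged` so the haul can be excluded from area-based tests only.
#'
#' @param hauls a hauls tibble (post quality control).
#' @param depth_grid,sediment_grid [env_grid()] objects.
#' @param config an [area_config()].
#' @return Tibble of annotated hauls: all haul fields plus `mid_lon`,
#'   `mid_lat`, `midpoint_fallback`, `year`, `season`, `area`,
#'   `area_flagged`, `depth_m`, `depth_stratum`, `sediment`.
#' @export
annotate_hauls <- function(hauls, depth_grid, sediment_grid,
                           config = area_config()) {
  out <- midpoint(hauls)
  d <- sample_grid(depth_grid, out$mid_lon, out$mid_lat)
  s <- sample_grid(sediment_grid, out$mid_lon, out$mid_lat)
  dplyr::mutate(
    out,
    year = as.integer(format(.data$set_time, "%Y")),
    season = season_of(.data$set_time),
    area = assign_area(.data$mid_lon, .data$mid_lat, config),
    area_flagged = d$status == "oob",
    depth_m = d$value,
    depth_stratum = depth_stratum(d$value),
    sediment = s$value
  )
}
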