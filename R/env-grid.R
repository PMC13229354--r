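#' Regular environmental raster grid
#'
#' A minimal single-band lon/lat raster used for bathymetry and seabed
#' sediment. Values are stored in a matrix whose first row is the
#' *southernmost* latitude band; `origin` is the lower-left (south-west)
#' corner of the grid. Depth is in meters, positive down. Sediment is stored
#' as an integer code into [sediment_classes()].
#'
#' @param values numeric matrix (rows = latitude bands south to north,
#'   columns = longitude west to east).
#' @param origin length-2 numeric, `c(lon, lat)` of the lower-left corner.
#' @param pixel cell size in decimal degrees; must be positive and below
#'   0.01 so that annotation operates at sub-kilometre resolution.
#' @param nodata sentinel value marking cells with no data.
#' @param kind `"depth"` or `"sediment"`.
#' @return An object of class `env_grid`.
#' @export
env_grid <- function(values, origin, pixel, nodata = -9999,
                     kind = c("depth", "sediment")) {
  kind <- match.arg(kind)
  if (!is.matrix(values)) stop("`values` must be a matrix", call. = FALSE)
  if (length(origin) != 2 || !is.numeric(origin)) {
    stop("`origin` must be numeric c(lon, lat)", call. = FALSE)
  }
  if (!is.numeric(pixel) || length(pixel) != 1 || pixel <= 0 || pixel >= 0.01) {
    stop("`pixel` must be a positive cell size below 0.01 degrees", call. = FALSE)
  }
  if (kind == "sediment") {
    v <- values[values != nodata & !is.na(values)]
    if (length(v) && !all(v %in% seq_along(sediment_classes()))) {
      stop("sediment codes must index sediment_classes()", call. = FALSE)
    }
  }
  structure(
    list(values = values, origin = as.numeric(origin), pixel = pixel,
         nodata = nodata, kind = kind),
    class = "env_grid"
  )
}

#' The six-class seabed sediment vocabulary
#'
#' Mud, sand, coarse-grained sediment, mixed sediment, rock/boulders, and an
#' explicit Unknown class for cells with no substrate information.
#'
#' @return Character vector of the six class names.
#' @export
sediment_classes <- function() {
  c("Mud", "Sand", "Coarse", "Mixed", "Rock", "Unknown")
}

#' @export
print.env_grid <- function(x, ...) {
  b <- grid_bounds(x)
  cat(sprintf("<env_grid %s> %d x %d cells, pixel %g deg\n",
              x$kind, nrow(x$values), ncol(x$values), x$pixel))
  cat(sprintf("  lon [%g, %g), lat [%g, %g)\n", b$lon[1], b$lon[2],
              b$lat[1], b$lat[2]))
  invisible(x)
}

grid_bounds <- function(grid) {
  list(
    lon = c(grid$origin[1], grid$origin[1] + ncol(grid$values) * grid$pixel),
    lat = c(grid$origin[2], grid$origin[2] + nrow(grid$values) * grid$pixel)
  )
}

#' Point-sample a grid (containing-cell lookup)
#'
#' Returns the value of the cell containing each point; no interpolation is
#' performed, mirroring point-sampling of a categorical raster. Points on or
#' beyond the upper grid edge are out of bounds.
#'
#' @param grid an [env_grid()].
#' @param lon,lat numeric vectors of equal length, decimal degrees (WGS84,
#'   longitude negative west).
#' @return A tibble with one row per point: `lon`, `lat`, `value`, `status`.
#'   `status` is `"ok"`, `"nodata"` or `"oob"` (out of bounds) so that
#'   missing data and out-of-coverage points stay distinguishable. For depth
#'   grids `value` is numeric (NA when nodata/oob); for sediment grids it is
#'   the class name, with nodata cells reported as `"Unknown"` and
#'   out-of-bounds points as NA.
#' @export
sample_grid <- function(grid, lon, lat) {
  stopifnot(inherits(grid, "env_grid"), length(lon) == length(lat))
  col <- floor((lon - grid$origin[1]) / grid$pixel) + 1L
  row <- floor((lat - grid$origin[2]) / grid$pixel) + 1L
  inb <- !is.na(lon) & !is.na(lat) &
    col >= 1L & col <= ncol(grid$values) & row >= 1L & row <= nrow(grid$values)
  raw <- rep(NA_real_, length(lon))
  raw[inb] <- grid$values[cbind(row[inb], col[inb])]
  status <- ifelse(!inb, "oob", ifelse(raw == grid$nodata, "nodata", "ok"))
  if (grid$kind == "sediment") {
    value <- rep(NA_character_, length(lon))
    value[status == "ok"] <- sediment_classes()[raw[status == "ok"]]
    value[status == "nodata"] <- "Unknown"
  } else {
    value <- raw
    value[status != "ok"] <- NA_real_
  }
  tibble::tibble(lon = lon, lat = lat, value = value, status = status)
}

#' Read / write the plain-text grid format
#'
#' A self-describing ASCII format (seven header lines then `nrows` rows of
#' `ncols` whitespace-separated values, first row = southernmost band) so
#' that grids need no binary geospatial dependency.
#'
#' @param path file path.
#' @return `read_env_grid()` returns an [env_grid()]; `write_env_grid()`
#'   returns `path` invisibly.
#' @export
read_env_grid <- function(path) {
  hdr <- readLines(path, n = 8L)
  if (!startsWith(hdr[1], "metierid_grid")) {
    stop("not a metierid grid file: ", path, call. = FALSE)
  }
  fields <- stats::setNames(
    sub("^\\S+\\s+", "", hdr[-1]),
    sub("\\s.*$", "", hdr[-1])
  )
  ncols <- as.integer(fields[["ncols"]])
  nrows <- as.integer(fields[["nrows"]])
  vals <- scan(path, skip = 8L, quiet = TRUE)
  if (length(vals) != ncols * nrows) {
    stop("grid body has ", length(vals), " values, expected ", ncols * nrows,
         call. = FALSE)
  }
  env_grid(
    matrix(vals, nrow = nrows, ncol = ncols, byrow = TRUE),
    origin = c(as.numeric(fields[["xll"]]), as.numeric(fields[["yll"]])),
    pixel = as.numeric(fields[["pixel"]]),
    nodata = as.numeric(fields[["nodata"]]),
    kind = fields[["kind"]]
  )
}

#' @rdname read_env_grid
#' @param grid an [env_grid()] to serialize.
#' @export
write_env_grid <- function(grid, path) {
  stopifnot(inherits(grid, "env_grid"))
  hdr <- c(
    "metierid_grid v1",
    paste("kind", grid$kind),
    paste("ncols", ncol(grid$values)),
    paste("nrows", nrow(grid$values)),
    paste("xll", format(grid$origin[1], digits = 12)),
    paste("yll", format(grid$origin[2], digits = 12)),
    paste("pixel", format(grid$pixel, digits = 12)),
    paste("nodata", format(grid$nodata, digits = 12))
  )
  # body written row-major, one latitude band per line
  body <- apply(grid$values, 1L, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}
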