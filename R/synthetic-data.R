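#' Specification of one planted metier for the synthetic fleet
#'
#' A metier spec describes one gear x target-species stratum the generator
#' plants: how valuable and heavy its target catches are, which nuisance
#' species contaminate it, how strongly the target dominates haul value
#' (`dominance`), and its seasonal, spatial, bathymetric and sediment
#' preferences. Weight vectors are normalized; they may be named by level or
#' given in level order ([season_levels()], [area_levels()],
#' [depth_levels()], the first five of [sediment_classes()]).
#'
#' @param name short unique label (e.g. `"octopus traps"`).
#' @param gear_code one of [main_gear_codes()].
#' @param target target species code.
#' @param hauls_per_year expected number of hauls per calendar year
#'   (Poisson).
#' @param price_mean mean landed price of the target, EUR/kg.
#' @param price_sdlog lognormal dispersion of trip-level prices.
#' @param detail_values mesh sizes (mm) or hook numbers the metier uses; one
#'   is drawn per haul. `NULL` for gear without recorded detail.
#' @param bycatch_pool named numeric vector: bycatch species and their
#'   relative weight share of the target weight.
#' @param dominance probability in (0, 1] that the target is the top-value
#'   species of a haul; with probability `1 - dominance` one bycatch species
#'   outvalues it (the misassignment mechanism).
#' @param season_weights,area_weights,depth_weights,sediment_weights
#'   preference weights over the respective level sets.
#' @param weight_meanlog,weight_sdlog lognormal parameters of the target
#'   catch weight (kg).
#' @return A list of class `metier_spec`.
#' @export
metier_spec <- function(name, gear_code, target, hauls_per_year,
                        price_mean, price_sdlog = 0.15,
                        detail_values = NULL, bycatch_pool = numeric(),
                        dominance = 0.9,
                        season_weights = rep(1, 4),
                        area_weights = rep(1, 4),
                        depth_weights = c(1, 0, 0),
                        sediment_weights = rep(1, 5),
                        weight_meanlog = log(40), weight_sdlog = 0.5) {
  stopifnot(gear_code %in% main_gear_codes(),
            hauls_per_year > 0, price_mean > 0,
            dominance > 0, dominance <= 1)
  norm <- function(w, levels) {
    if (!is.null(names(w))) {
      w <- w[levels]
      w[is.na(w)] <- 0
    }
    stopifnot(length(w) == length(levels), all(w >= 0), sum(w) > 0)
    stats::setNames(as.numeric(w) / sum(w), levels)
  }
  if (length(bycatch_pool)) {
    stopifnot(!is.null(names(bycatch_pool)), all(bycatch_pool > 0),
              !target %in% names(bycatch_pool))
  }
  structure(list(
    name = name, gear_code = gear_code, target = target,
    hauls_per_year = hauls_per_year, price_mean = price_mean,
    price_sdlog = price_sdlog, detail_values = detail_values,
    bycatch_pool = bycatch_pool, dominance = dominance,
    season_weights = norm(season_weights, season_levels()),
    area_weights = norm(area_weights, area_levels()),
    depth_weights = norm(depth_weights, depth_levels()),
    sediment_weights = norm(sediment_weights, sediment_classes()[1:5]),
    weight_meanlog = weight_meanlog, weight_sdlog = weight_sdlog
  ), class = "metier_spec")
}

#' Default planted fleet: twelve metiers across the six main gears
#'
#' Inspired by the leading metiers of the Portuguese multi-gear coastal
#' fleet: octopus traps dominating the trap fishery, hake gillnets, soles
#' trammel nets, the deep-water black scabbardfish bottom-longline fishery,
#' a surf-clam dredge fishery and a small swordfish drifting-longline
#' fishery, plus secondary metiers per gear. Within-gear haul-count ratios
#' decay steeply (roughly 1 : 0.12 : 0.03), echoing the strongly skewed
#' rank-frequency curves observed in the real fleet. Every metier has
#' decisive preferences (one level above 70% or two levels near 45% each)
#' so the planted structure is unambiguous.
#'
#' @return List of [metier_spec()] objects.
#' @export
default_metier_specs <- function() {
  list(
    metier_spec("octopus traps", "FPO", "OCC", 2100, 6,
                detail_values = c(30, 50),
                bycatch_pool = c(HOM = 0.20, POD = 0.30, CRA = 0.25,
                                 SBR = 0.15, GUU = 0.20, WEG = 0.15,
                                 SQR = 0.20, MUR = 0.25),
                season_weights = c(0.45, 0.05, 0.05, 0.45),
                area_weights = c(0.80, 0.10, 0.05, 0.05),
                depth_weights = c(0.85, 0.15, 0),
                sediment_weights = c(Sand = 0.5, Mixed = 0.5)),
    metier_spec("pouting traps", "FPO", "BIB", 250, 4,
                detail_values = 50,
                bycatch_pool = c(HOM = 0.25, POD = 0.25, CRA = 0.20,
                                 GUU = 0.20, WEG = 0.15, SQR = 0.15,
                                 SBR = 0.15, MUR = 0.20),
                season_weights = c(0.05, 0.45, 0.45, 0.05),
                area_weights = c(0.80, 0.20, 0, 0),
                depth_weights = c(0.90, 0.10, 0),
                sediment_weights = c(Mixed = 0.7, Sand = 0.3)),
    metier_spec("Norway lobster traps", "FPO", "NEP", 63, 25,
                detail_values = c(30, 50),
                bycatch_pool = c(CRA = 0.30, GUU = 0.20, POD = 0.20,
                                 SBR = 0.15, MUR = 0.20, HOM = 0.15),
                season_weights = c(0.10, 0.10, 0.70, 0.10),
                area_weights = c(0.05, 0.45, 0.45, 0.05),
                depth_weights = c(0.05, 0.25, 0.70),
                sediment_weights = c(Mud = 0.6, Sand = 0.4),
                weight_meanlog = log(15)),
    metier_spec("hake gillnets", "GNS", "HKE", 850, 5.5,
                detail_values = 100,
                bycatch_pool = c(HOM = 0.30, MAC = 0.30, POD = 0.20,
                                 GUU = 0.20, WHG = 0.15, OCC = 0.20,
                                 SQZ = 0.15, BOG = 0.25),
                season_weights = c(0.05, 0.45, 0.45, 0.05),
                area_weights = c(0.80, 0.15, 0.05, 0),
                depth_weights = c(0.45, 0.45, 0.10),
                sediment_weights = c(Sand = 0.8, Mud = 0.2)),
    metier_spec("monkfish gillnets", "GNS", "MON", 101, 9,
                detail_values = 220,
                bycatch_pool = c(HOM = 0.25, MAC = 0.20, POD = 0.20,
                                 GUU = 0.20, OCC = 0.20, BOG = 0.20,
                                 SQZ = 0.15, WHG = 0.15),
                season_weights = c(0.05, 0.45, 0.45, 0.05),
                area_weights = c(0.05, 0.05, 0.20, 0.70),
                depth_weights = c(0.45, 0.45, 0.10),
                sediment_weights = c(Sand = 0.8, Mud = 0.2)),
    metier_spec("soles gillnets", "GNS", "SOL", 26, 12,
                detail_values = 60,
                bycatch_pool = c(HOM = 0.25, POD = 0.25, GUU = 0.20,
                                 OCC = 0.25, BOG = 0.20, MAC = 0.20),
                season_weights = c(0.45, 0.05, 0.05, 0.45),
                area_weights = c(0.70, 0.10, 0.10, 0.10),
                depth_weights = c(0.85, 0.10, 0.05),
                sediment_weights = c(Sand = 0.9, Mud = 0.1),
                weight_meanlog = log(20)),
    metier_spec("soles trammel nets", "GTR", "SOL", 650, 12,
                detail_values = c(80, 100),
                bycatch_pool = c(HOM = 0.25, OCC = 0.30, MAC = 0.20,
                                 POD = 0.20, GUU = 0.15, SBR = 0.15,
                                 WEG = 0.20, SQR = 0.15),
                season_weights = c(0.70, 0.10, 0.10, 0.10),
                area_weights = c(0.80, 0.10, 0.05, 0.05),
                depth_weights = c(0.90, 0.10, 0),
                sediment_weights = c(Sand = 0.5, Mixed = 0.5),
                weight_meanlog = log(25)),
    metier_spec("John Dories trammel nets", "GTR", "JOD", 78, 15,
                detail_values = 200,
                bycatch_pool = c(HOM = 0.25, OCC = 0.25, MAC = 0.20,
                                 POD = 0.20, WEG = 0.15, SQR = 0.15),
                season_weights = c(0.10, 0.10, 0.70, 0.10),
                area_weights = c(0.45, 0.05, 0.45, 0.05),
                depth_weights = c(0.85, 0.15, 0),
                sediment_weights = c(Sand = 0.5, Rock = 0.5),
                weight_meanlog = log(20)),
    metier_spec("cuttlefish trammel nets", "GTR", "CTC", 20, 7,
                detail_values = c(80, 100),
                bycatch_pool = c(HOM = 0.25, OCC = 0.30, POD = 0.25,
                                 GUU = 0.15, MAC = 0.20),
                season_weights = c(0.45, 0.05, 0.05, 0.45),
                area_weights = c(0.70, 0.10, 0.10, 0.10),
                depth_weights = c(0.90, 0.10, 0),
                sediment_weights = c(Sand = 0.5, Mixed = 0.5),
                weight_meanlog = log(20)),
    metier_spec("black scabbardfish bottom longlines", "LLS", "BSF", 650, 4,
                detail_values = 5:8,
                bycatch_pool = c(SKA = 0.30, FOR = 0.25, SBA = 0.20,
                                 HKE = 0.20, GUU = 0.15, CBA = 0.15),
                season_weights = c(0.45, 0.05, 0.05, 0.45),
                area_weights = c(0.05, 0.80, 0.10, 0.05),
                depth_weights = c(0, 0.15, 0.85),
                sediment_weights = c(Sand = 0.5, Rock = 0.5),
                weight_meanlog = log(80)),
    metier_spec("swordfish drifting longlines", "LLD", "SWO", 30, 8,
                detail_values = c(16, 17),
                bycatch_pool = c(BSH = 0.30, SMA = 0.20, DOL = 0.15,
                                 ALB = 0.25, OIL = 0.20),
                season_weights = c(0.10, 0.10, 0.10, 0.70),
                area_weights = c(0.05, 0.45, 0.45, 0.05),
                depth_weights = c(0.05, 0.10, 0.85),
                sediment_weights = c(Sand = 0.6, Mud = 0.4),
                weight_meanlog = log(120)),
    metier_spec("surf clam dredges", "DRB", "SVE", 90, 1.8,
                detail_values = 30,
                bycatch_pool = c(WEG = 0.20, CLX = 0.30, RAZ = 0.25,
                                 CRA = 0.15, GUU = 0.10),
                season_weights = c(0.05, 0.45, 0.45, 0.05),
                area_weights = c(0.85, 0.05, 0.05, 0.05),
                depth_weights = c(1, 0, 0),
                sediment_weights = c(Sand = 1),
                weight_meanlog = log(200))
  )
}

base_price_table <- function(metiers) {
  base <- c(HOM = 1.5, MAC = 1.2, POD = 2, CRA = 8, SBR = 6, GUU = 2.5,
            WEG = 3, SQR = 9, MUR = 5, WHG = 2.5, OCC = 6, SQZ = 7,
            BOG = 1.5, SKA = 3, FOR = 3.5, SBA = 7, HKE = 5.5, CBA = 3,
            BSH = 2.5, SMA = 6, DOL = 5, ALB = 4, OIL = 1.5, CLX = 2,
            RAZ = 4)
  for (m in metiers) base[m$target] <- m$price_mean
  base
}

#' Configuration of a synthetic-fleet simulation
#'
#' Everything the generator needs: the seed, study years, fleet size, the
#' planted metiers, the rare tail of nuisance gear x species combinations,
#' the quality-control violation injection rates, and the environmental
#' grid parameters. A fixed seed makes [generate_env()] and
#' [generate_records()] fully reproducible.
#'
#' @param seed integer RNG seed.
#' @param years calendar years simulated.
#' @param n_vessels fleet size.
#' @param metiers list of [metier_spec()] objects (the planted, "important"
#'   metiers).
#' @param rare_tail list `(n, hauls_range)`: number of nuisance gear x
#'   species combinations and the range of their total haul counts over the
#'   whole period. An optional `gears` element restricts which gears the
#'   tail occurs in (default: all six main gears).
#' @param rates named list of violation injection rates in `[0, 1]`. All
#'   but `non_mainland_trip` are drawn mutually exclusively per haul;
#'   `non_mainland_trip` is applied at trip level (every haul of an
#'   affected trip is labelled). Defaults sum to about 1.8% of hauls, the
#'   removal rate observed in the real fleet.
#' @param grid environmental-grid parameters: bounding box (`lon`, `lat`),
#'   `pixel` size (degrees, < 0.01), the deterministic bathymetry gradient
#'   (`coast_lon`, `coast_lat`, `w_lon`, `w_lat`: depth grows linearly to
#'   3000 m over `w_*` degrees offshore of the two coastlines),
#'   `noise_amp` (m) for smooth bathymetric noise, sediment patch `block`
#'   size (degrees) and `unknown_frac`, the fraction of sediment patches
#'   with no substrate information.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, years = 2014:2023, n_vessels = 150,
                       metiers = default_metier_specs(),
                       rare_tail = list(n = 50, hauls_range = c(1, 10)),
                       rates = list(outside_subarea = 0.004,
                                    depth_gt_2000 = 0.002,
                                    misc_gear = 0.003,
                                    zero_catch = 0.003,
                                    missing_price = 0.003,
                                    inflated_weight = 0.002,
                                    non_mainland_trip = 0.0005),
                       grid = list()) {
  gdef <- list(lon = c(-10.2, -7.4), lat = c(36, 42), pixel = 0.0095,
               coast_lon = -8.6, coast_lon_south = -9.1, bend_lat = 38.4,
               coast_lat = 37.0, w_lon = 1.2, w_lat = 1.0,
               noise_amp = 150, block = 0.2, unknown_frac = 0.12)
  grid <- utils::modifyList(gdef, grid)
  stopifnot(diff(grid$lon) > 0, diff(grid$lat) > 0)
  rdef <- eval(formals(sim_config)$rates)
  rates <- utils::modifyList(rdef, rates)
  stopifnot(all(unlist(rates) >= 0), all(unlist(rates) <= 1),
            sum(unlist(rates)) < 1)
  stopifnot(length(metiers) >= 1,
            all(vapply(metiers, inherits, logical(1), "metier_spec")))
  structure(list(seed = as.integer(seed), years = as.integer(years),
                 n_vessels = n_vessels, metiers = metiers,
                 rare_tail = rare_tail, rates = rates, grid = grid),
            class = "sim_config")
}

#' Deterministic offshore bathymetry gradient
#'
#' Depth (m) grows linearly from the synthetic west and south coastlines,
#' reaching 3000 m over `w_lon` / `w_lat` degrees; the two gradients are
#' combined with a maximum and clipped to `[0, 3000]`. This is the
#' noise-free limit of the generated bathymetry.
#'
#' @param lon,lat numeric vectors.
#' @param grid the `grid` element of a [sim_config()].
#' @return Numeric depths in meters.
#' @export
depth_gradient <- function(lon, lat, grid) {
  # the west coastline bends offshore south of `bend_lat`, like the real
  # coast west of Sines/Sagres, so the southwest area keeps shelf waters
  coast_lon <- ifelse(lat >= grid$bend_lat, grid$coast_lon,
                      grid$coast_lon_south)
  g <- pmax((coast_lon - lon) / grid$w_lon,
            (grid$coast_lat - lat) / grid$w_lat)
  pmin(pmax(3000 * g, 0), 3000)
}

#' Generate the environmental grids of the synthetic study area
#'
#' Bathymetry: the deterministic offshore gradient of [depth_gradient()]
#' plus smooth low-frequency sinusoidal noise (amplitude `noise_amp`),
#' clipped to `[0, 3000]` m. Sediment: a seeded patchwork of the five
#' substrate classes in square blocks of `block` degrees, each block
#' flipped to Unknown with probability `unknown_frac`.
#'
#' @param config a [sim_config()].
#' @return List with elements `depth` and `sediment`, both [env_grid()].
#' @export
generate_env <- function(config) {
  g <- config$grid
  set.seed(config$seed)
  ncol <- ceiling(diff(g$lon) / g$pixel)
  nrow <- ceiling(diff(g$lat) / g$pixel)
  lon_c <- g$lon[1] + (seq_len(ncol) - 0.5) * g$pixel
  lat_c <- g$lat[1] + (seq_len(nrow) - 0.5) * g$pixel
  lon_m <- matrix(lon_c, nrow, ncol, byrow = TRUE)
  lat_m <- matrix(lat_c, nrow, ncol)

  base <- matrix(depth_gradient(lon_m, lat_m, g), nrow, ncol)
  if (g$noise_amp > 0) {
    ph <- stats::runif(4, 0, 2 * pi)
    noise <- g$noise_amp *
      (sin(2 * pi * lon_m / 0.9 + ph[1]) * sin(2 * pi * lat_m / 1.1 + ph[2]) +
         0.5 * sin(2 * pi * lon_m / 0.37 + ph[3]) *
         sin(2 * pi * lat_m / 0.43 + ph[4]))
    # noise only off the zero-depth shelf edge, so land stays land
    depth <- ifelse(base > 0, pmin(pmax(base + noise, 1), 3000), 0)
  } else {
    depth <- base
  }
  depth_grid <- env_grid(depth, origin = c(g$lon[1], g$lat[1]),
                         pixel = g$pixel, kind = "depth")

  nbx <- ceiling(diff(g$lon) / g$block)
  nby <- ceiling(diff(g$lat) / g$block)
  block_class <- matrix(sample.int(5L, nbx * nby, replace = TRUE), nby, nbx)
  unk <- matrix(stats::runif(nbx * nby) < g$unknown_frac, nby, nbx)
  block_class[unk] <- 6L
  bx <- pmin(floor((lon_m - g$lon[1]) / g$block) + 1L, nbx)
  by <- pmin(floor((lat_m - g$lat[1]) / g$block) + 1L, nby)
  sed <- matrix(block_class[cbind(as.vector(by), as.vector(bx))], nrow, ncol)
  sediment_grid <- env_grid(sed, origin = c(g$lon[1], g$lat[1]),
                            pixel = g$pixel, kind = "sediment")
  list(depth = depth_grid, sediment = sediment_grid)
}

# Cell inventory used for haul placement: fishable cells only (wet, at most
# 2000 m deep -- the fleet's operating range).
placement_cells <- function(env, config) {
  g <- config$grid
  depth <- env$depth$values
  sed <- env$sediment$values
  nrow <- nrow(depth); ncol <- ncol(depth)
  lon <- g$lon[1] + (rep(seq_len(ncol), each = nrow) - 0.5) * g$pixel
  lat <- g$lat[1] + (rep(seq_len(nrow), times = ncol) - 0.5) * g$pixel
  d <- as.vector(depth)
  keep <- d >= 1 & d <= 2000
  klon <- lon[keep]
  klat <- lat[keep]
  kd <- d[keep]
  tibble::tibble(
    lon = klon, lat = klat, depth = kd,
    stratum = depth_stratum(kd),
    area = assign_area(klon, klat),
    sediment = sediment_classes()[as.vector(sed)[keep]]
  )
}

sample_level <- function(n, weights) {
  names(weights)[sample.int(length(weights), n, replace = TRUE,
                            prob = weights)]
}

# Draw cells matching (area, stratum, sediment-preference), falling back to
# (area, stratum) when the preferred substrate does not occur there.
place_hauls <- function(cells, area, stratum, sediment, who) {
  n <- length(area)
  idx <- integer(n)
  key3 <- paste(area, stratum, sediment)
  ckey3 <- paste(cells$area, cells$stratum, cells$sediment)
  ckey2 <- paste(cells$area, cells$stratum)
  for (k in unique(key3)) {
    sel <- which(key3 == k)
    pool <- which(ckey3 == k)
    if (!length(pool)) {
      pool <- which(ckey2 == paste(area[sel[1]], stratum[sel[1]]))
    }
    if (!length(pool)) {
      stop(sprintf(
        "metier '%s' requires area %s / stratum %s but no such cells exist",
        who[sel[1]], area[sel[1]], stratum[sel[1]]), call. = FALSE)
    }
    idx[sel] <- pool[sample.int(length(pool), length(sel), replace = TRUE)]
  }
  idx
}

season_month <- function(season) {
  first <- c(Winter = 1L, Spring = 4L, Summer = 7L, Autumn = 10L)
  first[season] + sample.int(3L, length(season), replace = TRUE) - 1L
}

#' Mainland and island landing ports of the synthetic fleet
#' @return Character vectors of port codes.
#' @export
mainland_ports <- function() {
  c("MATOSINHOS", "AVEIRO", "NAZARE", "PENICHE", "LISBOA", "SESIMBRA",
    "SINES", "SAGRES", "PORTIMAO", "OLHAO")
}

#' @rdname mainland_ports
#' @export
island_ports <- function() c("FUNCHAL", "PONTA_DELGADA")

#' Generate a synthetic fleet's logbooks, sales notes and truth table
#'
#' Draws every haul from one planted [metier_spec()] (plus the rare tail of
#' nuisance combinations), places it on the environmental grids according
#' to the metier's area/depth/sediment preferences, builds catches in which
#' the target tops haul value with probability `dominance`, groups hauls
#' into trips (vessel x calendar day), prices species per trip, aggregates
#' trip catches into sales notes, and injects quality-control violations at
#' the configured rates. The truth table records the planted metier and the
#' injected violations of every haul, so downstream stages can be audited
#' exactly.
#'
#' @param config a [sim_config()].
#' @param env grids from [generate_env()]; regenerated from `config` when
#'   omitted.
#' @return List with `hauls`, `catches`, `sales` (list `notes`, `lines`,
#'   as [read_sales()] returns) and `truth` (list `hauls`, `violations`).
#' @export
generate_records <- function(config, env = generate_env(config)) {
  set.seed(config$seed + 1L)
  cells <- placement_cells(env, config)
  years <- config$years
  vessels <- sprintf("V%03d", seq_len(config$n_vessels))
  rate_tot <- vapply(config$metiers, function(m) m$hauls_per_year, numeric(1))

  # -- planted hauls ---------------------------------------------------------
  specs <- config$metiers
  per <- lapply(seq_along(specs), function(i) {
    m <- specs[[i]]
    n_y <- stats::rpois(length(years), m$hauls_per_year)
    n <- sum(n_y)
    if (n == 0) return(NULL)
    pool_size <- max(2L, round(config$n_vessels * rate_tot[i] /
                                 sum(rate_tot)))
    vpool <- sample(vessels, min(pool_size + 2L, length(vessels)))
    tibble::tibble(
      spec = i, spec_name = m$name, gear_code = m$gear_code,
      target = m$target, is_tail = FALSE,
      year = rep(years, n_y),
      season = sample_level(n, m$season_weights),
      area = sample_level(n, m$area_weights),
      stratum = sample_level(n, m$depth_weights),
      sediment_pref = sample_level(n, m$sediment_weights),
      vessel_id = sample(vpool, n, replace = TRUE),
      gear_detail = if (is.null(m$detail_values)) NA_real_ else
        as.numeric(sample(as.character(m$detail_values), n, replace = TRUE)),
      dominance = m$dominance
    )
  })
  hauls <- dplyr::bind_rows(per)

  # -- rare tail: nuisance gear x species combinations -----------------------
  rt <- config$rare_tail
  if (rt$n > 0) {
    tail_gears <- rt$gears
    if (is.null(tail_gears)) tail_gears <- main_gear_codes()
    counts <- sample(seq(rt$hauls_range[1], rt$hauls_range[2]), rt$n,
                     replace = TRUE)
    tail_gear <- sample(tail_gears, rt$n, replace = TRUE)
    tail_sp <- sprintf("RSP%02d", seq_len(rt$n))
    n <- sum(counts)
    tail_hauls <- tibble::tibble(
      spec = NA_integer_,
      spec_name = rep(paste0("tail:", tail_gear, "_", tail_sp), counts),
      gear_code = rep(tail_gear, counts), target = rep(tail_sp, counts),
      is_tail = TRUE,
      year = sample(years, n, replace = TRUE),
      season = sample(season_levels(), n, replace = TRUE),
      area = sample(area_levels(), n, replace = TRUE),
      stratum = "Shallow",
      sediment_pref = sample(sediment_classes()[1:5], n, replace = TRUE),
      vessel_id = sample(vessels, n, replace = TRUE),
      gear_detail = NA_real_, dominance = 1
    )
    hauls <- dplyr::bind_rows(hauls, tail_hauls)
  }
  n <- nrow(hauls)
  hauls$haul_id <- sprintf("H%06d", seq_len(n))

  # -- placement and timestamps ---------------------------------------------
  ci <- place_hauls(cells, hauls$area, hauls$stratum, hauls$sediment_pref,
                    hauls$spec_name)
  jit <- config$grid$pixel * 0.49
  lon <- cells$lon[ci] + stats::runif(n, -jit, jit)
  lat <- cells$lat[ci] + stats::runif(n, -jit, jit)
  month <- season_month(hauls$season)
  day <- sample.int(28L, n, replace = TRUE)
  set_time <- as.POSIXct(sprintf("%d-%02d-%02d %02d:%02d:00",
                                 hauls$year, month, day,
                                 sample.int(16L, n, replace = TRUE) + 3L,
                                 sample.int(60L, n, replace = TRUE) - 1L),
                         tz = "UTC")
  hauls <- dplyr::mutate(
    hauls,
    set_time = set_time,
    haul_time = set_time + round(stats::runif(n, 2, 8) * 3600),
    set_lat = lat, set_lon = lon, haul_lat = lat, haul_lon = lon,
    fao_subarea = "27.9",
    trip_id = paste0("T_", .data$vessel_id, "_",
                     format(set_time, "%Y%m%d"))
  )

  # -- catches ---------------------------------------------------------------
  meanlog <- vapply(specs, function(m) m$weight_meanlog, numeric(1))
  sdlog <- vapply(specs, function(m) m$weight_sdlog, numeric(1))
  ml <- ifelse(hauls$is_tail, log(20), meanlog[hauls$spec])
  sl <- ifelse(hauls$is_tail, 0.5, sdlog[hauls$spec])
  tw <- stats::rlnorm(n, ml, sl)
  target_catch <- tibble::tibble(
    haul_id = hauls$haul_id, species = hauls$target, weight_kg = tw,
    is_target = TRUE)

  by_list <- lapply(seq_along(specs), function(i) {
    m <- specs[[i]]
    if (!length(m$bycatch_pool)) return(NULL)
    rows <- which(hauls$spec == i & !hauls$is_tail)
    if (!length(rows)) return(NULL)
    pool <- m$bycatch_pool
    pres <- matrix(stats::runif(length(rows) * length(pool)) < 0.45,
                   length(rows), length(pool))
    none <- rowSums(pres) == 0L
    if (any(none)) {  # guarantee at least one bycatch species per haul
      pres[cbind(which(none),
                 sample.int(length(pool), sum(none), replace = TRUE))] <- TRUE
    }
    idx <- which(pres, arr.ind = TRUE)
    tibble::tibble(
      haul_id = hauls$haul_id[rows[idx[, 1]]],
      species = names(pool)[idx[, 2]],
      weight_kg = tw[rows[idx[, 1]]] * pool[idx[, 2]] *
        stats::rlnorm(nrow(idx), 0, 0.4),
      is_target = FALSE)
  })
  catches <- dplyr::bind_rows(target_catch, dplyr::bind_rows(by_list))

  # -- trip-level prices -----------------------------------------------------
  base <- base_price_table(specs)
  price_tbl <- dplyr::distinct(
    dplyr::left_join(catches, hauls[, c("haul_id", "trip_id")],
                     by = "haul_id"),
    .data$trip_id, .data$species)
  bp <- base[price_tbl$species]
  bp[is.na(bp)] <- 3  # default price for rare-tail species
  price_tbl$price <- bp * stats::rlnorm(nrow(price_tbl), 0, 0.1)

  # -- enforce target dominance with probability d ---------------------------
  catches <- dplyr::left_join(catches, hauls[, c("haul_id", "trip_id")],
                              by = "haul_id")
  catches <- dplyr::left_join(catches, price_tbl,
                              by = c("trip_id", "species"))
  catches$value <- catches$weight_kg * catches$price
  tval <- stats::setNames(catches$value[catches$is_target],
                          catches$haul_id[catches$is_target])
  win <- stats::runif(n) <= hauls$dominance
  win_h <- stats::setNames(win, hauls$haul_id)

  bc <- !catches$is_target
  v_t <- tval[catches$haul_id]
  # winning hauls: cap every bycatch value strictly below the target's
  cap <- bc & win_h[catches$haul_id] & catches$value >= v_t
  if (any(cap)) {
    frac <- stats::runif(sum(cap), 0.2, 0.8)
    catches$weight_kg[cap] <- frac * v_t[cap] / catches$price[cap]
  }
  # losing hauls: boost one bycatch species above the target
  lose_ids <- hauls$haul_id[!win]
  bc_idx <- which(bc & catches$haul_id %in% lose_ids)
  if (length(bc_idx)) {
    pick <- vapply(split(bc_idx, catches$haul_id[bc_idx]),
                   function(ix) ix[sample.int(length(ix), 1L)], integer(1))
    boost <- 1 + stats::runif(length(pick), 0.1, 0.8)
    catches$weight_kg[pick] <- boost * v_t[pick] / catches$price[pick]
  }
  catches$value <- NULL

  # -- violation injection ---------------------------------------------------
  haul_rates <- unlist(config$rates[c("outside_subarea", "depth_gt_2000",
                                      "misc_gear", "zero_catch",
                                      "missing_price", "inflated_weight")])
  draw <- sample(c(names(haul_rates), "clean"), n, replace = TRUE,
                 prob = c(haul_rates, 1 - sum(haul_rates)))
  viol <- tibble::tibble(haul_id = hauls$haul_id, rule = draw)
  viol <- viol[viol$rule != "clean", ]

  hauls$fao_subarea[draw == "outside_subarea"] <- "27.8"
  deep_cells <- which(env$depth$values > 2000)
  if (any(draw == "depth_gt_2000")) {
    k <- which(draw == "depth_gt_2000")
    pick <- deep_cells[sample.int(length(deep_cells), length(k),
                                  replace = TRUE)]
    rr <- (pick - 1L) %% nrow(env$depth$values) + 1L
    cc <- (pick - 1L) %/% nrow(env$depth$values) + 1L
    dlon <- config$grid$lon[1] + (cc - 0.5) * config$grid$pixel
    dlat <- config$grid$lat[1] + (rr - 0.5) * config$grid$pixel
    hauls$set_lon[k] <- hauls$haul_lon[k] <- dlon
    hauls$set_lat[k] <- hauls$haul_lat[k] <- dlat
  }
  hauls$gear_code[draw == "misc_gear"] <- "MIS"
  hauls$gear_detail[draw == "misc_gear"] <- NA_real_
  catches <- catches[!catches$haul_id %in% hauls$haul_id[draw == "zero_catch"], ]

  np <- which(draw == "missing_price")
  if (length(np)) {  # haul-unique species that never reaches the sales note
    catches <- dplyr::bind_rows(catches, tibble::tibble(
      haul_id = hauls$haul_id[np], species = paste0("NPX", np),
      weight_kg = 1, is_target = FALSE, trip_id = hauls$trip_id[np],
      price = NA_real_, no_sale = TRUE))
  }
  fl <- which(draw == "inflated_weight")
  if (length(fl)) {  # logbook weight four times the sold weight
    catches <- dplyr::bind_rows(catches, tibble::tibble(
      haul_id = hauls$haul_id[fl], species = paste0("IFL", fl),
      weight_kg = 20, is_target = FALSE, trip_id = hauls$trip_id[fl],
      price = 4, inflated = TRUE))
  }
  for (flagcol in c("no_sale", "inflated")) {
    if (!flagcol %in% names(catches)) catches[[flagcol]] <- FALSE
    catches[[flagcol]][is.na(catches[[flagcol]])] <- FALSE
  }

  # -- trips and sales notes -------------------------------------------------
  home_port <- stats::setNames(
    sample(mainland_ports(), length(vessels), replace = TRUE), vessels)
  trips <- dplyr::summarise(
    hauls, vessel_id = .data$vessel_id[1],
    landing_date = as.Date(max(.data$haul_time)),
    .by = "trip_id")
  nm <- stats::runif(nrow(trips)) < config$rates$non_mainland_trip
  trips$departure_port <- home_port[trips$vessel_id]
  trips$dep_mainland <- TRUE
  trips$return_port <- ifelse(nm, island_ports()[1],
                              home_port[trips$vessel_id])
  trips$ret_mainland <- !nm
  if (any(nm)) {
    viol <- dplyr::bind_rows(viol, tibble::tibble(
      haul_id = hauls$haul_id[hauls$trip_id %in% trips$trip_id[nm]],
      rule = "non_mainland_trip"))
  }

  sold <- catches[!catches$no_sale, ]
  sold$weight_kg[sold$inflated] <- sold$weight_kg[sold$inflated] / 4
  lines <- dplyr::summarise(
    sold, sold_weight_kg = sum(.data$weight_kg),
    price = .data$price[1], .by = c("trip_id", "species"))
  lines$sold_value <- lines$sold_weight_kg * lines$price
  lines <- lines[, c("trip_id", "species", "sold_weight_kg", "sold_value",
                     "price")]
  notes <- trips[, c("trip_id", "vessel_id", "landing_date",
                     "departure_port", "dep_mainland", "return_port",
                     "ret_mainland")]

  haul_cols <- c("haul_id", "trip_id", "vessel_id", "gear_code",
                 "gear_detail", "set_time", "haul_time", "set_lat",
                 "set_lon", "haul_lat", "haul_lon", "fao_subarea")
  truth <- list(
    hauls = tibble::tibble(
      haul_id = hauls$haul_id, metier = hauls$spec_name,
      target = hauls$target, is_tail = hauls$is_tail,
      season = hauls$season, area = hauls$area, stratum = hauls$stratum,
      year = hauls$year),
    violations = dplyr::arrange(viol, .data$haul_id)
  )

  list(
    hauls = dplyr::mutate(hauls[, haul_cols],
                          detail_kind = gear_detail_kind(.data$gear_code),
                          .after = "gear_detail"),
    catches = catches[, c("haul_id", "species", "weight_kg")],
    sales = list(notes = notes, lines = lines,
                 errors = tibble::tibble(line = integer(),
                                         field = character(),
                                         reason = character())),
    truth = truth
  )
}
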