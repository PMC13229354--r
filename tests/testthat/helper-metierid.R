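# Shared fixtures and independent oracles for the test suite.

tiny_grid <- function(value, kind = "depth", n = 10, origin = c(-10, 38),
                      pixel = 0.009, nodata = -9999) {
  env_grid(matrix(value, n, n), origin = origin, pixel = pixel,
           nodata = nodata, kind = kind)
}

# Brute-force chi-square statistics, written from the definition so they
# stay independent of stats::chisq.test.
oracle_gof_stat <- function(counts) {
  e <- sum(counts) / length(counts)
  sum((counts - e)^2 / e)
}

oracle_indep_stat <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# Upper-tail probability by numerical integration of the density (not the
# distribution function the implementation relies on).
oracle_upper_tail <- function(stat, df) {
  stats::integrate(function(x) stats::dchisq(x, df), stat, Inf,
                   rel.tol = 1e-10)$value
}

# Knee location by explicit point-to-line geometry (cross-product distance
# to the chord), evaluated at every rank of the normalized truncated curve.
oracle_knee <- function(counts, max_rank = 20) {
  n <- length(counts)
  if (n == 1) return(1L)
  r <- min(n, max_rank)
  c_r <- counts[seq_len(r)]
  if (c_r[1] == c_r[r]) return(n)
  x <- (seq_len(r) - 1) / (r - 1)
  y <- (c_r - c_r[r]) / (c_r[1] - c_r[r])
  p1 <- c(x[1], y[1]); p2 <- c(x[r], y[r])
  v <- p2 - p1
  d <- vapply(seq_len(r), function(i) {
    w <- c(x[i], y[i]) - p1
    abs(v[1] * w[2] - v[2] * w[1]) / sqrt(sum(v^2))
  }, numeric(1))
  max(which(d > max(d) - 1e-12))
}

# A minimal valid logbook/sales pair built in code (two trips, three hauls,
# one of them zero-catch evidence).
tiny_records <- function() {
  hauls <- tibble::tibble(
    haul_id = c("H1", "H2", "H3"),
    trip_id = c("T1", "T1", "T2"),
    vessel_id = c("V1", "V1", "V2"),
    gear_code = c("GNS", "GNS", "FPO"),
    gear_detail = c(100, 100, NA),
    detail_kind = gear_detail_kind(c("GNS", "GNS", "FPO")),
    set_time = as.POSIXct(c("2020-02-10 06:00:00", "2020-02-10 09:00:00",
                            "2020-07-01 05:00:00"), tz = "UTC"),
    haul_time = as.POSIXct(c("2020-02-10 08:00:00", "2020-02-10 12:00:00",
                             "2020-07-01 09:00:00"), tz = "UTC"),
    set_lat = c(39.0, 39.1, 37.5), set_lon = c(-9.5, -9.4, -9.2),
    haul_lat = c(39.2, 39.1, 37.5), haul_lon = c(-9.3, -9.4, -9.2),
    fao_subarea = "27.9")
  catches <- tibble::tibble(
    haul_id = c("H1", "H1", "H2"),
    species = c("HKE", "HOM", "HKE"),
    weight_kg = c(100, 30, 60))
  notes <- tibble::tibble(
    trip_id = c("T1", "T2"), vessel_id = c("V1", "V2"),
    landing_date = as.Date(c("2020-02-11", "2020-07-02")),
    departure_port = "PENICHE", dep_mainland = TRUE,
    return_port = "PENICHE", ret_mainland = TRUE)
  lines <- tibble::tibble(
    trip_id = c("T1", "T1"), species = c("HKE", "HOM"),
    sold_weight_kg = c(160, 30), sold_value = c(640, 45)) |>
    dplyr::mutate(price = sold_value / sold_weight_kg)
  list(hauls = hauls, catches = catches,
       sales = list(notes = notes, lines = lines))
}

# A reduced two-gear fleet for fast simulation tests: three planted metiers
# per gear with steeply decaying haul counts, as in the full default fleet.
small_specs <- function(d = 0.9, mult = 1) {
  pool <- c(HOM = 0.3, MAC = 0.25, GUU = 0.2, POD = 0.2, BOG = 0.2,
            WEG = 0.15)
  mk <- function(name, gear, target, rate, price, sw, aw, dw) {
    metier_spec(name, gear, target, rate * mult, price,
                detail_values = c(80, 100), bycatch_pool = pool,
                dominance = d, season_weights = sw, area_weights = aw,
                depth_weights = dw,
                sediment_weights = c(Sand = 0.6, Mud = 0.4))
  }
  list(
    mk("gnA", "GNS", "HKE", 2000, 5.5, c(.05, .45, .45, .05),
       c(.8, .1, .05, .05), c(.45, .45, .1)),
    mk("gnB", "GNS", "MON", 500, 9, c(.1, .1, .7, .1),
       c(.05, .05, .2, .7), c(.85, .15, 0)),
    mk("gnC", "GNS", "SOL", 200, 12, c(.45, .05, .05, .45),
       c(.7, .1, .1, .1), c(.9, .1, 0)),
    mk("gtA", "GTR", "CTC", 2000, 7, c(.45, .05, .05, .45),
       c(.8, .1, .05, .05), c(.9, .1, 0)),
    mk("gtB", "GTR", "JOD", 500, 15, c(.1, .1, .7, .1),
       c(.45, .05, .45, .05), c(.85, .15, 0)),
    mk("gtC", "GTR", "BSS", 200, 6, c(.7, .1, .1, .1),
       c(.7, .1, .1, .1), c(.9, .1, 0)))
}

small_config <- function(seed = 1, years = 2020, d = 0.9, tail_n = 20,
                         zero_rates = FALSE, mult = 1, metiers = NULL) {
  rates <- if (zero_rates) {
    list(outside_subarea = 0, depth_gt_2000 = 0, misc_gear = 0,
         zero_catch = 0, missing_price = 0, inflated_weight = 0,
         non_mainland_trip = 0)
  } else {
    list()  # package defaults
  }
  metiers <- metiers %||% small_specs(d = d, mult = mult)
  sim_config(seed = seed, years = years, n_vessels = 40,
             metiers = metiers,
             rare_tail = list(
               n = tail_n, hauls_range = c(1, 10),
               gears = unique(vapply(metiers, function(m) m$gear_code,
                                     character(1)))),
             rates = rates)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Environmental grids are deterministic given the config seed and identical
# grid parameters; build them once per test run.
local({
  cache <- new.env(parent = emptyenv())
  shared_env <<- function() {
    if (is.null(cache$env)) cache$env <- generate_env(small_config(seed = 99))
    cache$env
  }
})

dom_set <- function(s) sort(strsplit(s, "; ", fixed = TRUE)[[1]])

# A reported dominant-level set is consistent with a planted preference when
# it is non-empty and every reported level is among the planted dominant
# levels. The >50%/top-2 reporting rule is discontinuous at the majority
# boundary (a planted 0.45/0.45 pair can legitimately report either both
# levels or the one that crossed 50% in sample), so consistency, not set
# equality, is the meaningful recovery check.
dominant_consistent <- function(reported, weights) {
  got <- dom_set(reported)
  length(got) > 0 && all(got %in% dominant_levels(weights))
}
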