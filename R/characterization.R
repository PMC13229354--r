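variable_levels <- function(variable, years = NULL) {
  switch(variable,
         year = as.character(years),
         season = season_levels(),
         area = area_levels(),
         depth = depth_levels(),
         sediment = sediment_classes(),
         stop("unknown variable: ", variable, call. = FALSE))
}

#' Haul counts (effort proxy) over the levels of a variable
#'
#' The number of hauls is the proxy for fishing effort. Counts cover the
#' variable's full level set, zeros included. For the `area` variable,
#' hauls flagged as outside the area coverage are excluded.
#'
#' @param annotated annotated (and assigned) hauls.
#' @param variable one of `"year"`, `"season"`, `"area"`, `"depth"`,
#'   `"sediment"`.
#' @param metier optional metier key to filter on.
#' @param years the study years (level set of the `year` variable);
#'   defaults to the years present.
#' @return Named integer vector of counts.
#' @export
effort_counts <- function(annotated, variable, metier = NULL, years = NULL) {
  if (!is.null(metier)) {
    annotated <- annotated[annotated$metier == metier, ]
  }
  if (is.null(years)) years <- sort(unique(annotated$year))
  lev <- variable_levels(variable, years)
  x <- switch(variable,
              year = as.character(annotated$year),
              season = annotated$season,
              area = annotated$area[!annotated$area_flagged],
              depth = annotated$depth_stratum,
              sediment = annotated$sediment)
  tab <- table(factor(x, levels = lev))
  stats::setNames(as.integer(tab), lev)
}

#' Area x season contingency table for one metier
#'
#' @inheritParams effort_counts
#' @return Integer matrix, areas in rows, seasons in columns.
#' @export
area_season_table <- function(annotated, metier = NULL) {
  if (!is.null(metier)) {
    annotated <- annotated[annotated$metier == metier, ]
  }
  annotated <- annotated[!annotated$area_flagged, ]
  unclass(table(factor(annotated$area, levels = area_levels()),
                factor(annotated$season, levels = season_levels())))
}

new_test_result <- function(observed, statistic = NA_real_, df = NA_real_,
                            p = NA_real_, applied = FALSE, reason = NA_character_) {
  list(observed = observed, statistic = statistic, df = df, p = p,
       applied = applied, reason = reason,
       advisory_nonuniform = !applied && !is.na(reason) &&
         reason == "observed frequency below guard")
}

#' Guarded chi-square goodness-of-fit test against uniform effort
#'
#' Null hypothesis: fishing effort is uniformly distributed across the
#' levels. The test is not applied when any observed level frequency is
#' below `guard_min` (usually a zero); in that case `applied` is FALSE and
#' `advisory_nonuniform` is set — for large samples an absent level is an
#' intentional choice not to fish there, which the discussion treats as
#' non-uniform effort, but no p-value is reported.
#'
#' @param counts named integer vector of observed level counts (zeros
#'   included).
#' @param guard_min minimum observed frequency for the test to be applied.
#' @return List: `observed`, `statistic`, `df`, `p`, `applied`, `reason`,
#'   `advisory_nonuniform`.
#' @export
gof_uniform <- function(counts, guard_min = 5) {
  if (length(counts) < 2) stop("need at least two levels", call. = FALSE)
  if (sum(counts) == 0) {
    return(new_test_result(counts, reason = "no hauls"))
  }
  if (any(counts < guard_min)) {
    return(new_test_result(counts, reason = "observed frequency below guard"))
  }
  ct <- suppressWarnings(stats::chisq.test(counts))
  new_test_result(counts, statistic = unname(ct$statistic),
                  df = unname(ct$parameter), p = ct$p.value, applied = TRUE)
}

#' Guarded chi-square test of independence (area x season)
#'
#' All-zero rows and columns are dropped first; the test needs at least a
#' 2 x 2 table and, like [gof_uniform()], is not applied when any remaining
#' observed cell is below `guard_min`. No continuity correction is used.
#'
#' @param tab integer matrix of observed counts.
#' @param guard_min minimum observed cell frequency.
#' @return As [gof_uniform()].
#' @export
independence_test <- function(tab, guard_min = 5) {
  tab <- as.matrix(tab)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    return(new_test_result(tab, reason = "degenerate table"))
  }
  if (any(tab < guard_min)) {
    return(new_test_result(tab, reason = "observed frequency below guard"))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  new_test_result(tab, statistic = unname(ct$statistic),
                  df = unname(ct$parameter), p = ct$p.value, applied = TRUE)
}

#' Bonferroni adjustment across the applied tests of one variable
#'
#' `p_adj = min(1, p * m)` with `m` the number of tests actually applied
#' for that variable across metiers.
#'
#' @param p numeric vector of raw p-values (applied tests only).
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(p) stats::p.adjust(p, method = "bonferroni")

#' Ordinary-least-squares trend in yearly haul counts
#'
#' Counts are regressed on calendar year; missing years count zero and the
#' slope's two-sided p-value tests for a temporal trend in metier use.
#' Identical counts every year have zero variance: the slope is 0 and the
#' p-value is reported as 1 by convention.
#'
#' @param counts integer vector of yearly haul counts, one per year.
#' @param years the corresponding calendar years (>= 3).
#' @return List: `counts`, `years`, `slope` (hauls/year), `p`, `n_years`.
#' @export
trend_test <- function(counts, years) {
  stopifnot(length(counts) == length(years), length(years) >= 3)
  if (length(unique(counts)) == 1) {
    return(list(counts = counts, years = years, slope = 0, p = 1,
                n_years = length(years)))
  }
  fit <- stats::lm(counts ~ years)
  cf <- summary(fit)$coefficients
  list(counts = counts, years = years, slope = unname(cf[2, 1]),
       p = unname(cf[2, 4]), n_years = length(years))
}

#' Gridded fishing effort (haul counts per cell)
#'
#' Bins haul midpoints into square cells; the count grid is the analysis
#' surface behind effort heat maps.
#'
#' @param annotated annotated hauls (optionally pre-filtered to a metier).
#' @param metier optional metier key to filter on.
#' @param cell_size cell side in degrees.
#' @param bbox optional list with `lon` and `lat` ranges; defaults to the
#'   cell-aligned bounding box of the midpoints.
#' @return List of class `effort_grid`: `counts` matrix (rows = latitude
#'   bands, south first), `origin`, `cell_size`, `n_oob`.
#' @export
effort_grid <- function(annotated, metier = NULL, cell_size = 0.05,
                        bbox = NULL) {
  stopifnot(cell_size > 0)
  if (!is.null(metier)) {
    annotated <- annotated[annotated$metier == metier, ]
  }
  lon <- annotated$mid_lon
  lat <- annotated$mid_lat
  if (is.null(bbox)) {
    bbox <- list(
      lon = c(floor(min(lon) / cell_size), ceiling(max(lon) / cell_size +
                                                     1e-9)) * cell_size,
      lat = c(floor(min(lat) / cell_size), ceiling(max(lat) / cell_size +
                                                     1e-9)) * cell_size)
  }
  ncol <- max(1L, ceiling((bbox$lon[2] - bbox$lon[1]) / cell_size - 1e-9))
  nrow <- max(1L, ceiling((bbox$lat[2] - bbox$lat[1]) / cell_size - 1e-9))
  cc <- floor((lon - bbox$lon[1]) / cell_size) + 1L
  rr <- floor((lat - bbox$lat[1]) / cell_size) + 1L
  inb <- cc >= 1L & cc <= ncol & rr >= 1L & rr <= nrow
  counts <- matrix(0L, nrow, ncol)
  if (any(inb)) {
    t <- table(factor(rr[inb], levels = seq_len(nrow)),
               factor(cc[inb], levels = seq_len(ncol)))
    counts <- matrix(as.integer(t), nrow, ncol)
  }
  structure(list(counts = counts, origin = c(bbox$lon[1], bbox$lat[1]),
                 cell_size = cell_size, n_oob = sum(!inb)),
            class = "effort_grid")
}

#' Dominant levels of a share vector
#'
#' The reporting rule for the per-metier summary: levels holding more than
#' half of the hauls stand alone; otherwise the two largest levels are
#' listed (ties resolved in level order).
#'
#' @param shares named numeric vector of level shares (sums to 1).
#' @return Character vector of dominant level names.
#' @export
dominant_levels <- function(shares) {
  if (any(shares > 0.5)) {
    return(names(shares)[which.max(shares)])
  }
  names(shares)[order(-shares)[1:min(2, length(shares))]]
}

#' Chi-square and trend characterization of a set of metiers
#'
#' For each metier: guarded goodness-of-fit tests for area, season and
#' depth; the guarded independence test for area x season; and the OLS
#' yearly trend. Bonferroni families are formed per variable across
#' metiers, counting only the applied tests. Decisions use the adjusted
#' p-values at `alpha`.
#'
#' @param annotated annotated, assigned hauls.
#' @param metiers metier keys to characterize (default: all present).
#' @param years study years.
#' @param alpha significance level.
#' @param guard_min observed-frequency guard for the chi-square tests.
#' @return List with `tests` (one row per metier x variable) and `trends`
#'   (one row per metier).
#' @export
characterize_metiers <- function(annotated, metiers = NULL, years = NULL,
                                 alpha = 0.01, guard_min = 5) {
  if (is.null(metiers)) metiers <- sort(unique(annotated$metier))
  if (is.null(years)) years <- sort(unique(annotated$year))

  one <- function(m) {
    res <- list(
      area = gof_uniform(effort_counts(annotated, "area", m), guard_min),
      season = gof_uniform(effort_counts(annotated, "season", m), guard_min),
      depth = gof_uniform(effort_counts(annotated, "depth", m), guard_min),
      `area_x_season` = independence_test(area_season_table(annotated, m),
                                          guard_min))
    purrr::imap(res, function(t, v) {
      tibble::tibble(metier = m, variable = v, statistic = t$statistic,
                     df = t$df, p = t$p, applied = t$applied,
                     advisory_nonuniform = t$advisory_nonuniform)
    }) |> dplyr::bind_rows()
  }
  tests <- dplyr::bind_rows(lapply(metiers, one))
  tests <- tests |>
    dplyr::mutate(p_adj = {
      out <- rep(NA_real_, dplyr::n())
      out[.data$applied] <- bonferroni_adjust(.data$p[.data$applied])
      out
    }, .by = "variable") |>
    dplyr::mutate(reject = .data$applied & .data$p_adj < alpha)

  trends <- lapply(metiers, function(m) {
    tr <- trend_test(effort_counts(annotated, "year", m, years = years),
                     years)
    tibble::tibble(metier = m, slope = tr$slope, p = tr$p,
                   significant = tr$p < alpha, n_years = tr$n_years)
  }) |> dplyr::bind_rows()

  list(tests = tests, trends = trends)
}

detail_descriptor <- function(details) {
  d <- details[!is.na(details)]
  if (!length(d)) {
    return(list(modal = "0", range = "0"))
  }
  tab <- sort(table(d), decreasing = TRUE)
  vals <- sort(unique(d))
  rng <- if (length(vals) == 1) format(vals, trim = TRUE) else
    paste0(format(min(vals), trim = TRUE), "-", format(max(vals), trim = TRUE))
  list(modal = names(tab)[1], range = rng)
}

#' Per-metier summary table of the selected metiers
#'
#' One row per selected metier, sorted by descending haul count: gear,
#' metier key, rendered level-6-style label (selectivity descriptor from
#' the modal gear detail), haul count, the observed mesh/hook range, the
#' dominant season / area / depth / sediment levels (rule of
#' [dominant_levels()], multiple levels joined by `"; "`), and the
#' validation status carried over from the selection.
#'
#' @param annotated annotated, assigned hauls.
#' @param selection a [select_metiers()] result.
#' @param years study years.
#' @return A tibble.
#' @export
summary_report <- function(annotated, selection, years = NULL) {
  sel <- selection$table[selection$table$selected, ]
  rows <- lapply(seq_len(nrow(sel)), function(i) {
    m <- sel$metier[i]
    h <- annotated[annotated$metier == m, ]
    des <- detail_descriptor(h$gear_detail)
    dom <- function(variable) {
      cnt <- effort_counts(h, variable, years = years)
      paste(dominant_levels(cnt / sum(cnt)), collapse = "; ")
    }
    tibble::tibble(
      gear_code = sel$gear_code[i], metier = m,
      label = paste0(m, "_", des$modal),
      n_hauls = sel$n_hauls[i], detail_range = des$range,
      season = dom("season"), area = dom("area"), depth = dom("depth"),
      sediment = dom("sediment"),
      status = sel$status[i], source = sel$source[i])
  })
  dplyr::bind_rows(rows) |> dplyr::arrange(dplyr::desc(.data$n_hauls))
}
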