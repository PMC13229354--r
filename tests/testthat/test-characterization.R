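ann_fixture <- function() {
  # 10 winter hauls of one metier in the NW, plus filler for a second metier
  tibble::tibble(
    haul_id = sprintf("H%02d", 1:14),
    metier = c(rep("GNS_HKE", 10), rep("FPO_OCC", 4)),
    gear_code = c(rep("GNS", 10), rep("FPO", 4)),
    gear_detail = c(rep(100, 10), rep(NA, 4)),
    year = 2020L,
    season = c(rep("Winter", 10), rep("Summer", 4)),
    area = "NW", area_flagged = FALSE,
    depth_stratum = "Shallow", sediment = "Sand",
    mid_lon = -9.3, mid_lat = 39.8,
    vessel_id = "V1", trip_id = "T1")
}

test_that("effort counts cover the full level set with zeros", {
  ann <- ann_fixture()
  cnt <- effort_counts(ann, "season", metier = "GNS_HKE")
  expect_equal(cnt, c(Winter = 10L, Spring = 0L, Summer = 0L, Autumn = 0L))
  expect_equal(sum(effort_counts(ann, "area", metier = "GNS_HKE")), 10)
  expect_error(effort_counts(ann, "moon_phase"), "unknown variable")
})

test_that("effort proportions reproduce the planted weights", {
  spec <- metier_spec("prop", "GNS", "HKE", 5500, 5.5,
                      season_weights = c(.1, .2, .3, .4),
                      area_weights = c(.4, .3, .2, .1),
                      depth_weights = c(.5, .3, .2))
  cfg <- small_config(seed = 51, tail_n = 0, zero_rates = TRUE,
                      metiers = list(spec))
  env <- shared_env()
  rec <- generate_records(cfg, env)
  ann <- annotate_hauls(rec$hauls, env$depth, env$sediment)
  ann$metier <- paste(ann$gear_code, "HKE", sep = "_")
  cnt <- effort_counts(ann, "season", metier = "GNS_HKE")
  n <- sum(cnt)
  expect_gte(n, 5000)
  for (i in 1:4) {
    p <- spec$season_weights[i]
    se <- sqrt(n * p * (1 - p))
    expect_lt(abs(cnt[i] - n * p), 3 * se + 1)
  }
})

test_that("gof_uniform matches hand calculations and applies the guard", {
  r <- gof_uniform(c(50, 50, 50, 50))
  expect_true(r$applied)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)

  guarded <- gof_uniform(c(4, 100))
  expect_false(guarded$applied)
  expect_true(guarded$advisory_nonuniform)
  expect_true(is.na(guarded$statistic))

  r2 <- gof_uniform(c(30, 10))
  expect_equal(r2$statistic, 10)
  expect_equal(r2$df, 1)
  expect_equal(r2$p, oracle_upper_tail(10, 1), tolerance = 1e-8)
  expect_equal(r2$p, 1.565402e-3, tolerance = 1e-4)

  empty <- gof_uniform(c(0, 0, 0), guard_min = 0)
  expect_false(empty$applied)
  expect_false(empty$advisory_nonuniform)
})

test_that("independence_test matches hand calculations and applies the guard", {
  r <- independence_test(matrix(20, 2, 2))
  expect_true(r$applied)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)

  guarded <- independence_test(matrix(c(30, 10, 4, 30), 2, 2))
  expect_false(guarded$applied)

  r2 <- independence_test(matrix(c(30, 10, 10, 30), 2, 2))
  expect_equal(r2$statistic, 20)
  expect_equal(r2$df, 1)
  expect_equal(r2$p, oracle_upper_tail(20, 1), tolerance = 1e-8)

  degenerate <- independence_test(matrix(c(10, 20, 30, 0, 0, 0), 2, 3,
                                         byrow = TRUE))
  expect_false(degenerate$applied)
  expect_equal(degenerate$reason, "degenerate table")
})

test_that("chi-square statistics match the brute-force oracle on random tables", {
  set.seed(14)
  for (i in 1:100) {
    counts <- stats::rpois(sample(2:6, 1), 40) + 5
    r <- gof_uniform(counts)
    expect_equal(r$statistic, oracle_gof_stat(counts), tolerance = 1e-12)
    tab <- matrix(stats::rpois(4, 40) + 5, 2, 2)
    ri <- independence_test(tab)
    expect_equal(ri$statistic, oracle_indep_stat(tab), tolerance = 1e-12)
  }
})

test_that("guarded results are invariant under level reordering", {
  counts <- c(Winter = 30L, Spring = 12L, Summer = 44L, Autumn = 9L)
  perm <- counts[c(3, 1, 4, 2)]
  expect_equal(gof_uniform(counts)$statistic, gof_uniform(perm)$statistic)
  expect_equal(gof_uniform(counts)$p, gof_uniform(perm)$p)
  tab <- matrix(c(12, 9, 30, 17, 25, 7), 2, 3)
  expect_equal(independence_test(tab)$statistic,
               independence_test(tab[2:1, c(2, 3, 1)])$statistic)
})

test_that("Bonferroni adjustment is exact and never rejects beyond Holm", {
  expect_equal(bonferroni_adjust(c(0.004, 0.2, 0.3))[1], 0.012)
  expect_equal(bonferroni_adjust(c(0.5, rep(0.9, 9)))[1], 1)
  set.seed(15)
  for (i in 1:50) {
    p <- runif(sample(2:20, 1))^sample(1:3, 1)
    bon <- bonferroni_adjust(p) < 0.01
    holm <- stats::p.adjust(p, "holm") < 0.01
    expect_true(all(!bon | holm))  # Bonferroni rejections are a subset
  }
})

test_that("yearly trend regression recovers exact and planted slopes", {
  years <- 2014:2023
  r <- trend_test(seq(10, 100, by = 10), years)
  expect_equal(r$slope, 10)
  expect_lt(r$p, 1e-10)
  flat <- trend_test(rep(50, 10), years)
  expect_equal(flat$slope, 0)
  expect_equal(flat$p, 1)
  expect_error(trend_test(c(1, 2), 2014:2015), "length")

  set.seed(16)
  slopes <- replicate(50, {
    counts <- 100 + 5 * (years - 2014) + rnorm(10, 0, 3)
    trend_test(counts, years)$slope
  })
  se_mean <- 3 / sqrt(sum((years - mean(years))^2)) / sqrt(50)
  expect_lt(abs(mean(slopes) - 5), 3 * se_mean)
})

test_that("effort grids bin midpoints and conserve haul counts", {
  ann <- ann_fixture()
  g <- effort_grid(ann, metier = "GNS_HKE", cell_size = 0.05)
  expect_equal(sum(g$counts), 10)
  expect_equal(sum(g$counts > 0), 1)
  set.seed(17)
  ann2 <- tibble::tibble(metier = "M", mid_lon = runif(500, -10, -8),
                         mid_lat = runif(500, 36, 40))
  g2 <- effort_grid(ann2, cell_size = 0.05)
  expect_equal(sum(g2$counts) + g2$n_oob, 500)
  expect_equal(g2$n_oob, 0)
})

test_that("a planted single-area metier concentrates its effort mass there", {
  spec <- metier_spec("nw-only", "GNS", "HKE", 800, 5.5,
                      area_weights = c(1, 0, 0, 0),
                      depth_weights = c(.6, .4, 0))
  cfg <- small_config(seed = 61, tail_n = 0, zero_rates = TRUE,
                      metiers = list(spec))
  env <- shared_env()
  rec <- generate_records(cfg, env)
  ann <- annotate_hauls(rec$hauls, env$depth, env$sediment)
  expect_gte(mean(ann$area == "NW"), 0.95)
})

test_that("dominant levels follow the majority / top-two rule", {
  expect_equal(dominant_levels(c(Winter = .8, Spring = .1, Summer = .05,
                                 Autumn = .05)), "Winter")
  expect_equal(dominant_levels(c(A = .40, B = .35, C = .15, D = .10)),
               c("A", "B"))
})

test_that("characterize_metiers corrects within variable and flags guards", {
  ann <- ann_fixture()
  res <- characterize_metiers(ann, years = 2018:2020)
  tests <- res$tests
  # 10 hauls all in one season: guard triggers (three zero levels)
  gns_season <- tests[tests$metier == "GNS_HKE" &
                        tests$variable == "season", ]
  expect_false(gns_season$applied)
  expect_true(gns_season$advisory_nonuniform)
  expect_equal(nrow(res$trends), 2)

  # balanced fixture where every test is applied: Bonferroni multiplies by
  # the applied-test count of the variable family
  grid <- expand.grid(area = area_levels(), season = season_levels(),
                      rep = 1:5, metier = c("GNS_HKE", "GNS_MON"),
                      stringsAsFactors = FALSE)
  ann3 <- tibble::tibble(
    haul_id = sprintf("H%03d", seq_len(nrow(grid))),
    metier = grid$metier, gear_code = "GNS", gear_detail = 100,
    year = rep_len(2018:2020, nrow(grid)),
    season = grid$season, area = grid$area, area_flagged = FALSE,
    depth_stratum = rep_len(depth_levels(), nrow(grid)),
    sediment = "Sand", mid_lon = -9.3, mid_lat = 39.8,
    vessel_id = "V1", trip_id = "T1")
  res3 <- characterize_metiers(ann3, years = 2018:2020)
  applied <- res3$tests[res3$tests$applied, ]
  expect_equal(nrow(applied), 8)  # 2 metiers x 4 variables
  for (v in unique(applied$variable)) {
    fam <- applied[applied$variable == v, ]
    expect_equal(fam$p_adj, pmin(1, fam$p * nrow(fam)))
  }
  expect_false(any(applied$reject))  # perfectly balanced effort
})

test_that("the summary report applies the dominance rule per variable", {
  ann <- ann_fixture()
  sel <- select_metiers(rank_metiers(ann), n_years = 1)
  rep <- summary_report(ann, sel, years = 2020)
  expect_equal(rep$metier, c("GNS_HKE", "FPO_OCC"))  # descending hauls
  expect_equal(rep$season[rep$metier == "GNS_HKE"], "Winter")
  expect_equal(rep$label[rep$metier == "GNS_HKE"], "GNS_HKE_100")
  expect_equal(rep$detail_range[rep$metier == "FPO_OCC"], "0")
  # top-two listing when no level holds a majority
  ann$season[1:10] <- rep(c("Winter", "Spring", "Summer", "Autumn"),
                          c(4, 4, 1, 1))
  rep2 <- summary_report(ann, sel, years = 2020)
  expect_setequal(dom_set(rep2$season[rep2$metier == "GNS_HKE"]),
                  c("Winter", "Spring"))
})
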