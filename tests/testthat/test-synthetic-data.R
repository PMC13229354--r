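test_that("generation is byte-identical under a fixed seed", {
  cfg <- small_config(seed = 5, tail_n = 10)
  env <- shared_env()
  a <- generate_records(cfg, env)
  b <- generate_records(cfg, env)
  expect_identical(a, b)
  e1 <- generate_env(small_config(seed = 99))
  expect_identical(e1$depth$values, shared_env()$depth$values)
  expect_identical(e1$sediment$values, shared_env()$sediment$values)
})

test_that("zero-noise bathymetry equals the deterministic gradient", {
  cfg <- small_config(seed = 3)
  cfg$grid$noise_amp <- 0
  env <- generate_env(cfg)
  g <- cfg$grid
  nr <- nrow(env$depth$values); nc <- ncol(env$depth$values)
  lon <- g$lon[1] + (rep(seq_len(nc), each = nr) - 0.5) * g$pixel
  lat <- g$lat[1] + (rep(seq_len(nr), times = nc) - 0.5) * g$pixel
  expect_equal(as.vector(env$depth$values), depth_gradient(lon, lat, g))
})

test_that("unknown fraction zero yields no Unknown sediment", {
  cfg <- small_config(seed = 3)
  cfg$grid$unknown_frac <- 0
  env <- generate_env(cfg)
  expect_false(any(env$sediment$values == 6))
  cfg$grid$unknown_frac <- 0.3
  env2 <- generate_env(cfg)
  expect_true(any(env2$sediment$values == 6))
})

test_that("full dominance and no injections: targets recovered on all hauls", {
  cfg <- small_config(seed = 8, d = 1, tail_n = 0, zero_rates = TRUE,
                      mult = 0.2)
  env <- shared_env()
  rec <- generate_records(cfg, env)
  qc <- run_qc(rec$hauls, rec$catches, rec$sales, env$depth)
  expect_equal(qc$report$n_removed, 0)
  assigned <- assign_metiers(qc$valid_hauls, qc$valid_catches, rec$sales)
  j <- dplyr::inner_join(assigned, rec$truth$hauls, by = "haul_id")
  expect_equal(mean(j$target_species == j$target), 1)
})

test_that("empirical top-value fraction matches the dominance parameter", {
  cfg <- small_config(seed = 21, d = 0.8, tail_n = 0, zero_rates = TRUE,
                      mult = 0.4)  # ~2,000 planted hauls
  env <- shared_env()
  rec <- generate_records(cfg, env)
  assigned <- assign_metiers(rec$hauls, rec$catches, rec$sales)
  j <- dplyr::inner_join(assigned, rec$truth$hauls, by = "haul_id")
  n <- nrow(j)
  phat <- mean(j$target_species == j$target)
  se <- sqrt(0.8 * 0.2 / n)
  expect_gt(n, 1500)
  expect_lt(abs(phat - 0.8), 3 * se)
})

test_that("marginal season/area/stratum frequencies converge to the spec weights", {
  spec <- metier_spec("conv", "GNS", "HKE", 5500, 5.5,
                      bycatch_pool = c(HOM = 0.3, MAC = 0.2),
                      season_weights = c(.1, .2, .3, .4),
                      area_weights = c(.4, .3, .2, .1),
                      depth_weights = c(.5, .3, .2),
                      sediment_weights = c(Sand = .6, Mud = .4))
  cfg <- small_config(seed = 31, tail_n = 0, zero_rates = TRUE,
                      metiers = list(spec))
  env <- shared_env()
  rec <- generate_records(cfg, env)
  tr <- rec$truth$hauls
  expect_gte(nrow(tr), 5000)
  checks <- list(
    list(obs = table(factor(tr$season, season_levels())),
         w = spec$season_weights),
    list(obs = table(factor(tr$area, area_levels())),
         w = spec$area_weights),
    list(obs = table(factor(tr$stratum, depth_levels())),
         w = spec$depth_weights))
  for (ch in checks) {
    p <- stats::chisq.test(as.integer(ch$obs), p = ch$w)$p.value
    expect_gt(p, 0.001)
  }
  # the planted stratum is also what the bathymetry says at the midpoint
  ann <- annotate_hauls(rec$hauls, env$depth, env$sediment)
  j <- dplyr::inner_join(ann, tr, by = "haul_id")
  expect_gte(mean(j$depth_stratum == j$stratum), 0.99)
})

test_that("injected violation counts behave binomially", {
  cfg <- small_config(seed = 13)
  env <- shared_env()
  rec <- generate_records(cfg, env)
  n <- nrow(rec$hauls)
  viol <- rec$truth$violations
  per_haul <- c("outside_subarea", "depth_gt_2000", "misc_gear",
                "zero_catch", "missing_price", "inflated_weight")
  for (r in per_haul) {
    rate <- cfg$rates[[r]]
    got <- sum(viol$rule == r)
    se <- sqrt(n * rate * (1 - rate))
    expect_lt(abs(got - n * rate), 4 * se + 1)
  }
})

test_that("a metier demanding an impossible stratum fails loudly", {
  spec <- metier_spec("impossible", "GNS", "HKE", 100, 5,
                      area_weights = c(1, 0, 0, 0),
                      depth_weights = c(0, 0, 1))
  cfg <- small_config(seed = 2, tail_n = 0, metiers = list(spec))
  cfg$grid$lat <- c(36, 39)  # bounding box stops south of the NW area
  env <- generate_env(cfg)
  expect_error(generate_records(cfg, env), "impossible")
})
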