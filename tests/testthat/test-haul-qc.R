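# Hand-built single-rule fixtures: one constant-depth grid, two trips.
qc_fixture <- function(depth = 100) {
  rec <- tiny_records()
  grid <- env_grid(matrix(depth, 300, 300), origin = c(-10, 37),
                   pixel = 0.0095, kind = "depth")
  list(rec = rec, grid = grid)
}

test_that("each exclusion rule fires on its canonical violation", {
  fx <- qc_fixture()
  rec <- fx$rec

  # outside subarea
  h <- rec$hauls; h$fao_subarea[1] <- "27.8"
  r <- run_qc(h, rec$catches, rec$sales, fx$grid)
  expect_equal(unname(r$report$rule_counts["outside_subarea"]), 1L)
  expect_true("H1" %in% r$report$violations$haul_id)

  # depth beyond 2000 m at the midpoint
  deep <- qc_fixture(depth = 2500)
  r <- run_qc(rec$hauls, rec$catches, rec$sales, deep$grid)
  expect_equal(unname(r$report$rule_counts["depth_gt_2000"]), 3L)

  # exactly 2000 m is not "greater than 2,000"
  edge <- qc_fixture(depth = 2000)
  r <- run_qc(rec$hauls, rec$catches, rec$sales, edge$grid)
  expect_equal(unname(r$report$rule_counts["depth_gt_2000"]), 0L)

  # non-mainland trip removes all hauls of the trip
  s <- rec$sales; s$notes$ret_mainland[1] <- FALSE
  r <- run_qc(rec$hauls, rec$catches, s, fx$grid)
  expect_equal(unname(r$report$rule_counts["non_mainland_trip"]), 2L)
  # ... and the explicit port set overrides the flags
  r <- run_qc(rec$hauls, rec$catches, s, fx$grid,
              mainland_ports = c("PENICHE", "SINES"))
  expect_equal(unname(r$report$rule_counts["non_mainland_trip"]), 0L)

  # miscellaneous gear
  h <- rec$hauls; h$gear_code[3] <- "NK"
  r <- run_qc(h, rec$catches, rec$sales, fx$grid)
  expect_equal(unname(r$report$rule_counts["misc_gear"]), 1L)

  # zero catch: H3 has no catch lines
  r <- run_qc(rec$hauls, rec$catches, rec$sales, fx$grid)
  expect_equal(unname(r$report$rule_counts["zero_catch"]), 1L)
  expect_true("H3" %in% r$report$violations$haul_id)

  # missing price: species caught but absent from the trip's sales note
  c2 <- dplyr::bind_rows(rec$catches, tibble::tibble(
    haul_id = "H2", species = "XXX", weight_kg = 5))
  r <- run_qc(rec$hauls, c2, rec$sales, fx$grid)
  expect_equal(unname(r$report$rule_counts["missing_price"]), 1L)
  expect_true("H2" %in% r$report$violations$haul_id)
})

test_that("inflated weight is judged at trip level and flags all carriers", {
  fx <- qc_fixture()
  rec <- fx$rec
  # T1 hauls carry 160 kg of HKE in the logbook but only 100 kg were sold
  s <- rec$sales
  s$lines$sold_weight_kg[s$lines$species == "HKE"] <- 100
  r <- run_qc(rec$hauls, rec$catches, s, fx$grid)
  expect_equal(unname(r$report$rule_counts["inflated_weight"]), 2L)
  expect_setequal(
    r$report$violations$haul_id[r$report$violations$rule == "inflated_weight"],
    c("H1", "H2"))
  # a generous tolerance absorbs the discrepancy (monotonicity)
  r2 <- run_qc(rec$hauls, rec$catches, s, fx$grid, weight_tolerance = 2)
  expect_equal(unname(r2$report$rule_counts["inflated_weight"]), 0L)
  expect_lte(r2$report$rule_counts["inflated_weight"],
             r$report$rule_counts["inflated_weight"])
})

test_that("hauls referencing unknown trips fail loudly", {
  fx <- qc_fixture()
  rec <- fx$rec
  h <- rec$hauls; h$trip_id[3] <- "TX"
  expect_error(run_qc(h, rec$catches, rec$sales, fx$grid), "TX")
})

test_that("valid and removed hauls partition the input; QC is idempotent", {
  cfg <- small_config(seed = 17, mult = 0.3)
  env <- shared_env()
  rec <- generate_records(cfg, env)
  r <- run_qc(rec$hauls, rec$catches, rec$sales, env$depth)
  expect_equal(r$report$n_removed + nrow(r$valid_hauls), nrow(rec$hauls))
  expect_length(intersect(r$valid_hauls$haul_id,
                          r$report$violations$haul_id), 0)
  r2 <- run_qc(r$valid_hauls, r$valid_catches, rec$sales, env$depth)
  expect_equal(r2$report$n_removed, 0)
  # every rule was evaluated for every haul: multi-rule hauls list all rules
  expect_true(all(r$report$violations$rule %in% qc_rules()))
})

test_that("per-rule QC counts equal the generator's truth table exactly", {
  cfg <- small_config(seed = 23, mult = 0.5)
  env <- shared_env()
  rec <- generate_records(cfg, env)
  r <- run_qc(rec$hauls, rec$catches, rec$sales, env$depth)
  truth_counts <- table(rec$truth$violations$rule)
  for (rule in qc_rules()) {
    tc <- truth_counts[rule]
    expect_equal(unname(r$report$rule_counts[rule]),
                 if (is.na(tc)) 0L else as.integer(tc),
                 info = rule)
  }
  expect_equal(r$report$n_removed,
               length(unique(rec$truth$violations$haul_id)))
})
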