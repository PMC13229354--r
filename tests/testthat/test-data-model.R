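test_that("logbook write/read round-trips valid records field by field", {
  rec <- tiny_records()
  path <- withr::local_tempfile(fileext = ".csv")
  write_logbook(rec$hauls, rec$catches, path)
  got <- read_logbook(path)
  expect_equal(nrow(got$errors), 0)
  expect_equal(as.data.frame(got$hauls), as.data.frame(rec$hauls))
  expect_equal(as.data.frame(got$catches), as.data.frame(rec$catches))
  # H3 is zero-catch evidence: present as a haul, absent from catches
  expect_true("H3" %in% got$hauls$haul_id)
  expect_false("H3" %in% got$catches$haul_id)
})

test_that("malformed logbook rows become error records, never silent drops", {
  rec <- tiny_records()
  path <- withr::local_tempfile(fileext = ".csv")
  write_logbook(rec$hauls, rec$catches, path)
  txt <- readLines(path)
  bad1 <- sub("^H1,", "B1,", sub("39,", "123,", txt[2]))  # lat out of range
  bad2 <- sub("^H1,", "B2,", sub(",100$", ",-3", txt[2])) # negative weight
  writeLines(c(txt, bad1, bad2), path)
  got <- read_logbook(path)
  expect_false(any(c("B1", "B2") %in% got$hauls$haul_id))
  expect_true(any(grepl("out of range", got$errors$reason)))
  expect_true(any(grepl("positive", got$errors$reason)))
  expect_equal(got$errors$line[grepl("out of range", got$errors$reason)],
               length(txt) + 1L)
  # untouched rows still parse
  expect_setequal(got$hauls$haul_id, c("H1", "H2", "H3"))
})

test_that("a missing mandatory logbook column is a hard failure naming it", {
  rec <- tiny_records()
  path <- withr::local_tempfile(fileext = ".csv")
  write_logbook(rec$hauls, rec$catches, path)
  tab <- readr::read_csv(path, show_col_types = FALSE)
  tab$fao_subarea <- NULL
  readr::write_csv(tab, path)
  expect_error(read_logbook(path), "fao_subarea")
})

test_that("sales notes: prices, duplicate-line merging and round-trip", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "sales.csv")
  writeLines(c(
    "trip_id,vessel_id,landing_date,departure_port,dep_mainland,return_port,ret_mainland,species,sold_weight_kg,sold_value",
    "T1,V1,2020-02-11,PENICHE,TRUE,PENICHE,TRUE,HKE,100,400",
    "T2,V2,2020-03-01,SINES,TRUE,SINES,TRUE,HKE,60,210",
    "T2,V2,2020-03-01,SINES,TRUE,SINES,TRUE,HKE,40,190",
    "T3,V3,2020-04-01,SINES,TRUE,SINES,TRUE,,,",
    "T4,V4,2020-04-02,SINES,TRUE,SINES,TRUE,OCC,0,50"), path)
  got <- read_sales(path)
  # single division and additivity of duplicate lines
  expect_equal(got$lines$price[got$lines$trip_id == "T1"], 4)
  t2 <- got$lines[got$lines$trip_id == "T2", ]
  expect_equal(t2$sold_weight_kg, 100)
  expect_equal(t2$sold_value, 400)
  expect_equal(t2$price, 4)
  # zero weight with positive value: undefined price -> error record
  expect_true(any(got$errors$line == 6))
  expect_false("T4" %in% got$lines$trip_id)
  # empty note survives as trip metadata
  expect_true("T3" %in% got$notes$trip_id)
  # round trip
  path2 <- file.path(dir, "sales2.csv")
  write_sales(got$notes, got$lines, path2)
  again <- read_sales(path2)
  expect_equal(as.data.frame(again$notes), as.data.frame(got$notes))
  expect_equal(as.data.frame(dplyr::arrange(again$lines, trip_id, species)),
               as.data.frame(dplyr::arrange(got$lines, trip_id, species)))
})

test_that("sample_grid returns the containing cell value, no interpolation", {
  g <- tiny_grid(200)
  # cell centers
  got <- sample_grid(g, -10 + 0.009 * (0:9 + 0.5), rep(38.0045, 10))
  expect_true(all(got$value == 200))
  expect_true(all(got$status == "ok"))
})

test_that("nodata sediment samples as Unknown; out of bounds is distinct", {
  m <- matrix(2, 10, 10)
  m[5, 5] <- -9999
  g <- env_grid(m, c(-10, 38), 0.009, kind = "sediment")
  inside_nodata <- sample_grid(g, -10 + 4.5 * 0.009, 38 + 4.5 * 0.009)
  expect_equal(inside_nodata$value, "Unknown")
  expect_equal(inside_nodata$status, "nodata")
  ok <- sample_grid(g, -9.999, 38.001)
  expect_equal(ok$value, "Sand")
  oob <- sample_grid(g, -11, 38.001)
  expect_equal(oob$status, "oob")
  expect_true(is.na(oob$value))
})

test_that("sample_grid agrees with brute-force index computation", {
  set.seed(11)
  vals <- matrix(runif(15 * 12), 15, 12)
  g <- env_grid(vals, c(-9.5, 37.2), 0.0071, kind = "depth")
  lon <- runif(1000, -9.5, -9.5 + 12 * 0.0071 - 1e-9)
  lat <- runif(1000, 37.2, 37.2 + 15 * 0.0071 - 1e-9)
  got <- sample_grid(g, lon, lat)
  exp_val <- vapply(seq_along(lon), function(i) {
    col <- floor((lon[i] - -9.5) / 0.0071) + 1
    row <- floor((lat[i] - 37.2) / 0.0071) + 1
    vals[row, col]
  }, numeric(1))
  expect_equal(got$value, exp_val)
})

test_that("the plain-text grid format round-trips", {
  g <- tiny_grid(matrix(seq_len(100), 10, 10), kind = "depth")
  path <- withr::local_tempfile(fileext = ".grid")
  write_env_grid(g, path)
  got <- read_env_grid(path)
  expect_equal(got$values, g$values)
  expect_equal(got$origin, g$origin)
  expect_equal(got$pixel, g$pixel)
  expect_equal(got$kind, "depth")
})

test_that("env_grid enforces the sub-0.01-degree pixel contract", {
  expect_error(env_grid(matrix(0, 2, 2), c(0, 0), 0.05), "0.01")
  expect_silent(env_grid(matrix(0, 2, 2), c(0, 0), 0.0099))
})
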