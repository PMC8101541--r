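test_that("well-formed incident CSVs parse row for row", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "year,region,species,fatal,provoked",
    "1950,NSW,white,1,0",
    "1960,QLD,tiger,FALSE,true",
    "1970,WA,bull,0,No"
  ), path)
  rec <- read_incidents(path)
  expect_s3_class(rec, "shark_incidents")
  expect_equal(nrow(rec), 3L)
  expect_equal(rec$year, c(1950L, 1960L, 1970L))
  expect_equal(rec$fatal, c(TRUE, FALSE, FALSE))
  expect_equal(rec$provoked, c(FALSE, TRUE, FALSE))
})

test_that("unknown codes are rejected with the offending row number", {
  df <- data.frame(year = c(1950, 1960), region = c("NSW", "XYZ"),
                   species = c("white", "tiger"),
                   fatal = c(1, 0), provoked = c(0, 0))
  err <- expect_error(incident_records(df), class = "sharkcast_validation_error")
  expect_match(conditionMessage(err), "row 2")
  expect_match(conditionMessage(err), "XYZ")

  expect_error(
    incident_records(df[, setdiff(names(df), "species")]),
    class = "sharkcast_format_error", regexp = "species"
  )
})

test_that("species aliases map to canonical labels and survive a round trip", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "year,region,species,fatal,provoked",
    "1950,NSW,bronze whaler,0,0",
    "1960,NSW,Dusky,0,1",
    "1970,QLD,White Pointer,1,0"
  ), path)
  rec <- read_incidents(path)
  expect_equal(rec$species, c("whaler", "whaler", "white"))

  out <- withr::local_tempfile(fileext = ".csv")
  write_incidents(rec, out)
  again <- read_incidents(out)
  expect_equal(as.data.frame(again), as.data.frame(rec))
})

test_that("filter presets select the hand-enumerated subsets", {
  rec <- five_records()
  expect_equal(nrow(filter_incidents(rec, "all")), 5L)
  expect_equal(nrow(filter_incidents(rec, "fatal_only")), 2L)
  expect_equal(nrow(filter_incidents(rec, "unprovoked_only")), 3L)
  expect_equal(nrow(filter_incidents(rec, "white_only")), 1L)
  expect_equal(nrow(filter_incidents(rec, "white_tiger_bull")), 3L)
  empty <- rec[0, ]
  for (p in filter_presets()) {
    expect_equal(nrow(filter_incidents(empty, p)), 0L)
  }
})

test_that("count series tally records, fill gaps with zero and aggregate to AUS", {
  df <- incident_records(data.frame(
    year = c(1900, 1900, 1902), region = c("NSW", "QLD", "UNK"),
    species = "white", fatal = 0, provoked = 0
  ))
  cs <- build_count_series(df, "AUS", 1900:1902)
  expect_equal(cs$count, c(2L, 0L, 1L))
  # unknown-state records count toward the national series only
  per_state <- vapply(setdiff(region_codes(), "UNK"), function(r) {
    sum(build_count_series(df, r, 1900:1902)$count)
  }, numeric(1))
  expect_equal(sum(per_state), 2)
  expect_equal(sum(cs$count), 3)
})

test_that("filtered counts are conserved across regions and record order", {
  set.seed(11)
  sim <- generate_country(default_synthetic_country(), 1900:1919, seed = 11)
  rec <- sim$records
  for (p in filter_presets()) {
    f <- filter_incidents(rec, p)
    per_region <- vapply(setdiff(region_codes(), "UNK"), function(r) {
      sum(build_count_series(f, r, 1900:1919)$count)
    }, numeric(1))
    expect_equal(sum(per_region), nrow(f))
  }
  shuffled <- rec[sample(nrow(rec)), ]
  expect_equal(
    build_count_series(shuffled, "AUS", 1900:1919)$count,
    build_count_series(rec, "AUS", 1900:1919)$count
  )
})

test_that("per-capita conversion is elementwise division with alignment checks", {
  counts <- build_count_series(
    incident_records(data.frame(year = c(1900, 1900, 1900, 1901, 1901, 1901, 1901),
                                region = "NSW", species = "white",
                                fatal = 0, provoked = 0)),
    "NSW", 1900:1901
  )
  pop <- population_series("NSW", 1900:1901, c(1000, 2000))
  rates <- to_per_capita(counts, pop)
  expect_equal(rates$rate, c(0.003, 0.002))

  pop_short <- population_series("NSW", 1901:1902, c(1000, 2000))
  expect_error(to_per_capita(counts, pop_short),
               class = "sharkcast_alignment_error")
})

test_that("RMS scaling uses the n-1 divisor and is exactly invertible", {
  rates <- make_rates(c(3, 4))
  sc <- rms_scale(rates)
  expect_equal(attr(sc, "scale_factor"), 5)        # sqrt((9+16)/1)
  expect_equal(sc$scaled, c(0.6, 0.8))
  expect_equal(unscale(sc)$rate, rates$rate)

  const <- rms_scale(make_rates(rep(2e-6, 10)))
  expect_true(all(abs(const$scaled - const$scaled[1]) < 1e-15))

  expect_error(rms_scale(make_rates(rep(0, 5))),
               class = "sharkcast_degenerate_error")
  expect_error(rms_scale(make_rates(3)), class = "sharkcast_degenerate_error")

  no_sf <- make_rates(c(1, 2))
  names(no_sf)[2] <- "scaled"
  attr(no_sf, "scale_factor") <- NULL
  expect_error(unscale(no_sf), class = "sharkcast_state_error")
})

test_that("scale/unscale round-trips random series to 1e-12 relative error", {
  set.seed(5)
  for (i in 1:20) {
    x <- stats::runif(50, 0, 1e-5)
    rt <- unscale(rms_scale(make_rates(x)))$rate
    expect_lt(max(abs(rt - x) / pmax(x, 1e-300)), 1e-12)
  }
})

test_that("population tables round-trip through the long CSV format", {
  pops <- list(
    NSW = population_series("NSW", 1900:1905, 1e6 * 1.01^(0:5)),
    QLD = population_series("QLD", 1900:1905, 5e5 * 1.02^(0:5))
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_population(pops, path)
  back <- read_population(path)
  expect_equal(back$NSW$population, pops$NSW$population)
  expect_equal(back$QLD$year, pops$QLD$year)
})
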