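test_that("beta moment matching solves the worked examples", {
  expect_equal(beta_params(0.60, 0.05), c(a = 57, b = 38), tolerance = 1e-12)
  expect_equal(beta_params(0.5, 0.05), c(a = 49.5, b = 49.5), tolerance = 1e-12)
  expect_error(beta_params(0.5, 0.6), class = "sharkcast_domain_error")
  expect_error(beta_params(1.2, 0.05), class = "sharkcast_domain_error")
})

test_that("averted bites are exactly linear and monotone in uptake", {
  set.seed(51)
  mat <- matrix(rgamma(200 * 5, 4, 1), 200, 5)
  ens <- sharkcast:::new_ensemble(mat, 2020:2024, "NSW", "count", 1)
  grid <- uptake_grid(c(0.25, 0.5, 1.0))
  av <- averted_matrix(ens, deterrence_model(), grid, seed = 52)

  # within any iteration, full uptake averts exactly twice the 50% case
  expect_equal(av$averted[, , "1"], 2 * av$averted[, , "0.5"], tolerance = 1e-12)
  expect_equal(av$averted[, , "0.5"], 2 * av$averted[, , "0.25"], tolerance = 1e-12)
  # monotone non-decreasing in uptake everywhere
  expect_true(all(av$averted[, , "1"] >= av$averted[, , "0.5"]))
  # averted can never exceed the projected bites
  expect_true(all(av$averted[, , "1"] <= mat))
  # a scaled-units ensemble is rejected
  sc <- sharkcast:::new_ensemble(mat, 2020:2024, "NSW", "scaled", 1)
  expect_error(averted_matrix(sc, seed = 1), class = "sharkcast_state_error")
  expect_error(uptake_grid(numeric(0)), class = "sharkcast_config_error")
})

test_that("halving full-uptake interval bounds reproduces 50%-uptake bounds", {
  # person-count convention: continuous internally, round half away from zero
  full <- c(lo = 185, hi = 2121)
  expect_equal(unname(round_half_away(full * 0.5)), c(93, 1061))
})

test_that("effectiveness draws recover the configured moments", {
  det <- deterrence_model(0.60, 0.05)
  set.seed(53)
  draws <- rbeta(2e5, det$a, det$b)
  expect_lt(abs(mean(draws) - 0.60), 0.001)
  expect_lt(abs(sd(draws) - 0.05), 0.001)
})

test_that("reporting curves rise from their floor to full reporting", {
  A <- reporting_scenario("A")
  B <- reporting_scenario("B")
  # closed-form oracle values for scenario A
  expect_equal(reporting_proportion(1900, A), 0.603670, tolerance = 1e-4)
  expect_equal(reporting_proportion(1950, A), 0.803056, tolerance = 1e-4)
  expect_equal(reporting_proportion(1990, A), 0.994735, tolerance = 1e-4)
  # scenario B: 40% floor in 1900, asymptote during the 2000s
  expect_equal(reporting_proportion(1900, B), 0.399345, tolerance = 1e-4)
  expect_gt(reporting_proportion(2005, B), 0.99)

  yrs <- 1800:2100
  for (sc in list(A, B)) {
    p <- reporting_proportion(yrs, sc)
    expect_true(all(diff(p) > 0))
    expect_true(all(p > sc$gamma_floor & p < 1))
  }
  # B lies below A before 1950 and has the shallower slope
  expect_true(all(reporting_proportion(1800:1949, B) <
                  reporting_proportion(1800:1949, A)))
  expect_lt(B$beta_r, A$beta_r)

  # the literal printed orientation is decreasing: kept only for comparison
  lit <- reporting_proportion(c(1900, 1990), A, form = "literal")
  expect_gt(lit[1], lit[2])
})

test_that("correcting for reporting divides by the curve and never shrinks", {
  cs <- sharkcast:::new_series(
    data.frame(year = c(1900, 1950), count = c(6, 6)), "NSW", "count_series"
  )
  corr <- correct_for_reporting(cs, constant_reporting(0.6))
  expect_equal(corr$count, c(10, 10))
  ident <- correct_for_reporting(cs, constant_reporting(1))
  expect_equal(ident$count, cs$count)

  A <- reporting_scenario("A")
  rr <- make_rates(runif(120, 1e-7, 1e-6), years = 1900:2019)
  corrected <- correct_for_reporting(rr, A)
  expect_true(all(corrected$rate >= rr$rate))
})

test_that("abundance power law doubles the bite rate for fivefold abundance", {
  expect_equal(abundance_rate_factor(1), 1)
  expect_equal(abundance_rate_factor(5), 2, tolerance = 1e-3)
  expect_equal(abundance_rate_factor(0.2), 0.5, tolerance = 1e-3)
  expect_error(abundance_rate_factor(0), class = "sharkcast_domain_error")
  expect_error(abundance_rate_factor(-1), class = "sharkcast_domain_error")
})

test_that("abundance adjustment is separable, max-normalized and self-consistent", {
  years <- 1900:1999
  set.seed(54)
  nrel <- data.frame(
    year = years,
    white = 0.3 + 0.7 * exp(-(0:99) / 60),
    tiger = 0.4 + 0.6 * exp(-(0:99) / 80),
    bull_whaler = 0.5 + 0.5 * exp(-(0:99) / 50)
  )
  # species rates generated exactly as the power law times a constant
  base <- lapply(c(white = "white", tiger = "tiger", bull_whaler = "bull_whaler"),
                 function(sp) {
    make_scaled(0.5 * abundance_rate_factor(nrel[[sp]]), years = years)
  })
  total <- make_scaled(Reduce(`+`, lapply(base, `[[`, "scaled")), years = years)

  res <- adjust_series_for_abundance(base, nrel, total)
  expect_equal(max(res$proportional$proportion), 1)
  gen_total <- Reduce(`+`, lapply(names(base), function(sp)
    0.5 * abundance_rate_factor(nrel[[sp]])))
  expect_gt(cor(res$proportional$proportion, gen_total / max(gen_total)), 0.99)

  # changing one species' trajectory leaves the others' adjusted series alone
  nrel2 <- nrel
  nrel2$tiger <- pmin(1, nrel$tiger * 1.4)
  res2 <- adjust_series_for_abundance(base, nrel2, total)
  expect_equal(res2$species_adjusted$white$scaled, res$species_adjusted$white$scaled)
  expect_equal(res2$species_adjusted$bull_whaler$scaled,
               res$species_adjusted$bull_whaler$scaled)

  # constant trajectories mean no abundance signal: proportional series is the
  # species sum max-normalized, and the total is modulated only by itself
  nrel_const <- data.frame(year = years, white = 1, tiger = 1, bull_whaler = 1)
  res3 <- adjust_series_for_abundance(base, nrel_const, total)
  sum_base <- Reduce(`+`, lapply(base, `[[`, "scaled"))
  expect_equal(res3$proportional$proportion, sum_base / max(sum_base))
  expect_equal(res3$adjusted$scaled, total$scaled * sum_base / max(sum_base))

  expect_error(adjust_series_for_abundance(base[1:2], nrel, total),
               class = "sharkcast_config_error")
})
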