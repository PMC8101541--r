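test_that("noiseless sinusoids are recovered essentially exactly", {
  t <- 0:119
  y <- 0.5 + 0.3 * cos(2 * pi / 100 * t + 1.0)
  fit <- fit_sinusoid(make_scaled(y, years = 1900 + t))
  expect_lt(abs(fit$alpha - 0.5) / 0.5, 1e-6)
  expect_lt(abs(fit$beta - 0.3) / 0.3, 1e-6)
  expect_lt(abs(fit$period - 100) / 100, 1e-6)
  expect_lt(abs(fit$delta - 1.0), 1e-6)
})

test_that("negative-amplitude solutions are normalized to beta >= 0", {
  t <- 0:99
  y <- 0.5 - 0.3 * cos(2 * pi / 80 * t + 0.4)   # beta = -0.3 candidate
  fit <- fit_sinusoid(make_scaled(y, years = 1900 + t))
  expect_gte(fit$beta, 0)
  expect_true(fit$delta >= 0 && fit$delta < 2 * pi)
  expect_equal(fit$beta, 0.3, tolerance = 1e-6)
  expect_equal(fit$delta, (0.4 + pi) %% (2 * pi), tolerance = 1e-5)
  expect_equal(fit$fitted, y, tolerance = 1e-8)
})

test_that("fit preconditions are enforced", {
  expect_error(fit_sinusoid(make_scaled(c(1, 2, 3, 4))),
               class = "sharkcast_config_error")
  expect_error(fit_sinusoid(make_scaled(rep(1, 30))),
               class = "sharkcast_degenerate_error")
})

test_that("residuals partition into sign pools with alternating zeros", {
  years <- 1900:1903
  fit <- make_fit(alpha = 5, beta = 0, gamma = 0.1, delta = 0,
                  origin = 1900, years = years)
  obs <- fit$fitted + c(-1, 2, -3, 4)
  pools <- split_residuals(make_scaled(obs, years = years), fit)
  expect_setequal(pools$positive$residual, c(2, 4))
  expect_setequal(pools$negative$residual, c(-1, -3))
  expect_equal(nrow(pools$positive) + nrow(pools$negative), 4L)

  # perfect fit: every residual zero -> degenerate
  expect_error(split_residuals(make_scaled(fit$fitted, years = years), fit),
               class = "sharkcast_degenerate_error")

  # occasional exact zeros alternate between the pools
  years8 <- 1900:1907
  fit8 <- make_fit(5, 0, 0.1, 0, 1900, years8)
  obs8 <- fit8$fitted + c(-1, 0, 2, 0, -2, 1, 0, 0)
  p8 <- split_residuals(make_scaled(obs8, years = years8), fit8)
  expect_equal(nrow(p8$positive), 4L)  # {2, 1} plus zeros 1 and 3
  expect_equal(nrow(p8$negative), 4L)
  expect_equal(nrow(p8$positive) + nrow(p8$negative), 8L)
})

test_that("sampler weights are KDE-proportional and symmetric pools get equal weights", {
  pools <- make_pools(pos = c(1, -1), neg = c(-2, 2))
  s <- build_residual_sampler(pools)
  expect_equal(s$positive$weights, c(0.5, 0.5))
  expect_equal(s$negative$weights, c(0.5, 0.5))
  expect_equal(sum(s$positive$weights), 1)
  expect_gt(s$positive$bandwidth, 0)

  expect_error(build_residual_sampler(make_pools(pos = c(1, 1), neg = c(-1, -2))),
               class = "sharkcast_degenerate_error")
})

test_that("the pool KDE integrates to one over a wide grid", {
  set.seed(41)
  r <- rgamma(40, 2, 4)
  pools <- make_pools(pos = r, neg = -r)
  s <- build_residual_sampler(pools)
  d <- density(r, bw = s$positive$bandwidth, from = min(r) - 10, to = max(r) + 10,
               n = 4096)
  area <- sum(d$y) * diff(d$x[1:2])
  expect_lt(abs(area - 1), 1e-3)
})

test_that("Sheather-Jones bandwidth agrees with an independent plug-in oracle", {
  set.seed(42)
  x <- rnorm(500)
  pools <- make_pools(pos = x + 10, neg = -(x + 10))
  s <- build_residual_sampler(pools)
  oracle <- sj_dpi_oracle(x + 10)
  expect_lt(abs(s$positive$bandwidth - oracle) / oracle, 0.05)
})

test_that("magnitude scaling shrinks residuals in troughs and respects the floor", {
  set.seed(43)
  years <- 1900:1979
  fit <- make_fit(alpha = 1, beta = 0.5, gamma = 2 * pi / 40, delta = 0,
                  origin = 1900, years = years)
  # residual magnitude proportional to the sinusoid level
  noise <- (0.2 * fit$fitted) * rep(c(1, -1), 40)
  pools <- split_residuals(make_scaled(fit$fitted + noise, years = years), fit)
  s <- build_residual_sampler(pools)
  peak <- max(fit$fitted); trough <- min(fit$fitted)
  expect_gt(sharkcast:::pool_scale(s$positive, peak),
            sharkcast:::pool_scale(s$positive, trough))
  # far below the trough, the floor binds
  expect_equal(sharkcast:::pool_scale(s$positive, -100), 0.1)
})

test_that("degenerate residual pools collapse the ensemble onto the sinusoid", {
  years <- 1900:1919
  fit <- make_fit(alpha = 2, beta = 0.5, gamma = 2 * pi / 50, delta = 0.3,
                  origin = 1900, years = years)
  eps <- c(1e-9, 2e-9)
  s <- build_residual_sampler(make_pools(pos = eps, neg = -eps))
  ens <- project_ensemble(fit, s, years = 1920:1940, n_iter = 50, seed = 9)
  med <- predict_sinusoid(fit, 1920:1940)
  expect_lt(max(abs(sweep(unclass(ens), 2, med))), 1e-6)
})

test_that("projection is seeded, non-negative and reproducible", {
  years <- 1900:1959
  fit <- make_fit(alpha = 1, beta = 0.6, gamma = 2 * pi / 60, delta = 1,
                  origin = 1900, years = years)
  set.seed(44)
  obs <- fit$fitted + rnorm(60, sd = 0.5)
  pools <- split_residuals(make_scaled(obs, years = years), fit)
  s <- build_residual_sampler(pools)
  e1 <- project_ensemble(fit, s, 1960:2000, n_iter = 200, seed = 10)
  e2 <- project_ensemble(fit, s, 1960:2000, n_iter = 200, seed = 10)
  expect_identical(unclass(e1), unclass(e2))
  expect_true(all(e1 >= 0))
  e3 <- project_ensemble(fit, s, 1960:2000, n_iter = 200, seed = 11)
  expect_false(identical(unclass(e1), unclass(e3)))
  expect_error(project_ensemble(fit, s, 1960:2000, n_iter = 200),
               class = "sharkcast_config_error")

  # smoothed-bootstrap alternative: reproducible, non-negative, distinct
  k1 <- project_ensemble(fit, s, 1960:2000, n_iter = 200, seed = 10,
                         resample = "kde_smooth")
  k2 <- project_ensemble(fit, s, 1960:2000, n_iter = 200, seed = 10,
                         resample = "kde_smooth")
  expect_identical(unclass(k1), unclass(k2))
  expect_true(all(k1 >= 0))
  expect_false(identical(unclass(k1), unclass(e1)))
})

test_that("ensemble median converges to the direct Monte-Carlo oracle", {
  years <- 1900:1959
  fit <- make_fit(alpha = 1.2, beta = 0.4, gamma = 2 * pi / 70, delta = 2,
                  origin = 1900, years = years)
  set.seed(45)
  obs <- fit$fitted + rgamma(60, 2, 4) * rep(c(1, -1), 30)
  pools <- split_residuals(make_scaled(obs, years = years), fit)
  s <- build_residual_sampler(pools)

  yr <- 1975L
  ens <- project_ensemble(fit, s, years = yr, n_iter = 50000, seed = 12)
  med_pkg <- median(unclass(ens)[, 1])

  # direct oracle: sample the sign-mixed scaled residual distribution by hand
  set.seed(999)
  level <- predict_sinusoid(fit, yr)
  n <- 50000
  pos <- sample(s$positive$residuals, n, TRUE, s$positive$weights) *
    sharkcast:::pool_scale(s$positive, level)
  neg <- sample(s$negative$residuals, n, TRUE, s$negative$weights) *
    sharkcast:::pool_scale(s$negative, level)
  take <- runif(n) < 0.5
  oracle <- median(pmax(0, level + ifelse(take, pos, neg)))
  expect_lt(abs(med_pkg - oracle) / oracle, 0.02)
})

test_that("back-transform multiplies by scale factor and population linearly", {
  years <- 2020:2022
  ens <- sharkcast:::new_ensemble(matrix(2e-6, 3, 3), years, "NSW", "scaled", 1)
  pop <- population_series("NSW", 2020:2022, rep(1e6, 3))
  counts <- back_transform_to_counts(ens, 1, pop)
  expect_true(all(unclass(counts) == 2))

  pop2 <- population_series("NSW", 2020:2022, rep(2e6, 3))
  counts2 <- back_transform_to_counts(ens, 1, pop2)
  expect_equal(unclass(counts2), unclass(counts) * 2)

  zero <- sharkcast:::new_ensemble(matrix(0, 3, 3), years, "NSW", "scaled", 1)
  expect_true(all(unclass(back_transform_to_counts(zero, 1, pop)) == 0))

  pop_short <- population_series("NSW", 2020:2021, rep(1e6, 2))
  expect_error(back_transform_to_counts(ens, 1, pop_short),
               class = "sharkcast_alignment_error")
})
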