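# In-code fixtures and independent oracles shared across test files.

# five hand-enumerable records covering every filter preset
five_records <- function() {
  incident_records(data.frame(
    year = c(1950, 1960, 1970, 1980, 1990),
    region = c("NSW", "QLD", "WA", "SA", "VIC"),
    species = c("white", "tiger", "bull", "whaler", "unknown"),
    fatal = c(TRUE, FALSE, FALSE, TRUE, FALSE),
    provoked = c(FALSE, TRUE, FALSE, TRUE, FALSE)
  ))
}

make_scaled <- function(values, years = seq_along(values) + 1899, region = "NSW",
                        scale_factor = 1) {
  df <- data.frame(year = years, scaled = values)
  attr(df, "region") <- region
  attr(df, "scale_factor") <- scale_factor
  class(df) <- c("scaled_rate_series", "data.frame")
  df
}

make_rates <- function(values, years = seq_along(values) + 1899, region = "NSW") {
  df <- data.frame(year = years, rate = values)
  attr(df, "region") <- region
  class(df) <- c("rate_series", "data.frame")
  df
}

# a sinusoid_fit with known parameters, for driving the sampler directly
make_fit <- function(alpha, beta, gamma, delta, origin, years) {
  x <- years - origin
  fitted <- alpha + beta * cos(gamma * x + delta)
  structure(
    list(alpha = alpha, beta = beta, gamma = gamma, delta = delta,
         period = 2 * pi / gamma, origin = origin, year = years,
         observed = fitted, fitted = fitted, sse = 0),
    class = "sinusoid_fit"
  )
}

make_pools <- function(pos, neg, fitted_pos = rep(1, length(pos)),
                       fitted_neg = rep(1, length(neg))) {
  structure(
    list(
      positive = data.frame(year = seq_along(pos) + 1899, residual = pos,
                            fitted = fitted_pos),
      negative = data.frame(year = seq_along(neg) + 1899, residual = neg,
                            fitted = fitted_neg)
    ),
    class = "residual_pools"
  )
}

# reporting_scenario-shaped objects with exactly known curves, for oracle
# tests that need reporting proportions of exactly 1 or exactly 0.5
constant_reporting <- function(p) {
  if (p == 1) {
    structure(list(id = "const1", gamma_floor = 1, alpha_r = 0, beta_r = 0),
              class = "reporting_scenario")
  } else {
    # floor p with the logistic term pushed to 0
    structure(list(id = paste0("const", p), gamma_floor = p,
                   alpha_r = -1e6, beta_r = 0),
              class = "reporting_scenario")
  }
}

# Independent two-stage direct-plug-in Sheather-Jones bandwidth
# (normal-scale start for psi8, gaussian kernel), written from the standard
# plug-in recursion; serves as a cross-implementation oracle for bw.SJ.
sj_dpi_oracle <- function(x) {
  n <- length(x)
  sig <- stats::sd(x)
  psi8 <- 105 / (32 * sqrt(pi) * sig^9)
  K6_0 <- -15 / sqrt(2 * pi)
  g1 <- (-2 * K6_0 / (psi8 * n))^(1 / 9)
  d <- outer(x, x, "-")
  phi6 <- function(u) (u^6 - 15 * u^4 + 45 * u^2 - 15) * stats::dnorm(u)
  psi6 <- sum(phi6(d / g1)) / (n^2 * g1^7)
  K4_0 <- 3 / sqrt(2 * pi)
  g2 <- (-2 * K4_0 / (psi6 * n))^(1 / 7)
  phi4 <- function(u) (u^4 - 6 * u^2 + 3) * stats::dnorm(u)
  psi4 <- sum(phi4(d / g2)) / (n^2 * g2^5)
  (1 / (2 * sqrt(pi)) / (psi4 * n))^(1 / 5)
}
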