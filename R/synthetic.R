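# Synthetic incident registries with known sinusoidal per-capita structure.
# Every downstream stage (scaling, trend ranking, sinusoid fitting,
# projection, scenario analysis) is validated against the ground truth these
# generators record.

#' Configuration for one synthetic region
#'
#' Defines the ground truth from which synthetic incident records are drawn:
#' a sinusoidal scaled per-capita bite rate
#' `alpha + beta * cos(gamma * (year - origin) + delta)`, a deterministic
#' population trajectory, and the categorical composition of records.
#'
#' Default composition mirrors a century-scale national registry: 20% of
#' incidents fatal, 65% unprovoked, and species shares of 31% white, 21%
#' tiger, 14% bull, 6% whaler, with the remainder split between other
#' identified species (19%) and unattributed records (9%).
#'
#' @param region region code.
#' @param alpha sinusoid level in scaled-rate units; must satisfy
#'   `alpha >= beta` so the true rate is never negative.
#' @param beta sinusoid amplitude (>= 0), scaled-rate units.
#' @param period sinusoid period in years; `gamma = 2 * pi / period`.
#' @param delta phase in radians, reduced modulo `2 * pi`.
#' @param origin calendar year at which the sinusoid argument is zero.
#' @param rate_scale multiplies the dimensionless sinusoid into a per-capita
#'   rate (bites per person per year per scaled unit); plays the role the
#'   stored RMS scale factor plays for observed series.
#' @param base_pop population in the first generated year.
#' @param growth yearly fractional population growth (scalar, or one value
#'   per year transition).
#' @param mix named species mixture over [species_codes()], summing to 1.
#' @param p_fatal per-incident fatality probability.
#' @param p_provoked per-incident probability the incident was provoked.
#' @return a `synthetic_region_config` list.
#' @export
synthetic_region_config <- function(region,
                                    alpha = 0.9,
                                    beta = 0.5,
                                    period = 100,
                                    delta = pi,
                                    origin = 1900L,
                                    rate_scale = 4e-07,
                                    base_pop = 1e6,
                                    growth = 0.016,
                                    mix = c(white = 0.31, tiger = 0.21, bull = 0.14,
                                            whaler = 0.06, other = 0.19, unknown = 0.09),
                                    p_fatal = 0.20,
                                    p_provoked = 0.35) {
  for (nm in c("alpha", "beta", "period", "delta", "rate_scale", "base_pop",
               "p_fatal", "p_provoked")) {
    stopifnot_scalar_number(get(nm), nm)
  }
  if (beta < 0 || alpha < beta) {
    abort_sc("need alpha >= beta >= 0 so the true scaled rate is non-negative",
             "sharkcast_config_error")
  }
  if (!setequal(names(mix), species_codes())) {
    abort_sc("`mix` must name every species code exactly once", "sharkcast_config_error")
  }
  if (abs(sum(mix) - 1) > 1e-9 || any(mix < 0)) {
    abort_sc("species mixture must be non-negative and sum to 1 (tolerance 1e-9)",
             "sharkcast_config_error")
  }
  if (any(p_fatal < 0 | p_fatal > 1) || any(p_provoked < 0 | p_provoked > 1)) {
    abort_sc("probabilities must lie in [0, 1]", "sharkcast_config_error")
  }
  if (any(!is.finite(growth)) || any(1 + growth <= 0)) {
    abort_sc("growth factors must be positive", "sharkcast_config_error")
  }
  structure(
    list(
      region = region, alpha = alpha, beta = beta,
      gamma = 2 * pi / period, period = period,
      delta = delta %% (2 * pi), origin = as.integer(origin),
      rate_scale = rate_scale, base_pop = base_pop, growth = growth,
      mix = mix[species_codes()], p_fatal = p_fatal, p_provoked = p_provoked
    ),
    class = "synthetic_region_config"
  )
}

#' Default synthetic country
#'
#' Four-region synthetic country emulating a century of national shark-bite
#' records: three data-rich coastal states with distinct sinusoid phases and
#' amplitudes plus one sparse state, all sharing a multidecadal (100-year)
#' period. Base populations and growth are set so the 1900-2019 national
#' record totals roughly one thousand incidents, matching the density of the
#' registry the generator emulates.
#'
#' @return named list of `synthetic_region_config` objects.
#' @export
default_synthetic_country <- function() {
  list(
    NSW = synthetic_region_config("NSW", alpha = 0.95, beta = 0.55, period = 100,
                                  delta = 5.0, rate_scale = 1.0e-06,
                                  base_pop = 1.4e6, growth = 0.016),
    QLD = synthetic_region_config("QLD", alpha = 0.90, beta = 0.50, period = 100,
                                  delta = 3.8, rate_scale = 1.5e-06,
                                  base_pop = 0.5e6, growth = 0.019),
    WA  = synthetic_region_config("WA", alpha = 0.85, beta = 0.45, period = 100,
                                  delta = 2.6, rate_scale = 1.8e-06,
                                  base_pop = 0.19e6, growth = 0.022),
    SA  = synthetic_region_config("SA", alpha = 0.80, beta = 0.40, period = 100,
                                  delta = 4.4, rate_scale = 8.0e-07,
                                  base_pop = 0.36e6, growth = 0.013)
  )
}

#' Deterministic population trajectory for a synthetic region
#'
#' @param config a `synthetic_region_config`.
#' @param years consecutive integer years; the first year gets `base_pop`.
#' @return a `population_series`.
#' @export
generate_population <- function(config, years) {
  years <- as.integer(years)
  n <- length(years)
  growth <- config$growth
  if (length(growth) == 1L) growth <- rep(growth, n - 1L)
  if (length(growth) != n - 1L) {
    abort_sc("growth must be scalar or length(years) - 1", "sharkcast_config_error")
  }
  if (any(1 + growth <= 0)) {
    abort_sc("growth factors must be positive", "sharkcast_config_error")
  }
  pop <- config$base_pop * cumprod(c(1, 1 + growth))
  population_series(config$region, years, pop)
}

# true expected per-capita rate (bites person^-1 year^-1) at given years
true_expected_rate <- function(config, years) {
  x <- years - config$origin
  scaled <- config$alpha + config$beta * cos(config$gamma * x + config$delta)
  pmax(0, scaled) * config$rate_scale
}

#' Generate synthetic incident records for one region
#'
#' Draws yearly incident counts around the configured sinusoidal expectation
#' `mu_t = max(0, alpha + beta cos(gamma (t - origin) + delta)) * rate_scale *
#' population_t`, either as Poisson counts (`mode = "poisson"`, the natural
#' rare-event model) or as deterministic rounded expectations
#' (`mode = "expected"`). Each incident independently receives a species from
#' the configured mixture and fatal/provoked flags from Bernoulli draws.
#'
#' @param config a `synthetic_region_config`.
#' @param years consecutive integer years to generate.
#' @param seed integer seed; generation is bit-reproducible given the seed.
#' @param mode `"poisson"` or `"expected"`.
#' @param pop optional `population_series`; generated from `config` if omitted.
#' @return list with `records` (a `shark_incidents` data.frame) and `truth`
#'   (a `synthetic_truth` list holding the exact expected rates, expected
#'   counts, realized counts and the population used).
#' @export
generate_incidents <- function(config, years, seed,
                               mode = c("poisson", "expected"),
                               pop = NULL) {
  mode <- match.arg(mode)
  years <- as.integer(years)
  if (is.null(pop)) pop <- generate_population(config, years)
  idx <- match(years, pop$year)
  if (anyNA(idx)) {
    abort_sc("population does not cover the requested years", "sharkcast_alignment_error")
  }
  set.seed(as.integer(seed))
  rate <- true_expected_rate(config, years)
  mu <- rate * pop$population[idx]
  counts <- if (mode == "poisson") stats::rpois(length(mu), mu) else round(mu)

  n_total <- sum(counts)
  rec_years <- rep(years, counts)
  records <- data.frame(
    year = rec_years,
    region = rep(config$region, n_total),
    species = sample(species_codes(), n_total, replace = TRUE, prob = config$mix),
    fatal = stats::runif(n_total) < config$p_fatal,
    provoked = stats::runif(n_total) < config$p_provoked,
    stringsAsFactors = FALSE
  )
  class(records) <- c("shark_incidents", "data.frame")
  truth <- structure(
    list(
      region = config$region, years = years,
      expected_rate = rate, expected_count = mu,
      realized_count = counts, population = pop$population[idx],
      config = config, seed = as.integer(seed), mode = mode
    ),
    class = "synthetic_truth"
  )
  list(records = records, truth = truth)
}

#' Generate a multi-region synthetic country
#'
#' Runs [generate_incidents()] for each configured region with seeds derived
#' from `seed`, binds the records, and returns per-region truths plus the
#' implied national truth (sum of regional expectations).
#'
#' @param configs named list of `synthetic_region_config` objects.
#' @param years consecutive integer years for incident generation.
#' @param seed integer master seed.
#' @param pop_years years the population series must span (defaults to
#'   `years`); projections need population beyond the incident window.
#' @inheritParams generate_incidents
#' @return list with `records`, `populations` (named list incl. `AUS`),
#'   `truths` (named list incl. `AUS`).
#' @export
generate_country <- function(configs, years, seed,
                             mode = c("poisson", "expected"),
                             pop_years = years) {
  mode <- match.arg(mode)
  pop_years <- as.integer(pop_years)
  seeds <- as.integer(seed) + seq_along(configs) - 1L
  pops <- list()
  truths <- list()
  recs <- list()
  for (i in seq_along(configs)) {
    cfg <- configs[[i]]
    pop <- generate_population(cfg, pop_years)
    sim <- generate_incidents(cfg, years, seed = seeds[i], mode = mode, pop = pop)
    pops[[cfg$region]] <- pop
    truths[[cfg$region]] <- sim$truth
    recs[[cfg$region]] <- sim$records
  }
  records <- do.call(rbind, recs)
  class(records) <- c("shark_incidents", "data.frame")
  rownames(records) <- NULL

  pop_aus <- population_series(
    "AUS", pop_years,
    Reduce(`+`, lapply(pops, function(p) p$population))
  )
  pops$AUS <- pop_aus
  idx <- match(years, pop_years)
  expected_count_aus <- Reduce(`+`, lapply(truths, function(t) t$expected_count))
  truths$AUS <- structure(
    list(
      region = "AUS", years = years,
      expected_rate = expected_count_aus / pop_aus$population[idx],
      expected_count = expected_count_aus,
      realized_count = Reduce(`+`, lapply(truths, function(t) t$realized_count)),
      population = pop_aus$population[idx],
      config = NULL, seed = as.integer(seed), mode = mode
    ),
    class = "synthetic_truth"
  )
  list(records = records, populations = pops, truths = truths)
}

#' Expected bite counts implied by synthetic configs over arbitrary years
#'
#' Ground-truth expected counts (`rate * population`) for any window,
#' including projection years; `AUS` is the sum over regions.
#'
#' @param configs named list of `synthetic_region_config` objects.
#' @param years integer years.
#' @param pop_years years the deterministic population trajectory is built
#'   over (must contain `years`).
#' @return data.frame year x region matrix of expected counts (incl. `AUS`).
#' @export
synthetic_truth_counts <- function(configs, years, pop_years = years) {
  years <- as.integer(years)
  per_region <- lapply(configs, function(cfg) {
    pop <- generate_population(cfg, pop_years)
    idx <- match(years, pop$year)
    true_expected_rate(cfg, years) * pop$population[idx]
  })
  out <- as.data.frame(per_region)
  out$AUS <- Reduce(`+`, per_region)
  cbind(year = years, out)
}

#' Thin incident records by a reporting curve
#'
#' Emulates historical under-reporting: each record is independently retained
#' with probability `reporting(year)` given by the scenario's sigmoid. The
#' retained set is always a subset of the input.
#'
#' @param records a `shark_incidents` data.frame.
#' @param scenario a [reporting_scenario()].
#' @param seed integer seed.
#' @return the retained `shark_incidents` records.
#' @export
apply_underreporting <- function(records, scenario, seed) {
  set.seed(as.integer(seed))
  p <- reporting_proportion(records$year, scenario)
  keep <- stats::runif(nrow(records)) < p
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
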