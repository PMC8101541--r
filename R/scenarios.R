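# Intervention scenarios: beta-distributed deterrent effectiveness crossed
# with an uptake grid converts projected bite counts into averted-bite
# matrices; sigmoidal reporting curves and power-law abundance responses
# provide the sensitivity analyses.

#' Beta shape parameters by moment matching
#'
#' Solves for `Beta(a, b)` with the given mean and standard deviation:
#' `nu = mean (1 - mean) / sd^2 - 1`, `a = mean nu`, `b = (1 - mean) nu`.
#'
#' @param mean mean in (0, 1).
#' @param sd standard deviation; must satisfy `sd^2 < mean (1 - mean)`.
#' @return named numeric vector `c(a = , b = )`.
#' @export
#' @examples
#' beta_params(0.60, 0.05)  # a = 57, b = 38
beta_params <- function(mean, sd) {
  if (mean <= 0 || mean >= 1) {
    abort_sc("`mean` must lie strictly inside (0, 1)", "sharkcast_domain_error")
  }
  if (sd <= 0 || sd^2 >= mean * (1 - mean)) {
    abort_sc(
      sprintf("infeasible sd: need 0 < sd^2 < mean(1-mean) = %.4g", mean * (1 - mean)),
      "sharkcast_domain_error"
    )
  }
  nu <- mean * (1 - mean) / sd^2 - 1
  c(a = mean * nu, b = (1 - mean) * nu)
}

#' Electronic-deterrent effectiveness model
#'
#' Personal electronic deterrents reduce the probability of a shark bite by
#' roughly 60% (field trials report reductions of 56-67%); effectiveness
#' uncertainty is propagated by resampling from a beta distribution centred
#' on that reduction with a 5% standard deviation.
#'
#' @param effectiveness_mean mean probability-of-bite reduction, default 0.60.
#' @param effectiveness_sd standard deviation, default 0.05.
#' @return a `deterrence_model` list with the moments and matched beta
#'   shapes `a`, `b`.
#' @export
deterrence_model <- function(effectiveness_mean = 0.60, effectiveness_sd = 0.05) {
  shapes <- beta_params(effectiveness_mean, effectiveness_sd)
  structure(
    list(effectiveness_mean = effectiveness_mean,
         effectiveness_sd = effectiveness_sd,
         a = unname(shapes["a"]), b = unname(shapes["b"])),
    class = "deterrence_model"
  )
}

#' Deterrent-uptake grid
#'
#' Proportions of water users wearing a deterrent. The default grid runs in
#' steps of 0.1 from 0.1 to 0.9 and includes 1.0 because headline summaries
#' report the all-users case.
#'
#' @param proportions strictly increasing values in (0, 1].
#' @return validated numeric vector of class `uptake_grid`.
#' @export
uptake_grid <- function(proportions = seq(0.1, 1.0, by = 0.1)) {
  if (length(proportions) == 0) {
    abort_sc("uptake grid must not be empty", "sharkcast_config_error")
  }
  if (any(proportions <= 0 | proportions > 1) || is.unsorted(proportions, strictly = TRUE)) {
    abort_sc("uptake proportions must be strictly increasing within (0, 1]",
             "sharkcast_config_error")
  }
  structure(proportions, class = "uptake_grid")
}

#' Averted-bite matrix under deterrent uptake scenarios
#'
#' Draws a beta-distributed effectiveness for every iteration-year of a
#' count-unit projection ensemble and multiplies counts x effectiveness x
#' uptake proportion over the whole uptake grid, giving the
#' iterations x years x uptake array of bites averted. Within an iteration
#' the averted count is exactly linear and monotone non-decreasing in
#' uptake. Summaries report the per-(year, uptake) median and 95% band, and
#' cumulative totals over the projection window computed per iteration (sum
#' over years first, then quantiles across iterations - quantiles of sums,
#' not sums of quantiles).
#'
#' @param ensemble a `projection_ensemble` in count units.
#' @param det a [deterrence_model()].
#' @param grid an [uptake_grid()].
#' @param seed integer seed for the effectiveness draws.
#' @param effectiveness_draws `"per_iteration_year"` (default: an
#'   independent draw for every iteration-year) or `"per_iteration"` (one
#'   draw held constant along each trajectory).
#' @return an `averted_matrix` list: `averted` (3-d array), `years`,
#'   `uptake`, `summary` (data.frame year x uptake with median/lo95/hi95),
#'   `cumulative` (data.frame per uptake with mean, median, lo95, hi95 of
#'   the window total), `seed`.
#' @export
averted_matrix <- function(ensemble, det = deterrence_model(),
                           grid = uptake_grid(), seed,
                           effectiveness_draws = c("per_iteration_year", "per_iteration")) {
  effectiveness_draws <- match.arg(effectiveness_draws)
  if (missing(seed) || is.null(seed)) {
    abort_sc("`seed` is mandatory for effectiveness resampling", "sharkcast_config_error")
  }
  if (!identical(attr(ensemble, "units"), "count")) {
    abort_sc("ensemble must be in count units (back-transform first)",
             "sharkcast_state_error")
  }
  counts <- unclass(ensemble)
  n_iter <- nrow(counts); ny <- ncol(counts)
  years <- attr(ensemble, "years")
  set.seed(as.integer(seed))
  eff <- if (effectiveness_draws == "per_iteration_year") {
    matrix(stats::rbeta(n_iter * ny, det$a, det$b), n_iter, ny)
  } else {
    matrix(stats::rbeta(n_iter, det$a, det$b), n_iter, ny)
  }
  reduced <- counts * eff
  averted <- outer(reduced, as.numeric(grid))
  dimnames(averted) <- list(NULL, years, as.character(as.numeric(grid)))

  qs <- apply(averted, c(2, 3), stats::quantile, probs = c(0.025, 0.5, 0.975))
  summary_df <- expand.grid(year = years, uptake = as.numeric(grid))
  summary_df$median <- as.vector(qs[2, , ])
  summary_df$lo95 <- as.vector(qs[1, , ])
  summary_df$hi95 <- as.vector(qs[3, , ])

  totals <- apply(averted, c(1, 3), sum)   # iteration x uptake
  cumulative <- data.frame(
    uptake = as.numeric(grid),
    mean = colMeans(totals),
    median = apply(totals, 2, stats::median),
    lo95 = apply(totals, 2, stats::quantile, probs = 0.025),
    hi95 = apply(totals, 2, stats::quantile, probs = 0.975)
  )

  structure(
    list(averted = averted, years = years, uptake = as.numeric(grid),
         summary = summary_df, cumulative = cumulative,
         region = attr(ensemble, "region"), seed = as.integer(seed)),
    class = "averted_matrix"
  )
}

# Under-reporting -------------------------------------------------------------

#' Historical under-reporting scenarios
#'
#' Sigmoidal reporting-proportion curves describing hypothetical historical
#' under-recording of incidents. Scenario `"A"`: about 60% of incidents
#' recorded at the turn of the twentieth century, rising through the 1950s
#' television era and asymptoting to full reporting by the 1990s. Scenario
#' `"B"`: about 40% recorded in 1900, asymptoting during the 2000s with
#' social media.
#'
#' @param id `"A"` or `"B"`.
#' @return a `reporting_scenario` list with `gamma_floor`, `alpha_r`,
#'   `beta_r`.
#' @export
reporting_scenario <- function(id = c("A", "B")) {
  id <- match.arg(id)
  pars <- switch(id,
    A = list(gamma_floor = 0.602, alpha_r = -1601.064, beta_r = 211.348),
    B = list(gamma_floor = 0.394, alpha_r = -1381.997, beta_r = 182.430)
  )
  structure(c(list(id = id), pars), class = "reporting_scenario")
}

#' Proportion of incidents recorded in a given year
#'
#' Evaluates the scenario's sigmoid. The adopted orientation is
#' `reporting(x) = gamma + (1 - gamma) * plogis(alpha + beta * log(x))`
#' with natural log of the calendar year: it rises from the scenario floor
#' (about 0.60 for scenario A in 1900), crosses its midpoint near 1950, and
#' asymptotes to 1. The `"literal"` form `1 - gamma / (1 + exp(-alpha -
#' beta * log(x)))` is retained for comparison; with the same parameters it
#' is a decreasing curve and does not match the scenarios' described
#' behaviour (see the methods vignette).
#'
#' @param year calendar year(s), >= 1800.
#' @param scenario a [reporting_scenario()].
#' @param form `"adopted"` (default) or `"literal"`.
#' @return reporting proportion(s) in (0, 1).
#' @export
reporting_proportion <- function(year, scenario, form = c("adopted", "literal")) {
  form <- match.arg(form)
  if (any(year < 1800)) {
    abort_sc("reporting curves are defined for years >= 1800", "sharkcast_domain_error")
  }
  g <- scenario$gamma_floor
  lp <- scenario$alpha_r + scenario$beta_r * log(year)
  if (form == "adopted") {
    g + (1 - g) * stats::plogis(lp)
  } else {
    1 - g / (1 + exp(-lp))
  }
}

#' Correct a series for under-reporting
#'
#' Divides each observed value by the scenario's reporting proportion at its
#' year, inflating early observations where recording was incomplete. Works
#' on count, rate and scaled series alike (the scaled series keeps its
#' stored scale factor, so back-transforms remain exact for the uncorrected
#' scale).
#'
#' @param series a `count_series`, `rate_series` or `scaled_rate_series`.
#' @param scenario a [reporting_scenario()].
#' @param form sigmoid orientation passed to [reporting_proportion()].
#' @return the corrected series, same class and attributes.
#' @export
correct_for_reporting <- function(series, scenario, form = "adopted") {
  p <- reporting_proportion(series$year, scenario, form)
  value_col <- intersect(c("count", "rate", "scaled"), names(series))[1]
  if (is.na(value_col)) {
    abort_sc("series must have a count, rate or scaled column", "sharkcast_config_error")
  }
  series[[value_col]] <- series[[value_col]] / p
  series
}

# Relative shark abundance ----------------------------------------------------

#' Bite-rate factor from relative shark abundance
#'
#' Power-law response of per-capita bite rate to relative shark abundance,
#' `r_b = N_rel^0.4307`: a fivefold increase in relative abundance doubles
#' the bite rate (the default exponent is `log(2)/log(5)` to four decimals).
#'
#' @param n_rel relative abundance, positive, scaled so its maximum is 1.
#' @param exponent power-law exponent, default 0.4307.
#' @return bite-rate multiplier(s).
#' @export
abundance_rate_factor <- function(n_rel, exponent = 0.4307) {
  if (any(n_rel <= 0)) {
    abort_sc("relative abundance must be positive", "sharkcast_domain_error")
  }
  n_rel^exponent
}

#' Adjust a total scaled series for changing relative shark abundance
#'
#' Implements the species-level abundance correction: for each species group
#' (white, tiger, bull/whaler) a Gamma log-link GLM of the species' scaled
#' bite rate on its relative-abundance trajectory is fitted, and the
#' species series is rescaled multiplicatively by the fitted abundance
#' response `exp(b1 * N_rel)` (normalized to a maximum of 1). The adjusted
#' species series are summed, the sum is transformed to a proportion of its
#' maximum, and that proportional series multiplies the total scaled series,
#' which then feeds the standard sinusoid/projection path.
#'
#' @param species_scaled named list of `scaled_rate_series` (or data.frames
#'   with `year`, `scaled`) for `white`, `tiger`, `bull_whaler`.
#' @param n_rel data.frame with column `year` and one column per species
#'   group, values in (0, 1].
#' @param total_scaled the region's total `scaled_rate_series`.
#' @param zero_policy zero handling for the Gamma fits (see
#'   [fit_polynomial_gamma()]).
#' @return a list: `adjusted` (the adjusted total `scaled_rate_series`),
#'   `proportional` (the max-normalized species-sum series),
#'   `species_adjusted` (named list), `glm_coefficients` (named list of
#'   `(intercept, slope)` per species).
#' @export
adjust_series_for_abundance <- function(species_scaled, n_rel, total_scaled,
                                        zero_policy = "half_min") {
  needed <- c("white", "tiger", "bull_whaler")
  if (!all(needed %in% names(species_scaled))) {
    abort_sc(
      sprintf("species series missing: %s",
              paste(setdiff(needed, names(species_scaled)), collapse = ", ")),
      "sharkcast_config_error"
    )
  }
  if (!all(needed %in% names(n_rel))) {
    abort_sc("`n_rel` must have a trajectory column per species group",
             "sharkcast_config_error")
  }

  coefs <- list()
  adjusted_species <- list()
  for (sp in needed) {
    ss <- species_scaled[[sp]]
    idx <- match(ss$year, n_rel$year)
    if (anyNA(idx)) {
      abort_sc(sprintf("`n_rel` does not cover the years of the %s series", sp),
               "sharkcast_alignment_error")
    }
    nr <- n_rel[[sp]][idx]
    if (any(nr <= 0 | nr > 1)) {
      abort_sc("relative abundance trajectories must lie in (0, 1]",
               "sharkcast_domain_error")
    }
    pz <- positivize(ss$scaled, zero_policy)
    y <- pz$y; x <- nr[pz$keep]
    if (stats::sd(x) == 0) {
      # constant trajectory carries no abundance signal: slope pinned to 0
      b <- c(log(mean(y)), 0)
    } else {
      fit <- stats::glm(y ~ x, family = stats::Gamma(link = "log"))
      b <- unname(stats::coef(fit))
    }
    coefs[[sp]] <- c(intercept = b[1], slope = b[2])
    factor_t <- exp(b[2] * nr)
    factor_t <- factor_t / max(factor_t)
    adj <- ss
    adj$scaled <- ss$scaled * factor_t
    adjusted_species[[sp]] <- adj
  }

  years <- adjusted_species$white$year
  for (sp in needed[-1]) {
    if (!identical(adjusted_species[[sp]]$year, years)) {
      abort_sc("species series must share the same year window",
               "sharkcast_alignment_error")
    }
  }
  total_adj <- Reduce(`+`, lapply(adjusted_species, function(s) s$scaled))
  if (max(total_adj) <= 0) {
    abort_sc("adjusted species sum is identically zero", "sharkcast_degenerate_error")
  }
  prop <- total_adj / max(total_adj)

  idx <- match(total_scaled$year, years)
  if (anyNA(idx)) {
    abort_sc("species series do not cover the total series' years",
             "sharkcast_alignment_error")
  }
  out <- total_scaled
  out$scaled <- total_scaled$scaled * prop[idx]

  list(
    adjusted = out,
    proportional = data.frame(year = years, proportion = prop),
    species_adjusted = adjusted_species,
    glm_coefficients = coefs
  )
}
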