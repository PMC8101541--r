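# Stochastic projection: resampled sign-pool residuals added to the fitted
# sinusoid give an ensemble of future scaled-rate trajectories, which are
# back-transformed to bite counts via the stored RMS scale factor and the
# projected human population.

new_ensemble <- function(mat, years, region, units, seed) {
  structure(
    mat,
    years = as.integer(years), region = region, units = units, seed = seed,
    class = c("projection_ensemble", "matrix", "array")
  )
}

#' Project an ensemble of future scaled bite-rate series
#'
#' For every iteration and projection year: a fair coin (`sign_prob = 0.5`)
#' picks the positive or negative residual pool; one observed residual is
#' drawn from that pool with replacement, with probability proportional to
#' its KDE-density weight; the draw is multiplied by the pool's
#' year-dependent magnitude multiplier and added to the sinusoid's median
#' prediction; negative sums are floored at zero (a rate cannot be
#' negative). Draws are independent across iterations and years and the
#' whole ensemble is reproducible from `seed`.
#'
#' @param fit a `sinusoid_fit`.
#' @param sampler a `residual_sampler`.
#' @param years projection years (default 2020-2066).
#' @param n_iter number of future series (default 10000).
#' @param seed integer seed (mandatory).
#' @param resample `"weighted_observed"` (default: draw the observed
#'   residuals with KDE-density weights) or `"kde_smooth"` (smoothed
#'   bootstrap: jitter each draw with the pool's Gaussian kernel, i.e. draw
#'   from the KDE itself).
#' @return a `projection_ensemble` matrix (`n_iter` rows x years columns) in
#'   scaled units, with `years`, `region`, `units`, `seed` attributes.
#' @export
project_ensemble <- function(fit, sampler, years = 2020:2066,
                             n_iter = 10000L, seed,
                             resample = c("weighted_observed", "kde_smooth")) {
  resample <- match.arg(resample)
  if (missing(seed) || is.null(seed)) {
    abort_sc("`seed` is mandatory for stochastic projection", "sharkcast_config_error")
  }
  if (n_iter < 1) abort_sc("`n_iter` must be >= 1", "sharkcast_config_error")
  years <- as.integer(years)
  ny <- length(years)
  set.seed(as.integer(seed))

  med <- predict_sinusoid(fit, years)
  scale_pos <- pool_scale(sampler$positive, med)
  scale_neg <- pool_scale(sampler$negative, med)

  n <- n_iter * ny
  take_pos <- matrix(stats::runif(n) < sampler$sign_prob, n_iter, ny)
  rpos <- matrix(sample(sampler$positive$residuals, n, replace = TRUE,
                        prob = sampler$positive$weights), n_iter, ny)
  rneg <- matrix(sample(sampler$negative$residuals, n, replace = TRUE,
                        prob = sampler$negative$weights), n_iter, ny)
  if (resample == "kde_smooth") {
    rpos <- rpos + stats::rnorm(n, 0, sampler$positive$bandwidth)
    rneg <- rneg + stats::rnorm(n, 0, sampler$negative$bandwidth)
  }

  shock <- rpos * rep(scale_pos, each = n_iter)
  shock[!take_pos] <- (rneg * rep(scale_neg, each = n_iter))[!take_pos]
  proj <- pmax(0, rep(med, each = n_iter) + shock)
  dim(proj) <- c(n_iter, ny)

  new_ensemble(proj, years, attr(fit, "region") %||% NA_character_,
               "scaled", as.integer(seed))
}

#' Back-transform a scaled ensemble to bite counts
#'
#' Multiplies each scaled trajectory by the stored RMS scale factor (giving
#' bites per person per year) and by the projected population of the matching
#' year (giving expected people bitten). Counts stay continuous; rounding is
#' deferred to public summaries.
#'
#' @param ensemble a `projection_ensemble` in scaled units.
#' @param scale_factor the RMS divisor stored by [rms_scale()] (or a
#'   `scaled_rate_series`, from which it is taken).
#' @param pop a `population_series` covering every projection year.
#' @return a `projection_ensemble` in count units.
#' @export
back_transform_to_counts <- function(ensemble, scale_factor, pop) {
  if (inherits(scale_factor, "scaled_rate_series")) {
    scale_factor <- attr(scale_factor, "scale_factor")
  }
  years <- attr(ensemble, "years")
  idx <- match(years, pop$year)
  if (anyNA(idx)) {
    abort_sc(
      sprintf("population series missing projection year(s): %s",
              paste(years[is.na(idx)], collapse = ", ")),
      "sharkcast_alignment_error"
    )
  }
  counts <- pmax(unclass(ensemble), 0) * scale_factor *
    rep(pop$population[idx], each = nrow(ensemble))
  new_ensemble(counts, years, attr(ensemble, "region"), "count",
               attr(ensemble, "seed"))
}

#' Per-year summary of a projection ensemble
#'
#' @param ensemble a `projection_ensemble`.
#' @param probs quantile probabilities for the uncertainty band
#'   (default 2.5% and 97.5%).
#' @return data.frame with `year`, `median`, `lo`, `hi`, `mean`.
#' @export
ensemble_summary <- function(ensemble, probs = c(0.025, 0.975)) {
  m <- unclass(ensemble)
  data.frame(
    year = attr(ensemble, "years"),
    median = apply(m, 2, stats::median),
    lo = apply(m, 2, stats::quantile, probs = probs[1]),
    hi = apply(m, 2, stats::quantile, probs = probs[2]),
    mean = colMeans(m)
  )
}
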