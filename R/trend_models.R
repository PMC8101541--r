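# Polynomial trend models with Gamma errors and identity link, ranked by
# AICc, plus the percentage of deviance explained as goodness-of-fit.

# Gamma likelihood requires a strictly positive response; years with zero
# scaled rate are handled by a documented policy before fitting.
positivize <- function(y, zero_policy = c("half_min", "drop")) {
  zero_policy <- match.arg(zero_policy)
  if (all(y <= 0)) {
    abort_sc("response has no positive values; Gamma fit impossible",
             "sharkcast_degenerate_error")
  }
  if (zero_policy == "drop") {
    keep <- y > 0
    return(list(y = y[keep], keep = keep))
  }
  half_min <- min(y[y > 0]) / 2
  list(y = ifelse(y <= 0, half_min, y), keep = rep(TRUE, length(y)))
}

# Profile log-likelihood of a Gamma sample with known means mu: the shape is
# a nuisance maximized out numerically, not counted in k.
gamma_profile_ll <- function(y, mu) {
  nll <- function(log_shape) {
    shape <- exp(log_shape)
    -sum(stats::dgamma(y, shape = shape, rate = shape / mu, log = TRUE))
  }
  opt <- stats::optimize(nll, interval = c(-12, 16))
  list(ll = -opt$objective, shape = exp(opt$minimum))
}

gamma_deviance <- function(y, mu) {
  2 * sum(-log(y / mu) + (y - mu) / mu)
}

#' Fit a polynomial trend with Gamma errors and identity link
#'
#' Fits `mu_t = c0 + c1 x_t + ... + c_degree x_t^degree` to a scaled rate
#' series by Gamma maximum likelihood with an identity link, where `x` is the
#' year covariate centred and scaled to unit variance (raw calendar years cubed
#' are catastrophically conditioned). The log-likelihood is evaluated at the
#' maximum-likelihood shape, which is profiled out and not counted among the
#' `k = degree + 1` estimated regression coefficients.
#'
#' @param scaled a `scaled_rate_series` (or data.frame with `year` and
#'   `scaled` columns).
#' @param degree polynomial degree 0-3: intercept-only (no trend), linear,
#'   quadratic, or cubic (short-term periodicity).
#' @param zero_policy `"half_min"` (default: zero responses replaced by half
#'   the smallest positive value, preserving series length) or `"drop"`.
#' @return a `trend_fit` list: `degree`, `coefficients` (transformed basis),
#'   `coefficients_raw` (calendar-year basis), `log_likelihood`, `shape`,
#'   `k`, `n`, `aicc`, `deviance`, `null_deviance`, `pct_deviance_explained`,
#'   `fitted`, `year`.
#' @export
fit_polynomial_gamma <- function(scaled, degree, zero_policy = c("half_min", "drop")) {
  if (!degree %in% 0:3) {
    abort_sc("`degree` must be 0, 1, 2 or 3", "sharkcast_config_error")
  }
  pz <- positivize(scaled$scaled, zero_policy)
  y <- pz$y
  year <- scaled$year[pz$keep]
  n <- length(y)
  if (n <= degree + 2) {
    abort_sc("series too short for requested degree", "sharkcast_config_error")
  }

  x <- as.numeric(base::scale(year))
  X <- if (degree == 0) {
    matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    cbind("(Intercept)" = 1, outer(x, seq_len(degree), `^`))
  }
  if (degree > 0) colnames(X)[-1] <- paste0("x^", seq_len(degree))

  coefs <- fit_gamma_identity(y, X)
  mu <- drop(X %*% coefs)
  if (any(mu <= 0)) {
    abort_sc("fitted means not strictly positive; Gamma identity fit infeasible",
             "sharkcast_fit_error")
  }

  prof <- gamma_profile_ll(y, mu)
  dev <- gamma_deviance(y, mu)
  null_dev <- gamma_deviance(y, rep(mean(y), n))
  pct_de <- if (degree == 0 || null_dev <= 0) 0 else 100 * (null_dev - dev) / null_dev

  k <- degree + 1L
  structure(
    list(
      degree = degree,
      coefficients = coefs,
      coefficients_raw = rebase_poly(coefs, mean(year), stats::sd(year)),
      log_likelihood = prof$ll,
      shape = prof$shape,
      k = k, n = n,
      aicc = aicc(prof$ll, k, n),
      deviance = dev,
      null_deviance = null_dev,
      pct_deviance_explained = pct_de,
      fitted = mu,
      year = year
    ),
    class = "trend_fit"
  )
}

# ML fit of Gamma / identity-link regression. glm() with a least-squares
# start is tried first; if iteratively reweighted least squares steps outside
# the positive-mean region, fall back to direct deviance minimization with a
# feasibility barrier.
fit_gamma_identity <- function(y, X) {
  if (ncol(X) == 1L) {
    # identity-link null model: the ML constant mean is the sample mean
    return(c("(Intercept)" = mean(y)))
  }
  ls_start <- stats::coef(stats::lm.fit(X, y))
  if (any(X %*% ls_start <= 0)) {
    ls_start <- c(mean(y), rep(0, ncol(X) - 1))
  }
  fit <- tryCatch(
    stats::glm.fit(X, y, family = stats::Gamma(link = "identity"),
                   start = ls_start,
                   control = stats::glm.control(maxit = 100)),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (!is.null(fit) && fit$converged && all(fit$fitted.values > 0)) {
    return(stats::coef(fit))
  }
  obj <- function(b) {
    mu <- drop(X %*% b)
    if (any(mu <= 1e-12)) return(1e12 + sum(pmax(0, 1e-12 - mu)) * 1e12)
    gamma_deviance(y, mu)
  }
  opt <- stats::optim(ls_start, obj, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
  if (!is.finite(opt$value) || opt$value >= 1e12) {
    abort_sc("Gamma identity-link fit did not converge (no feasible mean found)",
             "sharkcast_fit_error")
  }
  b <- opt$par
  names(b) <- colnames(X)
  b
}

# express polynomial coefficients in x = (year - m)/s back on raw years
rebase_poly <- function(coefs, m, s) {
  degree <- length(coefs) - 1L
  out <- numeric(degree + 1L)
  for (j in 0:degree) {
    cj <- coefs[j + 1L]
    # c_j * ((t - m)/s)^j expanded in powers of t
    for (i in 0:j) {
      out[i + 1L] <- out[i + 1L] + cj * choose(j, i) * (-m)^(j - i) / s^j
    }
  }
  names(out) <- c("(Intercept)", if (degree > 0) paste0("year^", seq_len(degree)))
  out
}

#' Sample-size-corrected Akaike information criterion
#'
#' `AICc = -2 LL + 2k + 2k(k + 1)/(n - k - 1)`; converges to the ordinary AIC
#' as `n` grows.
#'
#' @param LL maximized log-likelihood.
#' @param k number of estimated parameters.
#' @param n number of observations; must exceed `k + 1`.
#' @return the AICc value.
#' @export
aicc <- function(LL, k, n) {
  if (n <= k + 1) {
    abort_sc("AICc undefined for n <= k + 1", "sharkcast_domain_error")
  }
  -2 * LL + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights from AICc values
#'
#' `w_i = exp(-delta_i / 2) / sum_j exp(-delta_j / 2)` with
#' `delta_i = AICc_i - min(AICc)`; the shift makes the exponentials
#' numerically safe and leaves the weights invariant to adding any constant.
#'
#' @param aiccs numeric vector of finite AICc values.
#' @return weights summing to 1, interpretable as model probabilities.
#' @export
akaike_weights <- function(aiccs) {
  if (length(aiccs) == 0 || any(!is.finite(aiccs))) {
    abort_sc("`aiccs` must be a non-empty vector of finite values",
             "sharkcast_config_error")
  }
  delta <- aiccs - min(aiccs)
  w <- exp(-delta / 2)
  w / sum(w)
}

#' Rank the four polynomial trend models on one series
#'
#' Fits the intercept-only, linear, quadratic and cubic Gamma identity-link
#' models to a scaled rate series and ranks them by AICc, reporting the
#' log-likelihood, number of estimated coefficients, AICc difference to the
#' top model, Akaike weight and percentage of deviance explained for each.
#' Models that fail to converge are dropped with a warning and the ranking
#' proceeds over the convergent subset.
#'
#' @inheritParams fit_polynomial_gamma
#' @return a `model_ranking` list: `fits` (by degree), `table` (one row per
#'   model, ordered by AICc ascending), `top_degree`.
#' @export
rank_models <- function(scaled, zero_policy = c("half_min", "drop")) {
  zero_policy <- match.arg(zero_policy)
  fits <- list()
  for (d in 0:3) {
    f <- tryCatch(fit_polynomial_gamma(scaled, d, zero_policy),
                  error = function(e) e)
    if (inherits(f, "error")) {
      warning(sprintf("degree-%d model failed: %s; ranking over remaining models",
                      d, conditionMessage(f)))
    } else {
      fits[[as.character(d)]] <- f
    }
  }
  if (length(fits) == 0) {
    abort_sc("no trend model converged", "sharkcast_fit_error")
  }
  aiccs <- vapply(fits, `[[`, numeric(1), "aicc")
  tab <- data.frame(
    model = c("~1", "~yr", "~yr+yr2", "~yr+yr2+yr3")[
      vapply(fits, `[[`, integer(1), "degree") + 1L],
    degree = vapply(fits, `[[`, integer(1), "degree"),
    LL = vapply(fits, `[[`, numeric(1), "log_likelihood"),
    k = vapply(fits, `[[`, integer(1), "k"),
    AICc = aiccs,
    dAICc = aiccs - min(aiccs),
    wAICc = akaike_weights(aiccs),
    pctDE = vapply(fits, `[[`, numeric(1), "pct_deviance_explained")
  )
  tab <- tab[order(tab$AICc), ]
  rownames(tab) <- NULL
  structure(
    list(fits = fits, table = tab, top_degree = tab$degree[1]),
    class = "model_ranking"
  )
}

#' @export
print.model_ranking <- function(x, ...) {
  cat("Gamma identity-link trend-model ranking\n")
  print(transform(x$table,
                  LL = round(LL, 3), AICc = round(AICc, 3),
                  dAICc = round(dAICc, 3), wAICc = signif(wAICc, 3),
                  pctDE = round(pctDE, 1)))
  invisible(x)
}
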