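# Sinusoidal model of multidecadal periodicity in scaled per-capita bite
# rates: y = alpha + beta * cos(gamma * x + delta), x = years since the
# series origin. Fitted by least squares with the linear parameters profiled
# out over a frequency grid, then polished by Levenberg-Marquardt.

#' Fit a sinusoid to a scaled rate series
#'
#' Fits `y = alpha + beta cos(gamma x + delta)` by least squares, with
#' `x = year - origin` (origin = first year of the series). For any fixed
#' angular frequency `gamma` the model is linear in
#' `(alpha, beta cos delta, -beta sin delta)`, so initialization profiles the
#' linear parameters over a dense frequency grid (augmented with the dominant
#' raw-periodogram frequencies) and the best candidates are refined with
#' Levenberg-Marquardt ([minpack.lm::nlsLM]). The solution is normalized to
#' `beta >= 0`, `gamma > 0`, `delta` in `[0, 2 pi)`.
#'
#' @param scaled a `scaled_rate_series` (or data.frame with `year`,`scaled`),
#'   length >= 8, not constant.
#' @param period_range candidate period range in years for initialization;
#'   default 4 to 5 times the series length.
#' @param n_grid number of (log-spaced) grid frequencies. Default 240.
#' @return a `sinusoid_fit` list: `alpha`, `beta`, `gamma`, `delta`,
#'   `period`, `origin`, `year`, `observed`, `fitted`, `sse`.
#' @export
fit_sinusoid <- function(scaled, period_range = NULL, n_grid = 240L) {
  y <- series_values(scaled)
  year <- scaled$year
  n <- length(y)
  if (n < 5) abort_sc("need at least 5 observations to fit a 4-parameter sinusoid",
                      "sharkcast_config_error")
  if (stats::sd(y) == 0) abort_sc("cannot fit a sinusoid to a constant series",
                                  "sharkcast_degenerate_error")
  origin <- year[1]
  x <- year - origin

  period_range <- period_range %||% c(4, 5 * n)
  periods <- exp(seq(log(period_range[1]), log(period_range[2]), length.out = n_grid))
  gammas <- 2 * pi / periods
  if (n >= 16) {
    pg <- smoothed_periodogram(y, spans = NULL)
    top <- order(pg$spec, decreasing = TRUE)[1:3]
    gammas <- c(gammas, 2 * pi * pg$freq[top])
  }

  profile_sse <- function(g) {
    fit <- stats::lm.fit(cbind(1, cos(g * x), sin(g * x)), y)
    sum(fit$residuals^2)
  }
  sses <- vapply(gammas, profile_sse, numeric(1))
  starts <- gammas[order(sses)[seq_len(min(6L, length(gammas)))]]

  best <- NULL
  tried <- character(0)
  for (g0 in starts) {
    lin <- stats::lm.fit(cbind(1, cos(g0 * x), sin(g0 * x)), y)
    st <- list(a = lin$coefficients[1], b = lin$coefficients[2],
               c = lin$coefficients[3], g = g0)
    st <- lapply(st, function(v) if (is.na(v)) 0 else unname(v))
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ a + b * cos(g * x) + c * sin(g * x),
        data = list(y = y, x = x),
        start = st,
        control = minpack.lm::nls.lm.control(maxiter = 400, ftol = 1e-15, ptol = 1e-15)
      ),
      error = function(e) e
    )
    tried <- c(tried, sprintf("period %.2f", 2 * pi / g0))
    if (inherits(fit, "error")) next
    sse <- sum(stats::residuals(fit)^2)
    if (is.null(best) || sse < best$sse) {
      best <- list(coef = stats::coef(fit), sse = sse)
    }
  }
  if (is.null(best)) {
    abort_sc(
      paste0("sinusoid optimizer failed from every start (tried: ",
             paste(tried, collapse = ", "), ")"),
      "sharkcast_fit_error"
    )
  }
  # grid-profile SSE can only be matched or beaten by the polish; keep the
  # better of the two in degenerate cases
  if (min(sses) < best$sse) {
    g <- gammas[which.min(sses)]
    lin <- stats::lm.fit(cbind(1, cos(g * x), sin(g * x)), y)
    best <- list(coef = c(a = unname(lin$coefficients[1]),
                          b = unname(lin$coefficients[2]),
                          c = unname(lin$coefficients[3]), g = g),
                 sse = min(sses))
  }

  a <- unname(best$coef["a"]); b <- unname(best$coef["b"])
  cc <- unname(best$coef["c"]); g <- unname(best$coef["g"])
  if (is.na(cc)) cc <- 0
  if (g < 0) { g <- -g; cc <- -cc }   # cos(-gx+d) = cos(gx-d)
  beta <- sqrt(b^2 + cc^2)
  delta <- if (beta > 0) atan2(-cc, b) %% (2 * pi) else 0
  fitted <- a + beta * cos(g * x + delta)

  structure(
    list(
      alpha = a, beta = beta, gamma = g, delta = delta,
      period = 2 * pi / g, origin = origin,
      year = year, observed = y, fitted = fitted,
      sse = sum((y - fitted)^2)
    ),
    class = "sinusoid_fit"
  )
}

#' Evaluate a fitted sinusoid at arbitrary years
#'
#' @param fit a `sinusoid_fit`.
#' @param years integer years (may extend beyond the fitting window).
#' @return numeric vector of sinusoid values (scaled-rate units).
#' @export
predict_sinusoid <- function(fit, years) {
  fit$alpha + fit$beta * cos(fit$gamma * (years - fit$origin) + fit$delta)
}

#' @export
print.sinusoid_fit <- function(x, ...) {
  cat(sprintf(
    "sinusoid fit: alpha=%.4f beta=%.4f period=%.1f yr delta=%.3f rad (SSE %.4g, n=%d)\n",
    x$alpha, x$beta, x$period, x$delta, x$sse, length(x$observed)
  ))
  invisible(x)
}

#' Split residuals from a sinusoid fit into sign pools
#'
#' Partition of the fitting-window residuals (`observed - fitted`) into the
#' positive and negative pools that drive stochastic projection. Exact zeros
#' are assigned alternately (first zero to the positive pool, second to the
#' negative, in year order) so the pools stay balanced.
#'
#' @param scaled the `scaled_rate_series` the fit was computed on.
#' @param fit the matching `sinusoid_fit`.
#' @return a `residual_pools` list: `positive` and `negative` data.frames
#'   with columns `year`, `residual`, `fitted`.
#' @export
split_residuals <- function(scaled, fit) {
  y <- series_values(scaled)
  if (length(y) != length(fit$fitted) || !all(scaled$year == fit$year)) {
    abort_sc("fit was not computed on this series", "sharkcast_state_error")
  }
  r <- y - fit$fitted
  if (all(r == 0)) {
    abort_sc("fit is perfect: all residuals are zero, no sampler can be built",
             "sharkcast_degenerate_error")
  }
  pos <- r > 0
  neg <- r < 0
  zero <- which(r == 0)
  if (length(zero)) {
    to_pos <- zero[seq_along(zero) %% 2 == 1]
    pos[to_pos] <- TRUE
    neg[setdiff(zero, to_pos)] <- TRUE
  }
  pools <- structure(
    list(
      positive = data.frame(year = fit$year[pos], residual = r[pos],
                            fitted = fit$fitted[pos]),
      negative = data.frame(year = fit$year[neg], residual = r[neg],
                            fitted = fit$fitted[neg])
    ),
    class = "residual_pools"
  )
  if (nrow(pools$positive) < 2 || nrow(pools$negative) < 2) {
    abort_sc(
      "a residual pool has fewer than 2 members; too few residuals to build a sampler (consider pooling)",
      "sharkcast_degenerate_error"
    )
  }
  pools
}

# gaussian KDE density of pool values evaluated at the pool values themselves
kde_self_density <- function(r, bw) {
  n <- length(r)
  d <- outer(r, r, function(a, b) stats::dnorm((a - b) / bw)) |> rowSums()
  d / (n * bw)
}

pool_bandwidth <- function(r) {
  if (length(unique(r)) < 2) {
    abort_sc("all pool residuals identical; bandwidth is zero", "sharkcast_degenerate_error")
  }
  bw <- tryCatch(stats::bw.SJ(r), error = function(e) NA_real_)
  if (!is.finite(bw) || bw <= 0) bw <- stats::bw.nrd0(r)
  if (!is.finite(bw) || bw <= 0) {
    abort_sc("could not estimate a positive bandwidth for residual pool",
             "sharkcast_degenerate_error")
  }
  bw
}

build_pool <- function(df, floor) {
  r <- df$residual
  bw <- pool_bandwidth(r)
  dens <- kde_self_density(r, bw)
  # |residual| regressed on the sinusoid level at the residual's year:
  # residual magnitude shrinks in troughs and grows at peaks
  if (stats::sd(df$fitted) == 0) {
    # flat sinusoid level: no magnitude trend is identifiable
    co <- c(mean(abs(r)), 0)
  } else {
    mag <- stats::lm(abs(r) ~ df$fitted)
    co <- unname(stats::coef(mag))
  }
  pred <- co[1] + co[2] * df$fitted
  list(
    residuals = r, year = df$year, bandwidth = bw,
    weights = dens / sum(dens),
    mag_intercept = co[1], mag_slope = co[2],
    mean_pred = mean(pred), floor = floor
  )
}

#' Build the stochastic residual sampler
#'
#' For each sign pool: a Gaussian KDE with Sheather-Jones bandwidth is fitted
#' to the residuals; each observed residual is assigned a resampling weight
#' proportional to the KDE density evaluated at itself (so resampling draws
#' the observed residuals, concentrated where the estimated density is high);
#' and the residual magnitude is regressed linearly on the sinusoid level at
#' the residual's year, giving a year-dependent scale multiplier
#' `max(floor, predicted |r| / mean predicted |r|)` that shrinks projected
#' residuals in sinusoid troughs and inflates them at peaks.
#'
#' If the Sheather-Jones bandwidth cannot be estimated (very sparse pools),
#' Silverman's rule is used instead.
#'
#' @param pools a `residual_pools` object.
#' @param floor positive lower bound on the magnitude multiplier
#'   (default 0.1), preventing degenerate or sign-flipping scalings.
#' @return a `residual_sampler` list with elements `positive`, `negative`
#'   (each: `residuals`, `bandwidth`, `weights`, magnitude coefficients) and
#'   `sign_prob = 0.5`.
#' @export
build_residual_sampler <- function(pools, floor = 0.1) {
  if (floor <= 0) abort_sc("`floor` must be positive", "sharkcast_config_error")
  structure(
    list(
      positive = build_pool(pools$positive, floor),
      negative = build_pool(pools$negative, floor),
      sign_prob = 0.5
    ),
    class = "residual_sampler"
  )
}

pool_scale <- function(pool, level) {
  pmax(pool$floor, (pool$mag_intercept + pool$mag_slope * level) / pool$mean_pred)
}
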