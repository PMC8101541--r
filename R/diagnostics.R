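# Periodicity diagnostics: autocorrelation, partial autocorrelation,
# smoothed periodogram, and the running mean used to strip fine-scale
# variability from climate-index comparators.

series_values <- function(series) {
  if (is.numeric(series)) return(as.numeric(series))
  for (nm in c("scaled", "rate", "count", "value")) {
    if (nm %in% names(series)) return(as.numeric(series[[nm]]))
  }
  abort_sc("cannot extract a numeric series from input", "sharkcast_config_error")
}

#' Autocorrelation and partial autocorrelation of a series
#'
#' Autocorrelations are computed about the sample mean (demeaned
#' covariances); partial autocorrelations come from the Durbin-Levinson
#' recursion as implemented by `stats::pacf`.
#'
#' @param series numeric vector or a rate/scaled series data.frame.
#' @param max_lag largest lag; must be below `n / 2`.
#' @return a `bite_diagnostics` list with `acf` (lags `0:max_lag`), `pacf`
#'   (lags `1:max_lag`) and their lag vectors.
#' @export
acf_pacf <- function(series, max_lag) {
  x <- series_values(series)
  n <- length(x)
  if (max_lag >= n / 2) {
    abort_sc("`max_lag` must be smaller than n / 2", "sharkcast_config_error")
  }
  if (stats::sd(x) == 0) {
    abort_sc("autocorrelation undefined for a constant series",
             "sharkcast_degenerate_error")
  }
  a <- stats::acf(x, lag.max = max_lag, demean = TRUE, plot = FALSE)
  p <- stats::pacf(x, lag.max = max_lag, plot = FALSE)
  structure(
    list(
      acf = drop(a$acf), acf_lags = drop(a$lag),
      pacf = drop(p$acf), pacf_lags = drop(p$lag)
    ),
    class = "bite_diagnostics"
  )
}

#' Smoothed periodogram via the fast Fourier transform
#'
#' Computes the FFT periodogram of the demeaned (optionally detrended)
#' series and smooths it with modified Daniell kernels of the given spans.
#' Ordinates follow the classical convention `I(f_j) = |DFT|^2 / n`; the
#' returned `density` column is `2 I(f_j)`, whose Riemann sum over the
#' frequency grid (spacing `1/n`) recovers the series' mean square about the
#' mean, up to the usual Nyquist-term convention for even `n`.
#'
#' @param series numeric vector or a rate/scaled series data.frame
#'   (length >= 16).
#' @param spans modified Daniell smoother spans; `NULL` for the raw
#'   periodogram. Default `c(3, 3)`.
#' @param detrend remove a linear trend before transforming? Default `FALSE`
#'   (the series is demeaned regardless).
#' @return a `bite_periodogram` data.frame with `freq` (cycles/year, in
#'   `(0, 0.5]`), `spec` (periodogram ordinates) and `density`.
#' @export
smoothed_periodogram <- function(series, spans = c(3, 3), detrend = FALSE) {
  x <- series_values(series)
  if (length(x) < 16) {
    abort_sc("need at least 16 observations for a periodogram",
             "sharkcast_config_error")
  }
  if (!is.null(spans) && (any(spans < 1) || any(spans != round(spans)))) {
    abort_sc("`spans` must be positive integers", "sharkcast_config_error")
  }
  sp <- stats::spec.pgram(x, spans = spans, detrend = detrend, demean = TRUE,
                          taper = 0, fast = FALSE, plot = FALSE)
  out <- data.frame(freq = sp$freq, spec = sp$spec, density = 2 * sp$spec)
  class(out) <- c("bite_periodogram", "data.frame")
  attr(out, "spans") <- spans
  out
}

#' Centred running mean
#'
#' Centred moving average with an odd window; endpoints are averaged over the
#' shrinking window that fits inside the series, so the output has the same
#' length as the input.
#'
#' @param series numeric vector or series data.frame.
#' @param window odd integer window width, at most the series length.
#' @return numeric vector of the same length.
#' @export
running_mean <- function(series, window = 5L) {
  x <- series_values(series)
  n <- length(x)
  if (window %% 2 != 1 || window < 1 || window > n) {
    abort_sc("`window` must be an odd integer no larger than the series length",
             "sharkcast_config_error")
  }
  half <- (window - 1L) / 2L
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    mean(x[lo:hi])
  }, numeric(1))
}
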