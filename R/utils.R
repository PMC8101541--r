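#' Round half away from zero
#'
#' Rounds to the nearest integer with ties going away from zero (so 92.5
#' becomes 93 and -92.5 becomes -93), the convention used for public
#' person-count summaries. Base `round()` rounds half to even, which would
#' turn 92.5 into 92.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @export
#' @examples
#' round_half_away(c(92.5, 1060.5, -0.5))
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() with a classed condition so callers can distinguish validation,
# alignment, config and state errors programmatically
abort_sc <- function(message, class) {
  stop(structure(
    class = c(class, "sharkcast_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

is_consecutive <- function(years) {
  length(years) >= 1L && all(diff(years) == 1L)
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_sc(sprintf("`%s` must be a single finite number", name), "sharkcast_config_error")
  }
}
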