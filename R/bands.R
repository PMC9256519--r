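#' Canonical MEG/EEG frequency bands
#'
#' The five bands used throughout the pipeline: delta (0.5-4 Hz), theta
#' (4-8 Hz), alpha (8-13 Hz), beta (13-30 Hz) and gamma (30-48 Hz).
#'
#' @return data.frame with columns `name`, `low_hz`, `high_hz`
#' @export
#' @examples
#' canonical_bands()
canonical_bands <- function() {
  data.frame(
    name    = c("delta", "theta", "alpha", "beta", "gamma"),
    low_hz  = c(0.5, 4, 8, 13, 30),
    high_hz = c(4, 8, 13, 30, 48),
    stringsAsFactors = FALSE
  )
}

#' Construct a band definition
#'
#' @param name band name
#' @param low_hz,high_hz band edges in Hz, `0 < low_hz < high_hz`
#' @return list of class `band_definition`
#' @export
band_definition <- function(name, low_hz, high_hz) {
  if (!is.numeric(low_hz) || !is.numeric(high_hz) ||
      low_hz <= 0 || high_hz <= low_hz)
    abort_invalid("band edges must satisfy 0 < low_hz < high_hz")
  structure(list(name = as.character(name), low_hz = low_hz,
                 high_hz = high_hz), class = "band_definition")
}

#' Look up one canonical band by name
#'
#' @param name one of delta, theta, alpha, beta, gamma
#' @return a `band_definition`
#' @export
get_band <- function(name) {
  b <- canonical_bands()
  i <- match(name, b$name)
  if (is.na(i)) abort_invalid(sprintf("unknown band '%s'", name))
  band_definition(b$name[i], b$low_hz[i], b$high_hz[i])
}

#' Band centre frequencies (midpoints), used as oscillator natural frequencies
#'
#' @param bands data.frame as returned by [canonical_bands()]
#' @return named numeric vector of centres in Hz
#' @export
band_centers <- function(bands = canonical_bands()) {
  stats::setNames((bands$low_hz + bands$high_hz) / 2, bands$name)
}
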