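#' Frequency band schemes
#'
#' Two fixed band schemes drive the pipeline: an 8-band scheme for spectral
#' features (with three beta sub-bands alongside broadband beta) whose edges
#' align to the 0.5 Hz Welch grid, and a 5-band contiguous scheme for
#' band-limited connectivity. Both cover 1.0-42.0 Hz.
#'
#' @param bands data frame with columns `band`, `low`, `high` (Hz).
#' @param total_range length-2 numeric, overall (low, high) in Hz.
#' @return A `band_scheme`: tibble of bands with attribute `total_range`.
#' @export
band_scheme <- function(bands, total_range) {
  bands <- tibble::as_tibble(bands)
  stopifnot(all(c("band", "low", "high") %in% names(bands)),
            all(bands$low < bands$high))
  structure(bands, total_range = as.numeric(total_range),
            class = c("band_scheme", class(bands)))
}

#' @rdname band_scheme
#' @details `spectral_bands()` returns delta (1.0-3.5), theta (4.0-7.5),
#'   alpha (8.0-12.5), low beta (13.0-15.5), middle beta (16.0-20.5), high beta
#'   (21.0-29.5), beta (13.0-29.5) and gamma (30.0-42.0) Hz. The five primary
#'   bands (delta, theta, alpha, beta, gamma) tile the 0.5 Hz grid of
#'   1.0-42.0 Hz under inclusive band edges.
#' @export
spectral_bands <- function() {
  band_scheme(data.frame(
    band = c("delta", "theta", "alpha", "beta_low", "beta_mid", "beta_high",
             "beta", "gamma"),
    low  = c(1.0, 4.0,  8.0, 13.0, 16.0, 21.0, 13.0, 30.0),
    high = c(3.5, 7.5, 12.5, 15.5, 20.5, 29.5, 29.5, 42.0)),
    total_range = c(1.0, 42.0))
}

#' @rdname band_scheme
#' @details `connectivity_bands()` returns the five contiguous bands delta
#'   (1-4), theta (4-8), alpha (8-13), beta (13-30), gamma (30-42) Hz.
#' @export
connectivity_bands <- function() {
  band_scheme(data.frame(
    band = c("delta", "theta", "alpha", "beta", "gamma"),
    low  = c(1, 4,  8, 13, 30),
    high = c(4, 8, 13, 30, 42)),
    total_range = c(1.0, 42.0))
}

#' The five primary band names used for sum-to-one relative power
#' @export
primary_bands <- function() c("delta", "theta", "alpha", "beta", "gamma")
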