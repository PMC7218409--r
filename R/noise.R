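#' Apply EMCCD camera noise to an expected-photon image
#'
#' Draws a noisy integer image from a noise-free expected image under a
#' scaled-Poisson approximation of the EM gain register: each pixel is drawn
#' as `g * Poisson(mean / g)` with `g = em_gain_factor^2`, which has the
#' requested mean and shot-noise variance `em_gain_factor^2 * mean`, plus
#' additive Gaussian read noise of SD `read_noise_sd`. Values are rounded and
#' clipped at zero. With `em_gain_factor = 1` this is exact Poisson shot
#' noise.
#'
#' @param expected Numeric matrix of expected photons (all values >= 0).
#' @param cfg An [acquisition_config()] or [frap_config()] supplying
#'   `read_noise_sd` and `em_gain_factor`.
#' @param seed Optional seed; when `NULL` the current RNG stream is used
#'   (the simulators seed the stream once per experiment).
#' @return Integer matrix of the same shape.
#' @export
apply_noise <- function(expected, cfg, seed = NULL) {
  if (any(expected < 0)) stop("expected image must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  g <- cfg$em_gain_factor^2
  n <- length(expected)
  x <- g * stats::rpois(n, as.vector(expected) / g)
  if (cfg$read_noise_sd > 0) x <- x + stats::rnorm(n, 0, cfg$read_noise_sd)
  out <- matrix(pmax(0, round(x)), nrow(expected), ncol(expected))
  storage.mode(out) <- "integer"
  out
}
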