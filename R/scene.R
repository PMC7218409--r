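#' Describe a synthetic cell scene
#'
#' A `cell_scene` holds the noise-free geometry and photon budget of one
#' simulated yeast cell: an elliptical cell outline on a dark extracellular
#' field, a set of diffraction-limited endocytic patches (sub-pixel centres,
#' rendered as pixel-integrated 2-D Gaussians), a uniform cytoplasmic level,
#' and the PSF width. Coordinates are 0-based `(x, y)` with pixel centres at
#' integer positions; the default pixel size downstream is 178 nm, so the
#' default PSF sigma of 1.1 px corresponds to roughly a 250 nm FWHM spot
#' (real patches are 50-80 nm, i.e. diffraction limited).
#'
#' @param shape Image size as `c(n_rows, n_cols)` in pixels.
#' @param n_patches Number of endocytic patches to place. Ignored when
#'   `patch_centers` is given. Default draws 5-15 patches, allowing apparent
#'   clustering of overlapping spots.
#' @param patch_centers Optional 2-column matrix of `(x, y)` patch centres
#'   (0-based, may be sub-pixel). All centres must lie inside the cell.
#' @param patch_amplitude_donor,patch_amplitude_acceptor Expected photons per
#'   patch per frame (integrated over the spot), before any quenching.
#' @param cytoplasm_level Expected photons per pixel inside the cell.
#' @param background_level Expected photons per pixel of the general
#'   background (added everywhere).
#' @param psf_sigma_px Gaussian PSF sigma in pixels (> 0).
#' @param cell_center,cell_radii Ellipse centre `(cx, cy)` and radii
#'   `(rx, ry)` in pixels; defaults fill most of the frame.
#' @param min_patch_sep_px Minimum separation between randomly placed patch
#'   centres (0 allows overlap).
#' @param patch_E Optional per-patch ground-truth FRET efficiencies
#'   (fractions in `[0, 1)`, one per patch) overriding the acquisition-level
#'   `E_true` for the patch signal; used for stage-resolved simulations
#'   where different endocytic sites carry different transfer efficiencies.
#' @param seed Optional seed for random patch placement.
#'
#' @return An object of class `cell_scene`.
#' @export
cell_scene <- function(shape = c(48L, 48L),
                       n_patches = NULL,
                       patch_centers = NULL,
                       patch_amplitude_donor = 4000,
                       patch_amplitude_acceptor = 4000,
                       cytoplasm_level = 300,
                       background_level = 20,
                       psf_sigma_px = 1.1,
                       cell_center = NULL,
                       cell_radii = NULL,
                       min_patch_sep_px = 0,
                       patch_E = NULL,
                       seed = NULL) {
  stopifnot(length(shape) == 2, all(shape >= 8))
  if (psf_sigma_px <= 0) stop("psf_sigma_px must be > 0")
  lv <- c(patch_amplitude_donor, patch_amplitude_acceptor,
          cytoplasm_level, background_level)
  if (any(lv < 0)) stop("all expected-photon levels must be >= 0")

  if (is.null(cell_center)) cell_center <- (rev(shape) - 1) / 2 # (cx, cy)
  if (is.null(cell_radii)) cell_radii <- (rev(shape) - 1) / 2 - 3

  if (is.null(patch_centers)) {
    if (!is.null(seed)) {
      patch_centers <- withr_seed(seed, function() {
        place_patches(cell_center, cell_radii,
                      n_patches %||% sample(5:15, 1), min_patch_sep_px)
      })
    } else {
      patch_centers <- place_patches(cell_center, cell_radii,
                                     n_patches %||% sample(5:15, 1),
                                     min_patch_sep_px)
    }
  } else {
    patch_centers <- as.matrix(patch_centers)
    stopifnot(ncol(patch_centers) == 2)
  }
  colnames(patch_centers) <- c("x", "y")

  if (!is.null(patch_E)) {
    if (length(patch_E) != nrow(patch_centers))
      stop("patch_E needs one value per patch")
    if (any(patch_E < 0 | patch_E >= 1)) stop("patch_E values must be in [0, 1)")
  }

  scene <- structure(
    list(shape = as.integer(shape),
         cell_center = as.numeric(cell_center),
         cell_radii = as.numeric(cell_radii),
         patch_centers = patch_centers,
         patch_amplitude_donor = patch_amplitude_donor,
         patch_amplitude_acceptor = patch_amplitude_acceptor,
         cytoplasm_level = cytoplasm_level,
         background_level = background_level,
         psf_sigma_px = psf_sigma_px,
         patch_E = patch_E),
    class = "cell_scene")

  inside <- point_in_ellipse(patch_centers[, 1], patch_centers[, 2],
                             cell_center, cell_radii)
  if (!all(inside)) stop("patch centers must lie inside the cell mask")
  scene
}

# Patches sit on the plasma membrane, so random placement samples an annulus
# near the cell edge (radial fraction 0.55-0.92 of the ellipse).
place_patches <- function(center, radii, n, min_sep) {
  out <- matrix(NA_real_, 0, 2)
  tries <- 0L
  while (nrow(out) < n && tries < 2000L) {
    tries <- tries + 1L
    th <- stats::runif(1, 0, 2 * pi)
    fr <- stats::runif(1, 0.55, 0.92)
    p <- c(center[1] + fr * radii[1] * cos(th),
           center[2] + fr * radii[2] * sin(th))
    if (min_sep > 0 && nrow(out) > 0) {
      d <- sqrt((out[, 1] - p[1])^2 + (out[, 2] - p[2])^2)
      if (any(d < min_sep)) next
    }
    out <- rbind(out, p)
  }
  if (nrow(out) < n) stop("could not place patches with requested separation")
  unname(out)
}

point_in_ellipse <- function(x, y, center, radii) {
  ((x - center[1]) / radii[1])^2 + ((y - center[2]) / radii[2])^2 <= 1
}

`%||%` <- function(a, b) if (is.null(a)) b else a

withr_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Acceptor-photobleaching acquisition settings
#'
#' Frame counts and physical parameters of one acceptor-photobleaching
#' acquisition: two acceptor frames and three to five donor frames are taken
#' before the bleach pulse, and the same numbers after it, mirroring the
#' wide-field protocol the pipeline is designed for.
#'
#' The ground-truth transfer efficiency `E_true` is defined on the donor
#' de-quenching scale: `E_true = 1 - D_pre / D_post` at complete acceptor
#' bleach, i.e. the fraction of donor emission quenched while the acceptor is
#' intact. `beta_bleach` is the fraction of acceptor destroyed by the pulse
#' and `delta_struct` the fractional donor loss per donor acquisition
#' (structural photobleaching), which makes donor-only cells read slightly
#' negative.
#'
#' @param n_pre_donor,n_post_donor Donor frame counts (3-5 typical).
#' @param n_pre_acceptor,n_post_acceptor Acceptor frame counts (2 typical).
#' @param frame_exposure_s Exposure per acquisition, seconds (0.5-1 typical).
#' @param bleach_pulse_s Duration of the bleach pulse, seconds.
#' @param E_true Ground-truth FRET efficiency, fraction in `[0, 1)`.
#' @param beta_bleach Fraction of acceptor destroyed by the pulse, `[0, 1]`.
#' @param delta_struct Fractional donor loss per donor acquisition, `[0, 1)`.
#' @param read_noise_sd Additive camera read noise (counts).
#' @param em_gain_factor Multiplicative excess-noise factor of the EM
#'   register; the default `sqrt(2)` is the asymptotic EMCCD excess-noise
#'   factor. Per-pixel variance is `em_gain_factor^2 * mean + read_noise_sd^2`.
#' @param rng_seed Integer seed used by the simulators.
#'
#' @return An object of class `acquisition_config`.
#' @export
acquisition_config <- function(n_pre_donor = 3L, n_post_donor = 3L,
                               n_pre_acceptor = 2L, n_post_acceptor = 2L,
                               frame_exposure_s = 0.5,
                               bleach_pulse_s = 4,
                               E_true = 0.10,
                               beta_bleach = 1,
                               delta_struct = 0.002,
                               read_noise_sd = 10,
                               em_gain_factor = sqrt(2),
                               rng_seed = 1L) {
  if (E_true < 0 || E_true >= 1) stop("E_true must be in [0, 1)")
  if (beta_bleach < 0 || beta_bleach > 1) stop("beta_bleach must be in [0, 1]")
  if (delta_struct < 0 || delta_struct >= 1) stop("delta_struct must be in [0, 1)")
  if (min(n_pre_donor, n_post_donor, n_pre_acceptor, n_post_acceptor) < 1)
    stop("all frame counts must be >= 1")
  if (read_noise_sd < 0 || em_gain_factor <= 0)
    stop("invalid noise parameters")
  structure(
    list(n_pre_donor = as.integer(n_pre_donor),
         n_post_donor = as.integer(n_post_donor),
         n_pre_acceptor = as.integer(n_pre_acceptor),
         n_post_acceptor = as.integer(n_post_acceptor),
         frame_exposure_s = frame_exposure_s,
         bleach_pulse_s = bleach_pulse_s,
         E_true = E_true,
         beta_bleach = beta_bleach,
         delta_struct = delta_struct,
         read_noise_sd = read_noise_sd,
         em_gain_factor = em_gain_factor,
         rng_seed = as.integer(rng_seed)),
    class = "acquisition_config")
}

#' FRAP acquisition settings
#'
#' Settings for a single-spot FRAP series: a few pre-bleach frames, a brief
#' bleach pulse on one endocytic patch, then recovery followed at a fixed
#' frame interval (0.5 s for 40-60 s typical). The expected bleached-spot
#' signal follows `F(t) = F_post0 + M * (F_pre - F_post0) * (1 - exp(-t/tau))`
#' with mobile fraction `M`; unbleached regions decay only by acquisition
#' photobleaching.
#'
#' @param n_pre_frames Pre-bleach frames (>= 3 recommended for normalisation).
#' @param bleach_depth Fraction of spot fluorescence destroyed by the pulse,
#'   in `(0, 1]`.
#' @param mobile_fraction Mobile fraction `M` in `[0, 1]`.
#' @param tau_s Exchange time constant, seconds (> 0).
#' @param frame_interval_s Time between frames, seconds.
#' @param duration_s Post-bleach follow-up time, seconds.
#' @param delta_struct Fractional fluorescence loss per acquisition.
#' @param read_noise_sd,em_gain_factor Camera noise model, as in
#'   [acquisition_config()].
#' @param rng_seed Integer seed.
#'
#' @return An object of class `frap_config`.
#' @export
frap_config <- function(n_pre_frames = 5L,
                        bleach_depth = 0.8,
                        mobile_fraction = 0.7,
                        tau_s = 5,
                        frame_interval_s = 0.5,
                        duration_s = 60,
                        delta_struct = 0.002,
                        read_noise_sd = 10,
                        em_gain_factor = sqrt(2),
                        rng_seed = 1L) {
  if (bleach_depth <= 0 || bleach_depth > 1) stop("bleach_depth must be in (0, 1]")
  if (mobile_fraction < 0 || mobile_fraction > 1) stop("mobile_fraction must be in [0, 1]")
  if (tau_s <= 0) stop("tau_s must be > 0")
  if (n_pre_frames < 1) stop("need at least one pre-bleach frame")
  structure(
    list(n_pre_frames = as.integer(n_pre_frames),
         bleach_depth = bleach_depth,
         mobile_fraction = mobile_fraction,
         tau_s = tau_s,
         frame_interval_s = frame_interval_s,
         duration_s = duration_s,
         delta_struct = delta_struct,
         read_noise_sd = read_noise_sd,
         em_gain_factor = em_gain_factor,
         rng_seed = as.integer(rng_seed)),
    class = "frap_config")
}
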