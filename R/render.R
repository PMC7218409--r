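# Noise-free forward model: scene -> expected-photon images.
#
# Patches are pixel-integrated symmetric Gaussians so that the sum of a fully
# contained spot equals its amplitude exactly; the cell interior adds a
# uniform cytoplasmic level and the general background is added everywhere.

# Pixel-integrated Gaussian spot, unit integral over the infinite plane.
# 0-based coordinates, pixel centres at integers.
gauss_spot <- function(shape, cx, cy, sigma) {
  xs <- seq_len(shape[2]) - 1
  ys <- seq_len(shape[1]) - 1
  fx <- stats::pnorm((xs + 0.5 - cx) / sigma) - stats::pnorm((xs - 0.5 - cx) / sigma)
  fy <- stats::pnorm((ys + 0.5 - cy) / sigma) - stats::pnorm((ys - 0.5 - cy) / sigma)
  outer(fy, fx)
}

#' Cell mask of a scene
#'
#' Boolean mask of pixels whose centres satisfy the inclusive ellipse
#' equation of the scene's cell outline.
#'
#' @param scene A [cell_scene()].
#' @return Logical matrix of the scene's shape.
#' @export
cell_mask <- function(scene) {
  stopifnot(inherits(scene, "cell_scene"))
  xs <- seq_len(scene$shape[2]) - 1
  ys <- seq_len(scene$shape[1]) - 1
  outer(ys, xs, function(y, x) point_in_ellipse(x, y, scene$cell_center, scene$cell_radii))
}

# Static per-channel components; frames differ only by scalar factors.
# When the scene carries per-patch efficiencies the individual unit spots
# are kept so each patch can be quenched independently.
scene_components <- function(scene) {
  m <- cell_mask(scene)
  spots <- lapply(seq_len(nrow(scene$patch_centers)), function(i)
    gauss_spot(scene$shape, scene$patch_centers[i, 1],
               scene$patch_centers[i, 2], scene$psf_sigma_px))
  spot_sum <- if (length(spots)) Reduce(`+`, spots) else
    matrix(0, scene$shape[1], scene$shape[2])
  list(mask = m, spots_unit = spot_sum,
       spots = if (!is.null(scene$patch_E)) spots else NULL)
}

# Scalar factors of the forward model.
donor_quench_factor <- function(cfg, phase) {
  if (phase == "pre") 1 - cfg$E_true
  else 1 - cfg$E_true * (1 - cfg$beta_bleach)
}

donor_struct_factor <- function(cfg, phase, frame_index) {
  k <- if (phase == "pre") frame_index - 1 else cfg$n_pre_donor + frame_index - 1
  (1 - cfg$delta_struct)^k
}

acceptor_bleach_factor <- function(cfg, phase) {
  if (phase == "pre") 1 else 1 - cfg$beta_bleach
}

#' Render a noise-free expected-photon image
#'
#' Evaluates the acceptor-photobleaching forward model for one frame. Donor
#' patch and cytoplasm signal is quenched by `1 - E_true` before the bleach
#' and by `1 - E_true * (1 - beta_bleach)` after it, and decays by
#' `(1 - delta_struct)^k` after `k` earlier donor acquisitions; acceptor
#' signal is scaled by `1 - beta_bleach` after the bleach. The extracellular
#' background is unaffected.
#'
#' @param scene A [cell_scene()].
#' @param channel `"donor"` or `"acceptor"`.
#' @param phase `"pre"` or `"post"` (relative to the bleach pulse).
#' @param cfg An [acquisition_config()].
#' @param frame_index 1-based frame index within the phase.
#' @param components Optional precomputed [scene_components] (internal reuse).
#' @return Numeric matrix of expected photons per pixel.
#' @export
render_expected_image <- function(scene, channel = c("donor", "acceptor"),
                                  phase = c("pre", "post"), cfg,
                                  frame_index = 1L, components = NULL) {
  channel <- match.arg(channel)
  phase <- match.arg(phase)
  stopifnot(inherits(scene, "cell_scene"), inherits(cfg, "acquisition_config"))
  n_in_phase <- switch(paste(channel, phase),
                       "donor pre" = cfg$n_pre_donor,
                       "donor post" = cfg$n_post_donor,
                       "acceptor pre" = cfg$n_pre_acceptor,
                       "acceptor post" = cfg$n_post_acceptor)
  if (frame_index < 1 || frame_index > n_in_phase)
    stop("frame_index out of range for this channel/phase")
  cmp <- components %||% scene_components(scene)
  if (channel == "donor") {
    struct <- donor_struct_factor(cfg, phase, frame_index)
    f_cyto <- donor_quench_factor(cfg, phase) * struct
    amp <- scene$patch_amplitude_donor
    if (is.null(scene$patch_E)) {
      patch_img <- amp * f_cyto * cmp$spots_unit
    } else {
      qi <- if (phase == "pre") 1 - scene$patch_E
            else 1 - scene$patch_E * (1 - cfg$beta_bleach)
      patch_img <- Reduce(`+`, Map(function(s, q) amp * q * struct * s,
                                   cmp$spots, as.list(qi)))
    }
  } else {
    f_cyto <- acceptor_bleach_factor(cfg, phase)
    patch_img <- scene$patch_amplitude_acceptor * f_cyto * cmp$spots_unit
  }
  scene$background_level +
    cmp$mask * (scene$cytoplasm_level * f_cyto) +
    patch_img
}
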