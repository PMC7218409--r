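#' Simulate an acceptor-photobleaching FRET experiment
#'
#' Generates a donor and an acceptor [image_series()] following the
#' wide-field protocol: two acceptor frames and `n_pre_donor` donor frames
#' before the bleach pulse, then `n_post_donor` donor and two acceptor frames
#' after it. Noise frames are drawn in acquisition order from a single RNG
#' stream seeded with `cfg$rng_seed`, so identical inputs give bit-identical
#' stacks. A ground-truth manifest records everything needed to recompute the
#' expected noise-free images exactly.
#'
#' @param scene A [cell_scene()].
#' @param cfg An [acquisition_config()].
#' @return A list with elements `donor`, `acceptor` (both [image_series()])
#'   and `manifest` (class `ground_truth_manifest`).
#' @export
simulate_apb_experiment <- function(scene, cfg) {
  stopifnot(inherits(scene, "cell_scene"), inherits(cfg, "acquisition_config"))
  cmp <- scene_components(scene)
  set.seed(cfg$rng_seed)

  t_now <- 0
  take <- function(channel, phase, idx) {
    exp_img <- render_expected_image(scene, channel, phase, cfg, idx, components = cmp)
    t_now <<- t_now + cfg$frame_exposure_s
    list(frame = apply_noise(exp_img, cfg), time = t_now)
  }

  acc_pre <- lapply(seq_len(cfg$n_pre_acceptor), function(i) take("acceptor", "pre", i))
  don_pre <- lapply(seq_len(cfg$n_pre_donor), function(i) take("donor", "pre", i))
  t_now <- t_now + cfg$bleach_pulse_s
  don_post <- lapply(seq_len(cfg$n_post_donor), function(i) take("donor", "post", i))
  acc_post <- lapply(seq_len(cfg$n_post_acceptor), function(i) take("acceptor", "post", i))

  donor <- image_series(
    frames = c(lapply(don_pre, `[[`, "frame"), lapply(don_post, `[[`, "frame")),
    channel = "donor",
    phase = c(rep("pre", cfg$n_pre_donor), rep("post", cfg$n_post_donor)),
    time_s = c(vapply(don_pre, `[[`, numeric(1), "time"),
               vapply(don_post, `[[`, numeric(1), "time")))
  acceptor <- image_series(
    frames = c(lapply(acc_pre, `[[`, "frame"), lapply(acc_post, `[[`, "frame")),
    channel = "acceptor",
    phase = c(rep("pre", cfg$n_pre_acceptor), rep("post", cfg$n_post_acceptor)),
    time_s = c(vapply(acc_pre, `[[`, numeric(1), "time"),
               vapply(acc_post, `[[`, numeric(1), "time")))

  manifest <- structure(
    list(kind = "acceptor_photobleaching",
         E_true = cfg$E_true,
         beta_bleach = cfg$beta_bleach,
         delta_struct = cfg$delta_struct,
         patch_centers = scene$patch_centers,
         patch_E = scene$patch_E,
         cytoplasm_level = scene$cytoplasm_level,
         background_level = scene$background_level,
         patch_amplitude_donor = scene$patch_amplitude_donor,
         patch_amplitude_acceptor = scene$patch_amplitude_acceptor,
         psf_sigma_px = scene$psf_sigma_px,
         cell_center = scene$cell_center,
         cell_radii = scene$cell_radii,
         shape = scene$shape,
         frame_exposure_s = cfg$frame_exposure_s,
         n_frames = c(donor_pre = cfg$n_pre_donor, donor_post = cfg$n_post_donor,
                      acceptor_pre = cfg$n_pre_acceptor, acceptor_post = cfg$n_post_acceptor),
         seed = cfg$rng_seed),
    class = "ground_truth_manifest")

  list(donor = donor, acceptor = acceptor, manifest = manifest)
}

#' Simulate a stage-marker channel image
#'
#' Renders a third-channel (e.g. Abp1) image in which only a subset of the
#' scene's patches carry the marker, over the cell's cytoplasmic marker
#' level, with the usual camera noise. Used for stage-resolved per-patch
#' analyses where marker presence labels the endocytic stage.
#'
#' @param scene A [cell_scene()].
#' @param marker_positive Logical vector, one per patch.
#' @param marker_amplitude Expected photons per marker-positive patch.
#' @param marker_cyto_level Expected cytoplasmic marker photons per pixel.
#' @param cfg Config supplying the noise model and `rng_seed`.
#' @return Noisy integer matrix.
#' @export
simulate_marker_image <- function(scene, marker_positive,
                                  marker_amplitude = 2000,
                                  marker_cyto_level = 100,
                                  cfg = acquisition_config()) {
  stopifnot(length(marker_positive) == nrow(scene$patch_centers))
  m <- cell_mask(scene)
  img <- scene$background_level + m * marker_cyto_level
  for (i in which(marker_positive)) {
    img <- img + marker_amplitude *
      gauss_spot(scene$shape, scene$patch_centers[i, 1],
                 scene$patch_centers[i, 2], scene$psf_sigma_px)
  }
  apply_noise(img, cfg)
}

# Expected bleached-spot amplitude over time (noise-free recovery model).
frap_expected_amplitude <- function(A_pre, fcfg, t_since_bleach) {
  A0 <- A_pre * (1 - fcfg$bleach_depth)
  A0 + fcfg$mobile_fraction * (A_pre - A0) * (1 - exp(-t_since_bleach / fcfg$tau_s))
}

#' Simulate a FRAP experiment on a single endocytic patch
#'
#' The first patch of the scene is the bleached spot; its expected amplitude
#' follows the single-exponential recovery model
#' `F(t) = F_post0 + M * (F_pre - F_post0) * (1 - exp(-t/tau))`. All in-cell
#' signal (spot, other patches, cytoplasm) additionally decays by
#' `(1 - delta_struct)` per acquisition, so unbleached reference regions
#' decay only by acquisition photobleaching.
#'
#' @param scene A [cell_scene()] with at least one patch.
#' @param fcfg A [frap_config()].
#' @return A list with elements `series` ([image_series()]), `expected_trace`
#'   (tibble of noise-free spot amplitudes), and `manifest`.
#' @export
simulate_frap_experiment <- function(scene, fcfg) {
  stopifnot(inherits(scene, "cell_scene"), inherits(fcfg, "frap_config"))
  if (nrow(scene$patch_centers) < 1) stop("scene needs at least one patch (the FRAP spot)")
  n_post <- as.integer(round(fcfg$duration_s / fcfg$frame_interval_s))
  if (n_post < 1) stop("duration too short for the frame interval")

  m <- cell_mask(scene)
  spot_unit <- gauss_spot(scene$shape, scene$patch_centers[1, 1],
                          scene$patch_centers[1, 2], scene$psf_sigma_px)
  others_unit <- matrix(0, scene$shape[1], scene$shape[2])
  if (nrow(scene$patch_centers) > 1) {
    for (i in 2:nrow(scene$patch_centers)) {
      others_unit <- others_unit + gauss_spot(scene$shape,
                                              scene$patch_centers[i, 1],
                                              scene$patch_centers[i, 2],
                                              scene$psf_sigma_px)
    }
  }

  n_pre <- fcfg$n_pre_frames
  n_tot <- n_pre + n_post
  phase <- c(rep("pre", n_pre), rep("post", n_post))
  time_s <- (seq_len(n_tot) - 1) * fcfg$frame_interval_s
  t_bleach <- time_s[n_pre + 1] # bleach happens just before the first post frame
  A_pre <- scene$patch_amplitude_donor

  amp <- ifelse(phase == "pre", A_pre,
                frap_expected_amplitude(A_pre, fcfg, time_s - t_bleach))
  struct <- (1 - fcfg$delta_struct)^(seq_len(n_tot) - 1)

  set.seed(fcfg$rng_seed)
  frames <- vector("list", n_tot)
  for (i in seq_len(n_tot)) {
    exp_img <- scene$background_level +
      m * scene$cytoplasm_level * struct[i] +
      (amp[i] * spot_unit + A_pre * others_unit) * struct[i]
    frames[[i]] <- apply_noise(exp_img, fcfg)
  }

  series <- image_series(frames, channel = "frap", phase = phase, time_s = time_s)

  expected_trace <- tibble::tibble(
    time_s = series$time_s, phase = phase,
    spot_amplitude = amp * struct,
    reference_level = scene$cytoplasm_level * struct)

  manifest <- structure(
    list(kind = "frap",
         mobile_fraction = fcfg$mobile_fraction,
         tau_s = fcfg$tau_s,
         bleach_depth = fcfg$bleach_depth,
         bleach_frame_index = n_pre + 1L,
         delta_struct = fcfg$delta_struct,
         spot_center = scene$patch_centers[1, ],
         cytoplasm_level = scene$cytoplasm_level,
         background_level = scene$background_level,
         spot_amplitude_pre = A_pre,
         frame_interval_s = fcfg$frame_interval_s,
         seed = fcfg$rng_seed),
    class = "ground_truth_manifest")

  list(series = series, expected_trace = expected_trace, manifest = manifest)
}
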