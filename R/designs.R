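# Ready-made simulated study designs: single cells, screen batches,
# stage-sorting fields and FRAP cells, all run through the full measurement
# pipeline. These are the configurations used to validate the estimators,
# so tests, scripts and vignettes share one definition of the conditions.

default_cell_rois <- function(scene) {
  prois <- lapply(seq_len(nrow(scene$patch_centers)), function(i)
    roi_oval(scene$patch_centers[i, 1], scene$patch_centers[i, 2], 2,
             role = "patches"))
  roi_set(c(prois, list(
    roi_oval(scene$cell_center[1], scene$cell_center[2], 6, role = "cytoplasm"),
    roi_oval(2, 2, 2, role = "reference"))))
}

#' Simulate and quantify one acceptor-photobleaching cell
#'
#' Generates one synthetic cell (8 membrane patches by default), runs the
#' full quantification pipeline (background subtraction from an
#' extracellular region, phase averaging, cytoplasm-level threshold, pooled
#' per-pixel efficiency over oval patch ROIs at the true centres, acceptor
#' bleach QC) and returns the measurement row.
#'
#' @param E_true Ground-truth FRET efficiency (fraction).
#' @param seed Seed controlling both patch placement and noise.
#' @param convention Estimator convention.
#' @param n_patches Patches per cell.
#' @param entity_id,batch_id Identifiers for the output row.
#' @param ... Further arguments to [acquisition_config()].
#' @return One-row measurement tibble (see [quantify_apb()]).
#' @export
simulate_apb_cell <- function(E_true, seed, convention = "dequench_over_post",
                              n_patches = 8, entity_id = paste0("cell", seed),
                              batch_id = "batch1", ...) {
  scene <- cell_scene(n_patches = n_patches, seed = seed)
  cfg <- acquisition_config(E_true = E_true, rng_seed = (seed + 7919L) %% .Machine$integer.max, ...)
  sim <- simulate_apb_experiment(scene, cfg)
  quantify_apb(sim$donor, sim$acceptor, default_cell_rois(scene),
               convention = convention, entity_id = entity_id,
               batch_id = batch_id)
}

#' Simulate a batch of cells for one protein pair
#'
#' @param n_cells Number of cells.
#' @param E_true Ground-truth FRET efficiency (fraction).
#' @param seed Batch seed (cell seeds derive from it).
#' @param batch_id Batch identifier.
#' @param ... Further arguments to [simulate_apb_cell()].
#' @return Measurement tibble, one row per cell.
#' @export
simulate_pair_batch <- function(n_cells, E_true, seed, batch_id = "batch1", ...) {
  seeds <- seed * 100000L + seq_len(n_cells)
  dplyr::bind_rows(lapply(seeds, function(s)
    simulate_apb_cell(E_true, s, batch_id = batch_id, ...)))
}

#' Simulate a stage-sorting field of cells
#'
#' Cells carry both marker-negative and marker-positive patches with
#' distinct per-patch ground-truth efficiencies; the marker channel is
#' simulated and the per-patch pipeline ([stage_resolved_fret()]) is run on
#' the true patch centres.
#'
#' @param n_cells Number of cells.
#' @param patches_per_cell Patches per cell (half marker-positive).
#' @param E_absent,E_present Per-patch efficiencies (fractions) of
#'   marker-absent and marker-present patches.
#' @param seed Field seed.
#' @return A `stage_fret`-shaped list pooled over cells: `patches`,
#'   `group_summaries`, `test`.
#' @export
simulate_stage_field <- function(n_cells = 14, patches_per_cell = 10,
                                 E_absent = 0, E_present = 0.06, seed = 1L) {
  rows <- lapply(seq_len(n_cells), function(ci) {
    s <- seed * 100000L + ci
    n_pos <- patches_per_cell %/% 2
    pe <- c(rep(E_absent, patches_per_cell - n_pos), rep(E_present, n_pos))
    marker <- c(rep(FALSE, patches_per_cell - n_pos), rep(TRUE, n_pos))
    scene <- cell_scene(n_patches = patches_per_cell, min_patch_sep_px = 6,
                        patch_E = pe, seed = s)
    cfg <- acquisition_config(E_true = 0, rng_seed = (s + 7919L) %% .Machine$integer.max)
    sim <- simulate_apb_experiment(scene, cfg)
    mk <- simulate_marker_image(scene, marker, cfg = cfg)
    db <- subtract_background(sim$donor, scene$background_level)
    sf <- stage_resolved_fret(
      tibble::tibble(x = scene$patch_centers[, 1], y = scene$patch_centers[, 2]),
      average_phase_frames(db, "pre"), average_phase_frames(db, "post"),
      pmax(mk - scene$background_level, 0),
      roi_oval(scene$cell_center[1], scene$cell_center[2], 6, role = "cytoplasm"),
      cell_id = paste0("cell", ci))
    sf$patches
  })
  patches <- dplyr::bind_rows(rows)
  valid <- patches[patches$valid, ]
  groups <- split(valid$E_raw_pct, valid$marker_present)
  summaries <- dplyr::bind_rows(lapply(names(groups), function(g) {
    v <- groups[[g]]
    if (length(v) >= 5)
      dplyr::mutate(boxplot_summary(v), marker_present = as.logical(g), .before = 1)
    else tibble::tibble(marker_present = as.logical(g), n = length(v))
  }))
  test <- if (length(groups) == 2 && all(lengths(groups) >= 2))
    welch_t_test(groups[["FALSE"]], groups[["TRUE"]]) else NULL
  structure(list(patches = patches, group_summaries = summaries, test = test),
            class = "stage_fret")
}

#' Simulate one FRAP cell and fit its recovery
#'
#' Full round trip: synthetic spot bleach, trace extraction from spot /
#' reference / background regions, double normalisation, and
#' single-exponential fit.
#'
#' @param mobile_fraction,tau_s Ground truth.
#' @param seed Seed.
#' @param duration_s Post-bleach follow-up (default 60 s).
#' @param ... Further arguments to [frap_config()].
#' @return One-row tibble: truth, fitted parameters and fit diagnostics.
#' @export
simulate_frap_cell <- function(mobile_fraction, tau_s, seed, duration_s = 60, ...) {
  scene <- cell_scene(shape = c(32L, 32L), n_patches = 1,
                      patch_centers = matrix(c(16, 9), 1),
                      patch_amplitude_donor = 60000, cytoplasm_level = 100,
                      cell_radii = c(14, 14))
  fcfg <- frap_config(mobile_fraction = mobile_fraction, tau_s = tau_s,
                      duration_s = duration_s,
                      rng_seed = (seed + 104729L) %% .Machine$integer.max, ...)
  sim <- simulate_frap_experiment(scene, fcfg)
  tr <- extract_trace(sim$series,
                      roi_oval(16, 9, 2, role = "frap_spot"),
                      roi_oval(16, 21, 4, role = "reference"),
                      roi_oval(2, 2, 2, role = "reference"))
  fit <- fit_recovery(normalize_trace(tr))
  dplyr::bind_cols(
    tibble::tibble(true_M = mobile_fraction, true_tau_s = tau_s, seed = seed),
    glance(fit))
}
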