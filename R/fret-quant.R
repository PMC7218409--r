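# Acceptor-photobleaching FRET quantification: background subtraction,
# phase averaging, cytoplasm-level thresholding, per-pixel donor
# de-quenching, acceptor bleach QC and donor-only baseline correction.

#' Subtract the general background from every frame
#'
#' Subtracts either a constant or the per-frame median of a background
#' region, then clips at zero. The median makes the estimate robust to the
#' occasional bright outlier pixel in the background region.
#'
#' @param series An [image_series()].
#' @param bg A non-negative constant, a `roi` or a [roi_set()] (regions with
#'   role `"reference"`) marking extracellular background.
#' @param cell_roi Optional `roi`/[roi_set()] of the analysed cell; an error
#'   is raised if the background region overlaps it.
#' @param clip Clip subtracted values at zero (default `TRUE`).
#' @return The background-subtracted [image_series()].
#' @export
subtract_background <- function(series, bg, cell_roi = NULL, clip = TRUE) {
  stopifnot(inherits(series, "image_series"))
  shape <- dim(series$frames[[1]])
  if (is.numeric(bg)) {
    if (bg < 0) stop("constant background must be >= 0")
    sub_fun <- function(f) f - bg
  } else {
    mask <- roi_arg_mask(bg, shape, role = "reference")
    if (!is.null(cell_roi)) {
      cmask <- roi_arg_mask(cell_roi, shape, role = NULL)
      if (any(mask & cmask)) stop("background region overlaps a cell ROI")
    }
    sub_fun <- function(f) f - stats::median(f[mask])
  }
  map_frames(series, function(f) {
    out <- sub_fun(f)
    if (clip) out <- pmax(out, 0)
    out
  })
}

# Accept a roi, roi_set, or logical mask.
roi_arg_mask <- function(roi, shape, role = NULL) {
  if (is.logical(roi) && is.matrix(roi)) return(roi)
  if (inherits(roi, "roi")) return(rasterize_roi(roi, shape))
  if (inherits(roi, "roi_set")) return(rasterize_role(roi, shape, role))
  stop("expected a roi, roi_set or logical mask")
}

#' Pixel-wise mean of the frames of one phase
#'
#' @param series An [image_series()].
#' @param phase Phase tag (`"pre"` or `"post"`).
#' @return Numeric matrix (the averaged image).
#' @export
average_phase_frames <- function(series, phase) {
  fr <- phase_frames(series, phase)
  if (length(fr) == 0) stop("no frames with phase: ", phase)
  Reduce(`+`, lapply(fr, function(f) f / length(fr)))
}

#' Cytoplasm-level intensity threshold
#'
#' Returns the mean donor intensity inside the cytoplasm region of the
#' averaged pre-bleach image; this per-cell value is the intensity threshold
#' that separates endocytic-patch pixels from cytoplasmic fluorescence. If
#' patch regions intersect the cytoplasm region a QC flag is raised (the
#' value is still returned).
#'
#' @param donor_pre Averaged, background-subtracted pre-bleach donor image.
#' @param cyto_roi `roi`/[roi_set()] of a patch-free cytoplasm area.
#' @param patch_rois Optional patch `roi`/[roi_set()] used only for the
#'   overlap QC check.
#' @return A single number with attribute `qc_flags` (character vector,
#'   empty when clean).
#' @export
estimate_cytoplasm_threshold <- function(donor_pre, cyto_roi, patch_rois = NULL) {
  shape <- dim(donor_pre)
  mask <- roi_arg_mask(cyto_roi, shape, role = "cytoplasm")
  if (!any(mask)) stop("empty cytoplasm ROI")
  flags <- character(0)
  if (!is.null(patch_rois)) {
    pmask <- roi_arg_mask(patch_rois, shape, role = "patches")
    if (any(mask & pmask)) flags <- c(flags, "cytoplasm_roi_overlaps_patches")
  }
  out <- mean(donor_pre[mask])
  attr(out, "qc_flags") <- flags
  out
}

#' Per-pixel acceptor-photobleaching FRET efficiency
#'
#' Over the pixels of `roi` whose averaged donor intensity exceeds the
#' threshold in both the pre- and post-bleach images, computes the per-pixel
#' de-quenching `e = 100 * (post - pre) / pre` (convention
#' `"increase_over_pre"`, the percentage increase in donor fluorescence
#' after acceptor photobleaching) or `e = 100 * (post - pre) / post`
#' (`"dequench_over_post"`, the classical transfer efficiency). The raw
#' efficiency is the mean of the per-pixel values and may be negative.
#'
#' @param donor_pre,donor_post Averaged, background-subtracted donor images.
#' @param roi `roi`/[roi_set()]/mask of the measured entity (pooled patches
#'   of a cell, a single patch, or a cytoplasm area).
#' @param threshold Intensity threshold in counts (see
#'   [estimate_cytoplasm_threshold()]).
#' @param convention `"increase_over_pre"` (default) or
#'   `"dequench_over_post"`.
#' @param threshold_on Apply the threshold to both images (default) or to
#'   the pre-bleach image only.
#' @param entity_id Identifier recorded in the output row.
#' @param batch_id Acquisition batch, used to match donor-only baselines.
#' @param min_pixels Minimum qualifying pixels for a valid measurement.
#' @return One-row tibble with both conventions (`e_increase_pct`,
#'   `e_dequench_pct`), the selected `E_raw_pct`, `n_pixels_used`,
#'   `threshold_used`, `valid` and `qc_flags`.
#' @export
compute_fret_efficiency <- function(donor_pre, donor_post, roi, threshold,
                                    convention = c("increase_over_pre",
                                                   "dequench_over_post"),
                                    threshold_on = c("both", "pre"),
                                    entity_id = NA_character_,
                                    batch_id = NA_character_,
                                    min_pixels = 1L) {
  convention <- match.arg(convention)
  threshold_on <- match.arg(threshold_on)
  stopifnot(all(dim(donor_pre) == dim(donor_post)))
  mask <- roi_arg_mask(roi, dim(donor_pre))
  qual <- mask & (donor_pre > threshold)
  if (threshold_on == "both") qual <- qual & (donor_post > threshold)
  n <- sum(qual)
  if (n < min_pixels) {
    return(tibble::tibble(
      entity_id = as.character(entity_id), batch_id = as.character(batch_id),
      convention = convention,
      e_increase_pct = NA_real_, e_dequench_pct = NA_real_,
      E_raw_pct = NA_real_, n_pixels_used = n,
      threshold_used = as.numeric(threshold),
      valid = FALSE, qc_flags = "no_qualifying_pixels"))
  }
  pre <- donor_pre[qual]
  post <- donor_post[qual]
  e_inc <- mean(100 * (post - pre) / pre)
  e_deq <- mean(100 * (post - pre) / post)
  tibble::tibble(
    entity_id = as.character(entity_id), batch_id = as.character(batch_id),
    convention = convention,
    e_increase_pct = e_inc, e_dequench_pct = e_deq,
    E_raw_pct = if (convention == "increase_over_pre") e_inc else e_deq,
    n_pixels_used = n, threshold_used = as.numeric(threshold),
    valid = TRUE, qc_flags = "")
}

#' Convert a FRET value between estimator conventions
#'
#' On noise-free data the two per-pixel conventions are deterministically
#' related: `e_pre = e_post / (1 - e_post/100)` and
#' `e_post = e_pre / (1 + e_pre/100)` (values in percent).
#'
#' @param e FRET value(s) in percent.
#' @param from,to `"increase_over_pre"` or `"dequench_over_post"`.
#' @return Converted value(s) in percent.
#' @export
convert_fret_convention <- function(e, from, to) {
  conv <- c("increase_over_pre", "dequench_over_post")
  from <- match.arg(from, conv)
  to <- match.arg(to, conv)
  if (from == to) return(e)
  if (from == "dequench_over_post") e / (1 - e / 100) else e / (1 + e / 100)
}

#' Measured acceptor bleach fraction
#'
#' QC measurement of how completely the pulse destroyed the acceptor:
#' `beta_hat = 1 - mean(post) / mean(pre)` over the region, clipped to
#' `[0, 1]`. Cells with `beta_hat` below the QC floor are flagged (not
#' dropped): incomplete bleach biases the efficiency estimate low.
#'
#' @param acceptor_pre,acceptor_post Averaged, background-subtracted
#'   acceptor images.
#' @param roi `roi`/[roi_set()]/mask over which to compare.
#' @param qc_floor Flag measurements with `beta_hat` below this (default 0.5).
#' @return One-row tibble with `beta_hat`, `mean_pre`, `mean_post`,
#'   `qc_flags`.
#' @export
measure_acceptor_bleach <- function(acceptor_pre, acceptor_post, roi,
                                    qc_floor = 0.5) {
  mask <- roi_arg_mask(roi, dim(acceptor_pre))
  mp <- mean(acceptor_pre[mask])
  if (mp <= 0) stop("non-positive pre-bleach acceptor mean")
  mq <- mean(acceptor_post[mask])
  beta <- min(1, max(0, 1 - mq / mp))
  tibble::tibble(beta_hat = beta, mean_pre = mp, mean_post = mq,
                 qc_flags = if (beta < qc_floor) "incomplete_bleach" else "")
}

#' Donor-only apparent-FRET baseline
#'
#' Summarises the apparent FRET of donor-only cells measured with the same
#' pipeline settings as the paired experiment batch. Structural donor
#' photobleaching during acquisition makes these baselines slightly
#' negative; they are subtracted from experimental values.
#'
#' @param measurements Measurement tibble of donor-only cells (output of
#'   [compute_fret_efficiency()]/[quantify_apb()]), with valid rows.
#' @param batch_id Baseline batch identifier.
#' @return One-row tibble: `batch_id`, `b_pct`, `n_cells`,
#'   `ci95_halfwidth_pct`.
#' @export
donor_only_baseline <- function(measurements, batch_id = "batch1") {
  vals <- measurements$E_raw_pct[measurements$valid]
  if (length(vals) < 2) stop("need >= 2 valid donor-only cells for a baseline")
  ci <- mean_ci(vals)
  tibble::tibble(batch_id = as.character(batch_id), b_pct = ci$mean,
                 n_cells = length(vals), ci95_halfwidth_pct = ci$ci_halfwidth)
}

#' Subtract the matched donor-only baseline
#'
#' `E_pct = E_raw_pct - b_pct` for every measurement, joining baselines by
#' acquisition batch. Every measurement batch must have a baseline.
#'
#' @param measurements Measurement tibble with `E_raw_pct` and `batch_id`.
#' @param baseline Tibble from [donor_only_baseline()] (one row per batch).
#' @return `measurements` with `E_pct` and `baseline_batch_id` columns.
#' @export
apply_donor_only_correction <- function(measurements, baseline) {
  stopifnot(all(c("E_raw_pct", "batch_id") %in% names(measurements)))
  missing <- setdiff(unique(measurements$batch_id), baseline$batch_id)
  if (length(missing) > 0)
    stop("no donor-only baseline for batch(es): ", paste(missing, collapse = ", "))
  b <- baseline |>
    dplyr::select(batch_id, b_pct) |>
    dplyr::rename(.b_pct = b_pct)
  measurements |>
    dplyr::left_join(b, by = "batch_id") |>
    dplyr::mutate(E_pct = .data$E_raw_pct - .data$.b_pct,
                  baseline_batch_id = .data$batch_id) |>
    dplyr::select(-".b_pct")
}

#' Quantify one acceptor-photobleaching acquisition end to end
#'
#' Convenience wrapper running the per-cell pipeline: background
#' subtraction, phase averaging, cytoplasm-level threshold estimation,
#' per-pixel efficiency over the patch regions, and acceptor-bleach QC.
#'
#' @param donor,acceptor Donor and acceptor [image_series()].
#' @param rois A [roi_set()] with roles `"patches"`, `"cytoplasm"` and
#'   (unless `background` is a constant) `"reference"` for the extracellular
#'   background region.
#' @param background A constant, or `NULL` to use the `"reference"` regions
#'   of `rois`.
#' @param convention Estimator convention, see [compute_fret_efficiency()].
#' @param threshold Intensity threshold; `NULL` (default) estimates it from
#'   the cytoplasm region.
#' @param entity_id,batch_id Identifiers recorded in the output row.
#' @return One-row measurement tibble with the efficiency fields plus
#'   `beta_hat`.
#' @export
quantify_apb <- function(donor, acceptor, rois, background = NULL,
                         convention = "increase_over_pre",
                         threshold = NULL,
                         entity_id = "cell1", batch_id = "batch1") {
  bg <- background %||% rois
  donor_bs <- subtract_background(donor, bg)
  acceptor_bs <- subtract_background(acceptor, bg)
  d_pre <- average_phase_frames(donor_bs, "pre")
  d_post <- average_phase_frames(donor_bs, "post")
  a_pre <- average_phase_frames(acceptor_bs, "pre")
  a_post <- average_phase_frames(acceptor_bs, "post")
  thr_flags <- character(0)
  if (is.null(threshold)) {
    threshold <- estimate_cytoplasm_threshold(d_pre, rois, patch_rois = NULL)
    thr_flags <- attr(threshold, "qc_flags")
  }
  meas <- compute_fret_efficiency(d_pre, d_post, rasterize_role(rois, dim(d_pre), "patches"),
                                  threshold = as.numeric(threshold),
                                  convention = convention,
                                  entity_id = entity_id, batch_id = batch_id)
  bleach <- measure_acceptor_bleach(a_pre, a_post,
                                    rasterize_role(rois, dim(a_pre), "patches"))
  meas$beta_hat <- bleach$beta_hat
  meas$qc_flags <- paste(c(meas$qc_flags[meas$qc_flags != ""],
                           bleach$qc_flags[bleach$qc_flags != ""],
                           thr_flags), collapse = ";")
  meas
}
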