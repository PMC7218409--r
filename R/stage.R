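# Stage-resolved per-patch FRET: blob detection, marker-presence
# classification, and the two-group (marker-absent vs marker-present)
# comparison.

# Separable Gaussian blur with replicated edges, pixel-integrated kernel.
# Implemented as banded-matrix products (images here are small).
gaussian_blur <- function(img, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  xs <- (-r):r
  k <- stats::pnorm(xs + 0.5, sd = sigma) - stats::pnorm(xs - 0.5, sd = sigma)
  k <- k / sum(k)
  pad <- pad_replicate(img, r)
  band <- function(n) {
    K <- matrix(0, n, n + 2 * r)
    for (i in seq_len(n)) K[i, i:(i + 2 * r)] <- k
    K
  }
  band(nrow(img)) %*% pad %*% t(band(ncol(img)))
}

pad_replicate <- function(img, r) {
  img <- img[c(rep(1, r), seq_len(nrow(img)), rep(nrow(img), r)), , drop = FALSE]
  img[, c(rep(1, r), seq_len(ncol(img)), rep(ncol(img), r)), drop = FALSE]
}

# Negated 5-point Laplacian with replicated edges (spot response is positive
# at intensity maxima of the smoothed image).
neg_laplacian <- function(sm) {
  p <- pad_replicate(sm, 1L)
  n <- nrow(sm); m <- ncol(sm)
  core <- p[2:(n + 1), 2:(m + 1)]
  4 * core - p[1:n, 2:(m + 1)] - p[3:(n + 2), 2:(m + 1)] -
    p[2:(n + 1), 1:m] - p[2:(n + 1), 3:(m + 2)]
}

#' Detect diffraction-limited patches
#'
#' Laplacian-of-Gaussian blob detection at the patch scale: the image is
#' smoothed at the PSF sigma, the negated discrete Laplacian of the smoothed
#' image is the spot response, and local maxima above a threshold are kept,
#' intensity-ranked, enforcing a minimum separation. Centres are refined to
#' sub-pixel precision by a local intensity centroid.
#'
#' @param image Background-subtracted 2-D image (matrix).
#' @param sigma_px Blob scale in pixels (defaults to the rendering PSF,
#'   1.1 px).
#' @param threshold Minimum LoG response; `NULL` (default) uses
#'   `5 * mad(response)`.
#' @param min_separation_px Minimum distance between accepted centres.
#' @param max_patches Optional cap on the number of returned patches.
#' @param edge_ratio_max Candidates whose smoothed-image Hessian has
#'   `trace^2 / det` above this (or non-positive determinant) are rejected:
#'   isotropic blobs score near 4 while step edges (e.g. the cell outline)
#'   score higher (the default 5 allows ~3.6-fold curvature anisotropy). Set
#'   `Inf` to disable.
#' @return Tibble with 0-based sub-pixel `x`, `y` and the blob `response`,
#'   strongest first. Empty when nothing is detected.
#' @export
detect_patches <- function(image, sigma_px = 1.1, threshold = NULL,
                           min_separation_px = 3, max_patches = Inf,
                           edge_ratio_max = 5) {
  sm <- gaussian_blur(image, sigma_px)
  resp <- neg_laplacian(sm)
  if (is.null(threshold)) threshold <- 5 * stats::mad(resp)
  nr <- nrow(resp); nc <- ncol(resp)
  # strict local maxima over the 8-neighbourhood
  is_max <- matrix(TRUE, nr, nc)
  shifts <- expand.grid(dy = -1:1, dx = -1:1)
  shifts <- shifts[!(shifts$dy == 0 & shifts$dx == 0), ]
  core_r <- 2:(nr - 1); core_c <- 2:(nc - 1)
  keep <- matrix(FALSE, nr, nc)
  center <- resp[core_r, core_c]
  ok <- matrix(TRUE, length(core_r), length(core_c))
  for (s in seq_len(nrow(shifts))) {
    nb <- resp[core_r + shifts$dy[s], core_c + shifts$dx[s]]
    ok <- ok & (center >= nb)
  }
  keep[core_r, core_c] <- ok & (center > threshold)
  idx <- which(keep, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(tibble::tibble(x = numeric(0), y = numeric(0), response = numeric(0)))
  cand <- tibble::tibble(row = idx[, 1], col = idx[, 2],
                         response = resp[idx])
  if (is.finite(edge_ratio_max)) {
    ok <- vapply(seq_len(nrow(cand)), function(i) {
      r <- cand$row[i]; c <- cand$col[i]
      if (r < 2 || r > nr - 1 || c < 2 || c > nc - 1) return(FALSE)
      dxx <- sm[r, c + 1] - 2 * sm[r, c] + sm[r, c - 1]
      dyy <- sm[r + 1, c] - 2 * sm[r, c] + sm[r - 1, c]
      dxy <- (sm[r + 1, c + 1] - sm[r + 1, c - 1] -
                sm[r - 1, c + 1] + sm[r - 1, c - 1]) / 4
      det <- dxx * dyy - dxy^2
      det > 0 && (dxx + dyy)^2 / det <= edge_ratio_max
    }, logical(1))
    cand <- cand[ok, , drop = FALSE]
    if (nrow(cand) == 0)
      return(tibble::tibble(x = numeric(0), y = numeric(0), response = numeric(0)))
  }
  cand <- cand[order(-cand$response), ]
  # greedy non-maximum suppression by minimum separation
  sel <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (length(sel) > 0) {
      d <- sqrt((cand$row[sel] - cand$row[i])^2 + (cand$col[sel] - cand$col[i])^2)
      if (any(d < min_separation_px)) next
    }
    sel <- c(sel, i)
    if (length(sel) >= max_patches) break
  }
  cand <- cand[sel, ]
  # sub-pixel centroid refinement on the smoothed image (3x3 window)
  cx <- cy <- numeric(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    rr <- max(1, cand$row[i] - 1):min(nr, cand$row[i] + 1)
    cc <- max(1, cand$col[i] - 1):min(nc, cand$col[i] + 1)
    w <- sm[rr, cc, drop = FALSE]
    w <- w - min(w)
    if (sum(w) == 0) w[] <- 1
    cy[i] <- sum((rr - 1) * rowSums(w)) / sum(w)
    cx[i] <- sum((cc - 1) * colSums(w)) / sum(w)
  }
  tibble::tibble(x = cx, y = cy, response = cand$response)
}

#' Classify marker presence at a patch
#'
#' A patch is marker-positive when its mean marker intensity exceeds the
#' cytoplasmic marker level by more than `k_sigma` cytoplasmic standard
#' deviations: `mean(marker[patch]) > cyto_level + k_sigma * cyto_sd`.
#'
#' @param patch_roi `roi`/mask of the patch on the marker image.
#' @param marker_image Background-subtracted marker-channel image.
#' @param cyto_level_marker Mean cytoplasmic marker intensity.
#' @param cyto_sd_marker Cytoplasmic marker standard deviation.
#' @param k_sigma Decision threshold in cytoplasmic SDs (default 3).
#' @return Logical scalar.
#' @export
classify_marker_presence <- function(patch_roi, marker_image,
                                     cyto_level_marker, cyto_sd_marker,
                                     k_sigma = 3) {
  mask <- roi_arg_mask(patch_roi, dim(marker_image))
  if (!any(mask)) stop("empty patch ROI")
  mean(marker_image[mask]) > cyto_level_marker + k_sigma * cyto_sd_marker
}

#' Stage-resolved per-patch FRET
#'
#' Measures FRET at individual endocytic patches and sorts them by the
#' presence or absence of a third-channel marker (e.g. Abp1, which labels
#' actin-driven invagination). Each patch gets an oval ROI around its
#' centre; per-patch efficiencies come from [compute_fret_efficiency()] on
#' that mask, marker presence from [classify_marker_presence()], and the
#' two groups are compared with [welch_t_test()] and summarised as box
#' plots. Groups with fewer than 5 patches have their summaries suppressed
#' (raw values are still returned).
#'
#' @param patches Tibble of patch centres (`x`, `y`; e.g. from
#'   [detect_patches()]), or a list of patch `roi`s.
#' @param donor_pre,donor_post Averaged, background-subtracted donor images.
#' @param marker_image Background-subtracted marker image, or `NULL` (all
#'   patches are then marker-absent).
#' @param cyto_roi Cytoplasm `roi`/[roi_set()] used for the donor threshold
#'   and the marker statistics.
#' @param patch_radius_px Oval ROI radius around each centre (default 2 px,
#'   about 360 nm at 178 nm pixels, covering the PSF-blurred patch).
#' @param k_sigma Marker decision threshold, see
#'   [classify_marker_presence()].
#' @param min_pixels Patches are measured only if at least this many pixels
#'   survive the intensity threshold (default 3).
#' @param convention Estimator convention, see [compute_fret_efficiency()].
#' @param cell_id Identifier copied into the patch records.
#' @return An object of class `stage_fret`: list with `patches` (per-patch
#'   tibble), `group_summaries` (box-plot summaries by group), and `test`
#'   (Welch comparison, `NULL` if only one group).
#' @export
stage_resolved_fret <- function(patches, donor_pre, donor_post, marker_image,
                                cyto_roi, patch_radius_px = 2, k_sigma = 3,
                                min_pixels = 3L,
                                convention = "increase_over_pre",
                                cell_id = "cell1") {
  shape <- dim(donor_pre)
  cyto_mask <- roi_arg_mask(cyto_roi, shape, role = "cytoplasm")
  thr <- mean(donor_pre[cyto_mask])
  if (!is.null(marker_image)) {
    cyto_marker <- mean(marker_image[cyto_mask])
    cyto_marker_sd <- stats::sd(marker_image[cyto_mask])
  }
  if (is.data.frame(patches)) {
    rois <- purrr::map2(patches$x, patches$y,
                        ~roi_oval(.x, .y, patch_radius_px, role = "patches"))
  } else rois <- patches
  rows <- purrr::imap(rois, function(r, i) {
    mask <- rasterize_roi(r, shape)
    m <- compute_fret_efficiency(donor_pre, donor_post, mask, thr,
                                 convention = convention,
                                 entity_id = paste0(cell_id, "_patch", i),
                                 min_pixels = min_pixels)
    m$patch_id <- as.integer(i)
    m$cell_id <- cell_id
    m$center_x <- r$cx
    m$center_y <- r$cy
    m$marker_mean_intensity <-
      if (is.null(marker_image)) NA_real_ else mean(marker_image[mask])
    m$marker_present <-
      if (is.null(marker_image)) FALSE
      else classify_marker_presence(mask, marker_image, cyto_marker,
                                    cyto_marker_sd, k_sigma)
    m
  })
  ptab <- dplyr::bind_rows(rows)
  valid <- ptab |> dplyr::filter(.data$valid)
  groups <- split(valid$E_raw_pct, valid$marker_present)
  summaries <- purrr::imap(groups, function(v, g) {
    if (length(v) >= 5) dplyr::mutate(boxplot_summary(v),
                                      marker_present = as.logical(g),
                                      .before = 1)
    else tibble::tibble(marker_present = as.logical(g), n = length(v))
  }) |> dplyr::bind_rows()
  test <- if (length(groups) == 2 && all(lengths(groups) >= 2))
    welch_t_test(groups[["FALSE"]], groups[["TRUE"]]) else NULL
  structure(list(patches = ptab, group_summaries = summaries, test = test),
            class = "stage_fret")
}

#' @export
print.stage_fret <- function(x, ...) {
  cat("<stage_fret>", nrow(x$patches), "patches;",
      sum(x$patches$marker_present), "marker-positive\n")
  if (!is.null(x$test))
    cat(sprintf("  Welch t = %.3f, df = %.1f, p = %.3g\n",
                x$test$t, x$test$df, x$test$p))
  invisible(x)
}

#' @rdname stage_resolved_fret
#' @param x A `stage_fret` object.
#' @param ... Unused.
#' @export
tidy.stage_fret <- function(x, ...) x$patches

#' @rdname stage_resolved_fret
#' @export
glance.stage_fret <- function(x, ...) {
  ns <- table(factor(x$patches$marker_present[x$patches$valid],
                     levels = c(FALSE, TRUE)))
  out <- tibble::tibble(n_absent = as.integer(ns[1]),
                        n_present = as.integer(ns[2]))
  if (!is.null(x$test)) out <- dplyr::bind_cols(out, x$test)
  out
}

#' @rdname stage_resolved_fret
#' @param object A `stage_fret` object.
#' @export
autoplot.stage_fret <- function(object, ...) {
  d <- object$patches |> dplyr::filter(.data$valid) |>
    dplyr::mutate(group = ifelse(.data$marker_present, "marker present",
                                 "marker absent"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$E_raw_pct)) +
    ggplot2::geom_boxplot(notch = TRUE, outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 0.8) +
    ggplot2::labs(x = NULL, y = "FRET efficiency (%)") +
    ggplot2::theme_minimal()
}
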