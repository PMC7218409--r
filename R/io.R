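# Input/output: multi-page 16-bit TIFF stacks with a structured-text (YAML)
# sidecar manifest, YAML ROI sets, and CSV measurement tables.

#' Write an image series to a multi-page TIFF with a sidecar manifest
#'
#' Frames are stored as 16-bit TIFF pages; channel, per-frame phase tags,
#' time stamps, pixel size and any extra (e.g. ground-truth) fields go into a
#' YAML manifest next to the TIFF.
#'
#' @param series An [image_series()].
#' @param path Output TIFF path.
#' @param manifest_path Manifest path; default replaces the extension with
#'   `.yaml`.
#' @param extra Named list of additional manifest fields (e.g. truth values).
#' @return `path`, invisibly.
#' @export
write_image_series <- function(series, path, manifest_path = NULL, extra = list()) {
  stopifnot(inherits(series, "image_series"))
  manifest_path <- manifest_path %||% sub("\\.[^.]+$", ".yaml", path)
  mx <- max(vapply(series$frames, max, numeric(1)))
  if (mx > 65535) stop("pixel values exceed the 16-bit range")
  pages <- lapply(series$frames, function(f) f / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  man <- list(
    format = "fretmap_image_series",
    schema_version = 1L,
    channel = series$channel,
    n_frames = length(series$frames),
    shape = as.integer(dim(series$frames[[1]])),
    phase = as.list(series$phase),
    time_s = as.list(series$time_s),
    pixel_size_nm = series$pixel_size_nm)
  yaml::write_yaml(c(man, extra), manifest_path)
  invisible(path)
}

#' Read an image series written by [write_image_series()]
#'
#' @param path TIFF path.
#' @param manifest_path Manifest path; default replaces the extension with
#'   `.yaml`.
#' @return An [image_series()]; extra manifest fields are attached as the
#'   `"manifest"` attribute.
#' @export
read_image_series <- function(path, manifest_path = NULL) {
  manifest_path <- manifest_path %||% sub("\\.[^.]+$", ".yaml", path)
  if (!file.exists(path)) stop("no such file: ", path)
  if (!file.exists(manifest_path)) stop("missing manifest: ", manifest_path)
  man <- yaml::read_yaml(manifest_path)
  if (is.null(man$phase)) stop("manifest is missing per-frame phase tags")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != man$n_frames)
    stop("frame count does not match manifest (", length(pages),
         " vs ", man$n_frames, ")")
  frames <- lapply(pages, function(p) {
    f <- round(p * 65535)
    storage.mode(f) <- "integer"
    f
  })
  out <- image_series(frames, channel = man$channel,
                      phase = unlist(man$phase), time_s = unlist(man$time_s),
                      pixel_size_nm = man$pixel_size_nm)
  known <- c("format", "schema_version", "channel", "n_frames", "shape",
             "phase", "time_s", "pixel_size_nm")
  attr(out, "manifest") <- man[setdiff(names(man), known)]
  out
}

#' Write an ROI set as structured text (YAML)
#'
#' @param rois A [roi_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_roi_set <- function(rois, path) {
  stopifnot(inherits(rois, "roi_set"))
  recs <- lapply(names(rois), function(nm) {
    r <- rois[[nm]]
    base <- list(name = nm, type = r$type, role = r$role)
    if (r$type == "oval") c(base, list(cx = r$cx, cy = r$cy, rx = r$rx, ry = r$ry))
    else c(base, list(x = as.list(r$x), y = as.list(r$y)))
  })
  yaml::write_yaml(list(format = "fretmap_roi_set", schema_version = 1L,
                        rois = recs), path)
  invisible(path)
}

#' Read an ROI set written by [write_roi_set()]
#'
#' @param path Input path.
#' @return A [roi_set()].
#' @export
read_roi_set <- function(path) {
  doc <- yaml::read_yaml(path)
  rois <- lapply(doc$rois, function(r) {
    if (r$type == "oval") roi_oval(r$cx, r$cy, r$rx, r$ry, role = r$role, name = r$name)
    else roi_polygon(unlist(r$x), unlist(r$y), role = r$role, name = r$name)
  })
  names(rois) <- vapply(doc$rois, `[[`, character(1), "name")
  roi_set(rois)
}

#' Write a measurement or screen table to CSV
#'
#' Adds a `schema_version` column so downstream readers can detect layout
#' changes.
#'
#' @param tbl A data frame of measurements.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(tbl, path) {
  tbl <- tibble::as_tibble(tbl)
  if (!"schema_version" %in% names(tbl)) tbl$schema_version <- 1L
  readr::write_csv(tbl, path)
  invisible(path)
}

#' Read a table written by [write_results_table()]
#'
#' @param path Input CSV path.
#' @return A tibble.
#' @export
read_results_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
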