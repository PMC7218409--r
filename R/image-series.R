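#' Annotated multi-frame image stack
#'
#' Container for one channel of an acquisition: an ordered list of 2-D
#' integer images with a channel label, a per-frame phase tag
#' (`"pre"`/`"bleach"`/`"post"`), per-frame time stamps in seconds, and the
#' pixel size (178 nm by default). All frames must share one pixel grid,
#' phase tags must be non-decreasing in the order pre -> bleach -> post, and
#' time stamps must be strictly increasing.
#'
#' @param frames List of numeric/integer matrices of identical shape.
#' @param channel Channel label (e.g. `"donor"`, `"acceptor"`, `"marker"`).
#' @param phase Character vector of per-frame phase tags.
#' @param time_s Numeric vector of per-frame time stamps (seconds).
#' @param pixel_size_nm Pixel size in nanometres.
#' @return An object of class `image_series`.
#' @export
image_series <- function(frames, channel, phase, time_s, pixel_size_nm = 178) {
  if (!is.list(frames) || length(frames) == 0)
    stop("frames must be a non-empty list of matrices")
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all frames must have the same shape")
  if (length(phase) != length(frames) || length(time_s) != length(frames))
    stop("phase and time_s must have one entry per frame")
  ord <- c(pre = 1L, bleach = 2L, post = 3L)
  if (any(!phase %in% names(ord))) stop("phase tags must be pre/bleach/post")
  if (is.unsorted(ord[phase])) stop("phase tags must follow pre -> bleach -> post")
  if (any(diff(time_s) <= 0)) stop("time stamps must be strictly increasing")
  structure(
    list(frames = frames, channel = channel, phase = phase,
         time_s = as.numeric(time_s), pixel_size_nm = pixel_size_nm),
    class = "image_series")
}

#' @export
print.image_series <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<image_series> channel=%s, %d frame(s) of %dx%d px, %g nm/px\n",
              x$channel, length(x$frames), d[1], d[2], x$pixel_size_nm))
  cat("  phases:", paste(x$phase, collapse = ","), "\n")
  invisible(x)
}

#' Number of frames in a series
#' @param series An [image_series()].
#' @param phase Optional phase tag to count.
#' @export
n_frames <- function(series, phase = NULL) {
  if (is.null(phase)) length(series$frames) else sum(series$phase == phase)
}

#' Extract the frames of one phase
#' @param series An [image_series()].
#' @param phase Phase tag (`"pre"` or `"post"`).
#' @return List of matrices.
#' @export
phase_frames <- function(series, phase) {
  series$frames[series$phase == phase]
}

# Map over frames keeping metadata.
map_frames <- function(series, fn) {
  series$frames <- lapply(series$frames, fn)
  series
}
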