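# Regions of interest. Coordinate convention (fixed package-wide): 0-based,
# (row, column) = (y, x), pixel centres at integer coordinates; ROI vertices
# and centres live in the same frame.

roi_roles <- c("patches", "cytoplasm", "whole_cell", "frap_spot", "reference")

#' Oval region of interest
#'
#' @param cx,cy Centre (0-based pixel coordinates).
#' @param rx,ry Radii in pixels (> 0). A pixel belongs to the oval when its
#'   centre satisfies the inclusive ellipse equation
#'   `((x-cx)/rx)^2 + ((y-cy)/ry)^2 <= 1`.
#' @param role One of `patches`, `cytoplasm`, `whole_cell`, `frap_spot`, `reference`.
#' @param name Optional region name.
#' @return An object of class `roi` (subclass `roi_oval`).
#' @export
roi_oval <- function(cx, cy, rx, ry = rx, role = "patches", name = NULL) {
  role <- match.arg(role, roi_roles)
  if (rx <= 0 || ry <= 0) stop("oval radii must be positive")
  structure(list(type = "oval", cx = cx, cy = cy, rx = rx, ry = ry,
                 role = role, name = name),
            class = c("roi_oval", "roi"))
}

#' Polygon region of interest
#'
#' @param x,y Vertex coordinates (0-based, same length >= 3).
#' @param role One of `patches`, `cytoplasm`, `whole_cell`, `frap_spot`, `reference`.
#' @param name Optional region name.
#' @return An object of class `roi` (subclass `roi_polygon`).
#' @export
roi_polygon <- function(x, y, role = "patches", name = NULL) {
  role <- match.arg(role, roi_roles)
  if (length(x) < 3 || length(x) != length(y)) stop("polygon needs >= 3 (x, y) vertices")
  if (abs(shoelace_area(x, y)) <= 0) stop("degenerate (zero-area) polygon ROI")
  structure(list(type = "polygon", x = as.numeric(x), y = as.numeric(y),
                 role = role, name = name),
            class = c("roi_polygon", "roi"))
}

shoelace_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Named collection of regions of interest
#'
#' @param ... `roi` objects (optionally named).
#' @return An object of class `roi_set` (a named list of `roi`).
#' @export
roi_set <- function(...) {
  rois <- list(...)
  if (length(rois) == 1 && is.list(rois[[1]]) && !inherits(rois[[1]], "roi"))
    rois <- rois[[1]]
  if (!all(vapply(rois, inherits, logical(1), "roi"))) stop("all elements must be roi objects")
  nm <- names(rois) %||% rep("", length(rois))
  auto <- vapply(seq_along(rois), function(i) {
    rois[[i]]$name %||% paste0(rois[[i]]$role, "_", i)
  }, character(1))
  names(rois) <- ifelse(nm == "" | is.na(nm), auto, nm)
  structure(rois, class = "roi_set")
}

#' Rasterize a region of interest to a pixel mask
#'
#' Pixel membership is decided at pixel centres: inclusive ellipse equation
#' for ovals, boundary-inclusive point-in-polygon for polygons.
#'
#' @param roi A `roi` object.
#' @param shape Image shape `c(n_rows, n_cols)`.
#' @return Logical matrix.
#' @export
rasterize_roi <- function(roi, shape) {
  stopifnot(inherits(roi, "roi"), length(shape) == 2)
  xs <- seq_len(shape[2]) - 1
  ys <- seq_len(shape[1]) - 1
  if (roi$type == "oval") {
    mask <- outer(ys, xs, function(y, x)
      ((x - roi$cx) / roi$rx)^2 + ((y - roi$cy) / roi$ry)^2 <= 1)
  } else {
    g <- expand.grid(y = ys, x = xs)
    inside <- pracma::inpolygon(g$x, g$y, roi$x, roi$y, boundary = TRUE)
    mask <- matrix(inside, shape[1], shape[2])
  }
  if (!any(mask)) stop("ROI rasterizes to an empty mask (degenerate or out of bounds)")
  mask
}

#' Combined mask of all regions with a given role
#'
#' @param rois A [roi_set()].
#' @param shape Image shape `c(n_rows, n_cols)`.
#' @param role Role to select (`NULL` for all regions).
#' @return Logical matrix (union of the selected regions).
#' @export
rasterize_role <- function(rois, shape, role = NULL) {
  stopifnot(inherits(rois, "roi_set"))
  sel <- if (is.null(role)) rois else rois[vapply(rois, function(r) r$role == role, logical(1))]
  if (length(sel) == 0) stop("no ROI with role: ", role)
  Reduce(`|`, lapply(sel, rasterize_roi, shape = shape))
}
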