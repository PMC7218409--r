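# FRAP analysis: trace extraction, double normalisation, single-exponential
# recovery fitting, and mean recovery curves.

#' Extract a FRAP trace from an image series
#'
#' Per-frame background-subtracted mean intensities of the bleached spot and
#' of an unbleached reference region inside the cell.
#'
#' @param series A FRAP [image_series()].
#' @param spot_roi `roi`/mask of the bleached spot.
#' @param reference_roi `roi`/mask of an unbleached in-cell region.
#' @param background_roi `roi`/mask of extracellular background, or a
#'   constant.
#' @return An object of class `frap_trace`: tibble with `time_s`, `phase`,
#'   `spot`, `reference`.
#' @export
extract_trace <- function(series, spot_roi, reference_roi, background_roi) {
  stopifnot(inherits(series, "image_series"))
  shape <- dim(series$frames[[1]])
  smask <- roi_arg_mask(spot_roi, shape, role = "frap_spot")
  rmask <- roi_arg_mask(reference_roi, shape, role = "reference")
  if (any(smask & rmask)) stop("spot and reference ROIs overlap")
  if (is.numeric(background_roi)) {
    bgv <- function(f) background_roi
  } else {
    bmask <- roi_arg_mask(background_roi, shape, role = "reference")
    if (any(bmask & (smask | rmask))) stop("background ROI overlaps spot/reference")
    bgv <- function(f) stats::median(f[bmask])
  }
  vals <- purrr::map_dfr(seq_along(series$frames), function(i) {
    f <- series$frames[[i]]
    b <- bgv(f)
    tibble::tibble(time_s = series$time_s[i], phase = series$phase[i],
                   spot = mean(f[smask]) - b,
                   reference = mean(f[rmask]) - b)
  })
  structure(vals, class = c("frap_trace", class(vals)))
}

#' Double-normalise a FRAP trace
#'
#' `F_norm(t) = (spot(t) / reference(t)) / mean_pre(spot / reference)`, so
#' the pre-bleach mean is exactly 1 and shared acquisition photobleaching
#' (which affects spot and reference alike) cancels.
#'
#' @param trace A `frap_trace` from [extract_trace()] (>= 3 pre-bleach
#'   frames recommended; >= 1 required).
#' @param smooth_reference Replace the raw reference trace by its fitted
#'   geometric decay (log-linear in time) before dividing (default `TRUE`).
#'   Acquisition photobleaching is multiplicative per frame, so the
#'   reference follows `a * b^t`; using the fitted curve keeps the
#'   correction while not injecting the reference region's shot noise into
#'   every time point.
#' @return The trace with an added `F_norm` column.
#' @export
normalize_trace <- function(trace, smooth_reference = TRUE) {
  stopifnot(all(c("time_s", "phase", "spot", "reference") %in% names(trace)))
  if (any(trace$reference <= 0)) stop("non-positive reference intensity")
  pre <- trace$phase == "pre"
  if (!any(pre)) stop("trace has no pre-bleach frames")
  ref <- trace$reference
  if (smooth_reference && length(ref) >= 3) {
    ref <- exp(stats::fitted(stats::lm(log(ref) ~ trace$time_s)))
  }
  ratio <- trace$spot / ref
  trace$F_norm <- ratio / mean(ratio[pre])
  trace
}

#' Fit a single-exponential recovery model
#'
#' Bounded least-squares fit of
#' `F_norm(t) = F0 + M * (1 - F0) * (1 - exp(-(t - t0)/tau))` to the
#' post-bleach part of a normalised trace, with `M` in `[0, 1.2]` and
#' `tau > 0`. The bleach frame is auto-detected as the largest single-frame
#' fractional drop of the spot trace (unless the trace carries phase tags,
#' which take precedence). Reports the mobile fraction `M`, exchange time
#' `tau`, and half-time `tau * log(2)`.
#'
#' @param trace Normalised trace from [normalize_trace()].
#' @param min_post_points Minimum post-bleach points required (default 10).
#' @return An object of class `frap_fit`.
#' @export
fit_recovery <- function(trace, min_post_points = 10L) {
  stopifnot("F_norm" %in% names(trace))
  if (all(c("pre", "post") %in% trace$phase)) {
    i0 <- which(trace$phase == "post")[1]
  } else {
    drops <- -diff(trace$F_norm) / pmax(trace$F_norm[-nrow(trace)], 1e-12)
    i0 <- which.max(drops) + 1L
  }
  post <- trace[seq(i0, nrow(trace)), ]
  if (nrow(post) < min_post_points)
    stop("need at least ", min_post_points, " post-bleach points")
  t0 <- post$time_s[1]
  tt <- post$time_s - t0
  yy <- post$F_norm
  # profiled least squares: for fixed tau the model
  # F = F0 + B * (1 - exp(-t/tau)) is linear in (F0, B); scanning a log
  # grid of tau and solving each profile exactly is robust even when the
  # trace is flat (M ~ 0), where tau is unidentifiable and descent methods
  # stall
  span <- max(tt[tt > 0])
  taus <- exp(seq(log(span / 500), log(5 * span), length.out = 80))
  best <- NULL
  for (tau in taus) {
    xb <- 1 - exp(-tt / tau)
    ft <- stats::lm.fit(cbind(1, xb), yy)
    rss <- sum(ft$residuals^2)
    if (is.null(best) || rss < best$rss)
      best <- list(F0 = ft$coefficients[1], B = ft$coefficients[2],
                   tau = tau, rss = rss)
  }
  F0 <- min(max(best$F0, 0), 1.5)
  M <- min(max(best$B / max(1 - F0, 1e-6), 0), 1.2)
  # polish with bounded Levenberg-Marquardt from the profile optimum
  fit <- tryCatch(
    minpack.lm::nlsLM(
      yy ~ F0 + M * (1 - F0) * (1 - exp(-tt / tau)),
      start = list(F0 = F0, M = max(M, 1e-4), tau = best$tau),
      lower = c(F0 = 0, M = 0, tau = 1e-6),
      # tau capped at the profile grid's range: beyond ~5x the observation
      # span the exponential is indistinguishable from a line and (M, tau)
      # drift along an unidentifiable ridge
      upper = c(F0 = 1.5, M = 1.2, tau = 5 * span),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(fit) && sum(stats::resid(fit)^2) <= best$rss + 1e-12) {
    cf <- stats::coef(fit)
    F0 <- unname(cf["F0"]); M <- unname(cf["M"]); tau <- unname(cf["tau"])
    res <- stats::resid(fit)
  } else {
    tau <- best$tau
    res <- yy - (F0 + M * (1 - F0) * (1 - exp(-tt / tau)))
  }
  params <- tibble::tibble(F_post0 = F0, mobile_fraction = M,
                           tau_s = tau, half_time_s = tau * log(2))
  diag <- tibble::tibble(converged = TRUE, rss = sum(res^2),
                         sigma = stats::sd(res), n_post = nrow(post))
  structure(list(params = params, diagnostics = diag, trace = trace,
                 t0 = t0, fit = fit),
            class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  if (x$diagnostics$converged) {
    cat(sprintf("<frap_fit> M = %.3f, tau = %.2f s (half-time %.2f s)\n",
                x$params$mobile_fraction, x$params$tau_s, x$params$half_time_s))
  } else cat("<frap_fit> did not converge\n")
  invisible(x)
}

#' @rdname fit_recovery
#' @param x,object A `frap_fit` object.
#' @param ... Unused.
#' @export
tidy.frap_fit <- function(x, ...) x$params

#' @rdname fit_recovery
#' @export
glance.frap_fit <- function(x, ...) dplyr::bind_cols(x$params, x$diagnostics)

#' @rdname fit_recovery
#' @export
autoplot.frap_fit <- function(object, ...) {
  d <- object$trace
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s, y = .data$F_norm)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::labs(x = "time (s)", y = "normalised fluorescence") +
    ggplot2::theme_minimal()
  if (object$diagnostics$converged) {
    post <- d[d$time_s >= object$t0, ]
    cf <- object$params
    curve <- tibble::tibble(
      time_s = seq(object$t0, max(d$time_s), length.out = 200))
    curve$F_norm <- cf$F_post0 + cf$mobile_fraction * (1 - cf$F_post0) *
      (1 - exp(-(curve$time_s - object$t0) / cf$tau_s))
    p <- p + ggplot2::geom_line(data = curve, colour = "firebrick")
  }
  p
}

#' Mean recovery curve across cells
#'
#' Per-timepoint mean of normalised traces with a Student-t confidence
#' interval. Traces are resampled onto the first trace's time base by linear
#' interpolation when their grids differ.
#'
#' @param traces List of normalised traces (each with `time_s`, `F_norm`).
#' @param level Confidence level (default 0.95).
#' @return Tibble with `time_s`, `mean`, `ci_halfwidth`, `n`.
#' @export
mean_recovery_curve <- function(traces, level = 0.95) {
  if (length(traces) < 2) stop("need at least 2 traces")
  base_t <- traces[[1]]$time_s
  mat <- vapply(traces, function(tr) {
    if (length(tr$time_s) == length(base_t) && all(tr$time_s == base_t)) tr$F_norm
    else stats::approx(tr$time_s, tr$F_norm, xout = base_t, rule = 2)$y
  }, numeric(length(base_t)))
  n <- ncol(mat)
  m <- rowMeans(mat)
  s <- apply(mat, 1, stats::sd)
  hw <- stats::qt(1 - (1 - level) / 2, n - 1) * s / sqrt(n)
  tibble::tibble(time_s = base_t, mean = m, ci_halfwidth = hw, n = n)
}
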