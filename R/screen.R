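# Screen-level statistics: mean with 95 % CI, FRET-positivity rule,
# Welch's t-test, box-plot summaries, and per-pair aggregation.

#' Mean with confidence interval
#'
#' Student-t interval on per-cell values:
#' `mean +/- t(1-alpha/2, n-1) * s / sqrt(n)`. A nonparametric bootstrap
#' percentile interval is available as an alternative.
#'
#' @param values Numeric vector (n >= 2).
#' @param level Confidence level (default 0.95).
#' @param method `"t"` (default) or `"bootstrap"`.
#' @param n_boot Bootstrap resamples when `method = "bootstrap"`.
#' @return One-row tibble: `mean`, `ci_halfwidth`, `n`.
#' @export
mean_ci <- function(values, level = 0.95, method = c("t", "bootstrap"),
                    n_boot = 2000L) {
  method <- match.arg(method)
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) stop("need at least 2 values for a confidence interval")
  m <- mean(values)
  if (method == "t") {
    hw <- stats::qt(1 - (1 - level) / 2, n - 1) * stats::sd(values) / sqrt(n)
  } else {
    bm <- vapply(seq_len(n_boot),
                 function(i) mean(sample(values, n, replace = TRUE)),
                 numeric(1))
    qs <- stats::quantile(bm, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
    hw <- max(m - qs[1], qs[2] - m)
  }
  tibble::tibble(mean = m, ci_halfwidth = hw, n = n)
}

#' FRET-positivity rule
#'
#' A pair is FRET-positive when its mean FRET and both 95 % confidence
#' bounds are positive, i.e. `mean > 0`, `mean - halfwidth > 0` and
#' `mean + halfwidth > 0`; otherwise it is negative.
#'
#' @param mean_E Mean FRET efficiency (percent).
#' @param ci_halfwidth 95 % CI half-width (percent).
#' @return `"positive"` or `"negative"` (vectorised).
#' @export
classify_fret_positive <- function(mean_E, ci_halfwidth) {
  ifelse(!is.na(mean_E) & !is.na(ci_halfwidth) &
           mean_E > 0 & (mean_E - ci_halfwidth) > 0 & (mean_E + ci_halfwidth) > 0,
         "positive", "negative")
}

#' Two-tailed Welch's t-test
#'
#' Unpaired comparison not assuming equal variances:
#' `t = (mean_a - mean_b) / sqrt(sa^2/na + sb^2/nb)` with
#' Welch-Satterthwaite degrees of freedom (delegated to [stats::t.test()]).
#' When both groups have zero variance, `p = 1` for equal means and `p = 0`
#' otherwise, by convention.
#'
#' @param values_a,values_b Numeric vectors (both n >= 2).
#' @return One-row tibble: `t`, `df`, `p`.
#' @export
welch_t_test <- function(values_a, values_b) {
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  if (length(values_a) < 2 || length(values_b) < 2)
    stop("both groups need at least 2 values")
  if (stats::var(values_a) == 0 && stats::var(values_b) == 0) {
    eq <- isTRUE(all.equal(mean(values_a), mean(values_b)))
    return(tibble::tibble(t = if (eq) 0 else sign(mean(values_a) - mean(values_b)) * Inf,
                          df = NA_real_, p = if (eq) 1 else 0))
  }
  ht <- stats::t.test(values_a, values_b, var.equal = FALSE)
  tibble::tibble(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value)
}

#' Box-plot summary with notches
#'
#' Quartiles by linear interpolation ([stats::quantile()] type 7), whiskers
#' at the most extreme data points within 1.5 interquartile ranges of the
#' quartiles, and a median notch half-width of `1.58 * IQR / sqrt(n)`
#' (approximate 95 % CI of the median).
#'
#' @param values Numeric vector (n >= 5).
#' @return One-row tibble: `median`, `q25`, `q75`, `whisker_low`,
#'   `whisker_high`, `notch_halfwidth`, `n`.
#' @export
boxplot_summary <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 5) stop("need at least 5 values for a box-plot summary")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  tibble::tibble(
    median = q[2], q25 = q[1], q75 = q[3],
    whisker_low = min(values[values >= lo_fence]),
    whisker_high = max(values[values <= hi_fence]),
    notch_halfwidth = 1.58 * iqr / sqrt(n),
    n = n)
}

#' Aggregate per-cell measurements into per-pair screen records
#'
#' One record per (pair, compartment): number of valid cells, mean FRET with
#' 95 % CI, and the FRET-positivity verdict. Pairs whose measurements are
#' all invalid (or fewer than 2 valid cells) are dropped from the table and
#' recorded in the `"dropped"` attribute with a reason.
#'
#' @param measurements Tibble with columns `pair_id`, `compartment`,
#'   `E_pct` (corrected efficiency) and `valid`. Any row with `pair_id` `NA`
#'   is an error: every measurement must be assigned to exactly one pair.
#' @param pair_metadata Optional tibble keyed by `pair_id` (e.g. donor and
#'   acceptor protein/terminus labels) joined onto the result.
#' @param level Confidence level for the CI.
#' @return Screen tibble: `pair_id`, `compartment`, `n_cells`,
#'   `mean_E_pct`, `ci95_halfwidth_pct`, `verdict`.
#' @export
aggregate_screen <- function(measurements, pair_metadata = NULL, level = 0.95) {
  req <- c("pair_id", "compartment", "E_pct", "valid")
  stopifnot(all(req %in% names(measurements)))
  if (any(is.na(measurements$pair_id)))
    stop("unassigned measurements: every row needs a pair_id")
  valid <- measurements |> dplyr::filter(.data$valid, !is.na(.data$E_pct))
  rec <- valid |>
    dplyr::group_by(.data$pair_id, .data$compartment) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      mean_E_pct = mean(.data$E_pct),
      ci95_halfwidth_pct = mean_ci(.data$E_pct, level = level)$ci_halfwidth,
      .groups = "drop") |>
    dplyr::mutate(verdict = classify_fret_positive(.data$mean_E_pct,
                                                   .data$ci95_halfwidth_pct))
  all_pairs <- dplyr::distinct(measurements, .data$pair_id, .data$compartment)
  dropped <- dplyr::anti_join(all_pairs, rec, by = c("pair_id", "compartment")) |>
    dplyr::mutate(reason = "fewer than 2 valid cells")
  if (!is.null(pair_metadata))
    rec <- dplyr::left_join(rec, pair_metadata, by = "pair_id")
  attr(rec, "dropped") <- dropped
  rec
}

#' Re-apply the positivity rule to a published-style summary table
#'
#' Takes a per-pair summary with `mean_E_pct` and `ci95_halfwidth_pct`
#' columns (the shape of a printed screen table) and recomputes the verdict
#' from the classification rule.
#'
#' @param tbl Summary tibble.
#' @return `tbl` with a recomputed `verdict` column.
#' @export
replay_screen_classification <- function(tbl) {
  stopifnot(all(c("mean_E_pct", "ci95_halfwidth_pct") %in% names(tbl)))
  dplyr::mutate(tbl, verdict = classify_fret_positive(.data$mean_E_pct,
                                                      .data$ci95_halfwidth_pct))
}

#' Strain-coverage summary
#'
#' Percentage of accessible tagged-pair strains actually constructed.
#'
#' @param n_constructed Number of strains constructed.
#' @param n_accessible Number of strains accessible to the tagging system.
#' @return One-row tibble with the counts and `coverage_pct`.
#' @export
strain_coverage <- function(n_constructed, n_accessible) {
  stopifnot(n_accessible > 0, n_constructed >= 0)
  tibble::tibble(n_constructed = n_constructed, n_accessible = n_accessible,
                 coverage_pct = 100 * n_constructed / n_accessible)
}
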