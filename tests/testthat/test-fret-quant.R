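make_series <- function(frames, phase = rep("pre", length(frames))) {
  image_series(frames, "donor", phase, seq_along(frames))
}

test_that("background subtraction handles constants and robust medians", {
  f <- matrix(100L, 10, 10)
  s <- make_series(list(f))
  out <- subtract_background(s, 50)
  expect_true(all(out$frames[[1]] == 50))
  # median of the bg region ignores 1 % salt-and-pepper outliers
  set.seed(1)
  f2 <- matrix(100, 40, 40)
  bg_mask <- matrix(FALSE, 40, 40); bg_mask[1:10, 1:10] <- TRUE
  f2[sample(which(bg_mask), 1)] <- 5000 # 1 outlier in a 100-px region
  out2 <- subtract_background(make_series(list(f2)), bg_mask)
  expect_true(all(out2$frames[[1]][!bg_mask] == 0))
  # background region overlapping the cell ROI is an error
  cellm <- matrix(FALSE, 40, 40); cellm[5:20, 5:20] <- TRUE
  expect_error(subtract_background(make_series(list(f2)), bg_mask, cell_roi = cellm),
               "overlaps")
})

test_that("subtracted extracellular field is centred near zero on simulations", {
  sc <- tiny_scene(seed = 21)
  sim <- simulate_apb_experiment(sc, acquisition_config(rng_seed = 21))
  out <- subtract_background(sim$donor, sc$background_level, clip = FALSE)
  outside <- !cell_mask(sc)
  # exclude the PSF skirt near the cell boundary
  outside[10:30, 10:30] <- FALSE
  resid <- average_phase_frames(out, "pre")[outside]
  expect_lt(abs(mean(resid)), sqrt(sc$background_level))
})

test_that("phase averaging is the pixel-wise mean", {
  f1 <- matrix(10, 2, 2); f2 <- matrix(20, 2, 2); f3 <- matrix(30, 2, 2)
  s <- make_series(list(f1, f2, f3))
  expect_equal(average_phase_frames(s, "pre"), matrix(20, 2, 2))
  expect_error(average_phase_frames(s, "post"), "no frames")
  # averaging k noise frames shrinks the pixel SD by sqrt(k)
  cfg <- acquisition_config(read_noise_sd = 0, em_gain_factor = 1)
  set.seed(31)
  fr <- lapply(1:4, function(i) apply_noise(matrix(1000, 100, 100), cfg))
  avg <- average_phase_frames(make_series(fr), "pre")
  expect_lt(abs(stats::sd(avg) - stats::sd(fr[[1]]) / 2) / (stats::sd(fr[[1]]) / 2),
            0.05)
})

test_that("cytoplasm threshold is the ROI mean and flags patch overlap", {
  img <- matrix(200, 20, 20)
  cyto <- roi_oval(10, 10, 4, role = "cytoplasm")
  thr <- estimate_cytoplasm_threshold(img, cyto)
  expect_equal(as.numeric(thr), 200)
  expect_length(attr(thr, "qc_flags"), 0)
  img2 <- img; img2[11, 11] <- 2000
  thr2 <- estimate_cytoplasm_threshold(img2, cyto,
                                       patch_rois = roi_oval(10, 10, 1))
  expect_true("cytoplasm_roi_overlaps_patches" %in% attr(thr2, "qc_flags"))
  expect_gt(as.numeric(thr2), 200) # value still returned
  # on simulations the threshold tracks the quenched cytoplasm level
  sc <- tiny_scene(seed = 22)
  cfg <- acquisition_config(E_true = 0.10, rng_seed = 22)
  sim <- simulate_apb_experiment(sc, cfg)
  d_pre <- average_phase_frames(subtract_background(sim$donor, sc$background_level), "pre")
  cyto_sim <- roi_oval(sc$cell_center[1], sc$cell_center[2], 6, role = "cytoplasm")
  thr_sim <- as.numeric(estimate_cytoplasm_threshold(d_pre, cyto_sim))
  expected <- sc$cytoplasm_level * (1 - cfg$E_true)
  n_px <- sum(rasterize_roi(cyto_sim, dim(d_pre)))
  se <- sqrt(2 * expected / cfg$n_pre_donor / n_px)
  expect_lt(abs(thr_sim - expected), 3 * se + 1)
})

test_that("per-pixel efficiency reproduces the two stated formulas", {
  pre <- matrix(90, 3, 3); post <- matrix(100, 3, 3)
  roi <- matrix(FALSE, 3, 3); roi[2, 2] <- TRUE
  m1 <- compute_fret_efficiency(pre, post, roi, threshold = 0)
  expect_equal(m1$E_raw_pct, 100 * 10 / 90, tolerance = 1e-12)
  m2 <- compute_fret_efficiency(pre, post, roi, threshold = 0,
                                convention = "dequench_over_post")
  expect_equal(m2$E_raw_pct, 10, tolerance = 1e-12)
  # pre == post everywhere gives exactly zero
  m0 <- compute_fret_efficiency(pre, pre, roi, threshold = 0)
  expect_equal(m0$E_raw_pct, 0)
  # zero qualifying pixels: invalid, flagged
  m3 <- compute_fret_efficiency(pre, post, roi, threshold = 1000)
  expect_false(m3$valid)
  expect_equal(m3$qc_flags, "no_qualifying_pixels")
})

test_that("noise-free simulated cell recovers E_true exactly per convention", {
  sc <- tiny_scene(seed = 23)
  cfg <- acquisition_config(E_true = 0.10, beta_bleach = 1, delta_struct = 0)
  cmp <- NULL
  pre <- render_expected_image(sc, "donor", "pre", cfg, 1) - sc$background_level
  post <- render_expected_image(sc, "donor", "post", cfg, 1) - sc$background_level
  mask <- cell_mask(sc)
  m_post <- compute_fret_efficiency(pre, post, mask, threshold = 1,
                                    convention = "dequench_over_post")
  m_pre <- compute_fret_efficiency(pre, post, mask, threshold = 1)
  expect_equal(m_post$E_raw_pct, 10, tolerance = 1e-9)
  expect_equal(m_pre$E_raw_pct, 100 / 9, tolerance = 1e-9)
})

test_that("convention conversion satisfies its algebraic identity", {
  e_post <- c(-3, 0, 2.5, 10, 15)
  e_pre <- convert_fret_convention(e_post, "dequench_over_post", "increase_over_pre")
  expect_equal(e_pre, e_post / (1 - e_post / 100), tolerance = 1e-12)
  back <- convert_fret_convention(e_pre, "increase_over_pre", "dequench_over_post")
  expect_equal(back, e_post, tolerance = 1e-9)
})

test_that("vectorised efficiency equals the per-pixel loop bit for bit", {
  set.seed(41)
  for (i in 1:10) {
    pre <- matrix(stats::runif(100, 50, 500), 10, 10)
    post <- pre * stats::runif(100, 0.9, 1.3)
    mask <- matrix(stats::runif(100) < 0.7, 10, 10)
    thr <- stats::runif(1, 60, 200)
    for (conv in c("increase_over_pre", "dequench_over_post")) {
      ref <- fret_pixel_loop(pre, post, mask, thr, conv)
      got <- compute_fret_efficiency(pre, post, mask, thr, convention = conv)
      if (ref$n == 0) expect_false(got$valid)
      else {
        expect_identical(got$E_raw_pct, ref$E)
        expect_identical(got$n_pixels_used, ref$n)
      }
    }
  }
})

test_that("raising the threshold never increases the pixel count", {
  set.seed(42)
  pre <- matrix(stats::runif(400, 0, 300), 20, 20)
  post <- pre + stats::rnorm(400, 0, 10)
  mask <- matrix(TRUE, 20, 20)
  ns <- sapply(seq(0, 250, by = 25), function(thr)
    compute_fret_efficiency(pre, pmax(post, 0), mask, thr, min_pixels = 0)$n_pixels_used)
  expect_true(all(diff(ns) <= 0))
})

test_that("acceptor bleach fraction is measured and QC-flagged", {
  pre <- matrix(100, 5, 5); roi <- matrix(TRUE, 5, 5)
  expect_equal(measure_acceptor_bleach(pre, matrix(0, 5, 5), roi)$beta_hat, 1)
  expect_equal(measure_acceptor_bleach(pre, pre, roi)$beta_hat, 0)
  expect_equal(measure_acceptor_bleach(pre, pre, roi)$qc_flags, "incomplete_bleach")
  expect_error(measure_acceptor_bleach(matrix(0, 5, 5), pre, roi), "non-positive")
  # simulated partial bleach recovered within sampling error
  sc <- tiny_scene(seed = 24)
  cfg <- acquisition_config(beta_bleach = 0.8, rng_seed = 24)
  sim <- simulate_apb_experiment(sc, cfg)
  bs <- subtract_background(sim$acceptor, sc$background_level)
  patch_mask <- Reduce(`|`, lapply(seq_len(nrow(sc$patch_centers)), function(i)
    rasterize_roi(roi_oval(sc$patch_centers[i, 1], sc$patch_centers[i, 2], 2),
                  sc$shape)))
  b <- measure_acceptor_bleach(average_phase_frames(bs, "pre"),
                               average_phase_frames(bs, "post"), patch_mask)
  expect_lt(abs(b$beta_hat - 0.8), 0.05)
})

test_that("donor-only correction subtracts the matched baseline", {
  meas <- tibble::tibble(E_raw_pct = c(3.0, 1.0), batch_id = "b1", valid = TRUE)
  bl <- tibble::tibble(batch_id = "b1", b_pct = -0.5)
  out <- apply_donor_only_correction(meas, bl)
  expect_equal(out$E_pct, c(3.5, 1.5))
  bl0 <- tibble::tibble(batch_id = "b1", b_pct = 0)
  expect_equal(apply_donor_only_correction(meas, bl0)$E_pct, meas$E_raw_pct)
  expect_error(apply_donor_only_correction(
    dplyr::mutate(meas, batch_id = "b2"), bl), "no donor-only baseline")
})

test_that("structural photobleaching makes donor-only baselines negative and correctable", {
  donor_only <- simulate_pair_batch(20, E_true = 0, seed = 61,
                                    convention = "increase_over_pre")
  bl <- donor_only_baseline(donor_only)
  expect_lt(bl$b_pct, 0) # mild acquisition bleaching reads as negative FRET
  carriers <- simulate_pair_batch(20, E_true = 0.05, seed = 62,
                                  convention = "increase_over_pre")
  corr <- apply_donor_only_correction(carriers, bl)
  ci <- mean_ci(corr$E_pct)
  truth <- convert_fret_convention(5, "dequench_over_post", "increase_over_pre")
  expect_lt(abs(ci$mean - truth), ci$ci_halfwidth + 0.3)
})
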