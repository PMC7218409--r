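test_that("patch detection finds simulated patches and nothing on blank fields", {
  expect_equal(nrow(detect_patches(matrix(0, 40, 40))), 0)
  sc <- cell_scene(n_patches = 8, min_patch_sep_px = 6, seed = 5)
  sim <- simulate_apb_experiment(sc, acquisition_config(rng_seed = 5))
  img <- average_phase_frames(subtract_background(sim$donor, sc$background_level), "pre")
  det <- detect_patches(img)
  d <- sqrt(outer(det$x, sc$patch_centers[, 1], "-")^2 +
              outer(det$y, sc$patch_centers[, 2], "-")^2)
  recall <- sum(apply(d, 2, min) <= 2)
  false_pos <- sum(apply(d, 1, min) > 2)
  expect_gte(recall, 7)
  expect_equal(false_pos, 0)
})

test_that("detection count is non-increasing in the response threshold", {
  sc <- cell_scene(n_patches = 10, min_patch_sep_px = 5, seed = 9)
  sim <- simulate_apb_experiment(sc, acquisition_config(rng_seed = 9))
  img <- average_phase_frames(subtract_background(sim$donor, sc$background_level), "pre")
  counts <- sapply(c(10, 40, 80, 120, 200), function(thr)
    nrow(detect_patches(img, threshold = thr)))
  expect_true(all(diff(counts) <= 0))
})

test_that("marker presence follows the k-sigma rule", {
  img <- matrix(100, 20, 20)
  roi <- rasterize_roi(roi_oval(10, 10, 2), c(20, 20))
  expect_false(classify_marker_presence(roi, img, 100, 5))
  img2 <- img; img2[roi] <- 500 # 5x cytoplasm
  expect_true(classify_marker_presence(roi, img2, 100, 5))
  # per-patch null misclassification stays near the Gaussian tail rate
  set.seed(10)
  n_px <- sum(roi)
  hits <- replicate(3000, {
    vals <- stats::rnorm(n_px, 100, 20)
    mean(vals) > 100 + 3 * (20 / sqrt(n_px))
  })
  # k-sigma applied to the SD of the patch MEAN bounds the false-present
  # rate by pnorm(-3) ~ 0.13 %
  expect_lt(mean(hits), 0.01)
})

test_that("simulated marker-positive patches are almost always called present", {
  set.seed(11)
  calls <- sapply(1:50, function(s) {
    sc <- cell_scene(n_patches = 6, min_patch_sep_px = 6, seed = 400 + s)
    cfg <- acquisition_config(rng_seed = 800 + s)
    mk <- simulate_marker_image(sc, rep(TRUE, 6), cfg = cfg)
    mkb <- pmax(mk - sc$background_level, 0)
    cyto <- rasterize_roi(roi_oval(sc$cell_center[1], sc$cell_center[2], 6), sc$shape)
    sapply(seq_len(6), function(i) {
      m <- rasterize_roi(roi_oval(sc$patch_centers[i, 1], sc$patch_centers[i, 2], 2),
                         sc$shape)
      classify_marker_presence(m, mkb, mean(mkb[cyto]), stats::sd(mkb[cyto]))
    })
  })
  expect_gte(mean(calls), 0.99)
})

test_that("stage-resolved pipeline separates planted group differences", {
  sf <- simulate_stage_field(n_cells = 8, E_absent = 0, E_present = 0.06, seed = 3)
  expect_s3_class(sf, "stage_fret")
  expect_lt(sf$test$p, 0.05)
  means <- tapply(sf$patches$E_raw_pct[sf$patches$valid],
                  sf$patches$marker_present[sf$patches$valid], mean)
  expect_gt(means[["TRUE"]], means[["FALSE"]])
  g <- glance(sf)
  expect_gte(g$n_absent, 5)
  expect_true(all(c("median", "q25", "q75") %in% names(sf$group_summaries)))
})

test_that("empty marker channel yields a single marker-absent group", {
  sc <- cell_scene(n_patches = 6, min_patch_sep_px = 6, seed = 12)
  sim <- simulate_apb_experiment(sc, acquisition_config(rng_seed = 12))
  db <- subtract_background(sim$donor, sc$background_level)
  sf <- stage_resolved_fret(
    tibble::tibble(x = sc$patch_centers[, 1], y = sc$patch_centers[, 2]),
    average_phase_frames(db, "pre"), average_phase_frames(db, "post"),
    marker_image = NULL,
    roi_oval(sc$cell_center[1], sc$cell_center[2], 6, role = "cytoplasm"))
  expect_true(all(!sf$patches$marker_present))
  expect_null(sf$test)
})

test_that("group labels and FRET values are computed independently", {
  # shuffling the marker channel relative to the donor destroys the group
  # difference while per-patch efficiencies are unchanged
  set.seed(13)
  sf <- simulate_stage_field(n_cells = 10, E_absent = 0, E_present = 0.06, seed = 5)
  shuffled <- sf$patches
  shuffled$marker_present <- sample(shuffled$marker_present)
  a <- shuffled$E_raw_pct[shuffled$valid & !shuffled$marker_present]
  b <- shuffled$E_raw_pct[shuffled$valid & shuffled$marker_present]
  t_orig <- abs(sf$test$t)
  t_shuf <- abs(welch_t_test(a, b)$t)
  expect_gt(t_orig, 3)
  expect_lt(t_shuf, t_orig / 2)
})

test_that("per-patch efficiency equals the generic estimator on the same mask", {
  sc <- cell_scene(n_patches = 4, min_patch_sep_px = 8, seed = 14)
  sim <- simulate_apb_experiment(sc, acquisition_config(E_true = 0.08, rng_seed = 14))
  db <- subtract_background(sim$donor, sc$background_level)
  dpre <- average_phase_frames(db, "pre"); dpost <- average_phase_frames(db, "post")
  cyto <- roi_oval(sc$cell_center[1], sc$cell_center[2], 6, role = "cytoplasm")
  sf <- stage_resolved_fret(
    tibble::tibble(x = sc$patch_centers[, 1], y = sc$patch_centers[, 2]),
    dpre, dpost, NULL, cyto)
  thr <- mean(dpre[rasterize_roi(cyto, dim(dpre))])
  for (i in 1:4) {
    mask <- rasterize_roi(roi_oval(sc$patch_centers[i, 1], sc$patch_centers[i, 2], 2),
                          dim(dpre))
    ref <- compute_fret_efficiency(dpre, dpost, mask, thr, min_pixels = 3)
    expect_identical(sf$patches$E_raw_pct[i], ref$E_raw_pct)
  }
})
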