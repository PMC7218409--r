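test_that("forward model: no quenching and no bleaching leave donor unchanged", {
  sc <- tiny_scene(seed = 3)
  cfg <- acquisition_config(E_true = 0, delta_struct = 0, beta_bleach = 0)
  pre <- render_expected_image(sc, "donor", "pre", cfg, 1)
  post <- render_expected_image(sc, "donor", "post", cfg, 1)
  expect_identical(pre, post)
  # ...and frame-by-frame across the whole series
  for (i in seq_len(cfg$n_post_donor)) {
    expect_equal(render_expected_image(sc, "donor", "pre", cfg, i),
                 render_expected_image(sc, "donor", "post", cfg, i))
  }
})

test_that("forward model: complete bleach de-quenches donor by 1/(1 - E)", {
  sc <- tiny_scene(seed = 4)
  cfg <- acquisition_config(E_true = 0.10, beta_bleach = 1, delta_struct = 0)
  pre <- render_expected_image(sc, "donor", "pre", cfg, 1)
  post <- render_expected_image(sc, "donor", "post", cfg, 1)
  m <- cell_mask(sc)
  in_cell <- (pre - sc$background_level)[m]
  ratio <- (post - sc$background_level)[m] / in_cell
  expect_true(all(abs(ratio - 1 / 0.9) < 1e-9))
})

test_that("rendered pixel sums match the closed-form spot integral", {
  # one patch centred well inside the grid: the pixel-integrated Gaussian
  # sums to the amplitude, analytically truncated at the image border
  sc <- cell_scene(shape = c(41L, 41L), patch_centers = matrix(c(20, 20), 1),
                   patch_amplitude_donor = 1234, cytoplasm_level = 0,
                   background_level = 7, psf_sigma_px = 1.1,
                   cell_radii = c(19, 19))
  cfg <- acquisition_config(E_true = 0, delta_struct = 0)
  img <- render_expected_image(sc, "donor", "pre", cfg, 1)
  s <- sc$psf_sigma_px
  frac <- (stats::pnorm((40 + 0.5 - 20) / s) - stats::pnorm((-0.5 - 20) / s))^2
  expect_equal(sum(img), 1234 * frac + 41^2 * 7, tolerance = 1e-12)
})

test_that("noise model matches its stated mean and variance law", {
  cfg1 <- acquisition_config(read_noise_sd = 0, em_gain_factor = 1)
  img <- matrix(10000, 100, 100)
  noisy <- apply_noise(img, cfg1, seed = 11)
  expect_lt(abs(mean(noisy) - 10000) / 10000, 0.01)
  # variance at mean 100 with excess-noise factor 2 and read noise 5
  cfg2 <- acquisition_config(read_noise_sd = 5, em_gain_factor = 2)
  noisy2 <- apply_noise(matrix(100, 320, 320), cfg2, seed = 12)
  expect_lt(abs(stats::var(as.numeric(noisy2)) - (400 + 25)) / 425, 0.05)
})

test_that("noise is bit-identical under the same seed", {
  cfg <- acquisition_config()
  img <- matrix(200, 30, 30)
  expect_identical(apply_noise(img, cfg, seed = 99), apply_noise(img, cfg, seed = 99))
  sc <- tiny_scene(seed = 5)
  s1 <- simulate_apb_experiment(sc, cfg)
  s2 <- simulate_apb_experiment(sc, cfg)
  expect_identical(s1$donor$frames, s2$donor$frames)
  expect_identical(s1$acceptor$frames, s2$acceptor$frames)
})

test_that("apb series has the protocol's frame ordering and counts", {
  sc <- tiny_scene(seed = 6)
  cfg <- acquisition_config(n_pre_donor = 3, n_post_donor = 3)
  sim <- simulate_apb_experiment(sc, cfg)
  expect_length(sim$donor$frames, 6)
  expect_identical(sim$donor$phase, c("pre", "pre", "pre", "post", "post", "post"))
  expect_identical(sim$acceptor$phase, c("pre", "pre", "post", "post"))
  expect_true(all(diff(sim$donor$time_s) > 0))
  expect_identical(sim$manifest$E_true, cfg$E_true)
})

test_that("complete bleach drops acceptor patches to background", {
  sc <- tiny_scene(seed = 7)
  cfg <- acquisition_config(beta_bleach = 1)
  post <- render_expected_image(sc, "acceptor", "post", cfg, 1)
  expect_true(all(post == sc$background_level))
})

test_that("expected donor de-quench ratio increases strictly with E_true", {
  sc <- tiny_scene(seed = 8)
  m <- cell_mask(sc)
  ratios <- sapply(c(0, 0.03, 0.08, 0.15, 0.3), function(E) {
    cfg <- acquisition_config(E_true = E, beta_bleach = 0.8, delta_struct = 0)
    pre <- render_expected_image(sc, "donor", "pre", cfg, 1)
    post <- render_expected_image(sc, "donor", "post", cfg, 1)
    mean(post[m]) / mean(pre[m])
  })
  expect_true(all(diff(ratios) > 0))
})

test_that("frap expected trace follows the recovery model exactly", {
  sc <- cell_scene(shape = c(32L, 32L), n_patches = 1,
                   patch_centers = matrix(c(16, 10), 1), cell_radii = c(14, 14))
  # immobile pool: flat at F_post0
  f0 <- frap_config(mobile_fraction = 0, bleach_depth = 0.8, delta_struct = 0,
                    duration_s = 20)
  tr0 <- simulate_frap_experiment(sc, f0)$expected_trace
  post0 <- tr0$spot_amplitude[tr0$phase == "post"]
  expect_true(all(abs(post0 - post0[1]) < 1e-9))
  expect_equal(post0[1], sc$patch_amplitude_donor * 0.2)
  # fully mobile pool returns to the pre-bleach level
  f1 <- frap_config(mobile_fraction = 1, tau_s = 2, delta_struct = 0,
                    duration_s = 60)
  tr1 <- simulate_frap_experiment(sc, f1)$expected_trace
  expect_lt(abs(utils::tail(tr1$spot_amplitude, 1) - sc$patch_amplitude_donor) /
              sc$patch_amplitude_donor, 0.01)
  # closed-form value at t = tau after the bleach
  f5 <- frap_config(mobile_fraction = 0.6, tau_s = 5, bleach_depth = 0.8,
                    delta_struct = 0, frame_interval_s = 0.5, duration_s = 30)
  tr5 <- simulate_frap_experiment(sc, f5)$expected_trace
  t_bleach <- tr5$time_s[which(tr5$phase == "post")[1]]
  A <- sc$patch_amplitude_donor
  at_tau <- tr5$spot_amplitude[tr5$time_s == t_bleach + 5]
  expect_equal(at_tau, 0.2 * A + 0.6 * 0.8 * A * (1 - exp(-1)), tolerance = 1e-12)
})

test_that("invalid scenes and configs are rejected", {
  expect_error(cell_scene(patch_centers = matrix(c(0, 0), 1)), "inside the cell")
  expect_error(cell_scene(psf_sigma_px = 0), "psf_sigma_px")
  expect_error(acquisition_config(E_true = 1), "E_true")
  expect_error(acquisition_config(beta_bleach = 1.2), "beta_bleach")
  expect_error(apply_noise(matrix(-1, 2, 2), acquisition_config()), "non-negative")
  sc <- tiny_scene()
  expect_error(render_expected_image(sc, "donor", "pre",
                                     acquisition_config(n_pre_donor = 3),
                                     frame_index = 4),
               "out of range")
})
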