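env <- flow_environment()

test_that("equipartition force is the thermal energy over variance per unit length", {
  g <- tether_geometry(bead_radius_nm = 1100, extension_nm = 900)  # l + r = 2000
  expect_equal(equipartition_force(8228, g, env), 1.000, tolerance = 1e-4)
  expect_equal(equipartition_force(2 * 8228, g, env),
               equipartition_force(8228, g, env) / 2)
  expect_error(equipartition_force(0, g, env), "positive")
  # exact linearity in the thermal energy
  hot <- flow_environment(thermal_energy = 2 * env$thermal_energy)
  expect_equal(equipartition_force(8228, g, hot),
               2 * equipartition_force(8228, g, env))
})

test_that("tether extension from in-plane displacement inverts exactly", {
  expect_equal(tether_extension_from_displacement(0, 1100), 0)
  l <- tether_extension_from_displacement(2600, 1100)
  expect_equal(l, sqrt(2600^2 + 1100^2) - 1100)
  expect_equal(l, 1723, tolerance = 1e-3)
  # round trip and asymptote
  expect_equal(tether_extension_from_displacement(
    displacement_from_tether_extension(l, 1100), 1100), l)
  r <- 50
  expect_equal(tether_extension_from_displacement(100 * r, r), 100 * r,
               tolerance = 0.01)
})

test_that("mean velocity scales inversely with channel width", {
  ch <- channel_geometry(width_um = 1000, height_um = 120)
  expect_equal(mean_velocity(0, ch), 0)
  expect_equal(mean_velocity(1, ch), 1 / (1 * 0.12), tolerance = 1e-12)
  expect_equal(mean_velocity(1, ch) /
                 mean_velocity(1, channel_geometry(5000, 120)), 5)
})

test_that("chip force scaling follows width ratios", {
  chip <- chip_layout(c(500, 1000, 1500, 2000, 2500), 120)
  expect_equal(channel_force_scale(chip), c(1, 1/2, 1/3, 1/4, 1/5))
  expect_equal(channel_force_scale(chip_layout(750, 60)), 1)
  # conservation: factor x width is constant
  expect_equal(channel_force_scale(chip) * chip$channels$width_um,
               rep(500, 5))
  expect_error(channel_force_scale(chip, 9), "out of range")
})

test_that("through-origin calibration fit recovers exact and noisy slopes", {
  v <- c(1, 2, 3, 4)
  fit <- fit_calibration(tibble::tibble(velocity_mm_s = v, force_pn = 1.4 * v))
  expect_equal(fit$model$slope_pn_s_mm, 1.4, tolerance = 1e-12)
  one <- fit_calibration(tibble::tibble(velocity_mm_s = 2, force_pn = 2.8))
  expect_equal(one$model$slope_pn_s_mm, 1.4)
  set.seed(8)
  noisy <- tibble::tibble(velocity_mm_s = rep(v, length.out = 30),
                          force_pn = 1.4 * velocity_mm_s *
                            (1 + stats::rnorm(30, sd = 0.1)))
  expect_equal(fit_calibration(noisy)$model$slope_pn_s_mm, 1.4,
               tolerance = 0.1)
  expect_error(fit_calibration(tibble::tibble(velocity_mm_s = c(0, 0),
                                              force_pn = c(0, 0))),
               "degenerate")
  # free-intercept variant reports an intercept diagnostic
  fi <- fit_calibration(noisy, intercept = TRUE)
  expect_true("(Intercept)" %in% tidy(fi)$term)
})

test_that("corner frequency scales with force and ignores thermal energy", {
  g <- tether_geometry(bead_radius_nm = 1100, extension_nm = 900)
  f1 <- lorentzian_corner_frequency(1, g, env)
  # dimensional oracle: kappa/(2 pi gamma), gamma = 6 pi eta r in pN s/nm
  gamma <- 6 * pi * 1e-3 * 1100 * 1e-6
  expect_equal(f1, (1 / 2000) / (2 * pi * gamma))
  expect_equal(lorentzian_corner_frequency(2, g, env), 2 * f1)
  expect_equal(lorentzian_corner_frequency(1, g, flow_environment(8.2)), f1)
})

test_that("simulated fluctuation records close the calibration loop", {
  g <- tether_geometry(bead_radius_nm = 1100, extension_nm = 800)
  for (f in c(0.2, 0.5, 1.0)) {
    tau <- 6 * pi * 1e-3 * 1100 * 1e-6 * 1900 / f
    fc <- lorentzian_corner_frequency(f, g, env)
    rec <- simulate_tethered_bead(f, g, env,
                                  sampling_frequency_hz = 10 * fc,
                                  duration_s = 2000 * tau,
                                  seed = round(10 * f))
    est <- equipartition_force(fluctuation_variance(rec), g, env)
    expect_equal(est, f, tolerance = 0.1)
  }
})

test_that("calibration slope round trip recovers the generating coefficient", {
  g <- tether_geometry(bead_radius_nm = 1100, extension_nm = 800)
  c_true <- 1.4
  set.seed(21)
  gamma <- 6 * pi * 1e-3 * 1100 * 1e-6
  rows <- purrr::map_dfr(c(0.1, 0.2, 0.4, 0.7), function(v) {
    f <- c_true * v
    tau <- gamma * 1900 / f
    purrr::map_dfr(1:8, function(b) {
      rec <- simulate_tethered_bead(f, g, env, sampling_frequency_hz = 20,
                                    duration_s = 220 * tau)
      tibble::tibble(velocity_mm_s = v,
                     force_pn = equipartition_force(fluctuation_variance(rec),
                                                    g, env))
    })
  })
  fit <- fit_calibration(rows, valid_bead_radius_nm = 1100,
                         valid_tether_length_nm = 800,
                         valid_channel_height_um = 120)
  expect_equal(fit$model$slope_pn_s_mm, c_true, tolerance = 0.1)
  expect_equal(fit$model$valid_channel_height_um, 120)
})
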