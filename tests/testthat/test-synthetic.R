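env <- flow_environment()

test_that("tethered-bead simulator honours the equipartition variance", {
  g <- tether_geometry(bead_radius_nm = 1100, extension_nm = 900)  # l+r = 2000
  rec <- simulate_tethered_bead(1, g, env, sampling_frequency_hz = 50,
                                duration_s = 120, seed = 1)
  expect_equal(fluctuation_variance(rec), 8228, tolerance = 0.05)
  # 1/F equipartition scaling at high force
  rec_hi <- simulate_tethered_bead(100, g, env, sampling_frequency_hz = 5000,
                                   duration_s = 1.2, seed = 2)
  ratio <- fluctuation_variance(rec) / fluctuation_variance(rec_hi)
  expect_equal(ratio, 100, tolerance = 0.1)
  # determinism
  expect_identical(
    simulate_tethered_bead(1, g, env, 50, 10, seed = 9)$dy_nm,
    simulate_tethered_bead(1, g, env, 50, 10, seed = 9)$dy_nm)
  expect_error(simulate_tethered_bead(1, g, env, 10, 1), "100 samples")
})

test_that("under-sampled records carry an aliasing warning", {
  g <- tether_geometry(bead_radius_nm = 1100, extension_nm = 900)
  fc <- lorentzian_corner_frequency(50, g, env)
  expect_warning(
    rec <- simulate_tethered_bead(50, g, env, sampling_frequency_hz = fc,
                                  duration_s = 200 / fc, seed = 1),
    "aliased")
  expect_true(attr(rec, "aliasing"))
})

test_that("rendered movies honour their construction", {
  tr <- tibble::tibble(bead_id = 1, frame = 1:4, y_px = 16.3, x_px = 14.7)
  mov <- render_bead_movie(tr, field_dim = c(32, 32), bead_radius_px = 3)
  # static bead, zero noise: frames pixel-identical
  for (k in 2:4) expect_identical(mov[, , k], mov[, , 1])
  # constructed dropout: area above threshold before, zero after
  tr2 <- tibble::tibble(bead_id = 1, frame = 1:6, y_px = 16, x_px = 16,
                        present = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  mov2 <- render_bead_movie(tr2, field_dim = c(32, 32), bead_radius_px = 3)
  areas <- apply(mov2 > 0.4, 3, sum)
  expect_true(all(areas[1:3] > 10))
  expect_true(all(areas[4:6] == 0))
  # positions outside the field are rejected; collisions warn
  expect_error(render_bead_movie(tibble::tibble(bead_id = 1, frame = 1,
                                                y_px = 40, x_px = 2),
                                 field_dim = c(32, 32)),
               "inside the field")
  expect_warning(render_bead_movie(
    tibble::tibble(bead_id = 1:2, frame = 1, y_px = c(16, 18), x_px = 16),
    field_dim = c(32, 32), bead_radius_px = 3), "collide")
})

test_that("registration recovers a rendered sub-pixel shift", {
  tr <- tibble::tibble(bead_id = 1, frame = 1:2, y_px = c(16, 16),
                       x_px = c(14, 14 + 3.40))
  mov <- render_bead_movie(tr, field_dim = c(32, 32), bead_radius_px = 3)
  d <- subpixel_displacement(mov[, , 2], mov[, , 1], upsample_factor = 100)
  expect_equal(d[["dx"]], 3.40, tolerance = 0.02)
  expect_equal(d[["dy"]], 0, tolerance = 0.02)
})

test_that("rupture-experiment loading rates scale inversely with width", {
  chip <- chip_layout(c(500, 1000), 120)
  prot <- loading_protocol(ramp_mm3_s2 = 0.01, duration_s = 600)
  tab <- simulate_rupture_experiment(chip, calibration_model(1.4), prot,
                                     dig_landscape(), env, 5, seed = 1)
  rates <- unique(tab[, c("channel_index", "loading_rate_pn_s")])
  expect_equal(rates$loading_rate_pn_s[1] / rates$loading_rate_pn_s[2], 2)
  # conservation: f_dot * width constant across channels
  expect_equal(length(unique(tab$loading_rate_pn_s * tab$width_um)), 1L)
  expect_error(
    simulate_rupture_experiment(chip, calibration_model(1.4),
                                loading_protocol(q0_mm3_s = 1, ramp_mm3_s2 = 0,
                                                 duration_s = 10),
                                dig_landscape(), env, 5),
    "ramp")
})

test_that("median rupture flow rate increases with channel width", {
  chip <- chip_layout(c(250, 500, 750, 1000), 60)
  prot <- loading_protocol(ramp_mm3_s2 = 0.002, duration_s = 1e6)
  tab <- simulate_rupture_experiment(chip, calibration_model(3.0), prot,
                                     dig_landscape(), env, 500, seed = 4)
  med <- tapply(tab$rupture_flow_rate_mm3_s, tab$channel_index, stats::median)
  expect_true(all(diff(med) > 0))
  # single bead, fixed seed: reproducible
  one1 <- simulate_rupture_experiment(chip, calibration_model(3.0), prot,
                                      dig_landscape(), env, 1, seed = 5)
  one2 <- simulate_rupture_experiment(chip, calibration_model(3.0), prot,
                                      dig_landscape(), env, 1, seed = 5)
  expect_identical(one1, one2)
})

test_that("survival simulator draws competing exponentials with censoring", {
  rec <- simulate_survival(1e-4, 1e-3, n_beads = 2000,
                           observation_time_s = 2e4, seed = 1)
  fit <- fit_removal_rate(rec)
  expect_equal(fit$rate, 1.1e-3, tolerance = 0.05)
  # KS test of the uncensored part against the total-rate exponential
  obs <- rec$removal_time_s[!rec$censored]
  ks <- suppressWarnings(stats::ks.test(obs, function(q) {
    stats::pexp(q, 1.1e-3) / stats::pexp(2e4, 1.1e-3)
  }))
  expect_gt(ks$p.value, 0.01)
  # degenerate cases
  empty <- simulate_survival(1e-4, 1e-3, n_beads = 0, observation_time_s = 10)
  expect_equal(nrow(empty), 0)
  expect_warning(allc <- simulate_survival(0, 0, 5, 100), "censored")
  expect_true(all(allc$censored))
})
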