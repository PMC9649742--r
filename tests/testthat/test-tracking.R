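env <- flow_environment()

test_that("bead detection finds rendered beads and flags merges", {
  expect_equal(nrow(detect_beads(matrix(0, 32, 32))), 0)
  tr <- tidyr::crossing(bead_id = 1:10, frame = 1) |>
    dplyr::mutate(y_px = rep(seq(15, 105, by = 10), length.out = 10)[bead_id],
                  x_px = rep(c(20, 60), 5)[bead_id])
  mov <- render_bead_movie(tr, field_dim = c(120, 80), bead_radius_px = 3)
  det <- detect_beads(mov[, , 1])
  expect_equal(nrow(det), 10)
  found <- det[order(det$y_px, det$x_px), ]
  truth <- tr[order(tr$y_px, tr$x_px), ]
  expect_lt(max(abs(found$y_px - truth$y_px)), 0.5)
  expect_lt(max(abs(found$x_px - truth$x_px)), 0.5)
  # a merged pair among well-separated singles is flagged by its area
  tr2 <- tibble::tibble(bead_id = 1:8, frame = 1,
                        y_px = c(20, 24, 60, 90, 20, 60, 90, 40),
                        x_px = c(30, 30, 30, 30, 70, 70, 70, 70))
  mov2 <- suppressWarnings(render_bead_movie(tr2, field_dim = c(110, 100),
                                             bead_radius_px = 3))
  det2 <- detect_beads(mov2[, , 1])
  expect_equal(nrow(det2), 7)  # the touching pair merges into one component
  expect_equal(sum(det2$merged), 1L)
})

test_that("sub-pixel registration is exact on identical windows and accurate on shifts", {
  ref <- bead_image(32, 16, 16)
  expect_equal(subpixel_displacement(ref, ref, 50), c(dx = 0, dy = 0))
  win <- bead_image(32, 16 - 1.25, 16 + 3.40)
  d <- subpixel_displacement(win, ref, 100)
  expect_equal(d[["dx"]], 3.40, tolerance = 0.05 / 3.4)
  expect_equal(d[["dy"]], -1.25, tolerance = 0.05 / 1.25)
  expect_error(subpixel_displacement(matrix(1, 16, 16), ref[1:16, 1:16]),
               "flat")
})

test_that("localized upsampled refinement equals full-grid upsampling", {
  set.seed(31)
  ref <- bead_image(24, 12, 12)
  for (i in 1:10) {
    win <- bead_image(24, 12 + stats::runif(1, -3, 3),
                      12 + stats::runif(1, -3, 3))
    loc <- subpixel_displacement(win, ref, upsample_factor = 8)
    full <- brute_force_displacement(win, ref, usfac = 8)
    expect_equal(loc, full, tolerance = 1e-6)
  }
})

test_that("registration stays accurate under image noise", {
  set.seed(32)
  shifts <- cbind(dx = stats::runif(10, -2, 2), dy = stats::runif(10, -2, 2))
  # 5% of the 0.8 peak on the tracked window, clean reference: <= 0.1 px each
  errs_clean_ref <- vapply(1:10, function(i) {
    ref <- bead_image(32, 16, 16)
    win <- bead_image(32, 16 + shifts[i, "dy"], 16 + shifts[i, "dx"]) +
      matrix(stats::rnorm(1024, sd = 0.04), 32, 32)
    max(abs(subpixel_displacement(win, ref, 20) - shifts[i, c("dx", "dy")]))
  }, numeric(1))
  expect_lt(max(errs_clean_ref), 0.1)
  # both windows noisy (as in frame-zero referencing): 0.1 px on average
  errs_both <- vapply(1:10, function(i) {
    ref <- bead_image(32, 16, 16) +
      matrix(stats::rnorm(1024, sd = 0.04), 32, 32)
    win <- bead_image(32, 16 + shifts[i, "dy"], 16 + shifts[i, "dx"]) +
      matrix(stats::rnorm(1024, sd = 0.04), 32, 32)
    max(abs(subpixel_displacement(win, ref, 20) - shifts[i, c("dx", "dy")]))
  }, numeric(1))
  expect_lt(mean(errs_both), 0.1)
})

test_that("tethered-bead selection applies the bidirectional threshold strictly", {
  mk <- function(ids, exc) {
    dplyr::bind_rows(lapply(seq_along(ids), function(i) {
      tibble::tibble(bead_id = ids[i], x_um = c(0, exc[i]), y_um = 0)
    }))
  }
  # 50 tethered (2.6 um) + 50 stuck (0.1 um)
  exc <- c(rep(2.6, 50), rep(0.1, 50))
  sel <- select_tethered_beads(mk(1:100, exc), mk(1:100, exc))
  expect_equal(sort(sel), 1:50)
  # exactly at threshold: rejected (strict inequality)
  sel2 <- select_tethered_beads(mk(1:2, c(2.0, 2.5)), mk(1:2, c(2.5, 2.5)))
  expect_equal(as.integer(sel2), 2L)
  # sub-threshold in one direction only: rejected
  sel3 <- select_tethered_beads(mk(1:2, c(2.5, 2.5)), mk(1:2, c(0.5, 2.5)))
  expect_equal(as.integer(sel3), 2L)
  # orphans rejected by default, error on request
  sel4 <- select_tethered_beads(mk(1:3, rep(2.5, 3)), mk(1:2, rep(2.5, 2)))
  expect_equal(sort(as.integer(sel4)), 1:2)
  expect_equal(attr(sel4, "rejected")$reason, "orphan")
  expect_error(select_tethered_beads(mk(1:3, rep(2.5, 3)),
                                     mk(1:2, rep(2.5, 2)),
                                     on_orphan = "error"), "only one flow")
  # permutation invariance in bead ordering
  perm <- sample(100)
  f <- mk(1:100, exc)
  selp <- select_tethered_beads(f[order(match(f$bead_id, perm)), ],
                                mk(1:100, exc))
  expect_setequal(selp, sel)
})

test_that("rupture detection reads the ramp flow rate at area dropout", {
  prot <- loading_protocol(ramp_mm3_s2 = 0.1, duration_s = 200)
  area <- c(rep(30L, 119), rep(0L, 81))
  track <- tibble::tibble(bead_id = "b1", time_s = 0:199, area_px = area)
  r <- detect_rupture(track, prot)
  expect_false(r$censored)
  expect_equal(r$rupture_flow_rate_mm3_s, 0.1 * 119)
  # never drops: censored at the final flow rate
  track2 <- tibble::tibble(bead_id = "b2", time_s = 0:199, area_px = 30L)
  r2 <- detect_rupture(track2, prot)
  expect_true(r2$censored)
  expect_equal(r2$rupture_flow_rate_mm3_s, 0.1 * 199)
  expect_error(detect_rupture(tibble::tibble(bead_id = "b3", time_s = 0:9,
                                             area_px = 0L), prot),
               "never detected")
})

test_that("movie -> tracks -> rupture table reproduces the generator", {
  chip <- chip_layout(250, 60)
  prot <- loading_protocol(ramp_mm3_s2 = 0.01, duration_s = 120)
  ex <- simulate_rupture_experiment(chip, calibration_model(3.0), prot,
                                    dig_landscape(), env, 100, seed = 2)
  sm <- simulate_rupture_movie(ex, prot, frame_interval_s = 1,
                               field_dim = c(320, 320), bead_radius_px = 3,
                               noise_sd = 0.02, seed = 3)
  tracks <- track_beads(sm$movie, pixel_size_nm = 65,
                        frame_times_s = sm$frame_times_s)
  expect_equal(length(unique(tracks$bead_id)), 100)
  rec <- detect_ruptures(tracks, prot)
  q_truth <- sort(pmin(sm$experiment$rupture_flow_rate_mm3_s,
                       prot$flow_rate(prot$duration_s)))
  dq <- prot$ramp_mm3_s2 * 1  # one frame's flow increment
  agree <- abs(sort(rec$rupture_flow_rate_mm3_s) - q_truth) <= dq + 1e-9
  expect_gte(mean(agree), 0.99)
  expect_equal(sum(rec$censored), sum(sm$experiment$censored))
})
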