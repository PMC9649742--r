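env <- flow_environment()

test_that("empirical CDF uses i/n plotting positions with ties at the top", {
  ec <- empirical_cdf(c(1, 2, 3))
  expect_equal(ec$prob, c(1, 2, 3) / 3)
  # ties share the highest position of their run
  ec2 <- empirical_cdf(c(1, 2, 2, 3))
  expect_equal(ec2$force_pn, c(1, 2, 3))
  expect_equal(ec2$prob, c(0.25, 0.75, 1))
  # large-sample ECDF tracks the exact CDF within the 1% KS band
  s <- sample_rupture_forces(dig_landscape(), 0.5, env, 1e4, seed = 13)
  ec3 <- empirical_cdf(s)
  gap <- max(abs(ec3$prob - rupture_cdf(ec3$force_pn, dig_landscape(), 0.5, env)))
  expect_lt(gap, 1.63 / sqrt(1e4))
  # binned variant accumulates to 1
  ecb <- empirical_cdf(s, binned = TRUE, bin_width_pn = 1)
  expect_equal(max(ecb$prob), 1)
  expect_true(all(diff(ecb$prob) >= 0))
})

test_that("CDF fitting recovers the sampling landscape", {
  dig <- dig_landscape()
  s <- sample_rupture_forces(dig, 0.5, env, 2000, seed = 17)
  fit <- fit_rupture_cdf(rupture_dataset(s, 0.5), env)
  expect_equal(fit$landscape$delta_x, 0.76, tolerance = 0.15)
  expect_lt(abs(log10(fit$landscape$k_off) - log10(4e-4)), 0.5)
  expect_error(fit_rupture_cdf(rupture_dataset(s[1:10], 0.5), env),
               "at least 20")
})

test_that("noiseless quantile data is recovered to optimizer precision", {
  dig <- dig_landscape()
  p <- (1:199) / 200
  q <- quantile_rupture(p, dig, 0.5, env)
  fit <- fit_rupture_cdf(rupture_dataset(q, 0.5), env, probs = p)
  expect_equal(fit$landscape$delta_x, 0.76, tolerance = 1e-4)
  expect_equal(fit$landscape$k_off, 4e-4, tolerance = 1e-4)
  expect_equal(fit$f_star, most_probable_force(dig, 0.5, env),
               tolerance = 1e-4)
})

test_that("series-method fitting agrees with exact-method fitting", {
  dig <- dig_landscape()
  s <- sample_rupture_forces(dig, 0.5, env, 2000, seed = 19)
  fe <- fit_rupture_cdf(rupture_dataset(s, 0.5), env, method = "exact")
  fs <- fit_rupture_cdf(rupture_dataset(s, 0.5), env, method = "series")
  expect_equal(fs$landscape$delta_x, fe$landscape$delta_x, tolerance = 0.02)
})

test_that("subgroup partition is disjoint, exhaustive and near-equal", {
  dig <- dig_landscape()
  s <- sample_rupture_forces(dig, 0.5, env, 3000, seed = 23)
  sg <- subgroup_statistics(rupture_dataset(s, 0.5), env, seed = 1)
  expect_equal(sum(sg$groups$n), 3000)
  expect_lte(diff(range(sg$groups$n)), 1)
  expect_lt(sg$f_star_sd, 1)  # pN
  expect_equal(sg$f_star_mean, most_probable_force(dig, 0.5, env),
               tolerance = 0.05)
  # reproducible partition under seed
  sg2 <- subgroup_statistics(rupture_dataset(s, 0.5), env, seed = 1)
  expect_equal(sg$groups, sg2$groups)
  expect_error(subgroup_statistics(rupture_dataset(s[1:50], 0.5), env),
               "n_groups")
})

test_that("global regression inverts the Evans-Ritchie line exactly", {
  truth <- energy_landscape(1e-4, 1.0)
  rates <- c(0.5, 1.5, 5)
  pts <- tibble::tibble(
    f_dot = rates,
    f_star = vapply(rates, function(fd) most_probable_force(truth, fd, env),
                    numeric(1)))
  fit <- fit_force_vs_loading_rate(pts, env)
  expect_equal(fit$landscape$delta_x, 1.0, tolerance = 1e-9)
  expect_equal(fit$landscape$k_off, 1e-4, tolerance = 1e-9)
  # serial-bond algebra: generate at N = 3, fit at N = 3 -> same; at N = 1 ->
  # k_off biased by exactly 3
  pts3 <- tibble::tibble(
    f_dot = rates,
    f_star = vapply(rates, function(fd) {
      most_probable_force(truth, fd, env, n_serial = 3)
    }, numeric(1)))
  fit3 <- fit_force_vs_loading_rate(pts3, env, n_serial = 3)
  expect_equal(fit3$landscape$k_off, 1e-4, tolerance = 1e-9)
  expect_equal(fit3$landscape$delta_x, 1.0, tolerance = 1e-9)
  fit1 <- fit_force_vs_loading_rate(pts3, env, n_serial = 1)
  expect_equal(fit1$landscape$k_off / 1e-4, 3, tolerance = 1e-9)
  # order invariance
  fit_rev <- fit_force_vs_loading_rate(pts[3:1, ], env)
  expect_equal(fit_rev$landscape, fit$landscape)
  # model violation
  bad <- tibble::tibble(f_dot = c(0.5, 5), f_star = c(30, 20))
  expect_error(fit_force_vs_loading_rate(bad, env), "slope")
  expect_error(fit_force_vs_loading_rate(pts[1, ], env), "distinct")
})

test_that("doubling the loading rate shifts the fitted F* by kBT/dX ln 2", {
  dig <- dig_landscape()
  f1 <- fit_rupture_cdf(
    rupture_dataset(sample_rupture_forces(dig, 0.5, env, 2000, seed = 29), 0.5),
    env)
  f2 <- fit_rupture_cdf(
    rupture_dataset(sample_rupture_forces(dig, 1.0, env, 2000, seed = 30), 1.0),
    env)
  shift <- env$thermal_energy / dig$delta_x * log(2)
  expect_equal(f2$f_star - f1$f_star, shift, tolerance = 0.25)
})

test_that("single-bond projection sits above the serial curve by kBT/dX ln N", {
  ls <- energy_landscape(4.7e-6, 0.95)
  grid <- c(0.5, 1, 2, 5)
  single <- project_single_bond(ls, env, grid)
  expect_true(all(diff(single$f_star) > 0))
  expect_false(any(single$flagged))
  serial <- vapply(grid, function(fd) {
    most_probable_force(ls, fd, env, n_serial = 3)
  }, numeric(1))
  expect_equal(single$f_star - serial,
               rep(env$thermal_energy / 0.95 * log(3), 4))
  # cross-check one point against the density-mode oracle
  expect_equal(single$f_star[single$f_dot == 1],
               grid_mode_oracle(ls, 1, env, upper = 80), tolerance = 1e-3)
})

test_that("the sample-to-landscape pipeline recovers published-scale parameter sets", {
  cases <- list(
    list(ls = energy_landscape(4.0e-4, 0.76), rates = c(0.5, 1.5, 5.0)),
    list(ls = energy_landscape(2.2e-4, 4.1), rates = c(0.02, 0.2, 2))
  )
  for (case in cases) {
    ds <- lapply(seq_along(case$rates), function(i) {
      rupture_dataset(
        sample_rupture_forces(case$ls, case$rates[i], env, 2000,
                              seed = 100 + i),
        case$rates[i])
    })
    fit <- fit_dfs(ds, env, seed = 7)
    expect_equal(fit$global$landscape$delta_x, case$ls$delta_x,
                 tolerance = 0.15)
    expect_lt(abs(log10(fit$global$landscape$k_off) - log10(case$ls$k_off)),
              0.5)
    expect_true(all(fit$per_rate$f_star_sd >= 0))
  }
})
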