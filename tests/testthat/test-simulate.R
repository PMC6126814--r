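# Synthetic-data generators: exact limits, event statistics, determinism.

test_that("noiseless circular motion traces an exact circle of radius v/psi", {
  ts <- simulate_circular_rt(sim_config(
    n_cells = 3, duration = 10, dt = 0.05, psi_value = 1, speed_mean = 20,
    speed_rel_width = 0, tumble_rate = 0, seed = 3))
  for (tr in ts$trajectories) {
    r <- fit_circle_radius(tr$x, tr$y)
    expect_lt(abs(r - 20) / 20, 1e-6)
  }
  # s = v/psi holds for heterogeneous speeds and curvatures too
  ts2 <- simulate_circular_rt(sim_config(
    n_cells = 5, duration = 10, dt = 0.05, psi_mode = "exponential",
    psi_lambda = 1, speed_mean = 20, speed_rel_width = 0.3, tumble_rate = 0,
    seed = 4))
  gt <- ts2$ground_truth
  for (i in seq_len(5)) {
    tr <- ts2$trajectories[[i]]
    expect_lt(abs(fit_circle_radius(tr$x, tr$y) - gt$v[i] / gt$psi[i]) /
                (gt$v[i] / gt$psi[i]), 1e-6)
  }
})

test_that("zero curvature, zero noise gives ballistic tracks with MSD = v^2 t^2", {
  ts <- simulate_circular_rt(sim_config(
    n_cells = 3, duration = 5, dt = 0.1, psi_value = 0, speed_mean = 10,
    speed_rel_width = 0, tumble_rate = 0, seed = 1))
  m <- empirical_msd(ts, max_lag = 1)
  expect_lt(max(abs(m$value - 100 * m$lag_s^2)), 1e-10)
})

test_that("tumble waiting times are exponential at the configured rate", {
  ts <- simulate_circular_rt(sim_config(
    n_cells = 500, duration = 100, dt = 0.1, psi_value = 0.5,
    speed_mean = 20, tumble_rate = 0.5, seed = 2))
  waits <- unlist(lapply(ts$ground_truth$tumble_times,
                         function(tt) diff(c(0, tt))))
  expect_gt(length(waits), 1000)
  se <- sd(waits) / sqrt(length(waits))
  expect_lt(abs(mean(waits) - 2.0), 3 * se)
  expect_gt(suppressWarnings(ks.test(waits, "pexp", 0.5)$p.value), 0.01)
})

test_that("per-cell speeds follow the configured Schulz distribution", {
  ts <- simulate_circular_rt(sim_config(
    n_cells = 3000, duration = 0.5, dt = 0.1, speed_mean = 25,
    speed_rel_width = 0.2, seed = 8))
  v <- ts$ground_truth$v
  expect_lt(abs(mean(v) - 25), 3 * sd(v) / sqrt(3000))
  expect_lt(abs(sd(v) / mean(v) - 0.2), 0.02)
})

test_that("identical config and seed reproduce tracks and movies bit-identically", {
  cfg <- sim_config(n_cells = 5, duration = 5, dt = 0.1, box_size = 50,
                    tumble_rate = 0.5, rot_diffusion = 0.05, seed = 9)
  t1 <- simulate_circular_rt(cfg)
  t2 <- simulate_circular_rt(cfg)
  expect_identical(t1$trajectories, t2$trajectories)
  expect_identical(t1$ground_truth, t2$ground_truth)
  opt <- optics_config(image_size = 32, pixel_size = 2, noise_sigma = 0.01)
  expect_identical(render_movie(t1, opt, seed = 2)$frames,
                   render_movie(t2, opt, seed = 2)$frames)
})

test_that("periodic wrapping keeps positions in the box and never teleports further than box_size", {
  ts <- simulate_circular_rt(sim_config(
    n_cells = 10, duration = 20, dt = 0.1, box_size = 30, speed_mean = 25,
    tumble_rate = 0.3, seed = 5))
  for (tr in ts$trajectories) {
    expect_true(all(tr$x >= 0 & tr$x < 30 & tr$y >= 0 & tr$y < 30))
    expect_true(all(abs(diff(tr$x)) <= 30 & abs(diff(tr$y)) <= 30))
  }
  # unwrapped ground truth has no jumps
  gx <- ts$ground_truth$unwrapped_x
  expect_lt(max(abs(diff(gx))), 25 * 0.1 * 1.5)
})

test_that("Brownian tracks have the right MSD, localization-noise covariance, and degenerate limits", {
  tb <- simulate_brownian(200, 100, 0.5, D = 1, seed = 4)
  m <- empirical_msd(tb, max_lag = 10, lag_stride = 4)
  slope <- sum(m$value * m$lag_s) / sum(m$lag_s^2)
  expect_lt(abs(slope / 4 - 1), 0.05)
  # static limit
  t0 <- simulate_brownian(3, 5, 0.5, D = 0, seed = 1)
  expect_equal(var(t0$trajectories[[1]]$x), 0)
  # lag-1 displacement covariance of pure localization noise is -noise^2
  tn <- simulate_brownian(300, 50, 0.5, D = 0, loc_noise = 0.1, seed = 5)
  covs <- vapply(tn$trajectories, function(tr) {
    d <- diff(tr$x)
    mean(head(d, -1) * tail(d, -1))
  }, numeric(1))
  expect_lt(abs(mean(covs) + 0.01), 0.001)
  expect_error(simulate_brownian(5, 10, 0, D = 1), "dt")
})

test_that("hook-length sampling follows the ruler line", {
  # noiseless draws sit exactly on the line
  h0 <- sample_hook_lengths(0.22, -37.9, c(405, 500), n_per = 5,
                            noise_sd = 0, seed = 1)
  expect_equal(h0$hook_length, 0.22 * h0$flik_length - 37.9)
  expect_equal(unique(h0$hook_length[h0$flik_length == 405]), 51.2,
               tolerance = 1e-12)
  # sample SD lands in the chi-square interval around the true SD
  h1 <- sample_hook_lengths(0.22, -37.9, 405, n_per = 200, noise_sd = 5,
                            seed = 2)
  expect_gt(sd(h1$hook_length), 4)
  expect_lt(sd(h1$hook_length), 6)
  expect_error(sample_hook_lengths(0.2, 0, c(-10, 405), 5, 1), "flik")
})

test_that("invalid simulation configs are rejected", {
  expect_error(sim_config(dt = 0), "dt")
  expect_error(sim_config(duration = 0.01, dt = 0.1), "duration")
  expect_error(sim_config(speed_rel_width = 1), "speed_rel_width")
  expect_error(sim_config(tumble_rate = -1), "tumble_rate")
  expect_error(sim_config(psi_mode = "exponential", psi_lambda = 0), "psi_lambda")
  expect_error(sim_config(speed_mean = NaN), "non-finite")
  expect_error(sim_config(geometry = "isotropic3d", psi_value = 1), "isotropic3d")
})
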