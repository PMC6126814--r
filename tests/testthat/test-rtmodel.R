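# Closed-form circular run-and-tumble model, empirical estimators, fitting.

test_that("single-curvature closed forms obey their exact identities", {
  expect_equal(acf_circular(0, 3.7), 1)
  expect_equal(acf_circular(1, pi), -1)
  expect_equal(acf_circular(2, 0.5), cos(1))
  expect_equal(msd_circular(0, 2, 1), 0)
  # half a revolution puts the cell at the antipode: diameter^2 = 4 s^2
  expect_equal(msd_circular(pi, 2, 1), 16)
  # short-time ballistic limit v^2 t^2
  expect_lt(abs(msd_circular(0.01, 2, 1) - 4e-4) / 4e-4, 1e-4)
  # bounded by 4 s^2 and periodic with period 2 pi / psi
  tgrid <- seq(0, 50, 0.05)
  expect_true(all(msd_circular(tgrid, 3, 0.7) <= 4 * 9 + 1e-12))
  expect_equal(msd_circular(tgrid, 3, 0.7),
               msd_circular(tgrid + 2 * pi / 0.7, 3, 0.7))
})

test_that("population-averaged ACF matches adaptive quadrature of the exponential mixture", {
  expect_equal(acf_population_exponential(0, 1), 1)
  expect_equal(acf_population_exponential(2, 2), 0.5)
  for (lam in c(0.1, 1, 10)) {
    tg <- c(0, 0.3, 1, 3, 10, 31.6, 100)
    quad <- vapply(tg, quad_cos_exp, numeric(1), lam = lam)
    expect_lt(max(abs(acf_population_exponential(tg, lam) - quad)), 1e-8)
  }
  # algebraic tail: decays like lam^2/t^2 and never crosses zero
  expect_true(all(acf_population_exponential(10^(0:4), 0.5) > 0))
  expect_equal(acf_population_exponential(1e4, 0.5) * 1e8 / 0.25, 1,
               tolerance = 1e-6)
  expect_error(acf_population_exponential(1, 0), "lam")
})

test_that("run-and-tumble ACF reduces to its limiting cases", {
  tg <- seq(0, 10, 0.1)
  expect_equal(acf_circular_rt(tg, 1.3, 0), acf_circular(tg, 1.3))
  expect_equal(acf_circular_rt(tg, 0, 0.5), exp(-0.5 * tg))
  expect_error(acf_circular_rt(1, 1, -0.1), "tumble_rate")
})

test_that("empirical ACF reproduces exact geometric cases", {
  tt <- seq(0, 10, 0.1)
  straight <- trajectory(tt, 5 * tt, rep(0, length(tt)))
  a <- empirical_acf(straight, max_lag = 2)
  expect_equal(a$value, rep(1, nrow(a)))
  expect_equal(a$value[1], 1)  # zero-lag identity
  # heading flips every frame: ACF at one lag is -1
  rev <- trajectory(tt, rep(c(0, 1), length.out = length(tt)), rep(0, length(tt)))
  ar <- empirical_acf(rev, max_lag = 0.1)
  expect_equal(ar$value[ar$lag_s > 0], -1)
  # exact circle: ACF(t) = cos(psi t) exactly for chord headings
  ts <- simulate_circular_rt(sim_config(
    n_cells = 1, duration = 10, dt = 0.05, psi_value = 1, speed_mean = 20,
    speed_rel_width = 0, tumble_rate = 0, seed = 1))
  ac <- empirical_acf(ts$trajectories[[1]], max_lag = 3)
  expect_lt(max(abs(ac$value - cos(ac$lag_s))), 1e-12)
})

test_that("empirical MSD handles static, ballistic and Brownian references", {
  tt <- seq(0, 10, 0.1)
  static <- trajectory(tt, rep(1, length(tt)), rep(1, length(tt)))
  expect_true(all(empirical_msd(static, max_lag = 2)$value == 0))
  ball <- trajectory(tt, 7 * tt, rep(0, length(tt)))
  mb <- empirical_msd(ball, max_lag = 2)
  expect_equal(mb$value, 49 * mb$lag_s^2, tolerance = 1e-12)
  tb <- simulate_brownian(300, 50, 0.25, D = 1, seed = 3)
  m <- empirical_msd(tb, max_lag = 5, lag_stride = 4)
  slope <- sum(m$value * m$lag_s) / sum(m$lag_s^2)
  expect_lt(abs(slope / 4 - 1), 0.05)
  expect_warning(empirical_msd(static, max_lag = 100), "truncat")
})

test_that("fitting a noiseless cosine ACF is exact to 1e-6", {
  lag <- seq(0, 8, 0.1)
  a <- motilitykit:::correlation_curve(lag, cos(0.8 * lag),
                                       rep(1000, length(lag)), "acf")
  m <- motilitykit:::correlation_curve(lag, (20 * lag)^2,
                                       rep(1000, length(lag)), "msd")
  f <- fit_circular_rt(a, m)
  expect_lt(abs(f$psi - 0.8), 1e-6)
  expect_lt(f$tumble_rate, 1e-4)
  expect_equal(f$v, 20, tolerance = 1e-9)
  expect_equal(f$s, 25, tolerance = 1e-4)
  expect_equal(predict(f, lag), f$fitted, tolerance = 1e-9)
})

test_that("fitting is scale-equivariant in space", {
  ts <- simulate_circular_rt(sim_config(
    n_cells = 200, duration = 20, dt = 0.1, psi_value = 1, speed_mean = 20,
    speed_rel_width = 0.1, tumble_rate = 0.3, seed = 12))
  a <- empirical_acf(ts, max_lag = 5)
  m <- empirical_msd(ts, max_lag = 5)
  f1 <- fit_circular_rt(a, m)
  scaled <- track_set(lapply(ts$trajectories, function(tr)
    trajectory(tr$times, 3 * tr$x, 3 * tr$y)))
  f2 <- fit_circular_rt(empirical_acf(scaled, max_lag = 5),
                        empirical_msd(scaled, max_lag = 5))
  expect_equal(f2$psi, f1$psi, tolerance = 1e-6)
  expect_equal(f2$tumble_rate, f1$tumble_rate, tolerance = 1e-6)
  expect_equal(f2$v, 3 * f1$v, tolerance = 1e-9)
  expect_equal(f2$s, 3 * f1$s, tolerance = 1e-6)
})

test_that("increasing tumble rate decreases fitted directional persistence", {
  taus <- vapply(c(0.25, 0.5, 1), function(r) {
    s <- simulate_circular_rt(sim_config(
      n_cells = 200, duration = 100, dt = 0.1, psi_value = 0,
      speed_mean = 20, speed_rel_width = 0.1, tumble_rate = r, seed = 32))
    mean(summarize_population(s)$tau_s)
  }, numeric(1))
  expect_true(all(diff(taus) < 0))
})
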