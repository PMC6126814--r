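# DDM: structure function properties, Schulz ISF, recovery from rendered
# movies.

test_that("identical frames give a vanishing structure function", {
  fr <- array(rep(matrix(runif(32 * 32), 32, 32), 5), dim = c(32, 32, 5))
  st <- image_stack(fr, 0.5, 0.01, "phase")
  sf <- image_structure_function(st, tau_frames = c(1, 2, 4))
  expect_lt(max(abs(sf$g), na.rm = TRUE), 1e-18)
})

test_that("i.i.d. noise frames give a flat plateau at twice the noise power", {
  set.seed(5)
  sig <- 0.05
  fr <- array(abs(rnorm(64 * 64 * 128, 1, sig)), dim = c(64, 64, 128))
  st <- image_stack(fr, 0.5, 0.01, "phase")
  sf <- image_structure_function(st, tau_frames = c(1, 5, 20, 60))
  expect_lt(max(abs(sf$g / (2 * sig^2) - 1), na.rm = TRUE), 0.15)
})

test_that("g is invariant to constant offsets and quadratic under intensity scaling", {
  stack <- ddm_small_stack()
  sub <- image_stack(stack$frames[, , 1:60], stack$pixel_size,
                     stack$frame_interval, stack$modality)
  sf0 <- image_structure_function(sub, tau_frames = c(1, 5, 20))
  shifted <- image_stack(sub$frames + 3, sub$pixel_size, sub$frame_interval)
  sfs <- image_structure_function(shifted, tau_frames = c(1, 5, 20))
  expect_equal(sfs$g, sf0$g, tolerance = 1e-10)
  scaled <- image_stack(sub$frames * 2.5, sub$pixel_size, sub$frame_interval)
  sfc <- image_structure_function(scaled, tau_frames = c(1, 5, 20))
  expect_equal(sfc$g, 2.5^2 * sf0$g, tolerance = 1e-10)
})

test_that("a single drifting blob decorrelates on the Bessel scale q v tau", {
  tt <- seq(0, 5, 0.05)
  tr <- trajectory(tt, 6 + 4 * tt, rep(16, length(tt)))
  st <- render_movie(track_set(list(tr)),
                     optics_config(image_size = 64, pixel_size = 0.5,
                                   background = 0), seed = 4)
  sf <- image_structure_function(st, tau_frames = 1:40)
  for (qt in c(0.75, 1.0, 1.5)) {
    iq <- which.min(abs(sf$q - qt))
    g <- sf$g[iq, ]
    imax <- which(diff(sign(diff(g))) == -2)[1] + 1
    # first maximum of g sits at the first minimum of J0: x = 3.83
    x <- sf$q[iq] * 4 * sf$tau[imax]
    expect_lt(abs(x - 3.8317) / 3.8317, 0.15)
  }
})

test_that("the Schulz term has the right limits and matches quadrature", {
  x <- seq(0.01, 12, 0.01)
  expect_equal(schulz_isf(0, 100), 1)
  # sinc limit as the width vanishes
  Zbig <- (1 / 0.001)^2 - 1
  expect_lt(max(abs(schulz_isf(x, Zbig) - sin(x) / x)), 1e-3)
  # agrees with quadrature over a narrow Gaussian speed distribution
  s_rel <- 0.02
  Z <- 1 / s_rel^2 - 1
  xs <- seq(0.5, 10, 1.5)
  quad <- vapply(xs, function(xx)
    stats::integrate(function(v) dnorm(v, 1, s_rel) * sin(xx * v) / (xx * v),
                     1 - 6 * s_rel, 1 + 6 * s_rel, rel.tol = 1e-10)$value,
    numeric(1))
  expect_lt(max(abs(schulz_isf(xs, Z) - quad)), 1e-3)
  # exact closed form: quadrature over the Schulz (gamma) density itself
  Z2 <- 1 / 0.2^2 - 1
  quad2 <- vapply(xs, function(xx)
    stats::integrate(function(v) dgamma(v, shape = Z2 + 1, scale = 1 / (Z2 + 1)) *
                       sin(xx * v) / (xx * v), 0, Inf, rel.tol = 1e-10)$value,
    numeric(1))
  expect_lt(max(abs(schulz_isf(xs, Z2) - quad2)), 1e-8)
})

test_that("the ISF model interpolates between noise floor and full plateau", {
  g0 <- 5 * (1 - motilitykit:::isf_model(1e-9, 1, 0.1, 20, 4, 0.7)) + 2
  expect_equal(g0, 2, tolerance = 1e-6)
  ginf <- 5 * (1 - motilitykit:::isf_model(1e6, 1, 0.1, 20, 4, 0.7)) + 2
  expect_equal(ginf, 7, tolerance = 1e-4)
})

test_that("rendered straight swimmers return the simulated speed within 5%", {
  fit <- fit_isf(image_structure_function(ddm_small_stack()))
  dd <- ddm_summary(fit)
  expect_lt(abs(dd$v - 25) / 25, 0.05)
  expect_lt(abs(dd$S - 0.2), 0.1)
})

test_that("rendered Brownian blobs return a flat D(q) near truth", {
  # 40 s movie so the slowest probed decay (q = 0.6) completes in the lags
  br <- simulate_brownian(60, 40, 0.02, D = 0.4, box_size = 64, seed = 62)
  stb <- render_movie(br, optics_config(image_size = 128, pixel_size = 0.5,
                                        psf_sigma = 0.6, background = 0.05),
                      modality = "phase", seed = 64)
  fb <- suppressMessages(fit_isf(image_structure_function(stb),
                                 q_range = c(0.6, 2.2), alpha_fixed = 0))
  tb <- fb$table[fb$table$converged, ]
  expect_lt(abs(mean(tb$D) - 0.4) / 0.4, 0.10)
  expect_lt(max(tb$D) - min(tb$D), 0.4)  # flat in q
})

test_that("a 50/50 swimmer-diffuser mixture recovers the swimming fraction", {
  sw <- simulate_circular_rt(sim_config(
    n_cells = 60, duration = 10, dt = 0.01, box_size = 64, speed_mean = 25,
    speed_rel_width = 0.2, psi_value = 0, tumble_rate = 0,
    geometry = "isotropic3d", seed = 61))
  br <- simulate_brownian(60, 10, 0.01, D = 0.4, box_size = 64, seed = 62)
  mix <- track_set(c(sw$trajectories, br$trajectories), config = sw$config)
  stack <- render_movie(mix, optics_config(image_size = 128, pixel_size = 0.5,
                                           psf_sigma = 0.6, background = 0.05),
                        modality = "phase", seed = 63)
  fit <- suppressMessages(fit_isf(image_structure_function(stack)))
  tab <- fit$table[fit$table$converged, ]
  expect_lt(abs(mean(tab$alpha) - 0.5), 0.1)
})

test_that("ddm_summary forms S and R from the fitted table as specified", {
  tab <- data.frame(q = seq(0.45, 2.2, 0.1))
  tab$A <- 1; tab$B <- 0; tab$D <- 0.1
  tab$v <- 20; tab$sigma <- 4; tab$alpha <- 1
  tab$rms <- 0; tab$converged <- TRUE
  fit <- structure(list(table = tab, q_range = c(0.4, 2.2), tau = 1:30),
                   class = "isf_fit")
  dd <- ddm_summary(fit)
  expect_equal(dd$R, 1)           # constant v(q) gives exactly 1
  expect_equal(dd$v, 20)
  expect_equal(dd$S, 0.2)
  tab2 <- tab
  tab2$v[which.min(abs(tab2$q - 2 * pi / 3))] <- 22
  fit2 <- structure(list(table = tab2, q_range = c(0.4, 2.2), tau = 1:30),
                    class = "isf_fit")
  expect_equal(ddm_summary(fit2)$R, 1.1)
  expect_error(ddm_summary(fit, q_window = c(5, 6)), "window")
})
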