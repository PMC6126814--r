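# Two-state tumble classifier: training, decoding, recovery, invariances.

test_that("training converges and labels the high-turning state as tumbling", {
  m <- tumble_model_fixture()
  expect_s3_class(m, "tumble_model")
  expect_equal(rowSums(m$transition), c(swimming = 1, tumbling = 1))
  expect_gt(m$means["tumbling", "abs_ang_acc"], m$means["swimming", "abs_ang_acc"])
  for (s in 1:2) {
    ev <- eigen(m$covariances[[s]], symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev > 0))
  }
  # log-likelihood is nondecreasing along Baum-Welch
  expect_true(all(diff(m$loglik) > -1e-6))
})

test_that("smooth swimmers decode to under 2% tumbling occupancy", {
  m <- tumble_model_fixture()
  sm <- simulate_circular_rt(sim_config(
    n_cells = 60, duration = 30, dt = 0.1, psi_value = 0.5, speed_mean = 25,
    speed_rel_width = 0.2, tumble_rate = 0, rot_diffusion = 0.02,
    loc_noise = 0.1, seed = 23))
  bias <- vapply(sm$trajectories,
                 function(tr) classify_tumbles(tr, m)$tumble_bias, numeric(1))
  expect_lt(mean(bias), 0.02)
  # a noiseless straight track has tumble bias exactly 0
  tt <- seq(0, 5, 0.1)
  straight <- trajectory(tt, 25 * tt, rep(0, length(tt)))
  expect_equal(classify_tumbles(straight, m)$tumble_bias, 0)
})

test_that("tumble bias and event counts are recovered from simulated ground truth", {
  m <- tumble_model_fixture()
  ts <- simulate_circular_rt(sim_config(
    n_cells = 300, duration = 30, dt = 0.1, psi_value = 0.5, speed_mean = 25,
    speed_rel_width = 0.2, tumble_rate = 0.5, tumble_style = "finite",
    rot_diffusion = 0.02, loc_noise = 0.1, seed = 22))
  res <- lapply(ts$trajectories, classify_tumbles, model = m)
  bias <- mean(vapply(res, `[[`, numeric(1), "tumble_bias"))
  expect_lt(abs(bias - mean(ts$ground_truth$occupancy)), 0.05)
  n_det <- sum(vapply(res, function(r) nrow(r$events), integer(1)))
  n_true <- sum(ts$ground_truth$n_tumbles)
  expect_lt(abs(n_det / n_true - 1), 0.15)
})

test_that("training is invariant to trajectory order", {
  ref <- tumble_reference()
  m1 <- tumble_model_fixture()
  set.seed(99)
  perm <- sample(length(ref$trajectories))
  ref2 <- track_set(ref$trajectories[perm], config = ref$config)
  m2 <- train_tumble_model(ref2)
  expect_equal(m1$transition, m2$transition, tolerance = 1e-6)
  expect_equal(m1$means, m2$means, tolerance = 1e-6)
})

test_that("emission means agree with a k-means oracle on well-separated clusters", {
  zigzag <- function(theta, n = 200, dt = 0.1, v = 20, seed = 1) {
    set.seed(seed)
    h <- rep(c(0, theta), length.out = n - 1)
    x <- c(0, cumsum(v * dt * cos(h))) + rnorm(n, 0, 1e-3)
    y <- c(0, cumsum(v * dt * sin(h))) + rnorm(n, 0, 1e-3)
    trajectory((0:(n - 1)) * dt, x, y)
  }
  pa <- lapply(1:30, function(i) zigzag(0.02, seed = i))
  pb <- lapply(1:30, function(i) zigzag(0.9, seed = 100 + i))
  m <- suppressWarnings(train_tumble_model(track_set(c(pa, pb))))
  pooled <- do.call(rbind, lapply(c(pa, pb), function(tr)
    motilitykit:::feature_matrix(compute_frame_features(tr))))
  set.seed(1)
  km <- kmeans(pooled[, 2], centers = 2, nstart = 5)
  hi <- which.max(km$centers); lo <- which.min(km$centers)
  expect_lt(abs(m$means["tumbling", "abs_ang_acc"] - km$centers[hi]) /
              km$centers[hi], 0.10)
  expect_lt(abs(m$means["swimming", "abs_ang_acc"] - km$centers[lo]) /
              km$centers[lo], 0.10)
})

test_that("median tumble bias is nondecreasing in the simulated tumble rate", {
  m <- tumble_model_fixture()
  med <- vapply(c(0, 0.3, 1), function(rate) {
    s <- simulate_circular_rt(sim_config(
      n_cells = 80, duration = 30, dt = 0.1, psi_value = 0.5,
      speed_mean = 25, speed_rel_width = 0.2, tumble_rate = rate,
      tumble_style = "finite", rot_diffusion = 0.02, loc_noise = 0.1,
      seed = 30))
    median(vapply(s$trajectories,
                  function(tr) classify_tumbles(tr, m)$tumble_bias,
                  numeric(1)))
  }, numeric(1))
  expect_true(all(diff(med) >= 0))
  expect_gt(med[3], med[1])
})
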