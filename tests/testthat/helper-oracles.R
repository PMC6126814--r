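# Shared oracles and memoized fixtures.

# Piecewise adaptive quadrature of the population ACF integral
# int_0^Inf cos(psi t) lam exp(-lam psi) dpsi, robust to fast oscillation.
quad_cos_exp <- function(t, lam) {
  if (t < 1e-12) return(1)
  upper <- 40 / lam
  width <- min(max(2 * pi / t, upper / 200), upper)
  brk <- unique(c(seq(0, upper, by = width), upper))
  s <- 0
  for (i in seq_len(length(brk) - 1))
    s <- s + stats::integrate(function(p) cos(p * t) * lam * exp(-lam * p),
                              brk[i], brk[i + 1], rel.tol = 1e-10,
                              abs.tol = 1e-13, subdivisions = 500L)$value
  s
}

# Algebraic (Kasa) circle fit: independent oracle for circle radius.
fit_circle_radius <- function(x, y) {
  A <- cbind(2 * x, 2 * y, 1)
  s <- qr.solve(A, x^2 + y^2)
  sqrt(s[3] + s[1]^2 + s[2]^2)
}

.fixtures <- new.env(parent = emptyenv())

# Wild-type-like reference with finite-duration tumbles, plus a trained
# tumble model. Built once, reused across test files.
tumble_reference <- function() {
  if (is.null(.fixtures$ref)) {
    .fixtures$ref <- simulate_circular_rt(sim_config(
      n_cells = 150, duration = 30, dt = 0.1, psi_value = 0.5,
      speed_mean = 25, speed_rel_width = 0.2, tumble_rate = 0.5,
      tumble_style = "finite", rot_diffusion = 0.02, loc_noise = 0.1,
      seed = 21))
  }
  .fixtures$ref
}

tumble_model_fixture <- function() {
  if (is.null(.fixtures$model))
    .fixtures$model <- train_tumble_model(tumble_reference())
  .fixtures$model
}

# Small straight-swimmer movie for DDM recovery checks.
ddm_small_stack <- function() {
  if (is.null(.fixtures$ddm_stack)) {
    opt <- optics_config(image_size = 128, pixel_size = 0.5, psf_sigma = 0.6,
                         background = 0.05)
    ts <- simulate_circular_rt(sim_config(
      n_cells = 80, duration = 6, dt = 0.01, box_size = 64, speed_mean = 25,
      speed_rel_width = 0.2, psi_value = 0, tumble_rate = 0,
      geometry = "isotropic3d", seed = 42))
    .fixtures$ddm_stack <- render_movie(ts, opt, modality = "phase", seed = 43)
  }
  .fixtures$ddm_stack
}
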