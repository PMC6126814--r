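# Seeded generators for every input the analysis pipeline consumes.

#' Simulate circular run-and-tumble trajectories
#'
#' Generates a population of quasi-2D swimmers. Each cell moves at a constant
#' tangential speed `v` (drawn once per cell) along a circular arc of angular
#' velocity `psi`, so the circle radius is `s = v/psi`. The heading advances
#' by an exact rotation of `psi * dt` per frame plus Gaussian rotational noise
#' of variance `2 * rot_diffusion * dt`; in the noiseless limit trajectories
#' are exact circles. Tumbles occur as a Poisson process at `tumble_rate`:
#' waiting times are drawn in continuous time (and stored in the ground
#' truth), while the uniformly redrawn heading takes effect at the next frame
#' boundary, since positions are only reported at frame times.
#'
#' With `tumble_style = "finite"` a tumble instead lasts an exponentially
#' distributed time (mean `tumble_duration`) during which the cell slows to
#' `tumble_speed_frac` of its speed and its heading scrambles; the per-frame
#' swim/tumble state is recorded in the ground truth, which is what the
#' hidden-Markov tumble classifier is trained and scored against.
#'
#' @param config a [sim_config()].
#' @return a [track_set()] whose `ground_truth` holds per-cell speeds `v`,
#'   curvatures `psi`, tumble times, unwrapped coordinates and (finite style)
#'   the per-frame tumble occupancy matrix.
#' @examples
#' ts <- simulate_circular_rt(sim_config(n_cells = 5, duration = 10,
#'                                       psi_value = 1, seed = 7))
#' ts
#' @export
simulate_circular_rt <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_cells
  dt <- config$dt
  nf <- floor(config$duration / dt + 1e-9) + 1L   # frames
  ns <- nf - 1L                                   # steps / chords

  v <- draw_speeds(n, config$speed_mean, config$speed_rel_width)
  psi <- switch(config$psi_mode,
                fixed = rep(config$psi_value, n),
                exponential = stats::rexp(n, rate = config$psi_lambda))
  if (config$psi_signs == "mixed")
    psi <- psi * sample(c(-1, 1), n, replace = TRUE)

  if (config$geometry == "isotropic3d")
    return(simulate_isotropic3d(config, v, nf, ns))

  x <- matrix(0, nf, n); y <- matrix(0, nf, n)
  if (is.finite(config$box_size)) {
    x[1, ] <- stats::runif(n, 0, config$box_size)
    y[1, ] <- stats::runif(n, 0, config$box_size)
  }
  h <- stats::runif(n, 0, 2 * pi)

  # exact-arc chord: length v*dt*sinc(psi*dt/2), direction offset psi*dt/2
  half <- psi * dt / 2
  chord <- ifelse(psi == 0, v * dt, (2 * v / psi) * sin(half))

  noise_sd <- sqrt(2 * config$rot_diffusion * dt)
  finite_style <- config$tumble_style == "finite" && config$tumble_rate > 0
  p_start <- 1 - exp(-config$tumble_rate * dt)

  tumble_times <- vector("list", n)
  occupancy <- NULL
  n_events <- integer(n)

  if (!finite_style && config$tumble_rate > 0) {
    # continuous-time event draws, applied at the enclosing frame boundary
    redraw_at <- vector("list", ns)  # step index -> cells redrawing then
    for (cell in seq_len(n)) {
      tt <- numeric(0); t_ev <- stats::rexp(1, config$tumble_rate)
      while (t_ev <= config$duration) {
        tt <- c(tt, t_ev)
        t_ev <- t_ev + stats::rexp(1, config$tumble_rate)
      }
      tumble_times[[cell]] <- tt
      n_events[cell] <- length(tt)
      steps <- unique(pmin(ceiling(tt / dt), ns))
      for (s in steps) redraw_at[[s]] <- c(redraw_at[[s]], cell)
    }
  }
  if (finite_style) {
    occupancy <- matrix(FALSE, ns, n)
    tumbling <- rep(FALSE, n)
    t_left <- numeric(n)
  }

  for (i in seq_len(ns)) {
    sp <- chord
    if (finite_style && any(tumbling)) sp[tumbling] <- sp[tumbling] * config$tumble_speed_frac
    dir <- h + half
    x[i + 1L, ] <- x[i, ] + sp * cos(dir)
    y[i + 1L, ] <- y[i, ] + sp * sin(dir)

    # heading for the next chord
    h <- h + psi * dt
    if (noise_sd > 0) h <- h + stats::rnorm(n, 0, noise_sd)
    if (finite_style) {
      occupancy[i, ] <- tumbling
      ending <- tumbling & (t_left <= dt)
      t_left <- t_left - dt
      if (any(ending)) {
        h[ending] <- stats::runif(sum(ending), 0, 2 * pi)
        tumbling[ending] <- FALSE
      }
      scramble <- tumbling
      if (any(scramble)) h[scramble] <- stats::runif(sum(scramble), 0, 2 * pi)
      starting <- !tumbling & !ending & (stats::runif(n) < p_start)
      if (any(starting)) {
        tumbling[starting] <- TRUE
        t_left[starting] <- stats::rexp(sum(starting), 1 / config$tumble_duration)
        n_events[starting] <- n_events[starting] + 1L
        t_now <- i * dt
        for (cell in which(starting))
          tumble_times[[cell]] <- c(tumble_times[[cell]], t_now)
        h[starting] <- stats::runif(sum(starting), 0, 2 * pi)
      }
    } else if (config$tumble_rate > 0 && !is.null(redraw_at[[i]])) {
      cells <- redraw_at[[i]]
      h[cells] <- stats::runif(length(cells), 0, 2 * pi)
    }
  }

  finish_track_set(config, x, y, list(
    v = v, psi = psi, tumble_times = tumble_times, n_tumbles = n_events,
    occupancy = occupancy))
}

# Straight 3D runs with uniform-on-sphere directions, imaged in projection.
simulate_isotropic3d <- function(config, v, nf, ns) {
  n <- config$n_cells
  dt <- config$dt
  dir <- random_sphere(n)
  x <- matrix(0, nf, n); y <- matrix(0, nf, n); z <- matrix(0, nf, n)
  if (is.finite(config$box_size)) {
    x[1, ] <- stats::runif(n, 0, config$box_size)
    y[1, ] <- stats::runif(n, 0, config$box_size)
  }
  p_t <- 1 - exp(-config$tumble_rate * dt)
  tumble_times <- vector("list", n)
  n_events <- integer(n)
  for (i in seq_len(ns)) {
    x[i + 1L, ] <- x[i, ] + v * dt * dir[1, ]
    y[i + 1L, ] <- y[i, ] + v * dt * dir[2, ]
    z[i + 1L, ] <- z[i, ] + v * dt * dir[3, ]
    if (config$tumble_rate > 0) {
      tum <- stats::runif(n) < p_t
      if (any(tum)) {
        dir[, tum] <- random_sphere(sum(tum))
        n_events[tum] <- n_events[tum] + 1L
        t_now <- i * dt
        for (cell in which(tum))
          tumble_times[[cell]] <- c(tumble_times[[cell]], t_now)
      }
    }
  }
  finish_track_set(config, x, y, list(
    v = v, psi = rep(0, n), tumble_times = tumble_times,
    n_tumbles = n_events, z = z))
}

random_sphere <- function(n) {
  u <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  r <- sqrt(pmax(0, 1 - u^2))
  rbind(r * cos(phi), r * sin(phi), u)
}

draw_speeds <- function(n, mean_v, rel_width) {
  if (rel_width == 0 || mean_v == 0) return(rep(mean_v, n))
  shape <- 1 / rel_width^2           # Schulz/gamma: CV = rel_width
  stats::rgamma(n, shape = shape, scale = mean_v / shape)
}

# Package true coordinates into a track_set: reported positions get the
# periodic wrap and localization noise; ground truth keeps the clean ones.
finish_track_set <- function(config, x, y, gt) {
  nf <- nrow(x)
  times <- (seq_len(nf) - 1) * config$dt
  xr <- wrap_box(x, config$box_size)
  yr <- wrap_box(y, config$box_size)
  if (config$loc_noise > 0) {
    xr <- xr + stats::rnorm(length(xr), 0, config$loc_noise)
    yr <- yr + stats::rnorm(length(yr), 0, config$loc_noise)
  }
  trajs <- lapply(seq_len(ncol(x)), function(j) trajectory(times, xr[, j], yr[, j]))
  gt$unwrapped_x <- x
  gt$unwrapped_y <- y
  track_set(trajs, config = config, ground_truth = gt)
}

#' Simulate Brownian control trajectories
#'
#' Pure diffusion with independent Gaussian increments of variance
#' `2 * D * dt` per axis, plus optional i.i.d. localization noise on the
#' reported positions. The main fixture for validating the covariance-based
#' diffusion estimator, whose expectation is unaffected by static noise.
#'
#' @param n_cells number of tracks.
#' @param duration track duration (s).
#' @param dt frame interval (s), > 0.
#' @param D diffusion coefficient (um^2/s), >= 0.
#' @param loc_noise SD of localization noise (um).
#' @param box_size square periodic box (um); `Inf` (default) starts all
#'   tracks at the origin with no wrapping, a finite box draws uniform
#'   initial positions (use this when the tracks feed the renderer, so the
#'   imaged population is spatially uniform).
#' @param seed integer seed.
#' @return a [track_set()]; ground truth keeps the noiseless coordinates.
#' @export
simulate_brownian <- function(n_cells, duration, dt, D, loc_noise = 0,
                              box_size = Inf, seed = 1L) {
  if (!is.finite(dt) || dt <= 0) stop("simulate_brownian: dt must be > 0", call. = FALSE)
  if (!is.finite(D) || D < 0) stop("simulate_brownian: D must be >= 0", call. = FALSE)
  set.seed(as.integer(seed))
  nf <- floor(duration / dt + 1e-9) + 1L
  n <- as.integer(n_cells)
  sd_step <- sqrt(2 * D * dt)
  x <- apply(matrix(stats::rnorm((nf - 1L) * n, 0, sd_step), nf - 1L, n), 2, cumsum)
  y <- apply(matrix(stats::rnorm((nf - 1L) * n, 0, sd_step), nf - 1L, n), 2, cumsum)
  x0 <- if (is.finite(box_size)) stats::runif(n, 0, box_size) else numeric(n)
  y0 <- if (is.finite(box_size)) stats::runif(n, 0, box_size) else numeric(n)
  x <- rbind(x0, sweep(matrix(x, nf - 1L, n), 2, x0, "+"))
  y <- rbind(y0, sweep(matrix(y, nf - 1L, n), 2, y0, "+"))
  rownames(x) <- rownames(y) <- NULL
  cfg <- sim_config(n_cells = n, duration = duration, dt = dt, speed_mean = 0,
                    speed_rel_width = 0, tumble_rate = 0, loc_noise = loc_noise,
                    box_size = box_size, seed = seed)
  finish_track_set(cfg, x, y, list(D = D))
}

#' Sample hook-length measurements around a linear ruler law
#'
#' Draws synthetic hook-length measurements scattered around the molecular
#' ruler line `hook = slope * flik + intercept`, Gaussian with SD `noise_sd`
#' and truncated at positive lengths.
#'
#' @param slope ruler slope (nm per amino acid).
#' @param intercept ruler intercept (nm).
#' @param flik_lengths ruler protein lengths (amino acids), all > 0.
#' @param n_per measurements per ruler length.
#' @param noise_sd measurement SD (nm), >= 0.
#' @param seed integer seed.
#' @return a data.frame with columns `flik_length`, `hook_length`,
#'   `controlled` (all `TRUE`), carrying the ground-truth ruler as attribute
#'   `ruler`.
#' @seealso [fit_ruler()]
#' @export
sample_hook_lengths <- function(slope, intercept, flik_lengths, n_per = 30,
                                noise_sd = 3, seed = 1L) {
  if (any(flik_lengths <= 0))
    stop("sample_hook_lengths: flik_lengths must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("sample_hook_lengths: noise_sd must be >= 0", call. = FALSE)
  set.seed(as.integer(seed))
  flik <- rep(flik_lengths, each = n_per)
  mu <- slope * flik + intercept
  hook <- stats::rnorm(length(flik), mu, noise_sd)
  while (any(bad <- hook <= 0))    # truncate at positive hook lengths
    hook[bad] <- stats::rnorm(sum(bad), mu[bad], noise_sd)
  out <- data.frame(flik_length = flik, hook_length = hook, controlled = TRUE)
  attr(out, "ruler") <- list(slope = slope, intercept = intercept,
                             noise_sd = noise_sd)
  out
}
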