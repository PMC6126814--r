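#' Simulation configuration for run-and-tumble swimmers
#'
#' Bundles the generative parameters of the circular run-and-tumble simulator.
#' Individual cells move at a constant tangential speed `v` along circular arcs
#' of angular velocity `psi` (circle radius `s = v/psi`); at exponentially
#' distributed waiting times they tumble and pick a fresh, uniformly random
#' heading. Population heterogeneity enters through a per-cell speed draw
#' (Schulz/gamma with relative width `speed_rel_width`) and, optionally, a
#' per-cell curvature draw `psi ~ Exponential(psi_lambda)`.
#'
#' @param n_cells number of independent cells.
#' @param duration total simulated time (s).
#' @param dt frame interval (s); positions are reported at frame times only.
#' @param box_size side of the square periodic box (um). `Inf` (default)
#'   disables wrapping, which is the right choice for trajectory analytics;
#'   use a finite box when the tracks feed the virtual microscope.
#' @param speed_mean population mean tangential speed (um/s).
#' @param speed_rel_width relative width `S = sigma/v` of the speed
#'   distribution, in `[0, 1)`. `0` gives identical speeds.
#' @param psi_mode `"fixed"` (all cells share `psi_value`) or `"exponential"`
#'   (per-cell `psi` drawn from `P(psi) = lambda exp(-lambda psi)`).
#' @param psi_value angular velocity of the circular motion (rad/s), fixed mode.
#' @param psi_lambda exponential rate `lambda` (s/rad), exponential mode.
#' @param psi_signs `"positive"` (default; curvature has a single handedness,
#'   as for cells swimming near a surface) or `"mixed"` (random sign per cell).
#' @param tumble_rate Poisson rate of tumble events (1/s).
#' @param tumble_style `"instant"` (default; zero-duration reorientation) or
#'   `"finite"` (speed drops to `tumble_speed_frac` for an exponentially
#'   distributed duration of mean `tumble_duration` while the heading
#'   scrambles; used to train the tumble classifier).
#' @param tumble_speed_frac fractional speed during a finite-duration tumble.
#' @param tumble_duration mean duration of a finite tumble (s).
#' @param rot_diffusion rotational diffusion coefficient (rad^2/s); Gaussian
#'   heading noise of variance `2 * rot_diffusion * dt` per step.
#' @param geometry `"planar"` (default; quasi-2D swimming in the image plane)
#'   or `"isotropic3d"` (straight 3D runs with uniform-on-sphere directions,
#'   positions reported in 2D projection as a bulk microscope sees them;
#'   requires `psi = 0`).
#' @param loc_noise i.i.d. Gaussian localization noise added to reported
#'   positions (um); ground truth keeps the noiseless coordinates.
#' @param seed integer seed; identical config + seed gives bit-identical
#'   output.
#'
#' @return an object of class `sim_config`.
#' @seealso [simulate_circular_rt()], [simulate_brownian()]
#' @export
sim_config <- function(n_cells = 100, duration = 20, dt = 0.1,
                       box_size = Inf, speed_mean = 25, speed_rel_width = 0.2,
                       psi_mode = c("fixed", "exponential"), psi_value = 0,
                       psi_lambda = 1, psi_signs = c("positive", "mixed"),
                       tumble_rate = 0, tumble_style = c("instant", "finite"),
                       tumble_speed_frac = 0.3, tumble_duration = 0.15,
                       rot_diffusion = 0,
                       geometry = c("planar", "isotropic3d"),
                       loc_noise = 0, seed = 1L) {
  psi_mode <- match.arg(psi_mode)
  psi_signs <- match.arg(psi_signs)
  tumble_style <- match.arg(tumble_style)
  geometry <- match.arg(geometry)
  cfg <- list(n_cells = as.integer(n_cells), duration = duration, dt = dt,
              box_size = box_size, speed_mean = speed_mean,
              speed_rel_width = speed_rel_width, psi_mode = psi_mode,
              psi_value = psi_value, psi_lambda = psi_lambda,
              psi_signs = psi_signs, tumble_rate = tumble_rate,
              tumble_style = tumble_style,
              tumble_speed_frac = tumble_speed_frac,
              tumble_duration = tumble_duration,
              rot_diffusion = rot_diffusion, geometry = geometry,
              loc_noise = loc_noise, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  num <- unlist(cfg[c("duration", "dt", "speed_mean", "speed_rel_width",
                      "psi_value", "psi_lambda", "tumble_rate",
                      "rot_diffusion", "loc_noise")])
  if (any(!is.finite(num)))
    stop("sim_config: non-finite numeric parameter", call. = FALSE)
  if (cfg$dt <= 0) stop("sim_config: dt must be > 0", call. = FALSE)
  if (cfg$duration < cfg$dt)
    stop("sim_config: duration must be >= dt", call. = FALSE)
  if (cfg$n_cells < 1) stop("sim_config: n_cells must be >= 1", call. = FALSE)
  if (cfg$speed_mean < 0) stop("sim_config: speed_mean must be >= 0", call. = FALSE)
  if (cfg$speed_rel_width < 0 || cfg$speed_rel_width >= 1)
    stop("sim_config: speed_rel_width must be in [0, 1)", call. = FALSE)
  if (cfg$tumble_rate < 0) stop("sim_config: tumble_rate must be >= 0", call. = FALSE)
  if (cfg$psi_mode == "exponential" && cfg$psi_lambda <= 0)
    stop("sim_config: psi_lambda must be > 0 in exponential mode", call. = FALSE)
  if (cfg$geometry == "isotropic3d" &&
      (cfg$psi_mode == "exponential" || cfg$psi_value != 0))
    stop("sim_config: isotropic3d geometry requires psi = 0", call. = FALSE)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_cells, "cells,", x$duration, "s at dt =", x$dt, "s\n")
  cat("  speed:", x$speed_mean, "um/s (S =", x$speed_rel_width, "),",
      "psi:", if (x$psi_mode == "fixed") paste(x$psi_value, "rad/s")
              else paste0("Exp(lambda=", x$psi_lambda, ")"), "\n")
  cat("  tumble rate:", x$tumble_rate, "/s (", x$tumble_style, "),",
      "rot. diffusion:", x$rot_diffusion, "rad^2/s,",
      "geometry:", x$geometry, "\n")
  invisible(x)
}

#' Virtual microscope optics configuration
#'
#' Parameters of the movie renderer. Cells are imaged as Gaussian spots of
#' width `psf_sigma`; in dark-field mode each cell's intensity is modulated at
#' the body-rotation frequency, `1 + wobble_depth * sin(2 pi f t + phi)`, with
#' a random phase per cell, mimicking the flicker produced by a wobbling cell
#' body.
#'
#' @param psf_sigma point-spread width (um), > 0.
#' @param cell_intensity peak intensity of one cell (a.u.).
#' @param background constant background level (a.u.).
#' @param noise_sigma SD of per-pixel Gaussian read noise (a.u.).
#' @param image_size image side (pixels, square).
#' @param pixel_size pixel size (um/px).
#' @param wobble_frequency dark-field intensity modulation frequency (Hz);
#'   equals the body angular velocity over 2 pi.
#' @param wobble_depth modulation depth, fraction of cell intensity in [0, 1].
#'
#' @return an object of class `optics_config`.
#' @seealso [render_movie()]
#' @export
optics_config <- function(psf_sigma = 0.6, cell_intensity = 1,
                          background = 0.1, noise_sigma = 0,
                          image_size = 256, pixel_size = 0.5,
                          wobble_frequency = 10, wobble_depth = 0.5) {
  if (!is.finite(psf_sigma) || psf_sigma <= 0)
    stop("optics_config: psf_sigma must be > 0", call. = FALSE)
  if (wobble_depth < 0 || wobble_depth > 1)
    stop("optics_config: wobble_depth must be in [0, 1]", call. = FALSE)
  if (pixel_size <= 0) stop("optics_config: pixel_size must be > 0", call. = FALSE)
  structure(list(psf_sigma = psf_sigma, cell_intensity = cell_intensity,
                 background = background, noise_sigma = noise_sigma,
                 image_size = as.integer(image_size), pixel_size = pixel_size,
                 wobble_frequency = wobble_frequency,
                 wobble_depth = wobble_depth),
            class = "optics_config")
}

#' @export
print.optics_config <- function(x, ...) {
  cat("<optics_config>", x$image_size, "x", x$image_size, "px at",
      x$pixel_size, "um/px, psf sigma", x$psf_sigma, "um\n")
  invisible(x)
}
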