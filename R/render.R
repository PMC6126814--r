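# Virtual microscope: renders track sets into phase-contrast-like or
# dark-field-like image stacks.

#' Construct an image stack
#'
#' Frames plus the acquisition metadata DDM/DFM need: pixel size and frame
#' interval.
#'
#' @param frames numeric array `ny x nx x n_frames`, nonnegative.
#' @param pixel_size um per pixel.
#' @param frame_interval s between frames.
#' @param modality `"phase"` or `"darkfield"`.
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(frames, pixel_size, frame_interval,
                        modality = c("phase", "darkfield")) {
  modality <- match.arg(modality)
  d <- dim(frames)
  if (length(d) != 3 || d[3] < 2)
    stop("image_stack: frames must be ny x nx x (>= 2 frames)", call. = FALSE)
  if (min(frames) < 0)
    stop("image_stack: intensities must be nonnegative", call. = FALSE)
  if (pixel_size <= 0 || frame_interval <= 0)
    stop("image_stack: pixel_size and frame_interval must be > 0", call. = FALSE)
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_interval = frame_interval, modality = modality),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat("<image_stack>", d[1], "x", d[2], "px,", d[3], "frames at",
      1 / x$frame_interval, "fps,", x$pixel_size, "um/px,", x$modality, "\n")
  invisible(x)
}

#' Render a track set into a synthetic microscope movie
#'
#' Each cell is imaged as a Gaussian spot of width `psf_sigma` at its
#' (periodically wrapped) position. In phase mode the per-cell intensity is
#' constant; in dark-field mode it is modulated as
#' `1 + wobble_depth * sin(2 pi wobble_frequency t + phi_cell)` with a random
#' phase per cell, standing in for the flicker of the wobbling cell body at
#' the body-rotation frequency. Per-pixel Gaussian read noise is added and
#' intensities are clipped at zero. Rendering is seeded and bit-reproducible.
#'
#' @param tracks a [track_set()]; positions must fit inside the field
#'   `image_size * pixel_size` (periodic-box tracks are wrapped into it).
#' @param optics an [optics_config()].
#' @param modality `"phase"` or `"darkfield"`.
#' @param seed integer seed for wobble phases and read noise.
#' @param n_frames,frame_interval time grid, only needed (and only used) when
#'   `tracks` is empty, to size the pure background + noise stack.
#' @return an [image_stack()].
#' @export
render_movie <- function(tracks, optics, modality = c("phase", "darkfield"),
                         seed = 1L, n_frames = NULL, frame_interval = NULL) {
  stopifnot(inherits(tracks, "track_set"), inherits(optics, "optics_config"))
  modality <- match.arg(modality)
  set.seed(as.integer(seed))
  npx <- optics$image_size
  field <- npx * optics$pixel_size
  n <- length(tracks$trajectories)
  if (n == 0) {
    if (is.null(n_frames) || is.null(frame_interval))
      stop("render_movie: empty track set needs n_frames and frame_interval",
           call. = FALSE)
    dt <- frame_interval
    nf <- as.integer(n_frames)
  } else {
    dt <- traj_dt(tracks$trajectories[[1]])
    nf <- length(tracks$trajectories[[1]]$times)
  }

  if (modality == "darkfield" && optics$wobble_frequency >= 1 / (2 * dt))
    stop("render_movie: wobble_frequency at or above Nyquist (",
         1 / (2 * dt), " Hz) would alias", call. = FALSE)

  xs <- vapply(tracks$trajectories, function(tr) tr$x, numeric(nf))
  ys <- vapply(tracks$trajectories, function(tr) tr$y, numeric(nf))
  xs <- matrix(xs, nf, n); ys <- matrix(ys, nf, n)
  box <- if (!is.null(tracks$config)) tracks$config$box_size else Inf
  if (is.finite(box)) {
    if (box > field + 1e-9)
      stop("render_movie: periodic box exceeds the imaged field", call. = FALSE)
    xs <- xs %% field; ys <- ys %% field
  } else if (n > 0 && (min(xs, ys) < 0 || max(xs, ys) > field)) {
    stop("render_movie: tracks leave the imaged field", call. = FALSE)
  }

  sig_px <- optics$psf_sigma / optics$pixel_size
  halfw <- max(2L, ceiling(4 * sig_px))
  rel <- -halfw:halfw
  phases <- stats::runif(n, 0, 2 * pi)
  times <- (seq_len(nf) - 1) * dt
  frames <- array(optics$background, dim = c(npx, npx, nf))

  for (t in seq_len(nf)) {
    fr <- frames[, , t]
    if (modality == "darkfield") {
      amp <- optics$cell_intensity *
        (1 + optics$wobble_depth * sin(2 * pi * optics$wobble_frequency *
                                         times[t] + phases))
    } else {
      amp <- rep(optics$cell_intensity, max(n, 1L))
    }
    for (j in seq_len(n)) {
      cx <- xs[t, j] / optics$pixel_size   # column (x), 0-based
      cy <- ys[t, j] / optics$pixel_size   # row (y)
      jc <- floor(cx); jr <- floor(cy)
      cols <- (jc + rel) %% npx + 1L
      rows <- (jr + rel) %% npx + 1L
      gx <- exp(-((jc + rel + 0.5) - cx)^2 / (2 * sig_px^2))
      gy <- exp(-((jr + rel + 0.5) - cy)^2 / (2 * sig_px^2))
      fr[rows, cols] <- fr[rows, cols] + amp[j] * outer(gy, gx)
    }
    if (optics$noise_sigma > 0)
      fr <- fr + stats::rnorm(npx * npx, 0, optics$noise_sigma)
    frames[, , t] <- fr
  }
  frames[frames < 0] <- 0
  image_stack(frames, optics$pixel_size, dt, modality)
}

#' Render a stack of static cells
#'
#' Convenience wrapper building a track set of motionless cells at given
#' positions and rendering it; the standard dark-field flicker fixture.
#'
#' @param positions two-column matrix of (x, y) positions (um).
#' @param n_frames number of frames.
#' @param frame_interval s between frames.
#' @param optics an [optics_config()].
#' @param modality `"phase"` or `"darkfield"`.
#' @param seed integer seed.
#' @return an [image_stack()].
#' @export
render_static_cells <- function(positions, n_frames, frame_interval, optics,
                                modality = "darkfield", seed = 1L) {
  times <- (seq_len(n_frames) - 1) * frame_interval
  trajs <- lapply(seq_len(nrow(positions)), function(i)
    trajectory(times, rep(positions[i, 1], n_frames),
               rep(positions[i, 2], n_frames)))
  render_movie(track_set(trajs), optics, modality = modality, seed = seed)
}
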