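# Trajectory and track-set containers shared by the simulator and the
# trajectory analytics.

#' Construct a single-cell trajectory
#'
#' A trajectory is one cell's timestamped planar positions on a uniform time
#' grid, the atom of the quasi-2D analysis.
#'
#' @param times sampling times (s), strictly increasing, uniform spacing.
#' @param x,y positions (um), finite, same length as `times`.
#' @return an object of class `trajectory` with attribute `dt`.
#' @export
trajectory <- function(times, x, y) {
  n <- length(times)
  if (n < 3) stop("trajectory: need at least 3 points", call. = FALSE)
  if (length(x) != n || length(y) != n)
    stop("trajectory: times, x, y lengths differ", call. = FALSE)
  if (any(!is.finite(times)) || any(!is.finite(x)) || any(!is.finite(y)))
    stop("trajectory: non-finite values", call. = FALSE)
  dts <- diff(times)
  if (any(dts <= 0)) stop("trajectory: times must be strictly increasing", call. = FALSE)
  if (max(dts) - min(dts) > 1e-9)
    stop("trajectory: time grid must be uniform (within 1e-9 s)", call. = FALSE)
  structure(list(times = as.numeric(times), x = as.numeric(x),
                 y = as.numeric(y)),
            dt = mean(dts), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory>", length(x$times), "points, dt =", attr(x, "dt"),
      "s, duration =", diff(range(x$times)), "s\n")
  invisible(x)
}

traj_dt <- function(traj) attr(traj, "dt")

#' Construct a track set
#'
#' A population of trajectories, optionally carrying the simulation config and
#' per-cell ground truth that produced them (used by parameter-recovery
#' tests). All trajectories must share the frame interval.
#'
#' @param trajectories list of [trajectory()] objects.
#' @param config the generating [sim_config()], or `NULL` for empirical data.
#' @param ground_truth list of per-cell truth (speeds, curvatures, tumble
#'   times, unwrapped coordinates), or `NULL`.
#' @return an object of class `track_set`.
#' @export
track_set <- function(trajectories, config = NULL, ground_truth = NULL) {
  if (length(trajectories)) {
    dts <- vapply(trajectories, traj_dt, numeric(1))
    if (max(dts) - min(dts) > 1e-9)
      stop("track_set: trajectories disagree on dt", call. = FALSE)
  }
  structure(list(trajectories = trajectories, config = config,
                 ground_truth = ground_truth),
            class = "track_set")
}

#' @export
print.track_set <- function(x, ...) {
  n <- length(x$trajectories)
  cat("<track_set>", n, "trajectories")
  if (n) cat(", dt =", traj_dt(x$trajectories[[1]]), "s")
  if (!is.null(x$config)) cat(", simulated (seed ", x$config$seed, ")", sep = "")
  cat("\n")
  invisible(x)
}

#' @export
length.track_set <- function(x) length(x$trajectories)

# Positions of every cell at every frame as n_frames x n_cells matrices.
# Uses unwrapped ground-truth coordinates when available (MSD and ACF must not
# see periodic-wrap jumps); falls back to the reported positions.
track_matrices <- function(tracks, unwrap = TRUE) {
  gt <- tracks$ground_truth
  if (unwrap && !is.null(gt$unwrapped_x)) {
    list(x = gt$unwrapped_x, y = gt$unwrapped_y)
  } else {
    list(x = vapply(tracks$trajectories, function(tr) tr$x,
                    numeric(length(tracks$trajectories[[1]]$times))),
         y = vapply(tracks$trajectories, function(tr) tr$y,
                    numeric(length(tracks$trajectories[[1]]$times))))
  }
}

# Wrap coordinates into [0, box); identity for infinite boxes.
wrap_box <- function(p, box) if (is.finite(box)) p %% box else p
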