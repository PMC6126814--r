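# Frame-level kinematic features feeding the tumble classifier.

#' Compute frame-level kinematic features of a trajectory
#'
#' From the frame-to-frame displacements, computes speed, heading, angular
#' velocity (wrapped heading change per unit time), relative acceleration
#' (fractional speed change per unit time, normalized by the track-mean speed
#' so that the feature is scale-free across slow and fast cells) and angular
#' acceleration. These are the emission features of the two-state
#' swim/tumble hidden Markov model.
#'
#' @param traj a [trajectory()] with at least 4 points.
#' @return an object of class `frame_features`: list with `speed` (length
#'   n-1), `heading` (n-1), `angular_velocity` (n-2), `relative_acceleration`
#'   (n-2), `angular_acceleration` (n-3), the frame interval `dt`, and
#'   `mean_speed`.
#' @export
compute_frame_features <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  n <- length(traj$times)
  if (n < 4)
    stop("compute_frame_features: need at least 4 points", call. = FALSE)
  dt <- traj_dt(traj)
  dx <- diff(traj$x); dy <- diff(traj$y)
  speed <- sqrt(dx^2 + dy^2) / dt
  heading <- atan2(dy, dx)
  dheading <- wrap_angle(diff(heading))
  angular_velocity <- dheading / dt
  vbar <- max(mean(speed), .Machine$double.eps)
  relative_acceleration <- diff(speed) / (dt * vbar)
  angular_acceleration <- diff(angular_velocity) / dt
  structure(list(speed = speed, heading = heading,
                 angular_velocity = angular_velocity,
                 relative_acceleration = relative_acceleration,
                 angular_acceleration = angular_acceleration,
                 dt = dt, mean_speed = mean(speed)),
            class = "frame_features")
}

# wrap angles into (-pi, pi]
wrap_angle <- function(a) {
  w <- (a + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

# Emission matrix for the HMM: columns (relative_acceleration,
# |angular_acceleration|), aligned to the n-3 interior frames.
feature_matrix <- function(feats) {
  k <- length(feats$angular_acceleration)
  cbind(rel_acc = feats$relative_acceleration[seq_len(k)],
        abs_ang_acc = abs(feats$angular_acceleration))
}
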