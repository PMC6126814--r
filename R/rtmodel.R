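# Closed-form circular run-and-tumble model: velocity autocorrelation and
# mean square displacement, population averaging over exponentially
# distributed curvatures, empirical estimators, and least-squares fitting.

#' Velocity autocorrelation of uniform circular swimming
#'
#' A cell moving on a circle with angular velocity `psi` has direction
#' autocorrelation `cos(psi * t)`.
#'
#' @param t lag time(s) (s), >= 0.
#' @param psi angular velocity (rad/s).
#' @return dimensionless ACF value(s).
#' @export
acf_circular <- function(t, psi) cos(psi * t)

#' Mean square displacement of uniform circular swimming
#'
#' `<r^2>(t) = 2 s^2 (1 - cos(psi t))` for a circle of radius `s_radius`;
#' at short times this reduces to the ballistic `v^2 t^2` with
#' `v = psi * s_radius`. Bounded by the squared diameter `4 s^2` and
#' periodic with period `2 pi / psi`.
#'
#' @param t lag time(s) (s), >= 0.
#' @param s_radius circle radius (um).
#' @param psi angular velocity (rad/s).
#' @return MSD (um^2).
#' @export
msd_circular <- function(t, s_radius, psi) 2 * s_radius^2 * (1 - cos(psi * t))

#' Population-averaged autocorrelation under exponential curvatures
#'
#' When the angular velocities are distributed as
#' `P(psi) = lambda exp(-lambda psi)` across the population, averaging
#' `cos(psi t)` gives the Lorentzian-like closed form
#' `lambda^2 / (lambda^2 + t^2)`, which decays algebraically and never
#' crosses zero (unlike the single-curvature cosine).
#'
#' @param t lag time(s) (s), >= 0.
#' @param lam exponential rate lambda (s/rad), > 0.
#' @return dimensionless ACF value(s).
#' @export
acf_population_exponential <- function(t, lam) {
  if (!is.finite(lam) || lam <= 0)
    stop("acf_population_exponential: lam must be > 0", call. = FALSE)
  lam^2 / (lam^2 + t^2)
}

#' Velocity autocorrelation of the circular run-and-tumble process
#'
#' Circular swimming at angular velocity `psi` interrupted by tumbles at
#' exponentially distributed waiting times (rate `tumble_rate`) with full
#' directional decorrelation at each tumble gives
#' `exp(-tumble_rate * t) * cos(psi * t)`: the run contributes the rotating
#' phase, the tumbles an exponential envelope equal to the probability that
#' no tumble occurred in the interval.
#'
#' @param t lag time(s) (s), >= 0.
#' @param psi angular velocity (rad/s).
#' @param tumble_rate tumble rate (1/s), >= 0.
#' @return dimensionless ACF value(s).
#' @export
acf_circular_rt <- function(t, psi, tumble_rate) {
  if (any(tumble_rate < 0))
    stop("acf_circular_rt: tumble_rate must be >= 0", call. = FALSE)
  exp(-tumble_rate * t) * cos(psi * t)
}

#' Empirical direction autocorrelation function
#'
#' Unit heading vectors are taken from frame displacements; the ACF at lag
#' `k * dt` is the mean over time origins (and over cells for a track set)
#' of the dot product of headings `k` frames apart. For simulated track sets
#' the unwrapped ground-truth coordinates are used, so periodic boundaries do
#' not inject spurious turns.
#'
#' @param x a [trajectory()] or [track_set()].
#' @param max_lag largest lag (s); truncated with a warning when it reaches
#'   the track duration.
#' @param lag_stride compute every `lag_stride`-th lag (1 = all).
#' @param se for track sets, also return the across-cell standard error.
#' @return an object of class `correlation_curve`: data.frame with `lag_s`,
#'   `value`, `n_pairs` (and `se` per cell mean if requested).
#' @export
empirical_acf <- function(x, max_lag = NULL, lag_stride = 1L, se = FALSE) {
  mats <- curve_input(x)
  dt <- mats$dt
  nf <- nrow(mats$x)
  max_k <- max_lag_frames(max_lag, dt, nf)
  lags <- seq(0L, max_k, by = lag_stride)
  hx <- diff(mats$x) / dt; hy <- diff(mats$y) / dt
  sp <- sqrt(hx^2 + hy^2)
  sp[sp == 0] <- NA              # stalled frames carry no direction
  ux <- hx / sp; uy <- hy / sp
  nh <- nrow(ux)
  ncell <- ncol(ux)
  value <- numeric(length(lags)); npairs <- integer(length(lags))
  sevec <- rep(NA_real_, length(lags))
  for (j in seq_along(lags)) {
    k <- lags[j]
    if (k >= nh) { value[j] <- NA; next }
    i1 <- seq_len(nh - k)
    dots <- ux[i1, , drop = FALSE] * ux[i1 + k, , drop = FALSE] +
      uy[i1, , drop = FALSE] * uy[i1 + k, , drop = FALSE]
    percell <- colMeans(dots, na.rm = TRUE)
    value[j] <- mean(percell, na.rm = TRUE)
    npairs[j] <- sum(!is.na(dots))
    if (se && ncell > 1)
      sevec[j] <- stats::sd(percell, na.rm = TRUE) / sqrt(sum(!is.na(percell)))
  }
  correlation_curve(lags * dt, value, npairs, kind = "acf",
                    se = if (se) sevec else NULL)
}

#' Empirical mean square displacement
#'
#' Time- and ensemble-averaged `<|r(t + tau) - r(t)|^2>`. Unwrapped
#' ground-truth coordinates are used for simulated data.
#'
#' @inheritParams empirical_acf
#' @return a `correlation_curve` with MSD values (um^2).
#' @export
empirical_msd <- function(x, max_lag = NULL, lag_stride = 1L) {
  mats <- curve_input(x)
  dt <- mats$dt
  nf <- nrow(mats$x)
  max_k <- max_lag_frames(max_lag, dt, nf)
  lags <- seq(0L, max_k, by = lag_stride)
  value <- numeric(length(lags)); npairs <- integer(length(lags))
  for (j in seq_along(lags)) {
    k <- lags[j]
    if (k == 0L) { value[j] <- 0; npairs[j] <- nf * ncol(mats$x); next }
    i1 <- seq_len(nf - k)
    d2 <- (mats$x[i1 + k, , drop = FALSE] - mats$x[i1, , drop = FALSE])^2 +
      (mats$y[i1 + k, , drop = FALSE] - mats$y[i1, , drop = FALSE])^2
    value[j] <- mean(d2)
    npairs[j] <- length(d2)
  }
  correlation_curve(lags * dt, value, npairs, kind = "msd")
}

curve_input <- function(x) {
  if (inherits(x, "trajectory"))
    return(list(x = cbind(x$x), y = cbind(x$y), dt = traj_dt(x)))
  if (inherits(x, "track_set")) {
    m <- track_matrices(x)
    return(list(x = m$x, y = m$y, dt = traj_dt(x$trajectories[[1]])))
  }
  stop("expected a trajectory or track_set", call. = FALSE)
}

max_lag_frames <- function(max_lag, dt, nf) {
  dur <- (nf - 1) * dt
  if (is.null(max_lag)) max_lag <- dur / 4
  if (max_lag >= dur) {
    warning("max_lag reaches the track duration; truncating")
    max_lag <- dur - dt
  }
  max(1L, floor(max_lag / dt + 1e-9))
}

correlation_curve <- function(lag_s, value, n_pairs, kind, se = NULL) {
  out <- data.frame(lag_s = lag_s, value = value, n_pairs = n_pairs)
  if (!is.null(se)) out$se <- se
  attr(out, "kind") <- kind
  class(out) <- c("correlation_curve", "data.frame")
  out
}

#' Fit the circular run-and-tumble model to empirical curves
#'
#' Least-squares fit of the model autocorrelation to an empirical direction
#' ACF, weighted by `sqrt(n_pairs)` to downweight noisy long lags, with a
#' bounded multistart over `psi` to avoid the cosine's local minima. The
#' tangential speed `v` is read off the first mean-square-displacement point
#' assuming ballistic short-time motion, `v = sqrt(MSD(dt))/dt`, and the
#' circle radius follows as `s = v / psi`.
#'
#' @param acf empirical `correlation_curve` from [empirical_acf()] (>= 10
#'   lags).
#' @param msd empirical `correlation_curve` from [empirical_msd()] on the
#'   same data.
#' @param mode `"single"` fits `exp(-rate t) cos(psi t)`; `"population"`
#'   fits `exp(-rate t) * lambda^2/(lambda^2 + t^2)` for exponentially
#'   distributed curvatures.
#' @param max_lag restrict the ACF fit to lags below this (s).
#' @param n_starts multistart grid size over `psi` in `[0, pi/dt]`.
#' @param v_method `"first_point"` (default) or `"quadratic"` (3-point
#'   quadratic through the origin, robust to a noisy first lag).
#' @return an object of class `circular_rt_fit` with components `psi`
#'   (or `lambda`), `tumble_rate`, `v`, `s`, residual RMS and the fitted
#'   curve; methods: `print`, `coef`, `predict`, `plot`.
#' @export
fit_circular_rt <- function(acf, msd, mode = c("single", "population"),
                            max_lag = NULL, n_starts = 20,
                            v_method = c("first_point", "quadratic")) {
  mode <- match.arg(mode)
  v_method <- match.arg(v_method)
  stopifnot(inherits(acf, "correlation_curve"), inherits(msd, "correlation_curve"))
  keep <- is.finite(acf$value) & acf$lag_s > 0
  if (!is.null(max_lag)) keep <- keep & acf$lag_s <= max_lag
  tt <- acf$lag_s[keep]; yy <- acf$value[keep]
  ww <- sqrt(pmax(acf$n_pairs[keep], 1))
  if (length(tt) < 10)
    stop("fit_circular_rt: need at least 10 ACF lags", call. = FALSE)
  dt_lag <- min(diff(sort(unique(acf$lag_s))))

  model_fun <- if (mode == "single")
    function(p, t) exp(-p[2] * t) * cos(p[1] * t)
  else
    function(p, t) exp(-p[2] * t) * p[1]^2 / (p[1]^2 + t^2)
  resid_fun <- function(p) ww * (model_fun(exp(p), tt) - yy)

  psi_hi <- pi / dt_lag
  starts <- if (mode == "single")
    pmax(seq(0, psi_hi, length.out = n_starts), 1e-3)
  else
    exp(seq(log(0.05), log(50), length.out = n_starts))
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = log(c(p0, 0.1)), fn = resid_fun,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ssr <- sum(fit$fvec^2)
    if (is.null(best) || ssr < best$ssr) best <- list(fit = fit, ssr = ssr)
  }
  if (is.null(best))
    stop("fit_circular_rt: no start converged", call. = FALSE)
  pars <- exp(best$fit$par)

  v <- v_from_msd(msd, v_method)
  psi <- if (mode == "single") pars[1] else NA_real_
  s <- if (mode == "single" && psi > 0) v / psi else NA_real_
  fitted_curve <- model_fun(pars, acf$lag_s)
  rms <- sqrt(mean((model_fun(pars, tt) - yy)^2))
  out <- list(mode = mode, psi = psi,
              lambda = if (mode == "population") pars[1] else NA_real_,
              tumble_rate = pars[2], v = v, s = s,
              residual_rms = rms, acf = acf, msd = msd,
              fitted = fitted_curve, n_lags = length(tt))
  class(out) <- "circular_rt_fit"
  out
}

v_from_msd <- function(msd, v_method) {
  pos <- msd[msd$lag_s > 0 & is.finite(msd$value), ]
  if (!nrow(pos)) stop("fit_circular_rt: MSD has no usable lags", call. = FALSE)
  if (v_method == "first_point") {
    sqrt(pos$value[1]) / pos$lag_s[1]
  } else {
    p3 <- utils::head(pos, 3)
    # MSD = a t^2 through the origin; v = sqrt(a)
    sqrt(sum(p3$value * p3$lag_s^2) / sum(p3$lag_s^4))
  }
}

#' @export
print.circular_rt_fit <- function(x, ...) {
  cat("<circular_rt_fit> mode:", x$mode, "\n")
  if (x$mode == "single")
    cat("  psi =", signif(x$psi, 4), "rad/s, tumble rate =",
        signif(x$tumble_rate, 4), "/s\n")
  else
    cat("  lambda =", signif(x$lambda, 4), ", tumble rate =",
        signif(x$tumble_rate, 4), "/s\n")
  cat("  v =", signif(x$v, 4), "um/s, s =", signif(x$s, 4),
      "um, residual RMS =", signif(x$residual_rms, 3), "\n")
  invisible(x)
}

#' @export
coef.circular_rt_fit <- function(object, ...) {
  c(psi = object$psi, lambda = object$lambda,
    tumble_rate = object$tumble_rate, v = object$v, s = object$s)
}

#' @export
predict.circular_rt_fit <- function(object, lag_s = NULL, ...) {
  if (is.null(lag_s)) lag_s <- object$acf$lag_s
  if (object$mode == "single")
    acf_circular_rt(lag_s, object$psi, object$tumble_rate)
  else
    exp(-object$tumble_rate * lag_s) *
      acf_population_exponential(lag_s, object$lambda)
}

#' @export
plot.circular_rt_fit <- function(x, ...) {
  graphics::plot(x$acf$lag_s, x$acf$value, pch = 16, cex = 0.5,
                 xlab = "lag (s)", ylab = "direction ACF", ...)
  graphics::lines(x$acf$lag_s, x$fitted, col = "red", lwd = 2)
  graphics::abline(h = 0, lty = 3)
  graphics::legend("topright", c("empirical", "model fit"),
                   pch = c(16, NA), lty = c(NA, 1), col = c("black", "red"))
  invisible(x)
}
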