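# Covariance-based diffusion estimation and per-cell population summaries.

#' Covariance-based estimator of the diffusion coefficient
#'
#' Subsamples the trajectory at `resample_interval` (chosen to exceed the
#' timescale of rotational diffusion, so the subsampled walk is diffusive)
#' and applies the covariance-based estimator per axis,
#' `D = <d^2>/(2 Delta) + <d_n d_(n+1)>/Delta`, where `d` are the subsampled
#' displacements. The adjacent-displacement covariance term cancels the bias
#' from static localization noise. The two axes are averaged. With the
#' default 10 s interval a 100 s track yields at most 10 subsampled
#' displacements, so single-track estimates are noisy (and may legitimately
#' be negative); ensemble averages are unbiased.
#'
#' @param traj a [trajectory()].
#' @param resample_interval subsampling interval Delta (s).
#' @return `D` (um^2/s), with attribute `negative` flagging `D < 0`.
#' @export
estimate_diffusion_cve <- function(traj, resample_interval = 10) {
  stopifnot(inherits(traj, "trajectory"))
  dt <- traj_dt(traj)
  dur <- diff(range(traj$times))
  if (dur < 3 * resample_interval)
    stop("estimate_diffusion_cve: track duration must be >= 3 * resample_interval",
         call. = FALSE)
  stride <- max(1L, round(resample_interval / dt))
  delta <- stride * dt
  idx <- seq(1L, length(traj$times), by = stride)
  Daxis <- function(p) {
    d <- diff(p[idx])
    mean(d^2) / (2 * delta) + mean(d[-length(d)] * d[-1]) / delta
  }
  D <- (Daxis(traj$x) + Daxis(traj$y)) / 2
  structure(D, negative = D < 0)
}

#' Directional persistence from diffusion and speed
#'
#' The persistence time of the swimming direction, defined through
#' `D = 1/2 v0^2 tau`, i.e. `tau = 2 D / v0^2`. A negative `D` (possible for
#' short tracks under the covariance-based estimator) passes through as a
#' negative `tau`, flagged via the `negative` attribute.
#'
#' @param D diffusion coefficient (um^2/s).
#' @param v0 mean swimming speed (um/s), > 0.
#' @return persistence time tau (s).
#' @export
directional_persistence <- function(D, v0) {
  if (!is.finite(v0) || v0 <= 0)
    stop("directional_persistence: v0 must be > 0", call. = FALSE)
  tau <- 2 * D / v0^2
  structure(tau, negative = tau < 0)
}

#' Per-cell behavioral statistics of a track population
#'
#' Computes one row of trajectory statistics per retained cell: mean speed
#' `v0`, tumble bias under the given tumble model, the covariance-based
#' diffusion coefficient `D`, the directional persistence `tau = 2 D / v0^2`
#' and the track duration. Cells failing the minimum-length filter
#' (duration below `min_duration` or mean speed below `min_speed`,
#' defaults chosen to exclude non-motile cells) are dropped.
#'
#' @param tracks a [track_set()].
#' @param model a [train_tumble_model()] fit, or `NULL` to skip tumble
#'   classification (`tumble_bias` becomes `NA`).
#' @param min_duration minimum track duration (s).
#' @param min_speed minimum mean speed (um/s).
#' @param resample_interval passed to [estimate_diffusion_cve()]; tracks too
#'   short for the estimator get `D = NA`.
#' @return an object of class `population_summary`: a data.frame with
#'   columns `cell_id`, `v0_um_s`, `tumble_bias`, `D_um2_s`, `tau_s`,
#'   `duration_s`, with per-column means and medians in attribute `pooled`.
#' @export
summarize_population <- function(tracks, model = NULL, min_duration = 10,
                                 min_speed = 5, resample_interval = 10) {
  stopifnot(inherits(tracks, "track_set"))
  n <- length(tracks$trajectories)
  if (!n) {
    warning("summarize_population: empty track set")
    return(empty_summary())
  }
  rows <- lapply(seq_len(n), function(i) {
    tr <- tracks$trajectories[[i]]
    dur <- diff(range(tr$times))
    feats <- compute_frame_features(tr)
    v0 <- feats$mean_speed
    if (dur < min_duration || v0 < min_speed) return(NULL)
    tb <- if (is.null(model)) NA_real_ else classify_tumbles(tr, model)$tumble_bias
    D <- if (dur >= 3 * resample_interval)
      as.numeric(estimate_diffusion_cve(tr, resample_interval)) else NA_real_
    tau <- if (is.na(D)) NA_real_ else as.numeric(directional_persistence(D, v0))
    data.frame(cell_id = i, v0_um_s = v0, tumble_bias = tb, D_um2_s = D,
               tau_s = tau, duration_s = dur)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    warning("summarize_population: no tracks pass the filters")
    return(empty_summary())
  }
  out <- do.call(rbind, rows)
  num <- out[, c("v0_um_s", "tumble_bias", "D_um2_s", "tau_s")]
  attr(out, "pooled") <- list(mean = colMeans(num, na.rm = TRUE),
                              median = apply(num, 2, stats::median, na.rm = TRUE),
                              n_cells = nrow(out))
  class(out) <- c("population_summary", "data.frame")
  out
}

empty_summary <- function() {
  out <- data.frame(cell_id = integer(0), v0_um_s = numeric(0),
                    tumble_bias = numeric(0), D_um2_s = numeric(0),
                    tau_s = numeric(0), duration_s = numeric(0))
  attr(out, "pooled") <- list(mean = NULL, median = NULL, n_cells = 0L)
  class(out) <- c("population_summary", "data.frame")
  out
}

#' @export
summary.population_summary <- function(object, ...) {
  p <- attr(object, "pooled")
  cat("population of", p$n_cells, "retained cells\n")
  if (p$n_cells) {
    cat("means:  "); print(round(p$mean, 4))
    cat("medians:"); print(round(p$median, 4))
  }
  invisible(p)
}

#' @export
plot.population_summary <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  p <- attr(x, "pooled")
  panels <- c(v0_um_s = "speed (um/s)", tumble_bias = "tumble bias",
              tau_s = "persistence tau (s)", D_um2_s = "D (um^2/s)")
  for (col in names(panels)) {
    v <- x[[col]]
    v <- v[is.finite(v)]
    if (!length(v)) next
    graphics::hist(v, breaks = 30, main = panels[[col]], xlab = panels[[col]],
                   col = "grey80", border = "white")
    graphics::points(mean(v), 0, pch = 3, col = "red", cex = 1.5)
    graphics::points(stats::median(v), 0, pch = 5, col = "blue", cex = 1.5)
  }
  invisible(x)
}
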