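# Dark-field flicker spectroscopy: per-cell intensity power spectra, the
# body angular velocity Omega from the lowest-frequency spectral peak, and
# the processivity v/Omega.

#' Average flicker power spectrum of segmented cells
#'
#' Segments cells on the temporal-mean image (Otsu threshold, connected
#' components, minimum area filter), extracts each cell's integrated
#' intensity over time, and averages the cells' one-sided periodograms
#' (mean-subtracted, Hann-windowed). For cells whose body wobbles at angular
#' velocity Omega the average spectrum peaks at `Omega / 2 pi`.
#'
#' @param stack a dark-field [image_stack()] with at least 256 frames.
#' @param min_area minimum segment area in pixels.
#' @return an object of class `flicker_spectrum`: data.frame with
#'   `frequency_hz` and `power`, number of cells as attribute `n_cells`.
#' @export
flicker_spectrum <- function(stack, min_area = 4) {
  stopifnot(inherits(stack, "image_stack"))
  if (stack$modality != "darkfield")
    stop("flicker_spectrum: stack must be dark-field modality", call. = FALSE)
  d <- dim(stack$frames)
  nf <- d[3]
  if (nf < 256) stop("flicker_spectrum: need >= 256 frames", call. = FALSE)

  avg <- apply(stack$frames, c(1, 2), mean)
  rng <- range(avg)
  norm <- (avg - rng[1]) / max(rng[2] - rng[1], .Machine$double.eps)
  thr <- EBImage::otsu(EBImage::Image(norm))
  mask <- norm > thr
  labels <- EBImage::bwlabel(mask)
  sizes <- tabulate(labels[labels > 0])
  keep <- which(sizes >= min_area)
  if (!length(keep)) stop("flicker_spectrum: no cells found", call. = FALSE)
  if (length(keep) < 10)
    warning("flicker_spectrum: fewer than 10 cells segmented")

  flat <- matrix(stack$frames, d[1] * d[2], nf)
  lab_vec <- as.integer(labels)
  win <- signal::hanning(nf)
  nfreq <- nf %/% 2
  pow <- numeric(nfreq + 1)
  for (lab in keep) {
    ts <- colSums(flat[lab_vec == lab, , drop = FALSE])
    ts <- (ts - mean(ts)) * win
    sp <- Mod(stats::fft(ts))^2 / nf
    pow <- pow + sp[seq_len(nfreq + 1)]
  }
  pow <- pow / length(keep)
  freq <- (0:nfreq) / (nf * stack$frame_interval)
  out <- data.frame(frequency_hz = freq, power = pow)
  attr(out, "n_cells") <- length(keep)
  class(out) <- c("flicker_spectrum", "data.frame")
  out
}

#' Body angular velocity from a flicker spectrum
#'
#' Identifies the lowest-frequency local maximum whose power exceeds
#' `prominence` times the median-smoothed background and reports
#' `Omega = 2 pi * f_peak`. Harmonics at higher frequency are ignored
#' because the lowest qualifying peak is taken.
#'
#' @param spectrum a [flicker_spectrum()] (or any data.frame with
#'   `frequency_hz` and `power`).
#' @param prominence peak height threshold relative to the smoothed
#'   background.
#' @param f_min ignore frequencies below this (Hz); excludes the DC
#'   neighborhood.
#' @return an object of class `dfm_result` with `Omega` (rad/s),
#'   `peak_frequency` (Hz) and the spectrum.
#' @export
body_angular_velocity <- function(spectrum, prominence = 4, f_min = 0.5) {
  f <- spectrum$frequency_hz
  p <- spectrum$power
  n <- length(p)
  if (n < 5) stop("body_angular_velocity: spectrum too short", call. = FALSE)
  k <- max(5L, 2L * (n %/% 40) + 1L)
  bg <- stats::runmed(p, k)
  cand <- which(f >= f_min)
  cand <- cand[cand > 1 & cand < n]
  is_peak <- p[cand] > p[cand - 1] & p[cand] >= p[cand + 1] &
    p[cand] > prominence * pmax(bg[cand], .Machine$double.eps)
  if (!any(is_peak))
    stop("body_angular_velocity: no qualifying spectral peak", call. = FALSE)
  ipk <- cand[is_peak][1]
  structure(list(Omega = 2 * pi * f[ipk], peak_frequency = f[ipk],
                 spectrum = spectrum),
            class = "dfm_result")
}

#' @export
print.dfm_result <- function(x, ...) {
  cat("<dfm_result> peak at", signif(x$peak_frequency, 4), "Hz, Omega =",
      signif(x$Omega, 5), "rad/s\n")
  invisible(x)
}

#' @export
plot.flicker_spectrum <- function(x, ...) {
  graphics::plot(x$frequency_hz[-1], x$power[-1], type = "l", log = "y",
                 xlab = "frequency (Hz)", ylab = "power (a.u.)", ...)
  invisible(x)
}

#' Propulsive efficiency (processivity)
#'
#' `P = v / Omega` (um/rad): the distance advanced per radian of body
#' rotation; `2 pi P` is the average run length per body revolution. With a
#' reference (e.g. wild type) the metrics are also reported normalized to
#' it.
#'
#' @param v swimming speed (um/s).
#' @param Omega body angular velocity (rad/s), > 0.
#' @param reference optional list with elements `v` and `Omega` of the
#'   reference condition.
#' @return an object of class `motility_summary` with `v`, `Omega`, `P`,
#'   `P_per_rev`, and (given a reference) `v_rel`, `Omega_rel`, `P_rel`.
#' @export
processivity <- function(v, Omega, reference = NULL) {
  if (!is.finite(Omega) || Omega <= 0)
    stop("processivity: Omega must be > 0", call. = FALSE)
  out <- list(v = v, Omega = Omega, P = v / Omega,
              P_per_rev = 2 * pi * v / Omega)
  if (!is.null(reference)) {
    out$v_rel <- v / reference$v
    out$Omega_rel <- Omega / reference$Omega
    out$P_rel <- (v / Omega) / (reference$v / reference$Omega)
  }
  structure(out, class = "motility_summary")
}

#' @export
print.motility_summary <- function(x, ...) {
  cat("<motility_summary> v =", signif(x$v, 4), "um/s, Omega =",
      signif(x$Omega, 5), "rad/s, P =", signif(x$P, 4), "um/rad (",
      signif(x$P_per_rev, 4), "um/rev )\n")
  if (!is.null(x$P_rel))
    cat("  normalized: v", signif(x$v_rel, 3), ", Omega",
        signif(x$Omega_rel, 3), ", P", signif(x$P_rel, 3), "\n")
  invisible(x)
}
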