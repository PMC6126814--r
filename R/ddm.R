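# Differential dynamic microscopy: image structure function, intermediate
# scattering function fits with a Schulz speed distribution, and the
# population motility summary (v, sigma, S, R).

#' Image structure function of a movie
#'
#' Computes `g(q, tau)`: the time-averaged power of the difference between
#' Fourier-transformed frames separated by lag `tau`,
#' `g(q, tau) = < |FFT2(I(t + tau)) - FFT2(I(t))|^2 > / (nx * ny)`,
#' radially averaged into annular `q` bins (one FFT pixel wide by default,
#' bins with fewer than `min_modes` Fourier modes discarded). `q` is the
#' spatial frequency in um^-1, `q = 2 pi * f`, so the probed length scale is
#' `L = 2 pi / q`. With this normalization a stack of pure i.i.d. noise of
#' variance `s^2` gives a flat `g = 2 s^2`.
#'
#' @param stack an [image_stack()].
#' @param tau_frames integer frame lags; default a log-spaced set up to a
#'   quarter of the stack.
#' @param max_origins per lag, cap on the number of time origins entering
#'   the average (evenly strided).
#' @param min_modes minimum Fourier modes per annular bin.
#' @return an object of class `structure_function`: list with `q` (um^-1),
#'   `tau` (s), matrix `g` (q x tau), `n_modes`, and the acquisition
#'   metadata.
#' @export
image_structure_function <- function(stack, tau_frames = NULL,
                                     max_origins = 60, min_modes = 8) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$frames)
  ny <- d[1]; nx <- d[2]; nf <- d[3]
  if (is.null(tau_frames)) {
    tau_frames <- unique(round(exp(seq(log(1), log(max(1, nf %/% 4)),
                                       length.out = 40))))
  }
  tau_frames <- sort(unique(as.integer(tau_frames)))
  if (any(tau_frames < 1L | tau_frames >= nf))
    stop("image_structure_function: tau_frames must lie in [1, n_frames)",
         call. = FALSE)

  # radial q-bin index per Fourier mode
  fx <- c(0:(nx %/% 2), -((nx - nx %/% 2 - 1):1)) / (nx * stack$pixel_size)
  fy <- c(0:(ny %/% 2), -((ny - ny %/% 2 - 1):1)) / (ny * stack$pixel_size)
  qmat <- 2 * pi * sqrt(outer(fy^2, fx^2, "+"))
  dq <- 2 * pi / (min(nx, ny) * stack$pixel_size)
  bin <- round(qmat / dq)
  bin[bin < 1] <- 1
  bin[1, 1] <- NA                        # drop the DC mode
  binv <- as.integer(bin)
  nbin <- max(binv, na.rm = TRUE)
  n_modes <- tabulate(binv, nbins = nbin)

  # FFT cache over the frames actually needed
  fhat <- vector("list", nf)
  get_fft <- function(t) {
    if (is.null(fhat[[t]])) fhat[[t]] <<- stats::fft(stack$frames[, , t])
    fhat[[t]]
  }

  npix <- nx * ny
  g <- matrix(NA_real_, nbin, length(tau_frames))
  for (j in seq_along(tau_frames)) {
    k <- tau_frames[j]
    origins <- seq_len(nf - k)
    if (length(origins) > max_origins)
      origins <- unique(round(seq(1, nf - k, length.out = max_origins)))
    acc <- numeric(npix)
    for (t0 in origins) {
      dF <- get_fft(t0 + k) - get_fft(t0)
      acc <- acc + Re(dF)^2 + Im(dF)^2
    }
    acc <- acc / (length(origins) * npix)
    sums <- rowsum(acc[!is.na(bin)], binv[!is.na(bin)])
    g[as.integer(rownames(sums)), j] <- sums / n_modes[as.integer(rownames(sums))]
  }

  keep <- n_modes >= min_modes
  structure(list(q = (seq_len(nbin) * dq)[keep], tau = tau_frames *
                   stack$frame_interval, g = g[keep, , drop = FALSE],
                 n_modes = n_modes[keep], pixel_size = stack$pixel_size,
                 frame_interval = stack$frame_interval),
            class = "structure_function")
}

#' @export
print.structure_function <- function(x, ...) {
  cat("<structure_function>", length(x$q), "q bins in [",
      signif(min(x$q), 3), ",", signif(max(x$q), 3), "] um^-1,",
      length(x$tau), "lags in [", signif(min(x$tau), 3), ",",
      signif(max(x$tau), 3), "] s\n")
  invisible(x)
}

#' Schulz swimming term of the intermediate scattering function
#'
#' The ISF of straight swimmers whose speeds follow a Schulz distribution of
#' mean `v` and relative width `sigma/v` (so `Z = (v/sigma)^2 - 1`), as a
#' function of the reduced variable `x = q v tau`:
#' `Ws(x; Z) = ((Z + 1)/(Z x)) * sin(Z atan(x/(Z + 1))) /
#'  (1 + (x/(Z + 1))^2)^(Z/2)`.
#' As `sigma -> 0` (`Z -> Inf`) this tends to `sinc(x)`, the single-speed
#' limit.
#'
#' @param x reduced variable `q v tau`, >= 0.
#' @param Z Schulz parameter, > 0.
#' @return dimensionless ISF value(s) in `[-1, 1]`.
#' @export
schulz_isf <- function(x, Z) {
  stopifnot(Z > 0)
  small <- abs(x) < 1e-8
  out <- numeric(length(x))
  out[small] <- 1
  xs <- x[!small]
  out[!small] <- ((Z + 1) / (Z * xs)) * sin(Z * atan(xs / (Z + 1))) /
    (1 + (xs / (Z + 1))^2)^(Z / 2)
  out
}

# full ISF model: diffusive envelope times (1 - alpha + alpha * swimming)
isf_model <- function(tau, q, D, v, sigma, alpha) {
  Z <- max((v / sigma)^2 - 1, 1e-6)
  exp(-D * q^2 * tau) * ((1 - alpha) + alpha * schulz_isf(q * v * tau, Z))
}

#' Fit the swimming ISF model per q bin
#'
#' For each `q` bin in `q_range`, fits
#' `g(q, tau) = A(q) * (1 - f(q, tau)) + B(q)` with
#' `f(q, tau) = exp(-D q^2 tau) * ((1 - alpha) + alpha * Ws(q v tau; Z))`:
#' a common diffusive envelope with a swimming fraction `alpha` whose speeds
#' are Schulz-distributed (mean `v`, width `sigma`, `Z = (v/sigma)^2 - 1`).
#' Signal and noise plateaus `A`, `B` are initialized from the large- and
#' small-tau limits of `g` and refined in the fit; the kinetic parameters
#' are found by bounded least squares with a multistart over `v`.
#'
#' @param sf a [image_structure_function()] result.
#' @param q_range fit window (um^-1), default `c(0.4, 2.2)`.
#' @param v_starts multistart grid for the mean speed (um/s).
#' @param alpha_fixed optionally pin the swimming fraction (e.g. `0` for a
#'   purely diffusing sample, `1` for fully motile), removing the
#'   diffusion/slow-swimming degeneracy when the fraction is known.
#' @return an object of class `isf_fit`: data.frame `table` with per-q
#'   `A`, `B`, `D`, `v`, `sigma`, `alpha`, residual RMS and a convergence
#'   flag; failed bins are flagged and excluded from downstream averages.
#' @export
fit_isf <- function(sf, q_range = c(0.4, 2.2), v_starts = c(5, 15, 30),
                    alpha_fixed = NULL) {
  stopifnot(inherits(sf, "structure_function"))
  if (length(sf$tau) < 20)
    stop("fit_isf: need at least 20 tau points", call. = FALSE)
  sel <- which(sf$q >= q_range[1] & sf$q <= q_range[2])
  if (!length(sel)) stop("fit_isf: no q bins inside q_range", call. = FALSE)
  rows <- lapply(sel, function(i) {
    q <- sf$q[i]
    y <- sf$g[i, ]
    ok <- is.finite(y)
    tau <- sf$tau[ok]; y <- y[ok]
    B0 <- max(min(y) * 0.5, 1e-12)
    A0 <- max(max(y) - B0, 1e-12)
    best <- NULL
    afree <- is.null(alpha_fixed)
    for (v0 in v_starts) {
      # parameters: A, B, D, v, sigma_rel (, alpha when free), bounded
      p0 <- c(A0, B0, 0.05, v0, 0.25, if (afree) 0.9)
      lo <- c(A0 * 1e-3, 0, 0, 0.5, 0.02, if (afree) 0)
      hi <- c(A0 * 10, max(B0 * 10, A0), 20, 150, 0.7, if (afree) 1)
      fit <- tryCatch(minpack.lm::nls.lm(
        par = p0, lower = lo, upper = hi,
        fn = function(p) {
          al <- if (afree) p[6] else alpha_fixed
          f <- isf_model(tau, q, p[3], p[4], p[4] * p[5], al)
          p[1] * (1 - f) + p[2] - y
        },
        control = minpack.lm::nls.lm.control(maxiter = 300)),
        error = function(e) NULL)
      if (is.null(fit)) next
      ssr <- sum(fit$fvec^2)
      if (is.null(best) || ssr < best$ssr) best <- list(fit = fit, ssr = ssr)
    }
    if (is.null(best))
      return(data.frame(q = q, A = NA, B = NA, D = NA, v = NA, sigma = NA,
                        alpha = NA, rms = NA, converged = FALSE))
    p <- best$fit$par
    data.frame(q = q, A = p[1], B = p[2], D = p[3], v = p[4],
               sigma = p[4] * p[5],
               alpha = if (afree) p[6] else alpha_fixed,
               rms = sqrt(best$ssr / length(y)),
               converged = best$fit$info %in% 1:4)
  })
  tab <- do.call(rbind, rows)
  bad <- !tab$converged | !is.finite(tab$v)
  if (any(bad))
    message("fit_isf: ", sum(bad), " of ", nrow(tab), " q bins flagged")
  structure(list(table = tab, q_range = q_range, tau = sf$tau),
            class = "isf_fit")
}

#' @export
print.isf_fit <- function(x, ...) {
  ok <- x$table$converged
  cat("<isf_fit>", sum(ok), "of", nrow(x$table), "q bins converged\n")
  if (any(ok))
    cat("  v:", signif(mean(x$table$v[ok]), 4), "um/s, sigma:",
        signif(mean(x$table$sigma[ok]), 4), "um/s (means over fitted bins)\n")
  invisible(x)
}

#' @export
coef.isf_fit <- function(object, ...) object$table

#' @export
plot.isf_fit <- function(x, ...) {
  ok <- x$table$converged
  graphics::plot(x$table$q[ok], x$table$v[ok], pch = 16,
                 xlab = "q (1/um)", ylab = "fitted v (um/s)", ...)
  invisible(x)
}

#' Population motility summary from an ISF fit
#'
#' Averages the per-q fitted mean speed and width over the analysis window
#' `q_window` to report `v`, `sigma` and the relative width `S = sigma/v`,
#' and forms the path-straightness ratio `R = v(L1)/v(L2)` from the fitted
#' speeds at the q bins nearest `2 pi / L1` and `2 pi / L2`. Straight paths
#' give `R = 1`; rotational diffusion or tumbling raises `R` above 1 because
#' the large-length-scale (small q) speed is depressed by reorientation.
#'
#' @param fit an [fit_isf()] result.
#' @param q_window averaging window (um^-1), default `c(0.5, 2)`
#'   (length scales 3-13 um).
#' @param L1,L2 the two length scales (um) of the ratio, `L1 < L2`.
#' @return an object of class `ddm_result` with `v`, `sigma`, `S`, `R`, the
#'   window, and the q bins used for `R`.
#' @export
ddm_summary <- function(fit, q_window = c(0.5, 2), L1 = 3, L2 = 13) {
  stopifnot(inherits(fit, "isf_fit"))
  tab <- fit$table[fit$table$converged & is.finite(fit$table$v), ]
  if (!nrow(tab)) stop("ddm_summary: no converged q bins", call. = FALSE)
  win <- tab[tab$q >= q_window[1] & tab$q <= q_window[2], ]
  if (!nrow(win)) stop("ddm_summary: empty q window after exclusions",
                       call. = FALSE)
  v <- mean(win$v)
  sigma <- mean(win$sigma)
  q1 <- 2 * pi / L1; q2 <- 2 * pi / L2
  i1 <- which.min(abs(tab$q - q1))
  i2 <- which.min(abs(tab$q - q2))
  R <- tab$v[i1] / tab$v[i2]
  structure(list(v = v, sigma = sigma, S = sigma / v, R = R,
                 q_window = q_window, L1 = L1, L2 = L2,
                 q_used = c(tab$q[i1], tab$q[i2]),
                 n_bins = nrow(win)),
            class = "ddm_result")
}

#' @export
print.ddm_result <- function(x, ...) {
  cat("<ddm_result> v =", signif(x$v, 4), "um/s, sigma =",
      signif(x$sigma, 4), "um/s, S =", signif(x$S, 3),
      ", R =", signif(x$R, 4), "\n")
  cat("  q window [", x$q_window[1], ",", x$q_window[2], "] um^-1 (",
      x$n_bins, "bins ); R from q =", signif(x$q_used[1], 3), "and",
      signif(x$q_used[2], 3), "um^-1\n")
  invisible(x)
}
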