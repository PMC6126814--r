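# Two-state ("swimming" / "tumbling") hidden Markov model over frame
# features, with bivariate Gaussian emissions on (relative acceleration,
# |angular acceleration|). Trained by Baum-Welch on pooled trajectories,
# decoded by Viterbi so tumble events come out as contiguous runs.

COV_FLOOR <- 1e-8

#' Train the two-state swim/tumble hidden Markov model
#'
#' Runs Baum-Welch over the pooled frame features of a reference track set
#' (ideally wild-type-like trajectories containing both smooth runs and
#' finite-duration tumbles). Emissions are bivariate Gaussians over
#' (relative acceleration, |angular acceleration|); using the absolute
#' angular acceleration makes left and right turns equivalent. After
#' training, the state with the larger mean |angular acceleration| is
#' labeled "tumbling"; on an exact tie state 1 is kept as "swimming".
#'
#' @param reference a [track_set()] used as the training corpus.
#' @param max_iter maximum Baum-Welch iterations.
#' @param tol convergence threshold on the log-likelihood gain per frame.
#' @return an object of class `tumble_model`: transition matrix (rows
#'   "swimming", "tumbling"), emission means and covariances, initial state
#'   distribution, and the training log-likelihood trace.
#' @seealso [classify_tumbles()]
#' @export
train_tumble_model <- function(reference, max_iter = 500, tol = 1e-6) {
  stopifnot(inherits(reference, "track_set"))
  seqs <- lapply(reference$trajectories,
                 function(tr) feature_matrix(compute_frame_features(tr)))
  seqs <- seqs[vapply(seqs, nrow, integer(1)) >= 2]
  if (!length(seqs)) stop("train_tumble_model: no usable trajectories", call. = FALSE)
  n_frames <- sum(vapply(seqs, nrow, integer(1)))

  # moment initialization: top-decile |angular acceleration| seeds "tumbling"
  pooled <- do.call(rbind, seqs)
  thr <- stats::quantile(pooled[, 2], 0.9, names = FALSE)
  hi <- pooled[, 2] >= thr
  mu <- rbind(colMeans(pooled[!hi, , drop = FALSE]),
              colMeans(pooled[hi, , drop = FALSE]))
  sig <- list(reg_cov(stats::cov(pooled[!hi, , drop = FALSE])),
              reg_cov(stats::cov(pooled[hi, , drop = FALSE])))
  A <- matrix(c(0.95, 0.05, 0.2, 0.8), 2, 2, byrow = TRUE)
  init <- c(0.9, 0.1)

  groups <- split(seq_along(seqs), vapply(seqs, nrow, integer(1)))
  ll_trace <- numeric(0)
  prev_ll <- -Inf
  for (iter in seq_len(max_iter)) {
    stats0 <- list(ll = 0, g_sum = matrix(0, 1, 2), g1 = c(0, 0),
                   xi = matrix(0, 2, 2),
                   m1 = matrix(0, 2, 2),      # state x feature weighted sums
                   m2 = vector("list", 2))
    stats0$m2 <- list(matrix(0, 2, 2), matrix(0, 2, 2))
    for (idx in groups) {
      es <- hmm_estep_group(seqs[idx], mu, sig, A, init)
      stats0$ll <- stats0$ll + es$ll
      stats0$g1 <- stats0$g1 + es$g1
      stats0$xi <- stats0$xi + es$xi
      for (s in 1:2) {
        stats0$m1[s, ] <- stats0$m1[s, ] + es$m1[s, ]
        stats0$m2[[s]] <- stats0$m2[[s]] + es$m2[[s]]
      }
      stats0$g_sum <- stats0$g_sum + es$g_sum
    }
    ll <- stats0$ll
    ll_trace <- c(ll_trace, ll)
    # M-step
    wts <- as.numeric(stats0$g_sum)
    for (s in 1:2) {
      mu[s, ] <- stats0$m1[s, ] / wts[s]
      cv <- stats0$m2[[s]] / wts[s] - tcrossprod(mu[s, ])
      sig[[s]] <- reg_cov((cv + t(cv)) / 2)
    }
    A <- stats0$xi / rowSums(stats0$xi)
    init <- stats0$g1 / sum(stats0$g1)
    if (is.finite(prev_ll) && (ll - prev_ll) / n_frames < tol) break
    prev_ll <- ll
  }

  # label states by mean |angular acceleration|
  if (mu[1, 2] > mu[2, 2]) {        # swap so state 2 is "tumbling"
    mu <- mu[2:1, , drop = FALSE]
    sig <- sig[2:1]
    A <- A[2:1, 2:1]
    init <- init[2:1]
  } else if (mu[1, 2] == mu[2, 2]) {
    message("train_tumble_model: emission means tied; keeping state 1 as swimming")
  }
  dimnames(A) <- list(c("swimming", "tumbling"), c("swimming", "tumbling"))
  rownames(mu) <- c("swimming", "tumbling")
  colnames(mu) <- c("rel_acc", "abs_ang_acc")
  structure(list(transition = A, means = mu, covariances = sig,
                 initial = init, loglik = ll_trace,
                 n_frames = n_frames, iterations = length(ll_trace)),
            class = "tumble_model")
}

reg_cov <- function(cv) {
  if (any(!is.finite(cv))) cv[!is.finite(cv)] <- 0
  if (any(diag(cv) < COV_FLOOR)) {
    warning("degenerate emission covariance; applying diagonal floor")
    diag(cv) <- pmax(diag(cv), COV_FLOOR)
  }
  cv
}

# log density of rows of X under a bivariate Gaussian
ldmvn2 <- function(X, mu, sig) {
  d <- det(sig)
  pr <- solve(sig)
  xc <- sweep(X, 2, mu)
  q <- pr[1, 1] * xc[, 1]^2 + 2 * pr[1, 2] * xc[, 1] * xc[, 2] +
    pr[2, 2] * xc[, 2]^2
  -log(2 * pi) - 0.5 * log(d) - 0.5 * q
}

# Scaled forward-backward for a group of equal-length sequences, vectorized
# across the group. Returns the summed sufficient statistics.
hmm_estep_group <- function(seqs, mu, sig, A, init) {
  G <- length(seqs)
  T_ <- nrow(seqs[[1]])
  X <- do.call(rbind, seqs)                   # (G*T_) x 2, sequence-major
  l1 <- matrix(ldmvn2(X, mu[1, ], sig[[1]]), T_, G)
  l2 <- matrix(ldmvn2(X, mu[2, ], sig[[2]]), T_, G)
  m <- pmax(l1, l2)
  b1 <- exp(l1 - m); b2 <- exp(l2 - m)        # scaled emission densities

  a1 <- matrix(0, T_, G); a2 <- matrix(0, T_, G)
  logc <- matrix(0, T_, G)
  f1 <- init[1] * b1[1, ]; f2 <- init[2] * b2[1, ]
  cs <- f1 + f2
  a1[1, ] <- f1 / cs; a2[1, ] <- f2 / cs
  logc[1, ] <- log(cs) + m[1, ]
  for (t in 2:T_) {
    f1 <- (a1[t - 1, ] * A[1, 1] + a2[t - 1, ] * A[2, 1]) * b1[t, ]
    f2 <- (a1[t - 1, ] * A[1, 2] + a2[t - 1, ] * A[2, 2]) * b2[t, ]
    cs <- f1 + f2
    a1[t, ] <- f1 / cs; a2[t, ] <- f2 / cs
    logc[t, ] <- log(cs) + m[t, ]
  }
  ll <- sum(logc)

  bb1 <- matrix(0, T_, G); bb2 <- matrix(0, T_, G)
  bb1[T_, ] <- 1; bb2[T_, ] <- 1
  xi <- matrix(0, 2, 2)
  for (t in (T_ - 1):1) {
    e1 <- b1[t + 1, ] * bb1[t + 1, ]
    e2 <- b2[t + 1, ] * bb2[t + 1, ]
    u1 <- A[1, 1] * e1 + A[1, 2] * e2
    u2 <- A[2, 1] * e1 + A[2, 2] * e2
    cs <- a1[t, ] * u1 + a2[t, ] * u2        # equals forward scale c_{t+1}
    bb1[t, ] <- u1 / cs; bb2[t, ] <- u2 / cs
    xi[1, 1] <- xi[1, 1] + sum(a1[t, ] * A[1, 1] * e1 / cs)
    xi[1, 2] <- xi[1, 2] + sum(a1[t, ] * A[1, 2] * e2 / cs)
    xi[2, 1] <- xi[2, 1] + sum(a2[t, ] * A[2, 1] * e1 / cs)
    xi[2, 2] <- xi[2, 2] + sum(a2[t, ] * A[2, 2] * e2 / cs)
  }
  g1 <- a1 * bb1; g2 <- a2 * bb2
  norm <- g1 + g2
  g1 <- g1 / norm; g2 <- g2 / norm

  w1 <- as.numeric(g1); w2 <- as.numeric(g2)  # sequence-major like X
  m1 <- rbind(colSums(X * w1), colSums(X * w2))
  m2 <- list(crossprod(X * sqrt(w1)), crossprod(X * sqrt(w2)))
  list(ll = ll,
       g1 = c(sum(g1[1, ]), sum(g2[1, ])),
       g_sum = matrix(c(sum(w1), sum(w2)), 1, 2),
       xi = xi, m1 = m1, m2 = m2)
}

#' @export
print.tumble_model <- function(x, ...) {
  cat("<tumble_model> two-state HMM,", x$iterations, "Baum-Welch iterations on",
      x$n_frames, "frames\n")
  cat("transition matrix:\n")
  print(round(x$transition, 4))
  cat("emission means:\n")
  print(round(x$means, 4))
  invisible(x)
}

#' Classify tumbles along a trajectory
#'
#' Viterbi-decodes the frame features of a trajectory under a trained
#' [train_tumble_model()] and reports the hard state path, the tumble bias
#' (fraction of frames in the tumbling state) and the tumble events (maximal
#' runs of the tumbling state).
#'
#' @param traj a [trajectory()].
#' @param model a `tumble_model`.
#' @param trim frames removed from each end of a detected tumbling run
#'   (keeping at least one frame) before the bias is computed. The
#'   acceleration features are second differences spanning three frame
#'   displacements, so a detected run overhangs the underlying tumble
#'   interval by about one frame per side; the default `trim = 1`
#'   compensates for that known kernel width. `trim = 0` reports the raw
#'   Viterbi occupancy.
#' @return list with `states` (factor, per interior frame, trimmed),
#'   `tumble_bias`, and `events` (data.frame of start/end frame indices and
#'   durations in s).
#' @export
classify_tumbles <- function(traj, model, trim = 1L) {
  stopifnot(inherits(model, "tumble_model"))
  feats <- compute_frame_features(traj)
  X <- feature_matrix(feats)
  path <- hmm_viterbi(X, model)
  r <- rle(path == 2L)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  starts <- starts[keep]; ends <- ends[keep]
  if (trim > 0L && length(starts)) {
    width <- ends - starts + 1L
    cut <- pmin(trim, (width - 1L) %/% 2L)
    path[] <- 1L
    starts <- starts + cut; ends <- ends - cut
    for (e in seq_along(starts)) path[starts[e]:ends[e]] <- 2L
  }
  events <- data.frame(start_frame = starts, end_frame = ends)
  events$duration_s <- (events$end_frame - events$start_frame + 1L) * feats$dt
  list(states = factor(c("swimming", "tumbling")[path],
                       levels = c("swimming", "tumbling")),
       tumble_bias = mean(path == 2L), events = events)
}

hmm_viterbi <- function(X, model) {
  T_ <- nrow(X)
  l1 <- ldmvn2(X, model$means[1, ], model$covariances[[1]])
  l2 <- ldmvn2(X, model$means[2, ], model$covariances[[2]])
  lA <- log(model$transition)
  d1 <- log(model$initial[1]) + l1[1]
  d2 <- log(model$initial[2]) + l2[1]
  back <- matrix(1L, T_, 2)
  if (T_ > 1) for (t in 2:T_) {
    c11 <- d1 + lA[1, 1]; c21 <- d2 + lA[2, 1]
    c12 <- d1 + lA[1, 2]; c22 <- d2 + lA[2, 2]
    if (c11 >= c21) { n1 <- c11; back[t, 1] <- 1L } else { n1 <- c21; back[t, 1] <- 2L }
    if (c12 >= c22) { n2 <- c12; back[t, 2] <- 1L } else { n2 <- c22; back[t, 2] <- 2L }
    d1 <- n1 + l1[t]; d2 <- n2 + l2[t]
  }
  path <- integer(T_)
  path[T_] <- if (d1 >= d2) 1L else 2L
  if (T_ > 1) for (t in (T_ - 1):1) path[t] <- back[t + 1, path[t + 1]]
  path
}
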