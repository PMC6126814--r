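# File interchange: trajectory CSV, correlation-curve CSV, TIFF image stacks
# with YAML metadata sidecars, and JSON serialization of fitted models.

#' Write / read a track set as CSV
#'
#' Long-format CSV with mandatory header `cell_id,t_s,x_um,y_um` (UTF-8,
#' '.' decimal). Ground-truth per-cell parameters, when present, go to a
#' sidecar CSV `<path>.truth.csv` with columns `cell_id,v_um_s,psi_rad_s,
#' n_tumbles`.
#'
#' @param tracks a [track_set()].
#' @param path output CSV path.
#' @param ground_truth also write the sidecar when ground truth is present.
#' @return `path`, invisibly.
#' @export
write_tracks_csv <- function(tracks, path, ground_truth = TRUE) {
  stopifnot(inherits(tracks, "track_set"))
  rows <- lapply(seq_along(tracks$trajectories), function(i) {
    tr <- tracks$trajectories[[i]]
    data.frame(cell_id = i, t_s = tr$times, x_um = tr$x, y_um = tr$y)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  gt <- tracks$ground_truth
  if (ground_truth && !is.null(gt$v)) {
    utils::write.csv(
      data.frame(cell_id = seq_along(gt$v), v_um_s = gt$v,
                 psi_rad_s = gt$psi,
                 n_tumbles = if (!is.null(gt$n_tumbles)) gt$n_tumbles else NA),
      paste0(path, ".truth.csv"), row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  need <- c("cell_id", "t_s", "x_um", "y_um")
  if (!all(need %in% names(df)))
    stop("read_tracks_csv: header must contain ", paste(need, collapse = ","),
         call. = FALSE)
  trajs <- lapply(split(df, df$cell_id), function(d)
    trajectory(d$t_s, d$x_um, d$y_um))
  names(trajs) <- NULL
  track_set(trajs)
}

#' Write / read a correlation curve as CSV
#'
#' Columns `lag_s,value,n_pairs`.
#'
#' @param curve a `correlation_curve` from [empirical_acf()] or
#'   [empirical_msd()].
#' @param path CSV path.
#' @return `path` invisibly; `read_correlation_csv` returns the curve.
#' @export
write_correlation_csv <- function(curve, path) {
  stopifnot(inherits(curve, "correlation_curve"))
  utils::write.csv(curve[, c("lag_s", "value", "n_pairs")], path,
                   row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_correlation_csv
#' @param kind `"acf"` or `"msd"` label restored on read.
#' @export
read_correlation_csv <- function(path, kind = "acf") {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  correlation_curve(df$lag_s, df$value, df$n_pairs, kind = kind)
}

#' Write / read an image stack as multi-page TIFF plus YAML sidecar
#'
#' Frames are stored scaled into [0, 1] (16-bit); the scale factor and the
#' acquisition metadata live in a YAML sidecar `<path>.yaml` with keys
#' `pixel_size_um`, `frame_interval_s`, `modality`, `intensity_scale`,
#' `intensity_offset`. Reading restores intensities from the sidecar.
#'
#' @param stack an [image_stack()].
#' @param path TIFF path.
#' @return `path` invisibly; `read_image_stack` returns the stack.
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  lo <- min(stack$frames)
  hi <- max(stack$frames)
  scale <- max(hi - lo, .Machine$double.eps)
  nf <- dim(stack$frames)[3]
  pages <- lapply(seq_len(nf), function(t) (stack$frames[, , t] - lo) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  yaml::write_yaml(list(pixel_size_um = stack$pixel_size,
                        frame_interval_s = stack$frame_interval,
                        modality = stack$modality,
                        intensity_scale = scale, intensity_offset = lo),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_image_stack
#' @param metadata sidecar path; defaults to `<path>.yaml`.
#' @export
read_image_stack <- function(path, metadata = paste0(path, ".yaml")) {
  meta <- yaml::read_yaml(metadata)
  pages <- tiff::readTIFF(path, all = TRUE)
  frames <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (t in seq_along(pages))
    frames[, , t] <- pages[[t]] * meta$intensity_scale + meta$intensity_offset
  frames[frames < 0] <- 0
  image_stack(frames, meta$pixel_size_um, meta$frame_interval_s,
              meta$modality)
}

#' Serialize / restore a tumble model as JSON
#'
#' @param model a [train_tumble_model()] fit.
#' @param path JSON path.
#' @return `path` invisibly; `read_tumble_model` returns the model.
#' @export
write_tumble_model <- function(model, path) {
  stopifnot(inherits(model, "tumble_model"))
  jsonlite::write_json(list(
    transition = model$transition, means = model$means,
    covariances = model$covariances, initial = model$initial),
    path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_tumble_model
#' @export
read_tumble_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  A <- matrix(unlist(obj$transition), 2, 2)
  dimnames(A) <- list(c("swimming", "tumbling"), c("swimming", "tumbling"))
  mu <- matrix(unlist(obj$means), 2, 2)
  rownames(mu) <- c("swimming", "tumbling")
  colnames(mu) <- c("rel_acc", "abs_ang_acc")
  covs <- if (is.list(obj$covariances))
    lapply(obj$covariances, function(m) matrix(unlist(m), 2, 2))
  else
    lapply(1:2, function(s) matrix(obj$covariances[s, , ], 2, 2))
  structure(list(transition = A, means = mu, covariances = covs,
                 initial = as.numeric(obj$initial), loglik = numeric(0),
                 n_frames = NA_integer_, iterations = NA_integer_),
            class = "tumble_model")
}

#' Write a fit report as JSON
#'
#' Flat JSON dump of the numeric components of a fitted-model object
#' (`circular_rt_fit`, `ddm_result`, `dfm_result`, `ruler_fit`,
#' `motility_summary`).
#'
#' @param fit the fitted object.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  keep <- Filter(function(v) is.numeric(v) || is.character(v),
                 unclass(fit)[!names(unclass(fit)) %in%
                                c("acf", "msd", "fitted", "lm", "data",
                                  "spectrum", "residuals")])
  jsonlite::write_json(keep, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
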