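# Phenotype utilities: molecular-ruler calibration of hook length,
# motility-halo normalization, and reporter relative light units.

#' Fit the molecular ruler line to hook-length measurements
#'
#' Ordinary least squares of hook length against ruler protein length.
#' By default each mutant's mean hook length enters the regression (one
#' point per distinct ruler length), matching how calibration data are
#' usually summarized; `per_point = TRUE` regresses on the raw
#' measurements instead. Records flagged uncontrolled (mutants whose hook
#' length escapes ruler control) are excluded.
#'
#' @param measurements data.frame with columns `flik_length` (amino acids),
#'   `hook_length` (nm) and optionally `controlled` (logical, default all
#'   `TRUE`), e.g. from [sample_hook_lengths()].
#' @param per_point regress on raw measurements rather than per-mutant
#'   means.
#' @return an object of class `ruler_fit`: slope (nm per amino acid),
#'   intercept (nm), `r_squared`, residuals, and the underlying [stats::lm()]
#'   fit; methods: `print`, `coef`, `predict`.
#' @export
fit_ruler <- function(measurements, per_point = FALSE) {
  stopifnot(all(c("flik_length", "hook_length") %in% names(measurements)))
  ctrl <- if ("controlled" %in% names(measurements))
    as.logical(measurements$controlled) else rep(TRUE, nrow(measurements))
  m <- measurements[ctrl & is.finite(measurements$flik_length) &
                      is.finite(measurements$hook_length), , drop = FALSE]
  if (!nrow(m)) stop("fit_ruler: all records uncontrolled", call. = FALSE)
  if (length(unique(m$flik_length)) < 2)
    stop("fit_ruler: need >= 2 distinct ruler lengths", call. = FALSE)
  dat <- if (per_point) {
    data.frame(flik = m$flik_length, hook = m$hook_length)
  } else {
    mh <- tapply(m$hook_length, m$flik_length, mean)
    data.frame(flik = as.numeric(names(mh)), hook = as.numeric(mh))
  }
  lmfit <- stats::lm(hook ~ flik, data = dat)
  structure(list(slope = unname(stats::coef(lmfit)[2]),
                 intercept = unname(stats::coef(lmfit)[1]),
                 r_squared = summary(lmfit)$r.squared,
                 residuals = stats::residuals(lmfit),
                 data = dat, per_point = per_point, lm = lmfit),
            class = "ruler_fit")
}

#' @export
print.ruler_fit <- function(x, ...) {
  cat("<ruler_fit> hook length =", signif(x$slope, 3), "nm/aa * FliK",
      ifelse(x$intercept < 0, "-", "+"), signif(abs(x$intercept), 3),
      "nm  (R^2 =", signif(x$r_squared, 4), ")\n")
  invisible(x)
}

#' @export
coef.ruler_fit <- function(object, ...) {
  c(slope = object$slope, intercept = object$intercept)
}

#' @export
predict.ruler_fit <- function(object, flik_length, ...) {
  object$intercept + object$slope * flik_length
}

#' @export
plot.ruler_fit <- function(x, ...) {
  graphics::plot(x$data$flik, x$data$hook, pch = 16,
                 xlab = "FliK length (aa)", ylab = "hook length (nm)", ...)
  graphics::abline(x$intercept, x$slope, col = "red")
  invisible(x)
}

#' Normalize motility halo areas to a reference strain
#'
#' Divides each halo (or disk) area by the mean area of the reference
#' strain, per batch when a `batch` column is present. Batches missing the
#' reference are flagged (`normalized_area = NA`) rather than dropped.
#' Idempotent on batches whose reference already averages 1.
#'
#' @param table data.frame with columns `strain`, `area` and optionally
#'   `batch`.
#' @param reference_strain the strain to normalize to.
#' @return the table with a `normalized_area` column and attribute
#'   `missing_reference` listing flagged batches.
#' @export
normalize_halos <- function(table, reference_strain) {
  stopifnot(all(c("strain", "area") %in% names(table)))
  if (!reference_strain %in% table$strain)
    stop("normalize_halos: reference strain absent from table", call. = FALSE)
  batch <- if ("batch" %in% names(table)) as.character(table$batch)
           else rep("all", nrow(table))
  out <- table
  out$normalized_area <- NA_real_
  flagged <- character(0)
  for (b in unique(batch)) {
    sel <- batch == b
    ref <- table$area[sel & table$strain == reference_strain]
    if (!length(ref)) {
      flagged <- c(flagged, b)
      warning("normalize_halos: batch '", b, "' lacks the reference strain")
      next
    }
    out$normalized_area[sel] <- table$area[sel] / mean(ref)
  }
  attr(out, "missing_reference") <- flagged
  out
}

#' Relative light units of a luciferase reporter
#'
#' `RLU = light * OD(t = 0) / OD(t = n)`: raw luminescence corrected for
#' growth between inoculation and reading, using blank-corrected optical
#' densities.
#'
#' @param light luminescence reading (a.u.).
#' @param od_t0 optical density at time zero.
#' @param od_tn optical density at the reading time, > 0.
#' @return RLU (a.u.), vectorized.
#' @export
compute_rlu <- function(light, od_t0, od_tn) {
  if (any(!is.finite(od_tn)) || any(od_tn <= 0))
    stop("compute_rlu: od_tn must be > 0", call. = FALSE)
  light * od_t0 / od_tn
}
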