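#' Framewise displacement from rigid-body realignment parameters
#'
#' Computes the per-frame head-motion summary of Power et al.: the sum of
#' absolute backward differences of the three translations (mm) plus the three
#' rotations (radians) converted to arc length on a sphere of radius
#' `rotation_radius_mm`. The first frame has no predecessor and gets FD 0.
#'
#' A `literal` mode instead sums the absolute parameter values themselves
#' (no temporal differencing, rotations still converted to mm); it exists for
#' sensitivity analyses against the non-standard reading of that definition
#' and is not used by the pipeline default.
#'
#' @param motion T x 6 matrix: translations in mm, rotations in radians.
#' @param rotation_radius_mm Sphere radius for rotation-to-mm conversion.
#' @param literal Use the no-differencing variant.
#' @return Numeric T-vector of FD in mm, `fd[1] = 0` (differenced mode).
#' @export
framewise_displacement <- function(motion, rotation_radius_mm = 50,
                                   literal = FALSE) {
  motion <- as.matrix(motion)
  if (!all(is.finite(motion))) stop("motion parameters contain non-finite values")
  if (ncol(motion) != 6) stop("motion must have 6 columns")
  if (nrow(motion) < 2) stop("need at least 2 frames to compute FD")
  scaled <- cbind(motion[, 1:3, drop = FALSE],
                  rotation_radius_mm * motion[, 4:6, drop = FALSE])
  if (literal) {
    return(rowSums(abs(scaled)))
  }
  d <- abs(diff(scaled))
  c(0, rowSums(d))
}

#' Motion-scrubbing mask
#'
#' Marks for removal every frame whose FD exceeds `threshold_mm` (strictly),
#' together with `n_before` frames before and `n_after` frames after each
#' excursion, clipped at the run boundaries.
#'
#' @param fd Numeric FD vector (mm).
#' @param threshold_mm Scrubbing threshold; comparison is `fd > threshold`.
#' @param n_before,n_after Padding window around each excursion.
#' @return Logical keep-vector of the same length as `fd`.
#' @export
scrub_mask <- function(fd, threshold_mm = 0.5, n_before = 1L, n_after = 2L) {
  if (!all(is.finite(fd))) stop("fd contains non-finite values")
  if (threshold_mm <= 0) stop("threshold_mm must be positive")
  T <- length(fd)
  keep <- rep(TRUE, T)
  for (s in which(fd > threshold_mm)) {
    lo <- max(1L, s - n_before)
    hi <- min(T, s + n_after)
    keep[lo:hi] <- FALSE
  }
  keep
}

#' Minimum retained-duration gate
#'
#' @param keep Logical keep-vector from [scrub_mask()].
#' @param TR Repetition time in seconds.
#' @param min_seconds Minimum retained scan time (default 240 s = 4 min).
#' @return `TRUE` iff `sum(keep) * TR >= min_seconds`.
#' @export
min_duration_ok <- function(keep, TR, min_seconds = 240) {
  stopifnot(TR > 0)
  sum(keep) * TR >= min_seconds
}

# Shared least-squares residualization engine: residuals of each column of
# `data` on [intercept, regressors], with named rank-deficiency diagnostics.
ls_residuals <- function(data, regressors, what = "regressor") {
  data <- as.matrix(data)
  X <- cbind(`(intercept)` = 1, as.matrix(regressors))
  if (ncol(X) - 1 >= nrow(X)) stop("more regressors than observations")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    if (is.null(bad)) bad <- qrX$pivot[(qrX$rank + 1):ncol(X)]
    stop("design is rank deficient; offending ", what, " column(s): ",
         paste(bad, collapse = ", "))
  }
  qr.resid(qrX, data)
}

#' Nuisance regression
#'
#' Removes the least-squares fit of the supplied nuisance regressors (plus an
#' always-included intercept) from every voxel time-course.
#'
#' @param data T x V time-course matrix.
#' @param regressors T x K nuisance matrix (e.g. WM and CSF mean signals and
#'   the six motion parameters).
#' @return T x V residual matrix, orthogonal to the design span.
#' @export
nuisance_regress <- function(data, regressors) {
  data <- as.matrix(data)
  regressors <- as.matrix(regressors)
  if (nrow(regressors) != nrow(data)) stop("regressor rows must match data rows")
  ls_residuals(data, regressors, what = "nuisance")
}

# Per-bin frequency (Hz) of an unshifted DFT of length T sampled every TR.
dft_freq <- function(T, TR) {
  k <- 0:(T - 1)
  pmin(k, T - k) / (T * TR)
}

#' Ideal frequency-domain band-pass filter
#'
#' Zeroes every Fourier coefficient whose frequency lies outside
#' `[f_lo, f_hi]` (the DC component is always removed) and inverse-transforms.
#' The hard cut makes the standard-deviation / ALFF equivalence exact.
#'
#' @param data T x V matrix or length-T vector.
#' @param TR Repetition time in seconds.
#' @param f_lo,f_hi Passband edges in Hz; `f_hi` must not exceed the Nyquist
#'   frequency `1 / (2 * TR)`.
#' @return Filtered data, same shape as the input.
#' @export
bandpass_filter <- function(data, TR, f_lo = 0.01, f_hi = 0.10) {
  vec <- is.null(dim(data))
  data <- as.matrix(data)
  T <- nrow(data)
  nyq <- 1 / (2 * TR)
  if (f_lo >= f_hi) stop("f_lo must be below f_hi")
  if (f_hi > nyq + 1e-12) {
    stop(sprintf("f_hi = %g Hz exceeds the Nyquist frequency %g Hz", f_hi, nyq))
  }
  freq <- dft_freq(T, TR)
  keep <- freq >= f_lo & freq <= f_hi
  keep[1] <- FALSE  # DC
  coef <- stats::mvfft(data)
  coef[!keep, ] <- 0
  out <- Re(stats::mvfft(coef, inverse = TRUE)) / T
  if (vec) out[, 1] else out
}

#' Per-voxel BOLD signal variability (standard deviation)
#'
#' Population standard deviation (divide by n) of each voxel time-course over
#' the kept frames only. The population convention pairs with [alff()] via
#' Parseval's identity; the subsequent within-participant z-scoring makes the
#' denominator choice immaterial downstream.
#'
#' @param data T x V matrix.
#' @param keep Logical keep-vector; `NULL` keeps every frame.
#' @return Length-V vector of SDs.
#' @export
variability_sd <- function(data, keep = NULL) {
  data <- as.matrix(data)
  if (!is.null(keep)) {
    if (length(keep) != nrow(data)) stop("keep length must match frame count")
    data <- data[keep, , drop = FALSE]
  }
  if (nrow(data) < 2) stop("need at least 2 kept frames to compute an SD")
  mu <- colMeans(data)
  sqrt(colMeans(sweep(data, 2, mu)^2))
}

#' Amplitude of low-frequency fluctuations (ALFF)
#'
#' Root of the summed squared Fourier amplitudes inside `[f_lo, f_hi]`,
#' normalized by the series length so that for a band-passed series it equals
#' [variability_sd()] exactly (Parseval).
#'
#' @inheritParams bandpass_filter
#' @return Length-V vector.
#' @export
alff <- function(data, TR, f_lo = 0.01, f_hi = 0.10) {
  vec <- is.null(dim(data))
  data <- as.matrix(data)
  T <- nrow(data)
  nyq <- 1 / (2 * TR)
  if (f_lo >= f_hi) stop("f_lo must be below f_hi")
  if (f_hi > nyq + 1e-12) {
    stop(sprintf("f_hi = %g Hz exceeds the Nyquist frequency %g Hz", f_hi, nyq))
  }
  freq <- dft_freq(T, TR)
  band <- freq >= f_lo & freq <= f_hi
  band[1] <- FALSE
  coef <- stats::mvfft(data)
  out <- sqrt(colSums(abs(coef[band, , drop = FALSE])^2)) / T
  if (vec) unname(out) else out
}

#' Mean-square successive differences (MSSD)
#'
#' Mean of squared first differences per voxel, computed only across pairs of
#' *consecutive* kept frames (a scrubbed gap contributes no pair).
#'
#' @param data T x V matrix.
#' @param keep Logical keep-vector; `NULL` keeps every frame.
#' @return Length-V vector.
#' @export
mssd <- function(data, keep = NULL) {
  data <- as.matrix(data)
  T <- nrow(data)
  if (is.null(keep)) keep <- rep(TRUE, T)
  if (length(keep) != T) stop("keep length must match frame count")
  pair <- which(keep[-T] & keep[-1])
  if (!length(pair)) stop("no consecutive pair of kept frames")
  d <- data[pair + 1, , drop = FALSE] - data[pair, , drop = FALSE]
  colMeans(d^2)
}

#' Analysis mask from gray-matter probability and exclusion masks
#'
#' `include = (gm_prob >= gm_threshold) & !exclusion`. Mirrors thresholding a
#' group gray-matter template at 50% probability and subtracting an exclusion
#' region (e.g. a cerebellum mask).
#'
#' @param gm_prob Length-V vector of gray-matter probabilities in \[0, 1\].
#' @param exclusion Optional logical V-vector of voxels to drop.
#' @param gm_threshold Inclusion threshold (comparison is `>=`).
#' @return A list of class `analysis_mask` with `include` and `source`.
#' @export
build_analysis_mask <- function(gm_prob, exclusion = NULL, gm_threshold = 0.5) {
  if (any(gm_prob < 0 | gm_prob > 1)) stop("gm_prob must lie in [0, 1]")
  if (is.null(exclusion)) exclusion <- rep(FALSE, length(gm_prob))
  if (length(exclusion) != length(gm_prob)) stop("exclusion length mismatch")
  include <- gm_prob >= gm_threshold & !exclusion
  if (!any(include)) stop("analysis mask is empty after thresholding/exclusion")
  structure(list(include = include,
                 source = sprintf("gm >= %g, %d voxels excluded, %d retained",
                                  gm_threshold, sum(exclusion), sum(include))),
            class = "analysis_mask")
}

#' Z-score a map across in-mask voxels
#'
#' Centers and scales the in-mask values to mean 0 and population SD 1 within
#' the participant; out-of-mask voxels are set to `NA`.
#'
#' @param values Length-V map vector.
#' @param mask An `analysis_mask`; `NULL` means all voxels in-mask.
#' @return A list of class `variability_map` with `values`, `zscored = TRUE`
#'   and `mask_id`.
#' @export
zscore_map <- function(values, mask = NULL) {
  V <- length(values)
  include <- if (is.null(mask)) rep(TRUE, V) else mask$include
  if (length(include) != V) stop("mask length does not match map length")
  x <- values[include]
  mu <- mean(x)
  s <- sqrt(mean((x - mu)^2))
  if (!is.finite(s) || s < 1e-15) {
    stop("in-mask variance is zero; cannot z-score (mask too small or map constant)")
  }
  out <- rep(NA_real_, V)
  out[include] <- (x - mu) / s
  structure(list(values = out, zscored = TRUE,
                 mask_id = if (is.null(mask)) "all-voxels" else mask$source),
            class = "variability_map")
}

#' Preprocessing / variability configuration
#'
#' @param f_lo,f_hi Band-pass edges in Hz.
#' @param fd_threshold_mm Scrubbing threshold.
#' @param n_before,n_after Scrubbing padding window.
#' @param min_seconds Minimum retained duration.
#' @param rotation_radius_mm FD rotation conversion radius.
#' @param literal_fd Use the no-differencing FD variant.
#' @return A list of class `variability_config`.
#' @export
variability_config <- function(f_lo = 0.01, f_hi = 0.10,
                               fd_threshold_mm = 0.5,
                               n_before = 1L, n_after = 2L,
                               min_seconds = 240,
                               rotation_radius_mm = 50,
                               literal_fd = FALSE) {
  stopifnot(f_lo > 0, f_hi > f_lo, fd_threshold_mm > 0, min_seconds > 0)
  structure(as.list(environment()), class = "variability_config")
}

#' Extract a z-scored variability map from one BOLD run
#'
#' Runs the full per-participant pipeline in its canonical order: nuisance
#' regression (WM/CSF regressors plus the run's six motion parameters) ->
#' band-pass filter -> framewise displacement -> scrubbing mask -> minimum
#' duration gate -> per-voxel SD over kept frames -> within-participant
#' z-scoring across in-mask voxels. Scrubbed frames are dropped only for the
#' SD computation; the filter sees the full series.
#'
#' @param run A `bold_run` (see [generate_bold_run()] for the layout).
#' @param nuisance Optional T x K matrix of additional nuisance signals
#'   (WM/CSF means); the motion parameters are always appended.
#' @param mask An `analysis_mask` or `NULL`.
#' @param config A [variability_config()].
#' @return If the run survives the duration gate, a list with
#'   `verdict = "included"`, the `variability_map`, `fd`, `keep`,
#'   `retained_seconds` and `mean_fd`; otherwise `verdict = "excluded"` with
#'   the FD/duration diagnostics and no map.
#' @export
extract_variability <- function(run, nuisance = NULL, mask = NULL,
                                config = variability_config()) {
  stopifnot(inherits(run, "bold_run") || is.list(run))
  data <- as.matrix(run$data)
  T <- nrow(data)
  if (T < 2) stop("run must have at least 2 frames")
  if (!all(is.finite(data))) stop("run data contains non-finite values")
  if (nrow(run$motion) != T) stop("motion rows must match frame count")

  regressors <- if (is.null(nuisance)) run$motion else cbind(nuisance, run$motion)
  resid <- nuisance_regress(data, regressors)
  filtered <- bandpass_filter(resid, run$TR, config$f_lo, config$f_hi)

  fd <- framewise_displacement(run$motion,
                               rotation_radius_mm = config$rotation_radius_mm,
                               literal = config$literal_fd)
  keep <- scrub_mask(fd, config$fd_threshold_mm, config$n_before, config$n_after)
  retained <- sum(keep) * run$TR
  base <- list(participant_id = run$participant_id, fd = fd, keep = keep,
               retained_seconds = retained, mean_fd = mean(fd))
  if (!min_duration_ok(keep, run$TR, config$min_seconds)) {
    return(c(list(verdict = "excluded"), base))
  }
  sd_map <- variability_sd(filtered, keep)
  map <- zscore_map(sd_map, mask)
  c(list(verdict = "included", map = map), base)
}
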