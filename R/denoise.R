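# OLS fit of `design` (frames x p) to every node's series on retained
# frames, evaluated at all frames; returns the fitted values (nodes x
# frames). Shared by detrending and nuisance regression.
fit_on_retained <- function(timeseries, design, retain) {
  xr <- design[retain, , drop = FALSE]
  beta <- solve(crossprod(xr), crossprod(xr, t(timeseries[, retain,
                                                          drop = FALSE])))
  t(design %*% beta)
}

#' Demean and detrend node time series
#'
#' Per node, subtracts the least-squares linear trend fit on retained frames
#' only, evaluated at (and subtracted from) all frames.
#'
#' @param timeseries Node x frame matrix.
#' @param retain Logical retain vector; defaults to all frames.
#' @return Node x frame matrix of residuals.
#' @export
demean_detrend <- function(timeseries, retain = NULL) {
  n_frames <- ncol(timeseries)
  if (is.null(retain)) retain <- rep(TRUE, n_frames)
  design <- cbind(1, seq_len(n_frames))
  timeseries - fit_on_retained(timeseries, design, retain)
}

#' Backward-difference derivative of regressors
#'
#' First element zero, matching the convention used for nuisance-signal
#' derivatives.
#'
#' @param x Frames x k matrix (or vector) of signals.
#' @return Matrix of the same shape.
#' @export
backward_difference <- function(x) {
  x <- as.matrix(x)
  rbind(0, diff(x))
}

#' Nuisance regression of node time series
#'
#' Ordinary least-squares residualization against a regressor matrix
#' (typically nuisance signals and their backward-difference derivatives):
#' betas are estimated on retained frames, the residualization is applied to
#' all frames. An intercept column is always included.
#'
#' @param timeseries Node x frame matrix.
#' @param regressors Frames x k matrix of nuisance signals.
#' @param retain Logical retain vector; defaults to all frames.
#' @param add_derivatives Append backward-difference derivatives of
#'   `regressors` (default TRUE).
#' @return Node x frame residual matrix.
#' @export
nuisance_regress <- function(timeseries, regressors, retain = NULL,
                             add_derivatives = TRUE) {
  n_frames <- ncol(timeseries)
  regressors <- as.matrix(regressors)
  stopifnot(nrow(regressors) == n_frames)
  if (is.null(retain)) retain <- rep(TRUE, n_frames)
  if (add_derivatives)
    regressors <- cbind(regressors, backward_difference(regressors))
  design <- cbind(1, regressors)
  timeseries - fit_on_retained(timeseries, design, retain)
}

# Sinusoid basis over the analysis band (plus guard) at Fourier frequencies
# k/(N*TR): the design for least-squares spectral interpolation.
spectral_basis <- function(n_frames, tr, band, guard = 0.2) {
  span <- n_frames * tr
  f_lo <- max(band[1] * (1 - guard), 1 / span)
  f_hi <- band[2] * (1 + guard)
  k <- seq(max(1L, floor(f_lo * span)), ceiling(f_hi * span))
  freqs <- k / span
  t_sec <- (seq_len(n_frames) - 1) * tr
  ang <- outer(t_sec, 2 * pi * freqs)
  cbind(1, cos(ang), sin(ang))
}

#' Least-squares spectral interpolation across censored frames
#'
#' Fits a basis of sinusoids at Fourier frequencies spanning the analysis
#' pass-band (plus a 20% guard) to the retained frames of each node by
#' ridge-regularized least squares, then replaces censored frames with the
#' fitted values. Retained frames are returned unchanged, so filtering the
#' interpolated series does not smear motion artifacts into clean frames.
#'
#' @param timeseries Node x frame matrix.
#' @param retain Logical retain vector (the processing mask).
#' @param tr Repetition time in seconds.
#' @param band Pass-band in Hz used to choose the basis frequencies.
#' @param ridge Ridge penalty for the normal equations.
#' @return Node x frame matrix with censored frames replaced.
#' @export
interpolate_censored <- function(timeseries, retain, tr,
                                 band = c(0.008, 0.10), ridge = 1e-6) {
  n_frames <- ncol(timeseries)
  stopifnot(length(retain) == n_frames)
  if (all(retain)) return(timeseries)
  basis <- spectral_basis(n_frames, tr, band)
  if (sum(retain) < ncol(basis))
    stop("insufficient retained data for spectral interpolation (",
         sum(retain), " frames < ", ncol(basis), " basis functions)")
  xr <- basis[retain, , drop = FALSE]
  a <- crossprod(xr) + ridge * diag(ncol(basis))
  beta <- solve(a, crossprod(xr, t(timeseries[, retain, drop = FALSE])))
  fitted <- t(basis %*% beta)
  out <- timeseries
  out[, !retain] <- fitted[, !retain]
  out
}

#' Zero-phase band-pass filter
#'
#' Forward-backward (zero-phase) Butterworth filtering of each node series,
#' order 2 per pass, attenuating power outside the band. Each series is
#' demeaned before filtering, which removes DC exactly and keeps the
#' filter's edge transients small. Apply after interpolation so
#' censored-frame artifacts do not propagate into retained frames.
#'
#' @param timeseries Node x frame matrix.
#' @param band Pass-band in Hz, `c(low, high)`; high must be below Nyquist.
#' @param tr Repetition time in seconds.
#' @return Filtered node x frame matrix.
#' @export
bandpass <- function(timeseries, band = c(0.008, 0.10), tr = 0.8) {
  fs <- 1 / tr
  nyq <- fs / 2
  stopifnot(band[1] > 0, band[1] < band[2], band[2] < nyq)
  bf <- signal::butter(2, band / nyq, type = "pass")
  out <- t(apply(timeseries, 1, function(x)
    signal::filtfilt(bf, x - mean(x))))
  dimnames(out) <- dimnames(timeseries)
  out
}

#' Run the full denoising chain on one subject
#'
#' Order of operations: (1) flag frames at the processing FD threshold
#' (0.3 mm); (2) demean/detrend on retained frames; (3) least-squares
#' spectral interpolation across censored frames; (4) nuisance regression of
#' the global mean signal and its derivative (betas from retained frames);
#' (5) zero-phase band-pass; (6) construct the final analysis mask at the
#' final FD threshold (0.2 mm) with the contiguity rule, used downstream for
#' correlation. The contiguity rule applies only at the final mask.
#'
#' @param timeseries Node x frame matrix (raw).
#' @param fd_trace Per-frame FD in mm.
#' @param config A [denoise_config()].
#' @param tr Repetition time in seconds.
#' @param nuisance Optional frames x k matrix of extra nuisance signals; the
#'   global (across-node mean) signal is always included.
#' @return List: `timeseries` (denoised), `retain` (final analysis mask),
#'   `retain_process` (processing mask), `n_retained`, `included`.
#' @export
preprocess_subject <- function(timeseries, fd_trace,
                               config = denoise_config(), tr = 0.8,
                               nuisance = NULL) {
  stopifnot(ncol(timeseries) == length(fd_trace))
  retain_proc <- flag_frames(fd_trace, config$process_fd_threshold)
  x <- demean_detrend(timeseries, retain_proc)
  x <- interpolate_censored(x, retain_proc, tr, config$band)
  global <- colMeans(x)
  regs <- if (is.null(nuisance)) cbind(global = global) else
    cbind(global = global, nuisance)
  x <- nuisance_regress(x, regs, retain_proc)
  x <- bandpass(x, config$band, tr)
  retain_final <- censor_mask(fd_trace, config$final_fd_threshold,
                              config$min_contig)
  n_ret <- sum(retain_final)
  list(timeseries = x,
       retain = as.logical(retain_final),
       retain_process = retain_proc,
       n_retained = n_ret,
       included = n_ret >= config$min_retained)
}
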