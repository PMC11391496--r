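# ROI-level denoising: outlier-frame detection, confound regression
# (motion, outlier spikes, task effect, nuisance signals) and band-pass
# filtering. Pipeline order is regress-then-filter.

#' Detect outlier frames from global signal and framewise motion
#'
#' A frame is flagged when the global-signal z-score exceeds `z_thresh`
#' OR the framewise motion differential (sum of absolute first
#' differences over the six parameters) exceeds `motion_thresh_mm`. The
#' default thresholds (z = 5, 0.9 mm) follow the conservative settings
#' conventional for artifact-detection tools.
#'
#' @param series a `vf_series` (regions x timepoints).
#' @param motion timepoints x 6 motion-parameter matrix (mm / radians
#'   treated on a common scale).
#' @param z_thresh global-signal z-score threshold (> 0).
#' @param motion_thresh_mm framewise motion threshold (> 0).
#' @return Logical vector, one flag per timepoint.
#' @export
detect_outlier_frames <- function(series, motion, z_thresh = 5,
                                  motion_thresh_mm = 0.9) {
  stopifnot(z_thresh > 0, motion_thresh_mm > 0)
  Tn <- ncol(series)
  if (nrow(motion) != Tn) {
    stop(sprintf("motion has %d rows but series has %d timepoints",
                 nrow(motion), Tn), call. = FALSE)
  }
  g <- colMeans(series)
  sdg <- stats::sd(g)
  z <- if (sdg > 0) abs(g - mean(g)) / sdg else rep(0, Tn)
  fd <- c(0, rowSums(abs(diff(as.matrix(motion)))))
  z > z_thresh | fd > motion_thresh_mm
}

#' Assemble a confound design table
#'
#' Motion columns, one-hot outlier-frame indicator columns, the
#' HRF-convolved task regressor plus its temporal derivative (removal of
#' the block "module" effect before connectivity), and nuisance signal
#' channels (white-matter/CSF analogues).
#'
#' @param motion timepoints x 6 matrix (or `NULL`).
#' @param outlier_frames logical vector (or `NULL`).
#' @param design a [make_design()] to build task regressors from (or
#'   `NULL` to omit them).
#' @param nuisance timepoints x k matrix (or `NULL`).
#' @return A numeric matrix, timepoints x confounds, with named columns.
#' @export
build_confound_table <- function(motion = NULL, outlier_frames = NULL,
                                 design = NULL, nuisance = NULL) {
  parts <- list()
  if (!is.null(motion)) parts$motion <- as.matrix(motion)
  if (!is.null(design)) parts$task <- task_regressor(design, derivative = TRUE)
  if (!is.null(nuisance) && NCOL(nuisance) > 0) parts$nuis <- as.matrix(nuisance)
  if (!is.null(outlier_frames) && any(outlier_frames)) {
    idx <- which(outlier_frames)
    oh <- matrix(0, length(outlier_frames), length(idx))
    oh[cbind(idx, seq_along(idx))] <- 1
    colnames(oh) <- paste0("outlier_t", idx)
    parts$outliers <- oh
  }
  if (!length(parts)) {
    stop("no confound sources supplied", call. = FALSE)
  }
  Tn <- unique(vapply(parts, nrow, integer(1)))
  if (length(Tn) != 1L) stop("confound sources disagree on timepoint count", call. = FALSE)
  do.call(cbind, unname(parts))
}

#' Regress confounds out of a time series
#'
#' Per region, ordinary least-squares residual of the signal on
#' \[intercept | confounds\]. Collinear confound columns are dropped with
#' a warning (rank detection via pivoted QR). Residuals are orthogonal to
#' every retained confound column.
#'
#' @param series a `vf_series`.
#' @param confounds timepoints x k numeric matrix.
#' @return A `vf_series` of residuals (same shape, zero mean per region).
#' @export
regress_confounds <- function(series, confounds) {
  Tn <- ncol(series)
  confounds <- as.matrix(confounds)
  if (nrow(confounds) != Tn) {
    stop(sprintf("confound table has %d rows but series has %d timepoints",
                 nrow(confounds), Tn), call. = FALSE)
  }
  X <- cbind(intercept = rep(1, Tn), confounds)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    drop_idx <- qr_x$pivot[seq.int(qr_x$rank + 1L, ncol(X))]
    warning(sprintf("dropping %d collinear confound column(s): %s",
                    length(drop_idx),
                    paste(colnames(X)[drop_idx], collapse = ", ")),
            call. = FALSE)
    X <- X[, -drop_idx, drop = FALSE]
    qr_x <- qr(X)
  }
  resid <- t(qr.resid(qr_x, t(unclass(series))))
  dimnames(resid) <- dimnames(series)
  new_vf_series(resid, attr(series, "tr_s"), prepped = attr(series, "prepped"))
}

#' Zero-phase band-pass filter
#'
#' Order-2 Butterworth band-pass applied forward and backward
#' (`signal::filtfilt`), so no temporal shift is introduced. Frequencies
#' outside \[`low_hz`, `high_hz`\] are attenuated; the default band
#' 0.009-0.10 Hz retains the slow BOLD fluctuations used for
#' connectivity.
#'
#' @param series a `vf_series`.
#' @param low_hz,high_hz band edges in Hz; `0 <= low < high <= Nyquist`.
#' @return A filtered `vf_series`.
#' @export
bandpass <- function(series, low_hz = 0.009, high_hz = 0.10) {
  tr <- attr(series, "tr_s")
  nyq <- 1 / (2 * tr)
  if (!(low_hz >= 0 && low_hz < high_hz)) {
    stop("band edges must satisfy 0 <= low < high", call. = FALSE)
  }
  if (high_hz > nyq) {
    stop(sprintf("high edge %g Hz exceeds the Nyquist frequency %g Hz (TR = %g s)",
                 high_hz, nyq, tr), call. = FALSE)
  }
  bf <- signal::butter(2, c(low_hz, high_hz) / nyq, type = "pass")
  Tn <- ncol(series)
  pad <- min(Tn - 1L, 100L) # reflect-padding suppresses filtfilt edge transients
  filt <- t(apply(unclass(series), 1, function(x) {
    mu <- mean(x)
    xp <- c(rev(x[seq_len(pad) + 1L]), x, rev(x[Tn - seq_len(pad)])) - mu
    y <- signal::filtfilt(bf, xp)
    y[pad + seq_len(Tn)]
  }))
  dimnames(filt) <- dimnames(series)
  new_vf_series(filt, tr, prepped = attr(series, "prepped"))
}

#' Full denoising pipeline for one subject
#'
#' Confound regression (motion, outlier spikes, task effect + temporal
#' derivative, nuisance channels) followed by zero-phase band-pass
#' filtering, in that order. The result carries `prepped = TRUE`, the
#' provenance flag required by [correlation_matrix()].
#'
#' @param series a `vf_series`.
#' @param motion,nuisance confound sources (see [build_confound_table()]).
#' @param design block design used for the task-effect regressors.
#' @param low_hz,high_hz band-pass edges (Hz).
#' @param z_thresh,motion_thresh_mm outlier-detection thresholds.
#' @param outlier_frames optional precomputed flags; detected when `NULL`.
#' @return A denoised, filtered `vf_series` with `prepped = TRUE`.
#' @export
prep_series <- function(series, motion, nuisance = NULL, design = NULL,
                        low_hz = 0.009, high_hz = 0.10,
                        z_thresh = 5, motion_thresh_mm = 0.9,
                        outlier_frames = NULL) {
  if (is.null(outlier_frames)) {
    outlier_frames <- detect_outlier_frames(series, motion, z_thresh,
                                            motion_thresh_mm)
  }
  conf <- build_confound_table(motion = motion, outlier_frames = outlier_frames,
                               design = design, nuisance = nuisance)
  res <- regress_confounds(series, conf)
  out <- bandpass(res, low_hz, high_hz)
  attr(out, "prepped") <- TRUE
  out
}
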