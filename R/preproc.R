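#' Remove initial volumes for signal equilibration
#'
#' Drops the first `n_drop` frames from the series; when a [nuisance_set()]
#' is supplied its traces are trimmed in lockstep so lengths stay aligned.
#'
#' @param b A [bold_series()].
#' @param n_drop Number of leading frames to remove (default 50).
#' @param nuisance Optional [nuisance_set()] to trim alongside.
#' @return The trimmed `bold_series`, or `list(bold, nuisance)` when a
#'   nuisance set is supplied.
#' @export
trim_volumes <- function(b, n_drop = 50L, nuisance = NULL) {
  stopifnot(inherits(b, "bold_series"))
  n_drop <- as.integer(n_drop)
  tt <- n_timepoints(b)
  if (n_drop < 0) stop("n_drop must be nonnegative")
  if (n_drop >= tt) stop("n_drop (", n_drop, ") must be < number of frames (", tt, ")")
  if (n_drop > 0) {
    b$data <- b$data[, , , (n_drop + 1L):tt, drop = FALSE]
    if (!is.null(nuisance)) {
      nuisance <- nuisance_set(nuisance$motion[(n_drop + 1L):tt, , drop = FALSE],
                               nuisance$ventricular[(n_drop + 1L):tt])
    }
  }
  b <- record_step(b, sprintf("trim(%d)", n_drop))
  if (is.null(nuisance)) b else list(bold = b, nuisance = nuisance)
}

#' Regress nuisance signals out of every voxel time course
#'
#' Ordinary least squares of each in-mask voxel time course on an intercept,
#' the six motion traces, and the mean ventricular signal; the voxel is
#' replaced by its residual. Collinear regressor columns are dropped with a
#' warning rather than failing.
#'
#' @param b A [bold_series()].
#' @param nuisance A [nuisance_set()] with traces of the same length.
#' @return The residualized `bold_series` (residuals orthogonal to the
#'   retained regressors).
#' @export
regress_nuisance <- function(b, nuisance) {
  stopifnot(inherits(b, "bold_series"), inherits(nuisance, "nuisance_set"))
  tt <- n_timepoints(b)
  if (nrow(nuisance$motion) != tt)
    stop("nuisance length (", nrow(nuisance$motion),
         ") does not match series length (", tt, ")")
  X <- cbind(intercept = 1, nuisance$motion, vent = nuisance$ventricular)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop_cols <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    warning("dropping collinear nuisance columns: ",
            paste(drop_cols, collapse = ", "))
    X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
    qx <- qr(X)
  }
  Y <- mask_matrix(b)
  res <- Y - X %*% qr.coef(qx, Y)
  b <- set_mask_matrix(b, res)
  record_step(b, sprintf("regress_nuisance(%d regressors)", ncol(X)))
}

# 1D Gaussian kernel sampled at voxel offsets, truncated at 4 sigma
gauss_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  half <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-((-half):half)^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# separable 1D convolution of a 3D array along one axis (zero padding)
conv_axis <- function(arr, kernel, axis) {
  if (length(kernel) == 1L) return(arr)
  half <- (length(kernel) - 1L) %/% 2L
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  a <- aperm(arr, perm)
  d <- dim(a)
  m <- matrix(a, d[1], d[2] * d[3])
  out <- matrix(0, d[1], ncol(m))
  for (j in seq_along(kernel)) {
    off <- j - half - 1L
    src <- seq_len(d[1]) + off
    ok <- src >= 1L & src <= d[1]
    out[ok, ] <- out[ok, ] + kernel[j] * m[src[ok], , drop = FALSE]
  }
  aperm(array(out, d), order(perm))
}

#' Mask-renormalized isotropic Gaussian smoothing
#'
#' Convolves each frame with a separable Gaussian of full width at half
#' maximum `fwhm_mm` (sigma = fwhm / (2 sqrt(2 ln 2)), converted to voxels
#' per axis). Voxels outside the mask contribute nothing and the kernel is
#' renormalized over in-mask voxels, so constants are conserved and edges
#' are not diluted.
#'
#' @param b A [bold_series()].
#' @param fwhm_mm Kernel FWHM in mm (default 0.6; 0 is the identity).
#' @return The smoothed `bold_series`.
#' @export
smooth_gaussian <- function(b, fwhm_mm = 0.6) {
  stopifnot(inherits(b, "bold_series"))
  if (fwhm_mm < 0) stop("fwhm_mm must be nonnegative")
  if (fwhm_mm == 0) return(record_step(b, "smooth(0)"))
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / b$voxel_size_mm
  kernels <- lapply(sigma_vox, gauss_kernel_1d)
  maskd <- array(as.numeric(b$mask), dim(b$mask))
  wt <- maskd
  for (ax in 1:3) wt <- conv_axis(wt, kernels[[ax]], ax)
  tt <- n_timepoints(b)
  for (f in seq_len(tt)) {
    frame <- b$data[, , , f] * maskd
    for (ax in 1:3) frame <- conv_axis(frame, kernels[[ax]], ax)
    sm <- frame / wt
    old <- b$data[, , , f]
    old[b$mask] <- sm[b$mask]
    b$data[, , , f] <- old
  }
  record_step(b, sprintf("smooth(%.3gmm)", fwhm_mm))
}

#' Ideal frequency-domain band-pass filter
#'
#' Per-voxel FFT filter: Fourier components with frequency inside
#' `[lo_hz, hi_hz]` are retained, all others (including DC) are zeroed, so
#' filtered time courses have mean ~0.
#'
#' @param b A [bold_series()].
#' @param lo_hz,hi_hz Pass-band edges in Hz (defaults 0.01 and 0.1);
#'   `0 <= lo < hi <= ` Nyquist (`1 / (2 TR)`).
#' @return The filtered `bold_series`.
#' @export
bandpass <- function(b, lo_hz = 0.01, hi_hz = 0.1) {
  stopifnot(inherits(b, "bold_series"))
  nyq <- 1 / (2 * b$tr_s)
  if (lo_hz < 0 || lo_hz >= hi_hz) stop("need 0 <= lo_hz < hi_hz")
  if (hi_hz > nyq)
    stop(sprintf("hi_hz (%g Hz) exceeds the Nyquist frequency %g Hz", hi_hz, nyq))
  tt <- n_timepoints(b)
  freq <- (seq_len(tt) - 1) / (tt * b$tr_s)
  freq <- pmin(freq, 1 / b$tr_s - freq)  # fold to [0, Nyquist]
  keep <- freq >= lo_hz & freq <= hi_hz & freq > 0
  Y <- mask_matrix(b)
  F <- stats::mvfft(Y)
  F[!keep, ] <- 0
  Yf <- Re(stats::mvfft(F, inverse = TRUE)) / tt
  b <- set_mask_matrix(b, Yf)
  record_step(b, sprintf("bandpass(%g,%g)", lo_hz, hi_hz))
}

#' Run the full time-series conditioning pipeline
#'
#' Trim, nuisance-regress, smooth, band-pass — in that order.
#'
#' @param b A [bold_series()].
#' @param nuisance A [nuisance_set()] (full length; trimmed with the data).
#' @param n_drop,fwhm_mm,band Stage parameters (defaults 50, 0.6 mm,
#'   0.01-0.1 Hz).
#' @return The preprocessed `bold_series`.
#' @export
preprocess_bold <- function(b, nuisance, n_drop = 50L, fwhm_mm = 0.6,
                            band = c(0.01, 0.1)) {
  tr <- trim_volumes(b, n_drop, nuisance)
  if (is.list(tr) && !inherits(tr, "bold_series")) {
    b <- tr$bold; nuisance <- tr$nuisance
  } else b <- tr
  b <- regress_nuisance(b, nuisance)
  b <- smooth_gaussian(b, fwhm_mm)
  bandpass(b, band[1], band[2])
}
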