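# Preprocessing chain for a BOLD series already in a common grid:
# initial-volume dropping, motion screening, Friston-24 nuisance
# regression, 3D Gaussian smoothing, temporal band-pass.

#' Drop initial volumes
#'
#' Removes the first `n` time points of a series (scanner equilibration;
#' 230 acquired volumes with `n = 10` leave 220 for analysis).
#'
#' @param series A [series_4d()].
#' @param n Number of leading volumes to remove.
#' @return The shortened [series_4d()].
#' @export
drop_initial_volumes <- function(series, n = 10L) {
  n <- as.integer(n)
  if (n < 0L) stop("n must be non-negative")
  if (n >= n_volumes(series))
    stop("cannot drop ", n, " volumes from a series of ", n_volumes(series))
  if (n == 0L) return(series)
  series$data <- series$data[-seq_len(n), , drop = FALSE]
  series
}

#' Head-motion exclusion rule
#'
#' `TRUE` when any volume moves strictly more than `trans_limit` mm of
#' translation or `rot_limit` degrees of rotation on any axis (absolute,
#' relative to the reference position).
#'
#' @param trace `n x 6` motion matrix (translations mm, rotations degrees).
#' @param trans_limit Translation limit in mm (default 2.5).
#' @param rot_limit Rotation limit in degrees (default 2.5).
#' @return Logical scalar.
#' @export
exceeds_motion_limit <- function(trace, trans_limit = 2.5, rot_limit = 2.5) {
  trace <- as.matrix(trace)
  if (nrow(trace) < 1L || ncol(trace) != 6L) stop("trace must be n x 6, n >= 1")
  any(abs(trace[, 1:3]) > trans_limit) || any(abs(trace[, 4:6]) > rot_limit)
}

#' Mean framewise displacement
#'
#' Power-style FD: per volume `t >= 2`, the sum of absolute frame-to-frame
#' translation changes plus `head_radius` times the sum of absolute
#' rotation changes in radians; returned as the mean over those volumes.
#' Used as the per-subject head-motion covariate.
#'
#' @param trace `n x 6` motion matrix (translations mm, rotations degrees).
#' @param head_radius Sphere radius converting rotations to arc length, mm.
#' @return Mean FD in mm.
#' @export
mean_framewise_displacement <- function(trace, head_radius = 50) {
  trace <- as.matrix(trace)
  if (nrow(trace) < 2L) stop("FD needs at least 2 volumes")
  d <- abs(diff(trace))
  fd <- rowSums(d[, 1:3, drop = FALSE]) +
    head_radius * rowSums(d[, 4:6, drop = FALSE] * pi / 180)
  mean(fd)
}

#' Friston 24-parameter motion expansion
#'
#' The 6 rigid-body parameters, their one-volume-back lags, and the
#' squares of both (24 columns).
#'
#' @param trace `n x 6` motion matrix.
#' @return `n x 24` matrix.
#' @export
friston24 <- function(trace) {
  trace <- as.matrix(trace)
  lag1 <- rbind(0, trace[-nrow(trace), , drop = FALSE])
  cbind(trace, lag1, trace^2, lag1^2)
}

#' Nuisance model specification
#'
#' @param include_linear_trend Include a linear trend regressor.
#' @param wm_signal,csf_signal Optional mean tissue time series (length
#'   `n_volumes`), e.g. white matter and CSF means.
#' @param motion_24 Use the Friston 24-parameter motion expansion.
#' @return An object of class `nuisance_model`.
#' @export
nuisance_model <- function(include_linear_trend = TRUE,
                           wm_signal = NULL, csf_signal = NULL,
                           motion_24 = TRUE) {
  structure(list(include_linear_trend = include_linear_trend,
                 wm_signal = wm_signal, csf_signal = csf_signal,
                 motion_24 = motion_24),
            class = "nuisance_model")
}

#' Regress nuisance signals out of a series
#'
#' Per voxel, returns residuals of the least-squares projection onto
#' an intercept, optional linear trend, optional tissue means, and the
#' Friston-24 motion expansion. Residuals are orthogonal to every
#' regressor. Rank-deficient designs are fit with a pseudo-inverse and a
#' warning.
#'
#' @param series A [series_4d()].
#' @param model A [nuisance_model()].
#' @param trace Motion trace matching the series length (required when
#'   `model$motion_24`).
#' @return The residual [series_4d()].
#' @export
regress_nuisance <- function(series, model = nuisance_model(), trace = NULL) {
  Tn <- n_volumes(series)
  X <- matrix(1, nrow = Tn, ncol = 1)
  if (isTRUE(model$include_linear_trend))
    X <- cbind(X, seq_len(Tn) - (Tn + 1) / 2)
  for (sig in list(model$wm_signal, model$csf_signal)) {
    if (!is.null(sig)) {
      if (length(sig) != Tn) stop("tissue regressor length != n_volumes")
      X <- cbind(X, sig)
    }
  }
  if (isTRUE(model$motion_24)) {
    if (is.null(trace)) stop("motion trace required for the 24-parameter model")
    if (nrow(trace) != Tn) stop("motion trace rows != n_volumes")
    X <- cbind(X, friston24(trace))
  }
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    warning("rank-deficient nuisance design (", qr_x$rank, " < ", ncol(X),
            "); using pseudo-inverse fit")
    sv <- svd(X)
    keep <- sv$d > max(sv$d) * 1e-10
    beta <- sv$v[, keep, drop = FALSE] %*%
      ((t(sv$u[, keep, drop = FALSE]) %*% series$data) / sv$d[keep])
    series$data <- series$data - X %*% beta
  } else {
    series$data <- qr.resid(qr_x, series$data)
  }
  series
}

#' Temporal band-pass filter
#'
#' Frequency-domain filter with unit gain in `[low, high]` Hz and a raised
#' cosine roll-off of width `transition` Hz on both edges; DC is always
#' removed. Passband amplitudes are preserved and stopband sinusoids
#' attenuated by more than 90 percent.
#'
#' @param series A [series_4d()].
#' @param low,high Passband edges in Hz (defaults 0.01 and 0.1).
#' @param transition Roll-off width in Hz.
#' @return The filtered [series_4d()].
#' @export
bandpass <- function(series, low = 0.01, high = 0.1, transition = 0.005) {
  Tn <- n_volumes(series)
  nyq <- 1 / (2 * series$tr)
  if (high >= nyq) stop("high edge ", high, " Hz >= Nyquist ", nyq, " Hz")
  if (low < 0 || low >= high) stop("need 0 <= low < high")
  freqs <- seq(0, Tn - 1) / (Tn * series$tr)
  freqs <- pmin(freqs, 1 / series$tr - freqs)  # two-sided spectrum
  H <- bandpass_response(freqs, low, high, transition)
  H[1] <- 0  # remove DC regardless of the low edge
  spec <- stats::mvfft(series$data)
  series$data <- Re(stats::mvfft(spec * H, inverse = TRUE)) / Tn
  series
}

# raised-cosine band-pass transfer function
bandpass_response <- function(f, low, high, transition) {
  H <- numeric(length(f))
  H[f >= low & f <= high] <- 1
  lo_ramp <- f >= low - transition & f < low
  H[lo_ramp] <- 0.5 * (1 + cos(pi * (low - f[lo_ramp]) / transition))
  hi_ramp <- f > high & f <= high + transition
  H[hi_ramp] <- 0.5 * (1 + cos(pi * (f[hi_ramp] - high) / transition))
  H
}

# 1D truncated, renormalized Gaussian convolution operator (zero padding
# outside the grid) as a dense n x n matrix
gauss_operator_1d <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  half <- max(1L, ceiling(4 * sigma_vox))
  x <- seq(-half, half)
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k <- k / sum(k)
  K <- matrix(0, n, n)
  for (j in seq_len(n)) {
    idx <- j + x
    ok <- idx >= 1 & idx <= n
    K[idx[ok], j] <- K[idx[ok], j] + k[ok]
  }
  K
}

# apply per-axis operators to a (X,Y,Z,T) array via axis-rotating matmuls
separable_apply <- function(arr, ops) {
  d <- dim(arr)
  for (ax in 1:3) {
    m <- matrix(aperm(arr, c(ax, setdiff(1:4, ax))), nrow = d[ax])
    m <- ops[[ax]] %*% m
    arr <- aperm(array(m, dim = c(d[ax], d[setdiff(1:4, ax)])),
                 order(c(ax, setdiff(1:4, ax))))
  }
  arr
}

#' Spatial Gaussian smoothing
#'
#' Per-volume separable 3D Gaussian convolution with kernel
#' `sigma = fwhm / (2 sqrt(2 ln 2))` per axis (in voxel units from the
#' grid's voxel size). Outside the grid the signal is zero-padded; when a
#' mask is supplied the result is renormalized inside the mask
#' (`smooth(x * m) / smooth(m)`) so FCD values near the mask border are
#' not attenuated.
#'
#' @param x A [series_4d()], or a per-voxel numeric vector (with `grid`).
#' @param fwhm_mm Kernel FWHM in mm (default 6); 0 is the identity.
#' @param mask Optional [brain_mask()] for masked renormalization.
#' @param grid Required when `x` is a bare vector.
#' @return Same shape as the input.
#' @export
smooth_gaussian <- function(x, fwhm_mm = 6, mask = NULL, grid = NULL) {
  if (fwhm_mm < 0) stop("fwhm must be non-negative")
  if (inherits(x, "series_4d")) {
    grid <- x$grid
    arr <- series_array(x)
  } else {
    if (is.null(grid)) stop("grid is required for bare per-voxel values")
    arr <- array(as.double(x), dim = c(grid$dims, 1L))
  }
  if (fwhm_mm == 0) return(x)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / grid$voxel_size
  ops <- lapply(1:3, function(ax) gauss_operator_1d(grid$dims[ax], sigma_vox[ax]))
  if (!is.null(mask)) {
    if (!grid_equal(grid, mask$grid)) stop("mask grid does not match")
    m <- array(as.double(mask$inside), dim = c(grid$dims, 1L))
    denom <- as.vector(separable_apply(m, ops))
    arr <- arr * as.vector(mask$inside)
    sm <- separable_apply(arr, ops)
    keep <- mask$inside & denom > 0
    out <- matrix(sm, nrow = prod(grid$dims))
    out[keep, ] <- out[keep, , drop = FALSE] / denom[keep]
    out[!mask$inside, ] <- 0
    sm <- array(out, dim = dim(sm))
  } else {
    sm <- separable_apply(arr, ops)
  }
  if (inherits(x, "series_4d")) {
    x$data <- t(matrix(sm, nrow = prod(grid$dims)))
    x
  } else {
    as.vector(sm)
  }
}

#' Run the preprocessing chain on one subject
#'
#' Fixed order: drop initial volumes, (optional) motion screening,
#' nuisance regression, spatial smoothing, band-pass filtering. Smoothing
#' before filtering follows the conventional step order; use
#' `smooth_before_bandpass = FALSE` to swap them.
#'
#' @param series A [series_4d()].
#' @param trace Motion trace for the full (pre-drop) series, or `NULL` to
#'   skip motion-dependent steps.
#' @param drop Leading volumes to discard.
#' @param fwhm_mm Smoothing kernel FWHM (mm).
#' @param band Passband `c(low, high)` in Hz.
#' @param motion_limits `c(translation mm, rotation degrees)` exclusion
#'   limits.
#' @param mask Optional [brain_mask()] for smoothing renormalization.
#' @param smooth_before_bandpass Step-order switch (default `TRUE`).
#' @return A list with `series` (preprocessed), `excluded` (motion rule),
#'   `mean_fd` (head-motion covariate, `NA` without a trace).
#' @export
preprocess_subject <- function(series, trace = NULL, drop = 10L, fwhm_mm = 6,
                               band = c(0.01, 0.1),
                               motion_limits = c(2.5, 2.5), mask = NULL,
                               smooth_before_bandpass = TRUE) {
  excluded <- FALSE
  mean_fd <- NA_real_
  if (!is.null(trace) && nrow(trace) != n_volumes(series))
    stop("motion trace rows != n_volumes")
  series <- drop_initial_volumes(series, drop)
  if (!is.null(trace)) {
    trace <- trace[-seq_len(drop), , drop = FALSE]
    excluded <- exceeds_motion_limit(trace, motion_limits[1], motion_limits[2])
    mean_fd <- mean_framewise_displacement(trace)
    series <- regress_nuisance(series, nuisance_model(), trace)
  } else {
    series <- regress_nuisance(series, nuisance_model(motion_24 = FALSE))
  }
  if (smooth_before_bandpass) {
    series <- smooth_gaussian(series, fwhm_mm, mask = mask)
    series <- bandpass(series, band[1], band[2])
  } else {
    series <- bandpass(series, band[1], band[2])
    series <- smooth_gaussian(series, fwhm_mm, mask = mask)
  }
  list(series = series, excluded = excluded, mean_fd = mean_fd)
}
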