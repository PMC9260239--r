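#' Framewise displacement
#'
#' Volume-to-volume head motion summarised per timepoint as the sum of
#' absolute translation changes plus absolute rotation changes converted to
#' mm as arc length on a sphere (Power-style FD). The first timepoint has no
#' predecessor and gets FD = 0; the reported mean is over timepoints 2..T.
#'
#' @param trace 6-column motion matrix (`tx, ty, tz` mm, `rx, ry, rz` rad),
#'   one row per volume.
#' @param head_radius sphere radius in mm used to convert rotations to
#'   displacements (default 50, the conventional value).
#' @return A list with `fd` (per-timepoint vector, first element 0) and
#'   `mean_fd`.
#' @export
framewise_displacement <- function(trace, head_radius = 50) {
  trace <- as.matrix(trace)
  if (ncol(trace) != 6L)
    nvc_format_error("motion trace must have 6 columns")
  if (nrow(trace) < 2L)
    nvc_data_error("framewise displacement needs >= 2 timepoints")
  d <- abs(diff(trace))
  fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
               head_radius * rowSums(d[, 4:6, drop = FALSE]))
  list(fd = fd, mean_fd = mean(fd[-1L]))
}

#' Friston-24 motion regressor matrix
#'
#' Expands 6 rigid-body parameters into the 24-regressor set: the 6
#' parameters, their one-step backward shifts (first row zero-padded), the
#' squared parameters, and the squared shifts.
#'
#' @inheritParams framewise_displacement
#' @return A T x 24 numeric matrix.
#' @export
friston24 <- function(trace) {
  trace <- as.matrix(trace)
  if (ncol(trace) != 6L)
    nvc_format_error("motion trace must have 6 columns")
  if (nrow(trace) < 2L)
    nvc_data_error("friston24 needs >= 2 timepoints")
  lagged <- rbind(0, trace[-nrow(trace), , drop = FALSE])
  out <- cbind(trace, lagged, trace^2, lagged^2)
  colnames(out) <- c(paste0(colnames(trace) %||% paste0("m", 1:6)),
                     paste0("lag_", 1:6), paste0("sq_", 1:6),
                     paste0("sqlag_", 1:6))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Ideal FFT band-pass of a T x k matrix of columns; retains frequency bins
## with low <= f <= high (plus their conjugate partners), removing the DC
## component, after removing a per-column linear trend.
detrend_bandpass_matrix <- function(x, tr, low, high) {
  x <- as.matrix(x)
  nt <- nrow(x)
  nyquist <- 1 / (2 * tr)
  if (!(low > 0 && high > low && high < nyquist))
    nvc_config_error(sprintf(
      "band [%g, %g] Hz must satisfy 0 < low < high < Nyquist (%g Hz)",
      low, high, nyquist))
  t0 <- seq_len(nt)
  X <- cbind(1, t0)
  x <- x - X %*% qr.coef(qr(X), x)            # linear detrend (incl. mean)
  freq <- c(0, seq_len(nt - 1)) / (nt * tr)
  freq <- pmin(freq, 1 / tr - freq)           # fold to [0, Nyquist]
  keep <- freq >= low & freq <= high
  xf <- stats::mvfft(x)
  xf[!keep, ] <- 0
  Re(stats::mvfft(xf, inverse = TRUE)) / nt
}

#' Linear detrend and temporal band-pass filter
#'
#' Removes a per-voxel linear trend (including the mean), then applies an
#' ideal FFT band-pass that zeroes all frequency components outside
#' `[low, high]`. The defaults select the conventional resting-state band
#' 0.01-0.08 Hz.
#'
#' @param series a [bold_series()].
#' @param low,high band edges in Hz; must satisfy 0 < low < high < Nyquist.
#' @return A filtered [bold_series()], per-voxel mean ~ 0.
#' @export
detrend_bandpass <- function(series, low = 0.01, high = 0.08) {
  stopifnot(inherits(series, "bold_series"))
  m <- detrend_bandpass_matrix(t(series_matrix(series)), series$tr_seconds,
                               low, high)
  bold_series(array(t(m), dim = dim(series$data)), series$grid,
              series$tr_seconds)
}

#' Nuisance regression
#'
#' Per-voxel ordinary-least-squares residualization on a regressor matrix
#' plus an intercept. Collinear regressor columns are dropped with a
#' warning. Residuals are exactly orthogonal to every retained regressor.
#'
#' @param series a [bold_series()].
#' @param regressors numeric matrix with `n_timepoints` rows (e.g. the
#'   output of [friston24()]).
#' @return The residual [bold_series()].
#' @export
regress_nuisance <- function(series, regressors) {
  stopifnot(inherits(series, "bold_series"))
  regressors <- as.matrix(regressors)
  if (nrow(regressors) != series$n_timepoints)
    nvc_format_error("regressor rows must equal n_timepoints")
  X <- cbind(intercept = 1, regressors)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    warning(sprintf("dropping %d collinear nuisance column(s): %s",
                    length(dropped), paste(dropped, collapse = ", ")))
    X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
    qx <- qr(X)
  }
  y <- t(series_matrix(series))
  res <- y - X %*% qr.coef(qx, y)
  bold_series(array(t(res), dim = dim(series$data)), series$grid,
              series$tr_seconds)
}

## 1D Gaussian kernel at given sigma (voxels); radius 3 sigma.
gaussian_kernel_1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-r):r / sigma)^2)
  k / sum(k)
}

## Convolve a 3D array along one axis with a 1D kernel, renormalizing the
## kernel at the edges so that constant arrays are preserved exactly.
convolve_axis <- function(arr, kernel, axis) {
  if (length(kernel) == 1L) return(arr)
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  n <- dim(a)[1]
  m <- matrix(a, nrow = n)
  r <- (length(kernel) - 1L) / 2L
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - r):(i + r)
    ok <- j >= 1 & j <= n
    K[i, j[ok]] <- kernel[ok] / sum(kernel[ok])
  }
  out <- array(K %*% m, dim = dim(a))
  aperm(out, order(perm))
}

#' Spatial Gaussian smoothing
#'
#' Separable Gaussian smoothing with the kernel width given as full width at
#' half maximum in mm (sigma = FWHM / (2 sqrt(2 ln 2)) per axis, converted
#' to voxels by the grid's voxel size). Kernels are renormalized at the
#' volume edges, so constant maps pass through unchanged; `fwhm = 0` is the
#' identity.
#'
#' @param x a [scalar_map()] or [bold_series()].
#' @param fwhm full width at half maximum in mm (default 6).
#' @return Smoothed object of the same class.
#' @export
smooth_gaussian <- function(x, fwhm = 6) {
  if (fwhm < 0) nvc_config_error("fwhm must be >= 0")
  if (fwhm == 0) return(x)
  grid <- x$grid
  sig <- (fwhm / (2 * sqrt(2 * log(2)))) / grid$voxel_size
  kernels <- lapply(sig, gaussian_kernel_1d)
  smooth3 <- function(a) {
    for (ax in 1:3) a <- convolve_axis(a, kernels[[ax]], ax)
    a
  }
  if (inherits(x, "bold_series")) {
    out <- x$data
    for (t in seq_len(x$n_timepoints))
      out[, , , t] <- smooth3(x$data[, , , t])
    bold_series(out, grid, x$tr_seconds)
  } else if (inherits(x, "scalar_map")) {
    scalar_map(smooth3(x$values), grid, units = x$units)
  } else {
    nvc_format_error("smooth_gaussian expects a scalar_map or bold_series")
  }
}

#' Proportional CBF quantification from ASL difference images
#'
#' Perfusion-weighted difference (control - label) scaled by a proton
#' density reference: `cbf = scale * (control - label) / pd_reference`. A
#' single proportionality constant replaces the full kinetic model, whose
#' constants (labeling efficiency, blood T1, post-label delay) are
#' acquisition-specific; downstream group statistics operate on gray-matter
#' standardized maps and are invariant to this global scale.
#'
#' @param control,label,pd_reference [scalar_map()]s on one grid.
#' @param scale proportionality constant (config key `cbf_scale`).
#' @param epsilon reference values `<= epsilon` yield NaN output.
#' @return CBF [scalar_map()] in nominal mL/100 g/min units.
#' @export
cbf_from_asl <- function(control, label, pd_reference, scale = 100,
                         epsilon = 1e-6) {
  stopifnot_same_grid(control$grid, label$grid, "ASL control/label")
  stopifnot_same_grid(control$grid, pd_reference$grid, "ASL/PD reference")
  pd <- pd_reference$values
  if (all(!is.finite(pd) | pd <= 0))
    nvc_data_error("proton-density reference is nowhere positive")
  out <- scale * (control$values - label$values) / pd
  out[!is.finite(pd) | pd <= epsilon] <- NaN
  scalar_map(out, control$grid, units = "mL/100g/min")
}

#' Standardize a CBF map by its gray-matter mean
#'
#' Divides every voxel by the mean CBF over the gray-matter mask, so the
#' standardized map has gray-matter mean exactly 1. This removes global
#' perfusion differences before between-subject comparison.
#'
#' @param cbf CBF [scalar_map()].
#' @param gm gray-matter [brain_mask()].
#' @return Standardized [scalar_map()] (gray-matter mean 1).
#' @export
standardize_cbf <- function(cbf, gm) {
  stopifnot_same_grid(cbf$grid, gm$grid, "CBF/gray-matter mask")
  v <- cbf$values[mask_logical(gm)]
  mu <- mean(v[is.finite(v)])
  if (!is.finite(mu) || mu == 0)
    nvc_data_error("gray-matter mean CBF is zero; cannot standardize")
  scalar_map(cbf$values / mu, cbf$grid, units = "gm-mean = 1")
}

#' BOLD preprocessing chain
#'
#' The implementable core of a standard resting-state stream: trim leading
#' volumes (magnetization equilibrium), compute framewise displacement,
#' regress Friston-24 motion regressors (plus any extra nuisance columns),
#' linear detrend + ideal band-pass, then Gaussian smoothing. Motion rows
#' are trimmed together with the volumes, and FD is computed after trimming,
#' so row counts always stay aligned.
#'
#' @param series raw [bold_series()].
#' @param motion 6-column motion matrix with one row per *untrimmed* volume.
#' @param trim_volumes leading volumes (and motion rows) to discard.
#' @param band two band edges in Hz.
#' @param fwhm_mm smoothing kernel FWHM in mm (0 disables smoothing).
#' @param head_radius_mm FD rotation radius.
#' @param extra_regressors optional additional nuisance matrix (post-trim
#'   row count); e.g. tissue-signal regressors. Default none: the pipeline's
#'   nuisance set is Friston-24 only.
#' @return A list with `series` (preprocessed), `fd`, `mean_fd`.
#' @export
preprocess_bold <- function(series, motion, trim_volumes = 10,
                            band = c(0.01, 0.08), fwhm_mm = 6,
                            head_radius_mm = 50, extra_regressors = NULL) {
  stopifnot(inherits(series, "bold_series"))
  motion <- as.matrix(motion)
  if (nrow(motion) != series$n_timepoints)
    nvc_format_error("motion rows must equal the untrimmed volume count")
  if (trim_volumes >= series$n_timepoints - 1L)
    nvc_config_error("trim_volumes leaves fewer than 2 volumes")
  if (trim_volumes > 0) {
    keep <- (trim_volumes + 1L):series$n_timepoints
    series <- bold_series(series$data[, , , keep, drop = FALSE],
                          series$grid, series$tr_seconds)
    motion <- motion[keep, , drop = FALSE]
  }
  fd <- framewise_displacement(motion, head_radius = head_radius_mm)
  reg <- friston24(motion)
  if (!is.null(extra_regressors)) reg <- cbind(reg, extra_regressors)
  series <- regress_nuisance(series, reg)
  series <- detrend_bandpass(series, band[1], band[2])
  if (fwhm_mm > 0) series <- smooth_gaussian(series, fwhm_mm)
  list(series = series, fd = fd$fd, mean_fd = fd$mean_fd)
}
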