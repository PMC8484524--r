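#' Discard initial volumes
#'
#' Drops the first `n` volumes of a run (steady-state magnetisation settling),
#' e.g. 240 acquired volumes with `n = 10` leave 230 time points.
#'
#' @param img A [bold_image()].
#' @param n Number of leading volumes to drop (`0 <= n < T`).
#' @return The truncated `bold_image`; grid metadata unchanged.
#' @export
discard_initial_volumes <- function(img, n = 10) {
  T <- n_volumes(img)
  if (!(n >= 0 && n < T)) stop("n must satisfy 0 <= n < number of volumes")
  if (n == 0) return(img)
  img$data <- img$data[, , , -(seq_len(n)), drop = FALSE]
  img
}

#' Motion-based subject exclusion rule
#'
#' A subject is excluded when the cumulative displacement — position relative
#' to the first volume — exceeds the translation limit on any axis or the
#' rotation limit about any axis.
#'
#' @param motion T x 6 matrix: translations (mm) then rotations (degrees).
#' @param trans_limit_mm Translation limit (default 3 mm).
#' @param rot_limit_deg Rotation limit (default 3 degrees).
#' @return `TRUE` if the subject should be excluded.
#' @export
exclude_by_motion <- function(motion, trans_limit_mm = 3, rot_limit_deg = 3) {
  stopifnot(is.matrix(motion), ncol(motion) == 6L, nrow(motion) >= 1L)
  disp <- sweep(motion, 2, motion[1, ])
  max(abs(disp[, 1:3])) > trans_limit_mm || max(abs(disp[, 4:6])) > rot_limit_deg
}

#' Friston 24-parameter motion expansion
#'
#' Autoregressive expansion of the 6 rigid parameters: current values, their
#' one-volume lag, and the squares of both. The lag at the first volume is
#' zero-filled.
#'
#' @param motion T x 6 motion matrix.
#' @return T x 24 matrix, columns ordered `p(t)`, `p(t-1)`, `p(t)^2`, `p(t-1)^2`.
#' @export
friston24 <- function(motion) {
  stopifnot(is.matrix(motion), ncol(motion) == 6L, nrow(motion) >= 2L)
  lag1 <- rbind(0, motion[-nrow(motion), , drop = FALSE])
  out <- cbind(motion, lag1, motion^2, lag1^2)
  colnames(out) <- c(paste0("p", 1:6), paste0("p", 1:6, "_lag"),
                     paste0("p", 1:6, "_sq"), paste0("p", 1:6, "_lag_sq"))
  out
}

#' Assemble the nuisance regressor set
#'
#' Friston-24 motion terms plus (optionally) the global, white-matter and CSF
#' mean signals — 27 columns when all components are enabled. Tissue means are
#' computed only over the supplied mask voxels.
#'
#' @param motion T x 6 motion matrix (already truncated to retained volumes).
#' @param img The matching `bold_image`.
#' @param wm_mask,csf_mask Logical 3D tissue masks (optional).
#' @param global Include the in-brain global mean signal?
#' @return T x p numeric matrix with column labels.
#' @export
build_nuisance <- function(motion, img, wm_mask = NULL, csf_mask = NULL,
                           global = TRUE) {
  if (nrow(motion) != n_volumes(img))
    stop("motion rows must equal the retained volume count")
  nuis <- friston24(motion)
  ts <- as_ts_matrix(img)
  if (isTRUE(global)) nuis <- cbind(nuis, global = rowMeans(ts[, as.vector(img$mask), drop = FALSE]))
  if (!is.null(wm_mask)) nuis <- cbind(nuis, wm = rowMeans(ts[, as.vector(wm_mask), drop = FALSE]))
  if (!is.null(csf_mask)) nuis <- cbind(nuis, csf = rowMeans(ts[, as.vector(csf_mask), drop = FALSE]))
  as.matrix(nuis)
}

#' Regress nuisance covariates out of voxel time series
#'
#' Ordinary least squares with an intercept; collinear regressor columns are
#' dropped (with a warning) before fitting. Residuals are orthogonal to every
#' retained regressor.
#'
#' @param ts T x V matrix of time series (or a vector).
#' @param nuis T x p nuisance matrix.
#' @return Residual matrix of the same shape as `ts`.
#' @export
regress_nuisance <- function(ts, nuis) {
  vec <- is.null(dim(ts))
  ts <- cbind(ts)
  nuis <- cbind(nuis)
  if (nrow(ts) != nrow(nuis)) stop("row counts of ts and nuis must match")
  X <- cbind(intercept = 1, nuis)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    keep <- qx$pivot[seq_len(qx$rank)]
    warning(sprintf("dropping %d collinear nuisance column(s)", ncol(X) - qx$rank))
    qx <- qr(X[, sort(keep), drop = FALSE])
  }
  res <- ts - qr.fitted(qx, ts)
  if (vec) drop(res) else res
}

#' Remove a linear trend
#'
#' @param ts T x V matrix or vector, T >= 3.
#' @return Residuals after removing the least-squares line in time; orthogonal
#'   to both the constant and the linear ramp.
#' @export
detrend_linear <- function(ts) {
  vec <- is.null(dim(ts))
  ts <- cbind(ts)
  T <- nrow(ts)
  if (T < 3) stop("need at least 3 samples to detrend")
  X <- cbind(1, seq_len(T))
  res <- ts - X %*% qr.coef(qr(X), ts)
  if (vec) drop(res) else res
}

#' Ideal frequency-domain band-pass filter
#'
#' Linear detrend followed by a rectangular FFT filter retaining Fourier bins
#' with `low <= f <= high` (the DPABI/REST convention). The DC component is
#' always removed.
#'
#' @param ts T x V matrix or vector.
#' @param tr Sampling interval in seconds.
#' @param low,high Passband edges in Hz (defaults 0.01 and 0.08).
#' @return Filtered series, same shape as `ts`.
#' @export
bandpass <- function(ts, tr, low = 0.01, high = 0.08) {
  vec <- is.null(dim(ts))
  ts <- cbind(ts)
  T <- nrow(ts)
  if (T < 3) stop("series must have at least 3 samples")
  if (!(tr > 0)) stop("tr must be positive")
  nyquist <- 1 / (2 * tr)
  if (!(low < high && high < nyquist)) stop("need low < high < Nyquist frequency")
  ts <- detrend_linear(ts)
  freq <- (seq_len(T) - 1) / (T * tr)
  folded <- pmin(freq, 1 / tr - freq)
  keep <- folded >= low - 1e-12 & folded <= high + 1e-12
  out <- Re(mvfft(mvfft(ts) * keep, inverse = TRUE)) / T
  if (vec) drop(out) else out
}

#' Spatial Gaussian smoothing
#'
#' Separable per-volume 3D Gaussian convolution with
#' `sigma = fwhm / (voxel_size * sqrt(8 * log(2)))` voxels, zero-padded at the
#' grid boundary (total intensity is conserved on interior support).
#'
#' @param img A `bold_image`.
#' @param fwhm_mm Full width at half maximum in mm (default 6); 0 is identity.
#' @return Smoothed `bold_image`.
#' @export
smooth_gaussian <- function(img, fwhm_mm = 6) {
  if (fwhm_mm < 0) stop("fwhm must be non-negative")
  if (fwhm_mm == 0) return(img)
  sigma <- fwhm_mm / (img$voxel_size_mm * sqrt(8 * log(2)))
  r <- max(1L, ceiling(4 * sigma))
  g <- exp(-((-r):r)^2 / (2 * sigma^2))
  g <- g / sum(g)
  d <- dim(img$data)
  band <- function(n) {
    A <- matrix(0, n, n)
    for (k in (-r):r) {
      i <- seq_len(n)
      j <- i + k
      ok <- j >= 1 & j <= n
      A[cbind(i[ok], j[ok])] <- g[k + r + 1]
    }
    A
  }
  A1 <- band(d[1]); A2 <- band(d[2]); A3 <- band(d[3])
  for (t in seq_len(d[4])) {
    v <- img$data[, , , t]
    v <- array(A1 %*% matrix(v, d[1], d[2] * d[3]), d[1:3])
    v <- aperm(v, c(2, 1, 3))
    v <- array(A2 %*% matrix(v, d[2], d[1] * d[3]), c(d[2], d[1], d[3]))
    v <- aperm(v, c(2, 1, 3))
    v <- aperm(v, c(3, 2, 1))
    v <- array(A3 %*% matrix(v, d[3], d[2] * d[1]), c(d[3], d[2], d[1]))
    img$data[, , , t] <- aperm(v, c(3, 2, 1))
  }
  img
}

#' Minimal volumetric preprocessing pipeline
#'
#' Fixed stage order: volume discard, linear detrend, nuisance regression
#' (Friston-24 + tissue signals), ideal band-pass, Gaussian smoothing. The
#' order is recorded in the `provenance` attribute of the result.
#'
#' @param img A `bold_image` (already on the common grid).
#' @param motion T x 6 motion trace matching the *acquired* volumes.
#' @param discard Leading volumes to drop (default 10).
#' @param band Passband in Hz (default `c(0.01, 0.08)`).
#' @param fwhm Smoothing FWHM in mm (default 6).
#' @param wm_mask,csf_mask Tissue masks for the nuisance signals.
#' @param global Include the global mean regressor (default TRUE).
#' @return Preprocessed `bold_image` with a `provenance` attribute.
#' @export
preprocess_bold <- function(img, motion, discard = 10, band = c(0.01, 0.08),
                            fwhm = 6, wm_mask = NULL, csf_mask = NULL,
                            global = TRUE) {
  if (nrow(motion) != n_volumes(img))
    stop("motion rows must equal the acquired volume count")
  img <- discard_initial_volumes(img, discard)
  if (discard > 0) motion <- motion[-seq_len(discard), , drop = FALSE]
  ts <- as_ts_matrix(img)
  ts <- detrend_linear(ts)
  nuis <- build_nuisance(motion, from_ts_matrix(ts, img), wm_mask, csf_mask, global)
  ts <- regress_nuisance(ts, nuis)
  ts <- bandpass(ts, img$tr, band[1], band[2])
  img <- from_ts_matrix(ts, img)
  img <- smooth_gaussian(img, fwhm)
  attr(img, "provenance") <- list(
    steps = c("discard", "detrend", "nuisance_regression", "bandpass", "smooth"),
    discard = discard, band = band, fwhm = fwhm,
    n_nuisance = ncol(nuis))
  img
}
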