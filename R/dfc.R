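#' Sliding-window scheme
#'
#' Rectangular (untapered) windows of `width` samples advanced by `step`,
#' 0-based half-open `[start, start + width)`. The number of windows is
#' `K = floor((T - width)/step) + 1`; e.g. 230 retained time points with the
#' default width 40 and step 2 give 96 windows. Trailing samples that do not
#' complete a window are dropped.
#'
#' @param T Number of retained time points.
#' @param width Window width in TRs (default 40).
#' @param step Window step in TRs (default 2).
#' @return A list of class `window_scheme` with fields `width`, `step`,
#'   `n_windows` and 0-based `starts`.
#' @export
make_windows <- function(T, width = 40, step = 2) {
  stopifnot(step >= 1, width >= 2)
  if (T < width) stop("series is shorter than the window width")
  starts <- seq(0L, T - width, by = step)
  structure(list(width = as.integer(width), step = as.integer(step),
                 n_windows = length(starts), starts = as.integer(starts)),
            class = "window_scheme")
}

#' @export
print.window_scheme <- function(x, ...) {
  cat(sprintf("<window_scheme> width %d TR, step %d TR, %d windows\n",
              x$width, x$step, x$n_windows))
  invisible(x)
}

#' Windowed Fisher-z connectivity series
#'
#' Pearson correlation between the two series within each window, clipped at
#' |r| = 1 - 1e-7 and Fisher z-transformed. Windows in which either series has
#' zero variance yield z = 0 and are flagged.
#'
#' @param seed_ts,voxel_ts Numeric vectors of equal length covering the scheme.
#' @param scheme A [make_windows()] scheme.
#' @return Numeric vector of K z-values with a logical `degenerate` attribute.
#' @export
windowed_z_series <- function(seed_ts, voxel_ts, scheme) {
  T <- length(seed_ts)
  stopifnot(length(voxel_ts) == T)
  last <- scheme$starts[scheme$n_windows] + scheme$width
  if (T < last) stop("series shorter than the last window end")
  z <- numeric(scheme$n_windows)
  degen <- logical(scheme$n_windows)
  for (k in seq_len(scheme$n_windows)) {
    idx <- scheme$starts[k] + seq_len(scheme$width)
    x <- seed_ts[idx]; y <- voxel_ts[idx]
    if (sd(x) == 0 || sd(y) == 0) {
      degen[k] <- TRUE
    } else {
      z[k] <- fisher_z(cor(x, y))
    }
  }
  attr(z, "degenerate") <- degen
  z
}

#' Temporal variability of a windowed connectivity series
#'
#' Sample standard deviation (denominator K - 1) of the K windowed Fisher-z
#' values — the per-voxel dynamic connectivity statistic.
#'
#' @param z_series Numeric vector, length >= 2.
#' @return Non-negative scalar.
#' @export
variability <- function(z_series) {
  if (length(z_series) < 2) stop("need at least 2 windows")
  sd(z_series)
}

#' Seed-based DFC variability map
#'
#' Applies [windowed_z_series()] + [variability()] to every in-mask voxel
#' against the seed mean time series, vectorised over voxels. Zero-variance
#' windows contribute z = 0, and voxels with zero variance in every window
#' map to 0.
#'
#' @param img A preprocessed [bold_image()].
#' @param seed A [seed_spec()], or a precomputed logical seed mask.
#' @param scheme A [make_windows()] scheme matching the image length.
#' @param mask Analysis mask; defaults to the image brain mask.
#' @return 3D variability map (0 outside `mask`) with attributes `scheme` and
#'   `seed_name`.
#' @export
variability_map <- function(img, seed, scheme, mask = img$mask) {
  T <- n_volumes(img)
  if (scheme$starts[scheme$n_windows] + scheme$width > T)
    stop("window scheme does not fit the image")
  if (inherits(seed, "seed_spec")) {
    seed_mask <- make_seed_mask(seed, dim(img$data)[1:3], img$affine)
    seed_name <- seed$name
  } else {
    seed_mask <- seed
    seed_name <- "custom"
  }
  s <- seed_timeseries(img, seed_mask)
  M <- as_ts_matrix(img)[, as.vector(mask), drop = FALSE]
  K <- scheme$n_windows
  zs <- matrix(0, K, ncol(M))
  for (k in seq_len(K)) {
    idx <- scheme$starts[k] + seq_len(scheme$width)
    zs[k, ] <- fisher_z(cor_vec_mat(s[idx], M[idx, , drop = FALSE]))
  }
  v <- apply(zs, 2, sd)
  out <- array(0, dim(img$data)[1:3])
  out[as.vector(mask)] <- v
  attr(out, "scheme") <- unclass(scheme)[c("width", "step", "n_windows")]
  attr(out, "seed_name") <- seed_name
  out
}
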