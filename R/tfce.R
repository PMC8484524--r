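#' Threshold-free cluster enhancement parameters
#'
#' Field-standard defaults: height exponent `H = 2`, extent exponent
#' `E = 0.5`, integration step `dh = max(map)/100` (set `dh = NULL` for that
#' rule, or a fixed positive value), 26-voxel neighbourhood.
#'
#' @param H Height exponent.
#' @param E Extent exponent.
#' @param dh Threshold step; `NULL` means `max(map)/100` per map.
#' @param connectivity 6 or 26.
#' @return A list of class `tfce_params`.
#' @export
tfce_params <- function(H = 2, E = 0.5, dh = NULL, connectivity = 26) {
  stopifnot(H > 0, E > 0, connectivity %in% c(6L, 26L))
  if (!is.null(dh)) stopifnot(dh > 0)
  structure(list(H = H, E = E, dh = dh, connectivity = as.integer(connectivity)),
            class = "tfce_params")
}

#' Threshold-free cluster enhancement
#'
#' Discrete TFCE transform
#' `TFCE(v) = sum_h extent(v, h)^E * h^H * dh` over thresholds
#' `h = dh, 2 dh, ...` up to the map maximum, where `extent(v, h)` is the size
#' of the connected component of supra-threshold voxels containing `v`.
#' Negative values are handled by transforming the negated map separately and
#' negating the result.
#'
#' @param map Numeric array (1D–3D) of statistic values; must be finite.
#' @param params A [tfce_params()] object.
#' @return Array of TFCE scores, same shape as `map`.
#' @export
tfce_transform <- function(map, params = tfce_params()) {
  if (!all(is.finite(map))) stop("map must be finite")
  dims <- dim(map)
  if (is.null(dims)) dims <- length(map)
  dims3 <- as.integer(c(dims, rep(1L, 3 - length(dims))))
  one_side <- function(x) {
    mx <- max(x)
    if (mx <= 0) return(numeric(length(x)))
    dh <- if (is.null(params$dh)) mx / 100 else params$dh
    tfce_cpp(as.numeric(x), dims3, params$H, params$E, dh, params$connectivity)
  }
  out <- one_side(pmax(map, 0)) - one_side(pmax(-map, 0))
  if (!is.null(dim(map))) dim(out) <- dim(map)
  out
}

#' Label connected clusters of a logical mask
#'
#' @param mask Logical array (1D–3D).
#' @param connectivity 6 or 26.
#' @return Integer array of cluster labels (0 outside the mask).
#' @export
label_clusters <- function(mask, connectivity = 26) {
  dims <- dim(mask)
  if (is.null(dims)) dims <- length(mask)
  dims3 <- as.integer(c(dims, rep(1L, 3 - length(dims))))
  lab <- label_components_cpp(as.logical(mask), dims3, as.integer(connectivity))
  if (!is.null(dim(mask))) dim(lab) <- dim(mask)
  lab
}
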