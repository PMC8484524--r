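#' Spherical seed specification
#'
#' @param name Anatomical label of the seed.
#' @param center MNI centre in mm, length-3 numeric.
#' @param radius_mm Sphere radius in mm (default 10).
#' @param network Name of the network the seed generates.
#' @return A list of class `seed_spec`.
#' @export
seed_spec <- function(name, center, radius_mm = 10, network = name) {
  stopifnot(length(center) == 3L, radius_mm > 0)
  structure(list(name = name, center = as.numeric(center),
                 radius_mm = radius_mm, network = network),
            class = "seed_spec")
}

#' Default triple-network seeds
#'
#' The four canonical 10-mm spherical seeds: ventromedial prefrontal cortex
#' (0, 52, -6) for the anterior DMN, posterior cingulate cortex (0, -53, 26)
#' for the posterior DMN, right anterior insula (38, 22, -10) for the salience
#' network, and dorsolateral prefrontal cortex (48, 12, 34) for the executive
#' control network.
#'
#' @return Named list of four [seed_spec()] objects.
#' @export
default_seeds <- function() {
  list(
    aDMN = seed_spec("vmPFC", c(0, 52, -6), 10, "aDMN"),
    pDMN = seed_spec("PCC", c(0, -53, 26), 10, "pDMN"),
    SN   = seed_spec("rAI", c(38, 22, -10), 10, "SN"),
    ECN  = seed_spec("DLPFC", c(48, 12, 34), 10, "ECN")
  )
}

#' Voxelize a spherical seed
#'
#' Marks every voxel whose centre lies within `radius_mm` of the seed centre.
#'
#' @param seed A [seed_spec()].
#' @param dims Grid dimensions (length 3).
#' @param affine 4x4 voxel-to-mm affine.
#' @return Logical 3D mask.
#' @export
make_seed_mask <- function(seed, dims, affine) {
  vox <- mm_to_voxel(affine, seed$center)
  if (any(vox < -0.5) || any(vox > dims - 0.5))
    stop(sprintf("seed '%s' centre lies outside the grid", seed$name))
  mm <- voxel_centers_mm(affine, dims)
  d2 <- (mm[, 1] - seed$center[1])^2 + (mm[, 2] - seed$center[2])^2 +
    (mm[, 3] - seed$center[3])^2
  mask <- array(d2 <= seed$radius_mm^2, dims)
  if (!any(mask)) stop(sprintf("seed '%s' produced an empty mask", seed$name))
  mask
}

#' Mean time series over a voxel mask
#'
#' @param img A [bold_image()].
#' @param mask Logical 3D mask (non-empty).
#' @return Numeric vector of length T (unweighted voxel mean per volume).
#' @export
seed_timeseries <- function(img, mask) {
  if (!any(mask)) stop("mask is empty")
  rowMeans(as_ts_matrix(img)[, as.vector(mask), drop = FALSE])
}

# Fisher z with |r| clipped at 1 - 1e-7 so seed self-correlation stays finite.
r_clip <- 1 - 1e-7

fisher_z <- function(r) atanh(pmin(pmax(r, -r_clip), r_clip))

# Pearson correlation of one vector against every column of a matrix;
# zero-variance columns yield 0 (flagged by the caller).
cor_vec_mat <- function(x, M) {
  xc <- x - mean(x)
  Mc <- sweep(M, 2, colMeans(M))
  num <- as.vector(crossprod(Mc, xc))
  den <- sqrt(sum(xc^2) * colSums(Mc^2))
  r <- ifelse(den > 0, num / den, 0)
  r
}

#' Seed-based static functional connectivity z-map
#'
#' Voxelwise Pearson correlation between the seed mean time series and every
#' in-mask voxel, Fisher r-to-z transformed. Zero-variance voxels get z = 0
#' and are flagged in the `degenerate` attribute.
#'
#' @param img A preprocessed [bold_image()].
#' @param seed_ts Seed mean time series (length T, variance > 0).
#' @param mask Analysis mask; defaults to the image brain mask (a grey-matter
#'   mask may be supplied instead).
#' @return 3D array of Fisher-z values (0 outside `mask`), with attribute
#'   `degenerate` marking zero-variance voxels.
#' @export
static_fc_zmap <- function(img, seed_ts, mask = img$mask) {
  T <- n_volumes(img)
  if (T < 3) stop("need at least 3 time points")
  if (sd(seed_ts) == 0) stop("seed time series has zero variance")
  M <- as_ts_matrix(img)[, as.vector(mask), drop = FALSE]
  r <- cor_vec_mat(seed_ts, M)
  degen <- colSums(sweep(M, 2, colMeans(M))^2) == 0
  z <- array(0, dim(img$data)[1:3])
  z[as.vector(mask)] <- fisher_z(r)
  flag <- array(FALSE, dim(z))
  flag[as.vector(mask)] <- degen
  attr(z, "degenerate") <- flag
  z
}

#' Positive-connectivity network template via one-sample permutation inference
#'
#' Voxelwise one-sample t-test of subject z-maps against zero, sign-flip
#' permutation of the subject maps, TFCE transform of each permuted t-map, and
#' family-wise error control from the max-TFCE null distribution. The template
#' is the set of voxels with positive t and FWE-corrected p below `alpha`.
#'
#' @param zmaps List of per-subject 3D z-maps (>= 8), or an N x V matrix of
#'   in-mask values.
#' @param mask Analysis mask (required when `zmaps` is a matrix).
#' @param n_perm Number of sign-flip permutations (>= 100; default 1000).
#' @param alpha FWE threshold (default 0.05).
#' @param params TFCE parameters.
#' @param seed Optional RNG seed for the permutations.
#' @return Logical 3D template mask with a `provenance` attribute
#'   (n subjects, n permutations, alpha) and a `p_fwe` attribute map.
#' @export
one_sample_template <- function(zmaps, mask = NULL, n_perm = 1000, alpha = 0.05,
                                params = tfce_params(), seed = NULL) {
  if (is.list(zmaps)) {
    dims <- dim(zmaps[[1]])
    if (is.null(mask)) mask <- array(TRUE, dims)
    Y <- do.call(rbind, lapply(zmaps, function(m) as.numeric(m)[as.vector(mask)]))
  } else {
    Y <- zmaps
    if (is.null(mask)) stop("mask is required for matrix input")
    dims <- dim(mask)
  }
  n <- nrow(Y)
  if (n < 8) stop("need at least 8 subject maps")
  if (n_perm < 100) stop("n_perm must be at least 100")
  if (all(Y == 0)) stop("all maps are zero")
  if (!is.null(seed)) set.seed(seed)

  mask_vec <- as.vector(mask)
  tfce_in_mask <- function(tvals) {
    m <- array(0, dims)
    m[mask_vec] <- tvals
    tfce_transform(m, params)[mask_vec]
  }
  tstat <- function(Ys) {
    mu <- colMeans(Ys)
    s <- sqrt(pmax(colSums(sweep(Ys, 2, mu)^2) / (n - 1), 0))
    mu / pmax(s, 1e-12) * sqrt(n)
  }
  t_obs <- tstat(Y)
  tf_obs <- tfce_in_mask(t_obs)
  max_null <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    flips <- sample(c(-1, 1), n, replace = TRUE)
    max_null[b] <- max(tfce_in_mask(tstat(Y * flips)))
  }
  # the observed statistic is part of the null distribution
  p_fwe <- vapply(tf_obs, function(v) (1 + sum(max_null >= v)) / (n_perm + 1),
                  numeric(1))
  template <- array(FALSE, dims)
  template[mask_vec] <- t_obs > 0 & p_fwe < alpha
  pmap <- array(1, dims)
  pmap[mask_vec] <- p_fwe
  attr(template, "p_fwe") <- pmap
  attr(template, "provenance") <- list(n_subjects = n, n_perm = n_perm,
                                       alpha = alpha, test = "one-sample t, sign-flip, TFCE-FWE")
  template
}
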