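#' Cognitive-domain composite z-scores
#'
#' Each raw test score is standardised against reference statistics (by
#' default the healthy-control group mean and sd), and a domain composite is
#' the mean of its tests' z-scores.
#'
#' @param raw Data frame of raw test scores (one row per subject).
#' @param domain_map Named list mapping each domain (e.g. EM, EF, IPS, VF) to
#'   the test column names it comprises.
#' @param ref_rows Logical/index vector selecting the reference subjects
#'   (default: all rows). Typically the HC group.
#' @param ref_stats Optional list with `mean` and `sd` named vectors,
#'   overriding `ref_rows`.
#' @return Data frame of domain composites, one column per domain.
#' @export
composite_z <- function(raw, domain_map, ref_rows = NULL, ref_stats = NULL) {
  tests <- unique(unlist(domain_map))
  if (!all(tests %in% names(raw))) stop("domain_map names tests missing from raw")
  if (is.null(ref_stats)) {
    ref <- if (is.null(ref_rows)) raw else raw[ref_rows, , drop = FALSE]
    ref_stats <- list(mean = vapply(ref[tests], mean, numeric(1)),
                      sd = vapply(ref[tests], sd, numeric(1)))
  }
  if (any(ref_stats$sd[tests] == 0)) stop("zero reference sd")
  z <- sweep(sweep(as.matrix(raw[tests]), 2, ref_stats$mean[tests]), 2,
             ref_stats$sd[tests], "/")
  out <- as.data.frame(lapply(domain_map, function(cols)
    rowMeans(z[, cols, drop = FALSE])))
  names(out) <- names(domain_map)
  out
}

#' Mean variability within each significant cluster
#'
#' @param maps List of per-subject 3D maps (or an N x V in-mask matrix with a
#'   `mask` argument).
#' @param labels Integer cluster-label array from the inference stage.
#' @param mask Analysis mask (required for matrix input).
#' @return Data frame: one row per subject, one column per cluster
#'   (`cluster_1`, ...), the unweighted mean of the map over cluster voxels.
#' @export
extract_cluster_means <- function(maps, labels, mask = NULL) {
  ids <- setdiff(sort(unique(as.vector(labels))), 0L)
  if (length(ids) == 0) stop("no clusters to extract")
  if (is.matrix(maps)) {
    if (is.null(mask)) stop("mask is required for matrix input")
    lab_vec <- as.vector(labels)[as.vector(mask)]
    out <- sapply(ids, function(id) rowMeans(maps[, lab_vec == id, drop = FALSE]))
  } else {
    out <- sapply(ids, function(id) {
      vox <- which(as.vector(labels) == id)
      vapply(maps, function(m) mean(as.numeric(m)[vox]), numeric(1))
    })
  }
  out <- as.data.frame(matrix(out, ncol = length(ids)))
  names(out) <- paste0("cluster_", ids)
  out
}

#' Covariate-adjusted (partial) correlation
#'
#' Pearson correlation of the residuals of `x` and `y` after regressing both
#' on the covariates plus an intercept; two-sided p from the t distribution
#' with n - k - 2 degrees of freedom (k = number of covariates). With no
#' covariates this reduces to the plain Pearson correlation.
#'
#' @param x,y Numeric vectors.
#' @param covariates Numeric matrix/data frame of covariates, or NULL.
#' @return List with `estimate`, `p`, `df` and `n`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  k <- if (is.null(covariates)) 0L else ncol(cbind(covariates))
  if (n <= k + 2) stop("need n > number of covariates + 2")
  if (k > 0) {
    X <- cbind(1, as.matrix(covariates))
    qx <- qr(X)
    x <- x - qr.fitted(qx, x)
    y <- y - qr.fitted(qx, y)
  }
  if (sd(x) == 0 || sd(y) == 0) stop("degenerate residual variance")
  r <- cor(x, y)
  df <- n - k - 2
  tstat <- r * sqrt(df) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  list(estimate = r, p = 2 * pt(abs(tstat), df, lower.tail = FALSE),
       df = df, n = n)
}

#' Brain-behavior correlation table with Bonferroni correction
#'
#' Partial correlations between every extracted cluster mean and every
#' cognitive domain composite, adjusted for the covariates, with Bonferroni
#' correction over the full (cluster x domain) family.
#'
#' @param extracts Data frame of cluster means (one column per cluster).
#' @param composites Data frame of domain composites.
#' @param covariates Covariate matrix/data frame (same rows).
#' @return Data frame with columns `cluster`, `domain`, `r`, `p`,
#'   `p_bonferroni` and `significant`.
#' @export
behavior_correlations <- function(extracts, composites, covariates = NULL) {
  grid <- expand.grid(cluster = names(extracts), domain = names(composites),
                      stringsAsFactors = FALSE)
  m <- nrow(grid)
  res <- lapply(seq_len(m), function(i) {
    pc <- partial_correlation(extracts[[grid$cluster[i]]],
                              composites[[grid$domain[i]]], covariates)
    data.frame(grid[i, ], r = pc$estimate, p = pc$p)
  })
  out <- do.call(rbind, res)
  out$p_bonferroni <- pmin(out$p * m, 1)
  out$significant <- out$p_bonferroni < 0.05
  rownames(out) <- NULL
  out
}
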