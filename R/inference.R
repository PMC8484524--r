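#' Inference configuration
#'
#' Thresholding rules for the group analyses: the ANCOVA path forms clusters
#' at voxelwise permutation p < `voxel_alpha` and keeps clusters that have at
#' least `ancova_min_voxels` voxels (20 voxels = 540 mm^3 at 3 mm isotropic)
#' and survive the max-cluster-size null at `ancova_alpha`; the post-hoc path
#' uses TFCE-FWE at `posthoc_alpha` with clusters larger than
#' `posthoc_min_voxels - 1` voxels (> 9 voxels = > 243 mm^3).
#'
#' @param n_perm Number of permutations (default 1000).
#' @param ancova_alpha Cluster-level corrected alpha for the ANCOVA (0.05).
#' @param voxel_alpha Cluster-forming voxelwise permutation p (0.05).
#' @param ancova_min_voxels Minimum ANCOVA cluster extent in voxels (20).
#' @param posthoc_alpha TFCE-FWE alpha for post-hoc contrasts (0.05).
#' @param posthoc_min_voxels Minimum post-hoc cluster extent (10, i.e. "> 9").
#' @param tfce TFCE parameters, see [tfce_params()].
#' @return A list of class `inference_config`.
#' @export
inference_config <- function(n_perm = 1000, ancova_alpha = 0.05,
                             voxel_alpha = 0.05, ancova_min_voxels = 20,
                             posthoc_alpha = 0.05, posthoc_min_voxels = 10,
                             tfce = tfce_params()) {
  stopifnot(n_perm >= 99, ancova_alpha > 0, voxel_alpha > 0,
            ancova_min_voxels >= 1, posthoc_alpha > 0, posthoc_min_voxels >= 1)
  structure(list(n_perm = n_perm, ancova_alpha = ancova_alpha,
                 voxel_alpha = voxel_alpha, ancova_min_voxels = ancova_min_voxels,
                 posthoc_alpha = posthoc_alpha, posthoc_min_voxels = posthoc_min_voxels,
                 tfce = tfce),
            class = "inference_config")
}

#' Group design matrix with nuisance covariates
#'
#' Group indicators (reference = first level) plus mean-centred age, sex
#' (coded 0/1) and education, with an intercept. The reduced design drops the
#' group indicators and is used for Freedman-Lane permutation.
#'
#' @param cohort Data frame with columns `group`, `age`, `sex`, `education`.
#' @param groups Group levels in order; the first is the reference.
#' @return List with `X_full`, `X_reduced`, the group factor and `q` (number
#'   of group indicator columns).
#' @export
design_matrix <- function(cohort, groups = c("HC", "SCD", "aMCI")) {
  groups <- groups[groups %in% unique(cohort$group)]
  if (!all(cohort$group %in% groups)) stop("unknown group label in cohort")
  g <- factor(cohort$group, levels = groups)
  sex <- cohort$sex
  if (!is.numeric(sex)) sex <- as.numeric(factor(sex)) - 1
  covs <- cbind(age = cohort$age, sex = sex, education = cohort$education)
  covs <- sweep(covs, 2, colMeans(covs))
  G <- sapply(groups[-1], function(lev) as.numeric(g == lev))
  G <- matrix(G, nrow = length(g), dimnames = list(NULL, groups[-1]))
  X_full <- cbind(intercept = 1, G, covs)
  if (qr(X_full)$rank < ncol(X_full)) stop("design matrix is rank deficient")
  list(X_full = X_full, X_reduced = cbind(intercept = 1, covs),
       group = g, q = ncol(G))
}

# Partial F statistics for the group factor at every column of Y (T x V),
# from the nested comparison of X_full vs X_reduced.
glm_f_stats <- function(Y, X_full, X_reduced) {
  n <- nrow(Y)
  q <- ncol(X_full) - ncol(X_reduced)
  rss <- function(X) {
    qx <- qr(X)
    colSums((Y - qr.fitted(qx, Y))^2)
  }
  rss_f <- rss(X_full)
  rss_r <- rss(X_reduced)
  df2 <- n - ncol(X_full)
  ((rss_r - rss_f) / q) / pmax(rss_f / df2, .Machine$double.eps)
}

# Stack subject maps into an N x V matrix of in-mask values.
stack_maps <- function(maps, mask) {
  if (is.matrix(maps)) return(maps)
  do.call(rbind, lapply(maps, function(m) as.numeric(m)[as.vector(mask)]))
}

#' Voxelwise ANCOVA F map
#'
#' Per-voxel partial F for the group factor after adjusting for age, sex and
#' education (df q, N - p; 2 and N - 5 with three groups).
#'
#' @param maps List of per-subject 3D variability maps, or an N x V matrix of
#'   in-mask values (rows align with `design`).
#' @param design A [design_matrix()].
#' @param mask Logical analysis mask (e.g. a network template).
#' @return 3D F map (0 outside the mask) with attribute `df`.
#' @export
ancova_f_map <- function(maps, design, mask) {
  if (!any(mask)) stop("mask is empty")
  Y <- stack_maps(maps, mask)
  f <- glm_f_stats(Y, design$X_full, design$X_reduced)
  out <- array(0, dim(mask))
  out[as.vector(mask)] <- f
  attr(out, "df") <- c(design$q, nrow(Y) - ncol(design$X_full))
  out
}

# Freedman-Lane permutation F (or t) matrix: row 1 is the observed statistic,
# rows 2..n_perm+1 come from refitting after permuting the reduced-model
# residuals.
freedman_lane <- function(Y, design, n_perm, stat = c("F", "t")) {
  stat <- match.arg(stat)
  qr_red <- qr(design$X_reduced)
  fitted_red <- qr.fitted(qr_red, Y)
  resid_red <- Y - fitted_red
  n <- nrow(Y)
  compute <- function(Ys) {
    if (stat == "F") glm_f_stats(Ys, design$X_full, design$X_reduced)
    else glm_t_stats(Ys, design$X_full, design$coef_index)
  }
  out <- matrix(0, n_perm + 1, ncol(Y))
  out[1, ] <- compute(Y)
  for (b in seq_len(n_perm)) {
    out[b + 1, ] <- compute(fitted_red + resid_red[sample.int(n), , drop = FALSE])
  }
  out
}

# t statistics for one coefficient of the full model at every column of Y.
glm_t_stats <- function(Y, X_full, coef_index) {
  n <- nrow(Y)
  xtx_inv <- solve(crossprod(X_full))
  B <- xtx_inv %*% crossprod(X_full, Y)
  rss <- colSums((Y - X_full %*% B)^2)
  df <- n - ncol(X_full)
  se <- sqrt(pmax(rss / df, .Machine$double.eps) * xtx_inv[coef_index, coef_index])
  B[coef_index, ] / se
}

# Tabulate suprathreshold clusters: extent, mm^3, peak location (by largest
# |stat|, ties broken by first column-major voxel) and peak statistic.
cluster_table <- function(labels, stat_map, affine, voxel_size_mm,
                          p_corrected = NULL) {
  ids <- setdiff(sort(unique(as.vector(labels))), 0L)
  rows <- lapply(ids, function(id) {
    vox <- which(labels == id)
    peak <- vox[which.max(abs(stat_map[vox]))]
    ijk <- arrayInd(peak, dim(labels)) - 1L
    mm <- voxel_to_mm(affine, ijk)
    data.frame(cluster = id, n_voxels = length(vox),
               size_mm3 = length(vox) * voxel_size_mm^3,
               peak_x = mm[1], peak_y = mm[2], peak_z = mm[3],
               peak_stat = stat_map[peak])
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster = integer(), n_voxels = integer(), size_mm3 = numeric(),
               peak_x = numeric(), peak_y = numeric(), peak_z = numeric(),
               peak_stat = numeric())
  if (!is.null(p_corrected)) tab$p_corrected <- p_corrected[seq_len(nrow(tab))]
  tab
}

#' ANCOVA permutation test with cluster-extent thresholding
#'
#' Freedman-Lane permutation of the group F map: clusters are formed at a
#' voxelwise permutation p below `cfg$voxel_alpha`, and retained when their
#' extent reaches `cfg$ancova_min_voxels` voxels and their corrected p (from
#' the max-cluster-size null distribution) is below `cfg$ancova_alpha`.
#'
#' @param maps Subject maps (list of 3D arrays or N x V matrix).
#' @param design A [design_matrix()].
#' @param mask Analysis mask.
#' @param affine Voxel-to-mm affine for peak coordinates.
#' @param cfg An [inference_config()].
#' @param seed Optional RNG seed for the permutations.
#' @return List with the observed `f_map`, voxelwise permutation `p_map`,
#'   the significant-cluster mask `cluster_mask`, and `clusters` (a cluster
#'   table; may have zero rows).
#' @export
permutation_cluster_threshold <- function(maps, design, mask, affine,
                                          cfg = inference_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!any(mask)) stop("mask is empty")
  Y <- stack_maps(maps, mask)
  voxel_size <- sqrt(sum(affine[1:3, 1]^2))
  Fall <- freedman_lane(Y, design, cfg$n_perm, stat = "F")
  B1 <- nrow(Fall)
  # voxelwise permutation p for each row against the pooled distribution
  pass <- matrix(FALSE, B1, ncol(Fall))
  for (v in seq_len(ncol(Fall))) {
    r <- rank(Fall[, v], ties.method = "min")
    pass[, v] <- (B1 + 1 - r) / B1 < cfg$voxel_alpha
  }
  to_map <- function(vals, fill = 0) {
    m <- array(fill, dim(mask)); m[as.vector(mask)] <- vals; m
  }
  # null distribution of the largest cluster extent (row 1 = observed)
  max_size <- vapply(seq_len(B1), function(b) {
    lab <- label_clusters(to_map(pass[b, ], FALSE) > 0, cfg$tfce$connectivity)
    if (any(lab > 0)) max(tabulate(lab[lab > 0])) else 0L
  }, numeric(1))
  obs_lab <- label_clusters(to_map(pass[1, ], FALSE) > 0, cfg$tfce$connectivity)
  f_map <- to_map(Fall[1, ])
  sizes <- tabulate(obs_lab[obs_lab > 0])
  keep_ids <- which(sizes >= cfg$ancova_min_voxels &
                      vapply(sizes, function(s) mean(max_size >= s), numeric(1)) <
                      cfg$ancova_alpha)
  final_lab <- array(0L, dim(mask))
  for (i in seq_along(keep_ids)) final_lab[obs_lab == keep_ids[i]] <- i
  p_corr <- vapply(keep_ids, function(id) mean(max_size >= sizes[id]), numeric(1))
  p_map <- to_map(vapply(seq_len(ncol(Fall)), function(v)
    (1 + sum(Fall[-1, v] >= Fall[1, v])) / B1, numeric(1)), fill = 1)
  list(f_map = f_map, p_map = p_map,
       cluster_mask = final_lab > 0, labels = final_lab,
       clusters = cluster_table(final_lab, f_map, affine, voxel_size, p_corr))
}

#' Post-hoc pairwise contrast with TFCE-FWE correction
#'
#' Covariate-adjusted two-sample t-test restricted to the ANCOVA mask:
#' Freedman-Lane permutation of the group-coefficient t map, signed TFCE, and
#' family-wise error control via the max-|TFCE| null. Surviving voxels are
#' clustered and clusters larger than `cfg$posthoc_min_voxels - 1` voxels are
#' reported. Positive t means the second group of `pair` exceeds the first.
#'
#' @param maps Subject maps (all subjects; rows of `cohort`).
#' @param cohort Data frame with `group`, `age`, `sex`, `education`.
#' @param pair Character vector of two group labels, e.g. `c("HC", "aMCI")`.
#' @param mask Analysis mask (the significant ANCOVA cluster mask).
#' @param affine Voxel-to-mm affine.
#' @param cfg An [inference_config()].
#' @param seed Optional RNG seed.
#' @return List with `t_map`, `tfce_map`, `p_fwe` map, `sig_mask`, `labels`
#'   and `clusters`.
#' @export
posthoc_pairwise <- function(maps, cohort, pair, mask, affine,
                             cfg = inference_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(pair) == 2L)
  if (!any(mask)) stop("mask is empty")
  sel <- cohort$group %in% pair
  if (sum(cohort$group == pair[1]) < 2 || sum(cohort$group == pair[2]) < 2)
    stop("both groups need at least 2 subjects")
  Y <- stack_maps(maps, mask)[sel, , drop = FALSE]
  design <- design_matrix(cohort[sel, , drop = FALSE], groups = pair)
  design$coef_index <- 2L  # the group indicator column
  voxel_size <- sqrt(sum(affine[1:3, 1]^2))
  Tall <- freedman_lane(Y, design, cfg$n_perm, stat = "t")
  to_map <- function(vals, fill = 0) {
    m <- array(fill, dim(mask)); m[as.vector(mask)] <- vals; m
  }
  tf <- function(tvals) tfce_transform(to_map(tvals), cfg$tfce)
  tf_obs <- tf(Tall[1, ])
  max_null <- vapply(seq_len(nrow(Tall)), function(b) max(abs(tf(Tall[b, ]))),
                     numeric(1))
  p_fwe_vec <- vapply(abs(tf_obs[as.vector(mask)]), function(v)
    sum(max_null >= v) / length(max_null), numeric(1))
  sig <- array(FALSE, dim(mask))
  sig[as.vector(mask)] <- p_fwe_vec < cfg$posthoc_alpha
  lab <- label_clusters(sig, cfg$tfce$connectivity)
  sizes <- tabulate(lab[lab > 0])
  keep_ids <- which(sizes >= cfg$posthoc_min_voxels)
  final_lab <- array(0L, dim(mask))
  for (i in seq_along(keep_ids)) final_lab[lab == keep_ids[i]] <- i
  t_map <- to_map(Tall[1, ])
  p_map <- to_map(p_fwe_vec, fill = 1)
  list(t_map = t_map, tfce_map = tf_obs, p_fwe = p_map,
       sig_mask = final_lab > 0, labels = final_lab,
       clusters = cluster_table(final_lab, t_map, affine, voxel_size))
}

#' Pearson chi-squared test on a contingency table
#'
#' No continuity correction; df = (r - 1)(c - 1).
#'
#' @param tab 2D matrix of counts.
#' @return List with `statistic`, `df` and `p`.
#' @export
chisq_contingency <- function(tab) {
  tab <- as.matrix(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) stop("zero marginal")
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  if (any(ct$expected <= 0)) stop("expected counts must be positive")
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value))
}

#' One-way ANOVA from per-group summary statistics
#'
#' F = MSB/MSW computed from group sizes, means and standard deviations only —
#' the demographics-table situation where raw values are not available.
#'
#' @param n,mean,sd Numeric vectors, one entry per group (k >= 2, all n >= 2).
#' @return List with `F`, `df1`, `df2` and `p`.
#' @export
anova_from_summary <- function(n, mean, sd) {
  k <- length(n)
  stopifnot(k >= 2, length(mean) == k, length(sd) == k, all(n >= 2))
  N <- sum(n)
  grand <- sum(n * mean) / N
  ssb <- sum(n * (mean - grand)^2)
  ssw <- sum((n - 1) * sd^2)
  if (ssw == 0 && ssb == 0) stop("no variance within or between groups")
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  list(F = f, df1 = k - 1, df2 = N - k, p = pf(f, k - 1, N - k, lower.tail = FALSE))
}
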