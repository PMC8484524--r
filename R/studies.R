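#' Null calibration study of the permutation inference paths
#'
#' Empirical family-wise false-positive rate of the ANCOVA cluster-extent path
#' and of the post-hoc TFCE-FWE path under an exchangeable null: per repeat,
#' subject maps are spatially smoothed Gaussian noise with an age effect but
#' no group effect, and a detection is any retained cluster. Under a valid
#' procedure the rate stays at or below the nominal alpha up to binomial
#' noise.
#'
#' @param n_repeats Number of simulated datasets per path.
#' @param n_per_group Subjects per group (3 groups for the ANCOVA path; the
#'   post-hoc path uses the first two).
#' @param grid Grid dimensions for the noise maps.
#' @param n_perm Permutations per dataset.
#' @param fwhm Smoothing FWHM (mm) applied to the noise maps.
#' @param seed RNG seed.
#' @return List with `ancova_rate`, `posthoc_rate` and `n_repeats`.
#' @export
null_calibration_study <- function(n_repeats = 200, n_per_group = 6,
                                   grid = c(12, 12, 12), n_perm = 99,
                                   fwhm = 6, seed = 1L) {
  set.seed(seed)
  affine <- centered_affine(grid, 3)
  mm <- voxel_centers_mm(affine, grid)
  mask <- array(sqrt(rowSums(mm^2)) <= 12, grid)  # compact ball, ~ template size
  cfg <- inference_config(n_perm = n_perm, ancova_min_voxels = 1,
                          posthoc_min_voxels = 1)
  n3 <- 3 * n_per_group
  groups3 <- rep(c("HC", "SCD", "aMCI"), each = n_per_group)
  ancova_fp <- posthoc_fp <- logical(n_repeats)
  for (r in seq_len(n_repeats)) {
    cohort <- data.frame(group = groups3,
                         age = rnorm(n3, 64, 7), sex = rbinom(n3, 1, 0.5),
                         education = rnorm(n3, 12, 2.5))
    noise <- bold_image(array(rnorm(prod(grid) * n3), c(grid, n3)),
                        affine = affine, tr = 1)
    noise <- smooth_gaussian(noise, fwhm)
    maps <- lapply(seq_len(n3), function(i)
      noise$data[, , , i] + 0.02 * (cohort$age[i] - 64))
    dmx <- design_matrix(cohort)
    anc <- permutation_cluster_threshold(maps, dmx, mask, affine, cfg)
    ancova_fp[r] <- nrow(anc$clusters) > 0
    pair_rows <- cohort$group %in% c("HC", "SCD")
    ph <- posthoc_pairwise(maps[pair_rows], cohort[pair_rows, , drop = FALSE],
                           c("HC", "SCD"), mask, affine, cfg)
    posthoc_fp[r] <- nrow(ph$clusters) > 0
  }
  list(ancova_rate = mean(ancova_fp), posthoc_rate = mean(posthoc_fp),
       n_repeats = n_repeats)
}

#' Parameter-recovery study on scaled-down synthetic cohorts
#'
#' Repeated end-to-end runs of the scaled-down design measuring (i) whether
#' the injected ECN-target group difference (aMCI vs HC fluctuation amplitude)
#' is detected — a surviving post-hoc cluster overlapping the target region
#' with the correct sign — (ii) the covariate-adjusted correlation between
#' extracted target variability and the EM/EF composites in the patient
#' groups, and (iii) the in-sample multivariable AUC per group contrast.
#'
#' Scaled-down analysis settings: one network (ECN), template permutations
#' 100, inference permutations 99, cluster extents 5 (ANCOVA) and 3
#' (post-hoc) voxels in proportion to the miniature grid.
#'
#' @param n_repeats Number of simulated cohorts.
#' @param n_per_group Subjects per group.
#' @param seed RNG seed.
#' @return Data frame with one row per repeat: `detected`, `partial_r_EM`,
#'   `partial_r_EF`, and `auc_<contrast>` columns.
#' @export
recovery_study <- function(n_repeats = 20, n_per_group = 12, seed = 1L) {
  set.seed(seed)
  repeat_seeds <- sample.int(2^31 - 10L, n_repeats)
  cfg_inf <- inference_config(n_perm = 99, ancova_min_voxels = 5,
                              posthoc_min_voxels = 3)
  contrasts <- list(c("HC", "SCD"), c("HC", "aMCI"), c("SCD", "aMCI"))
  out <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    d <- small_cohort_design(n_per_group = c(HC = n_per_group, SCD = n_per_group,
                                             aMCI = n_per_group),
                             rng_seed = repeat_seeds[r])
    sim <- simulate_cohort(d, keep_data = TRUE)
    masks <- tissue_masks(d)
    pp <- lapply(sim$subjects, function(s)
      preprocess_bold(s$bold, s$motion, wm_mask = masks$wm, csf_mask = masks$csf))
    scheme <- make_windows(n_volumes(pp[[1]]))
    cohort <- sim$cohort
    hc <- which(cohort$group == "HC")
    seed_mask <- make_seed_mask(d$seeds$ECN, d$grid_shape, d$affine)
    target <- make_seed_mask(d$regions$ECN, d$grid_shape, d$affine)
    sn_target <- make_seed_mask(d$regions$SN, d$grid_shape, d$affine)

    zmaps <- lapply(hc, function(i)
      static_fc_zmap(pp[[i]], seed_timeseries(pp[[i]], seed_mask), mask = masks$gm))
    template <- one_sample_template(zmaps, mask = masks$gm, n_perm = 100,
                                    seed = repeat_seeds[r] + 1L)
    varmaps <- lapply(pp, function(img)
      variability_map(img, seed_mask, scheme, mask = masks$gm))
    dmx <- design_matrix(cohort)
    detected <- FALSE
    if (any(template)) {
      anc <- permutation_cluster_threshold(varmaps, dmx, template, d$affine,
                                           cfg_inf, seed = repeat_seeds[r] + 2L)
      if (any(anc$cluster_mask)) {
        ph <- posthoc_pairwise(varmaps, cohort, c("HC", "aMCI"),
                               anc$cluster_mask, d$affine, cfg_inf,
                               seed = repeat_seeds[r] + 3L)
        # correct sign: aMCI (coded 1) has the larger injected amplitude
        detected <- any(ph$labels > 0 & target & ph$t_map > 0)
      }
    }
    # behavior: extracted target variability vs composites in the patients
    extract <- vapply(varmaps, function(m) mean(m[target]), numeric(1))
    sn_varmaps <- lapply(pp, function(img)
      variability_map(img, make_seed_mask(d$seeds$SN, d$grid_shape, d$affine),
                      scheme, mask = masks$gm))
    sn_extract <- vapply(sn_varmaps, function(m) mean(m[sn_target]), numeric(1))
    composites <- composite_z(cohort, list(EM = "EM", EF = "EF",
                                           IPS = "IPS", VF = "VF"),
                              ref_rows = cohort$group == "HC")
    pat <- cohort$group %in% c("SCD", "aMCI")
    covs <- cbind(age = cohort$age, sex = cohort$sex, education = cohort$education)
    r_em <- partial_correlation(extract[pat], composites$EM[pat],
                                covs[pat, , drop = FALSE])$estimate
    r_ef <- partial_correlation(extract[pat], composites$EF[pat],
                                covs[pat, , drop = FALSE])$estimate
    # classification: region extracts + composites, backward elimination
    cls <- cbind(cohort["group"], composites, ecn_target = extract,
                 sn_target = sn_extract)
    aucs <- vapply(contrasts, function(pair) {
      cc <- classify_contrast(cls, pair,
                              c("EM", "EF", "IPS", "VF", "ecn_target", "sn_target"))
      cc$multivariable$roc$auc
    }, numeric(1))
    out[[r]] <- data.frame(detected = detected, partial_r_EM = r_em,
                           partial_r_EF = r_ef,
                           auc_HC_vs_SCD = aucs[1], auc_HC_vs_aMCI = aucs[2],
                           auc_SCD_vs_aMCI = aucs[3])
  }
  do.call(rbind, out)
}
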