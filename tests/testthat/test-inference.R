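test_that("TFCE matches the discrete brute-force definition", {
  # 1D worked example: centre voxel sums 1^0.5 * (1 + 4 + 9) * 1 = 14
  m <- c(0, 0, 3, 0, 0)
  tf <- tfce_transform(m, tfce_params(dh = 1))
  expect_equal(tf, c(0, 0, 14, 0, 0))
  expect_equal(tf, as.vector(tfce_brute(m, dh = 1)))
  # random tiny 3D maps, default dh rule, both connectivities
  set.seed(21)
  for (conn in c(6L, 26L)) {
    m3 <- array(round(runif(4 * 4 * 3, 0, 5), 2), c(4, 4, 3))
    p <- tfce_params(connectivity = conn)
    got <- tfce_transform(m3, p)
    want <- if (conn == 26L) tfce_brute(m3) else NULL
    if (conn == 26L) expect_equal(got, want, tolerance = 1e-10)
    # monotonicity: doubling strictly increases every positive value
    expect_true(all(tfce_transform(2 * m3, p)[m3 > 0] > got[m3 > 0]))
  }
  expect_true(all(tfce_transform(array(0, c(3, 3, 3))) == 0))
  # negative lobes: transform of the negated map, negated
  m <- array(rnorm(27), c(3, 3, 3))
  p <- tfce_params(dh = 0.1)
  expect_equal(tfce_transform(-m, p), -tfce_transform(m, p))
})

test_that("cluster labelling agrees with breadth-first search", {
  set.seed(22)
  mask <- array(runif(6 * 5 * 4) < 0.35, c(6, 5, 4))
  lab <- label_clusters(mask, 26)
  brute <- label_brute(mask)
  # same partition (labels may differ only by renaming)
  expect_equal(max(lab), max(brute))
  expect_true(all((lab > 0) == mask))
  for (id in seq_len(max(lab))) {
    members <- which(lab == id)
    expect_equal(length(unique(brute[members])), 1)
  }
})

test_that("voxelwise ANCOVA F equals the scalar regression oracle", {
  set.seed(23)
  n <- 30
  cohort <- data.frame(group = rep(c("HC", "SCD", "aMCI"), each = 10),
                       age = rnorm(n, 64, 7), sex = rbinom(n, 1, 0.5),
                       education = rnorm(n, 12, 3))
  Y <- matrix(rnorm(n * 5), n, 5)
  Y[cohort$group == "aMCI", 2] <- Y[cohort$group == "aMCI", 2] + 1
  dmx <- design_matrix(cohort)
  mask <- array(TRUE, c(5, 1, 1))
  fmap <- ancova_f_map(Y, dmx, mask)
  expect_equal(attr(fmap, "df"), c(2, n - 6))
  g <- factor(cohort$group, levels = c("HC", "SCD", "aMCI"))
  for (v in 1:5) {
    full <- lm(Y[, v] ~ g + age + sex + education, data = cohort)
    red <- lm(Y[, v] ~ age + sex + education, data = cohort)
    f_oracle <- anova(red, full)$F[2]
    expect_equal(as.vector(fmap)[v], f_oracle, tolerance = 1e-8)
  }
})

test_that("cluster extent thresholds follow the voxel and mm^3 rules", {
  set.seed(24)
  dims <- c(8, 8, 8)
  mask <- array(TRUE, dims)
  n <- 30
  cohort <- data.frame(group = rep(c("HC", "SCD", "aMCI"), each = 10),
                       age = rnorm(n, 64, 7), sex = rbinom(n, 1, 0.5),
                       education = rnorm(n, 12, 3))
  # strong group effect in a 9-voxel block (3 x 3 x 1)
  block <- array(FALSE, dims)
  block[3:5, 3:5, 3] <- TRUE
  maps <- lapply(seq_len(n), function(i) {
    m <- array(rnorm(prod(dims), sd = 0.1), dims)
    if (cohort$group[i] == "aMCI") m[block] <- m[block] + 3
    m
  })
  dmx <- design_matrix(cohort)
  aff <- tripledfc:::centered_affine(dims, 3)
  # low extent threshold: the block is recovered, mm^3 arithmetic exact
  res5 <- permutation_cluster_threshold(maps, dmx, mask, aff,
                                        inference_config(n_perm = 99,
                                                         ancova_min_voxels = 5),
                                        seed = 1)
  expect_gt(nrow(res5$clusters), 0)
  expect_true(any(res5$cluster_mask & block))
  expect_true(all(res5$clusters$n_voxels >= 5))
  expect_equal(res5$clusters$size_mm3, res5$clusters$n_voxels * 27)
  expect_true(all(res5$clusters$p_corrected >= 1 / 100))
  # extent boundary: a cluster one voxel short of the minimum is excluded
  # (same data and permutation seed, threshold raised just past the largest
  # observed cluster)
  smax <- max(res5$clusters$n_voxels)
  res_hi <- permutation_cluster_threshold(maps, dmx, mask, aff,
                                          inference_config(n_perm = 99,
                                                           ancova_min_voxels = smax + 1),
                                          seed = 1)
  expect_equal(nrow(res_hi$clusters), 0)
  expect_false(any(res_hi$cluster_mask))
})

test_that("post-hoc contrasts stay inside the mask and carry the right sign", {
  set.seed(25)
  dims <- c(8, 8, 8)
  n <- 24
  cohort <- data.frame(group = rep(c("HC", "aMCI"), each = 12),
                       age = rnorm(n, 64, 7), sex = rbinom(n, 1, 0.5),
                       education = rnorm(n, 12, 3))
  block <- array(FALSE, dims)
  block[5:7, 5:7, 5:6] <- TRUE
  mask <- array(FALSE, dims)
  mask[3:8, 3:8, 3:8] <- TRUE
  maps <- lapply(seq_len(n), function(i) {
    m <- array(rnorm(prod(dims), sd = 0.15), dims)
    if (cohort$group[i] == "aMCI") m[block] <- m[block] - 2  # aMCI < HC
    m
  })
  aff <- tripledfc:::centered_affine(dims, 3)
  cfg <- inference_config(n_perm = 99, posthoc_min_voxels = 3)
  ph <- posthoc_pairwise(maps, cohort, c("HC", "aMCI"), mask, aff, cfg, seed = 2)
  expect_gt(nrow(ph$clusters), 0)
  # never reports voxels outside the analysis mask
  expect_false(any(ph$labels > 0 & !mask))
  # decreased variability in aMCI: negative t at the detected peak
  expect_true(any(ph$labels > 0 & block))
  expect_lt(ph$clusters$peak_stat[which.max(ph$clusters$n_voxels)], 0)
  expect_equal(ph$clusters$size_mm3, ph$clusters$n_voxels * 27)
  # a surviving 10-voxel cluster passes the "> 9 voxels" rule at 270 mm^3
  expect_true(all(ph$clusters$n_voxels[ph$clusters$n_voxels == 10] * 27 == 270))
})

test_that("demographic statistics reproduce the printed cohort table", {
  sex <- rbind(male = c(25, 8, 13), female = c(33, 36, 36))
  cs <- chisq_contingency(sex)
  expect_equal(cs$statistic, 7.865, tolerance = 1e-3)
  expect_equal(cs$df, 2)
  # proportional rows carry no association
  prop <- rbind(c(10, 20, 30), c(20, 40, 60))
  expect_equal(chisq_contingency(prop)$statistic, 0, tolerance = 1e-12)
  # random table matches the sum((O-E)^2/E) definition
  set.seed(26)
  tab <- matrix(rpois(6, 30) + 1, 2, 3)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(chisq_contingency(tab)$statistic, sum((tab - E)^2 / E),
               tolerance = 1e-10)
  expect_error(chisq_contingency(rbind(c(0, 0, 0), c(1, 2, 3))), "marginal")
})

test_that("ANOVA from summary statistics matches the printed age row and t^2", {
  res <- anova_from_summary(n = c(58, 44, 49),
                            mean = c(63.328, 66.000, 63.633),
                            sd = c(6.28, 7.80, 7.58))
  expect_equal(res$F, 1.966, tolerance = 0.005)
  expect_identical(c(res$df1, res$df2), c(2, 148))
  expect_equal(anova_from_summary(c(10, 12), c(5, 5), c(1, 2))$F, 0)
  # two groups: F equals the squared pooled-variance t statistic
  set.seed(27)
  x <- rnorm(15, 1)
  y <- rnorm(20, 1.6)
  tt <- stats::t.test(x, y, var.equal = TRUE)
  res2 <- anova_from_summary(c(15, 20), c(mean(x), mean(y)), c(sd(x), sd(y)))
  expect_equal(res2$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res2$p, tt$p.value, tolerance = 1e-10)
})
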