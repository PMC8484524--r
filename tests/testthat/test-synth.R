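test_that("default design encodes the cohort and acquisition conditions", {
  d <- cohort_design()
  expect_identical(unname(d$group_sizes), c(58, 44, 49))
  expect_equal(sum(d$group_sizes), 151)
  expect_equal(d$n_volumes * d$tr, 480)  # 8-minute runs
  expect_equal(d$voxel_size_mm, 3)
  expect_equal(d$seeds$aDMN$center, c(0, 52, -6))
  expect_equal(d$seeds$pDMN$center, c(0, -53, 26))
  expect_equal(d$seeds$SN$center, c(38, 22, -10))
  expect_equal(d$seeds$ECN$center, c(48, 12, 34))
  expect_true(all(vapply(d$seeds, function(s) s$radius_mm, numeric(1)) == 10))
})

test_that("design validation rejects infeasible or malformed inputs", {
  expect_error(small_cohort_design(n_per_group = c(HC = 0, SCD = 2, aMCI = 2)),
               "positive")
  expect_error(small_cohort_design(n_volumes = 45), "window")
  expect_error(simulate_subject(small_cohort_design(), "patient", 1), "group")
})

test_that("subject simulation is a pure function of its seed", {
  d <- small_cohort_design(n_volumes = 60)
  a <- simulate_subject(d, "aMCI", 77)
  b <- simulate_subject(d, "aMCI", 77)
  expect_identical(a$bold$data, b$bold$data)
  expect_identical(a$motion, b$motion)
  expect_identical(a$truth$amplitude, b$truth$amplitude)
  c <- simulate_subject(d, "aMCI", 78)
  expect_false(identical(a$bold$data, c$bold$data))
  expect_equal(dim(a$bold$data)[4], 60)
  expect_equal(dim(a$motion), c(60L, 6L))
})

test_that("zero fluctuation amplitude yields constant latent coupling", {
  d <- small_cohort_design(n_volumes = 60)
  d$effect_table$amplitude <- 0
  sub <- simulate_subject(d, "HC", 5)
  expect_true(all(apply(sub$truth$coupling, 1, sd) == 0))
  expect_identical(unname(sub$truth$amplitude), rep(0, 4))
})

test_that("windowed-coupling variability increases with injected amplitude", {
  # ground-truth monotonicity: expected windowed-z sd in the target region
  # grows strictly with the fluctuation amplitude A
  amps <- c(0, 0.3, 0.6)
  mean_var <- vapply(amps, function(A) {
    d <- small_cohort_design(n_per_group = c(HC = 1, SCD = 1, aMCI = 1))
    d$effect_table$amplitude <- A
    tgt <- make_seed_mask(d$regions$ECN, d$grid_shape, d$affine)
    scheme <- make_windows(d$n_volumes, 40, 2)
    vals <- vapply(1:6, function(s) {
      sub <- simulate_subject(d, "HC", 1000 + s)
      vm <- variability_map(sub$bold, d$seeds$ECN, scheme)
      mean(vm[tgt])
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(mean_var) > 0))
})

test_that("cohort generation writes the documented dataset layout", {
  d <- small_cohort_design(n_per_group = c(HC = 2, SCD = 2, aMCI = 2),
                           n_volumes = 60, rng_seed = 9L)
  out <- file.path(tempdir(), "synthds")
  sim <- simulate_cohort(d, out_dir = out, keep_data = FALSE)
  expect_identical(as.vector(table(sim$cohort$group)[c("HC", "SCD", "aMCI")]),
                   c(2L, 2L, 2L))
  tsv <- read.table(file.path(out, "cohort.tsv"), header = TRUE, sep = "\t")
  expect_identical(names(tsv), c("subject_id", "group", "age", "sex",
                                 "education", "EM", "EF", "IPS", "VF"))
  expect_equal(nrow(tsv), 6)
  expect_true(file.exists(file.path(out, "ground_truth.json")))
  expect_true(file.exists(file.path(out, "sub-001_bold.nii.gz")))
  expect_true(file.exists(file.path(out, "sub-001_motion.txt")))
  # round-trip: image and motion readable and consistent
  img <- read_bold(file.path(out, "sub-001_bold.nii.gz"))
  expect_equal(dim(img$data), c(12, 12, 12, 60))
  expect_equal(img$tr, 2)
  expect_equal(dim(read_motion(file.path(out, "sub-001_motion.txt"))), c(60L, 6L))
  # determinism: the whole cohort is a pure function of (design, rng_seed)
  sim2 <- simulate_cohort(d, keep_data = FALSE)
  expect_equal(sim$cohort, sim2$cohort)
  unlink(out, recursive = TRUE)
})

test_that("cognitive scores track the injected amplitude with the set sign", {
  # negative coefficient on the ECN-target amplitude -> negative sample
  # correlation, with magnitude growing in |k|
  cors <- vapply(c(0.5, 3), function(k) {
    d <- small_cohort_design(n_per_group = c(HC = 10, SCD = 10, aMCI = 10),
                             n_volumes = 60, rng_seed = 21L)
    d$cog_coef <- c(EM = -k, EF = -k, IPS = 0, VF = 0)
    sim <- simulate_cohort(d, keep_data = FALSE)
    A <- vapply(sim$truth, function(tt) tt$amplitude[["ECN"]], numeric(1))
    cor(A, sim$cohort$EM)
  }, numeric(1))
  expect_true(all(cors < 0))
  expect_gt(abs(cors[2]), abs(cors[1]))
})
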