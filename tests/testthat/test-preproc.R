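test_that("initial-volume discard keeps metadata and errors on empty output", {
  img <- toy_bold(c(4, 4, 4), T = 240)
  out <- discard_initial_volumes(img, 10)
  expect_equal(dim(out$data)[4], 230)
  expect_identical(out$affine, img$affine)
  expect_identical(out$tr, img$tr)
  expect_identical(discard_initial_volumes(img, 0), img)
  tiny <- toy_bold(c(2, 2, 2), T = 5)
  expect_error(discard_initial_volumes(tiny, 5))
})

test_that("motion exclusion follows the cumulative 3 mm / 3 degree rule", {
  zero <- matrix(0, 50, 6)
  expect_false(exclude_by_motion(zero))
  one_axis <- zero
  one_axis[, 2] <- seq(0, 3.5, length.out = 50)
  expect_true(exclude_by_motion(one_axis))
  # at most 2.9 mm and 2.9 degrees relative to the first volume: retained,
  # even when the absolute position starts away from zero
  set.seed(2)
  near <- matrix(rnorm(50 * 6, sd = 0.3), 50, 6)
  near <- sweep(near, 2, near[1, ])          # displacement from first volume
  near <- near / max(abs(near)) * 2.9
  near[, 1] <- near[, 1] + 1.5               # shifted starting position
  expect_false(exclude_by_motion(near))
  rot <- zero
  rot[, 5] <- c(rep(0, 25), rep(3.01, 25))
  expect_true(exclude_by_motion(rot))
})

test_that("Friston-24 expansion matches its per-element definition", {
  zero <- matrix(0, 10, 6)
  expect_true(all(friston24(zero) == 0))
  ramp <- matrix(0, 10, 6)
  ramp[, 3] <- 1:10
  f <- friston24(ramp)
  expect_equal(unname(f[, "p3_sq"]), (1:10)^2)
  expect_equal(unname(f[, "p3_lag"]), c(0, 1:9))
  # brute-force oracle on a random trace
  set.seed(4)
  m <- matrix(rnorm(20 * 6), 20, 6)
  f <- friston24(m)
  expect_equal(ncol(f), 24)
  for (j in 1:6) {
    lag <- c(0, m[-20, j])
    expect_equal(unname(f[, j]), m[, j])
    expect_equal(unname(f[, 6 + j]), lag)
    expect_equal(unname(f[, 12 + j]), m[, j]^2)
    expect_equal(unname(f[, 18 + j]), lag^2)
  }
})

test_that("nuisance regression produces residuals orthogonal to regressors", {
  set.seed(7)
  nuis <- matrix(rnorm(60 * 4), 60, 4)
  # series equal to a regressor vanishes
  expect_lt(max(abs(regress_nuisance(nuis[, 2], nuis))), 1e-10)
  # random case matches the normal-equations oracle
  ts <- matrix(rnorm(60 * 5), 60, 5)
  res <- regress_nuisance(ts, nuis)
  X <- cbind(1, nuis)
  oracle <- ts - X %*% solve(crossprod(X), crossprod(X, ts))
  expect_lt(max(abs(res - oracle)), 1e-8)
  expect_lt(max(abs(crossprod(cbind(1, nuis), res))), 1e-8)
  # collinear columns are dropped with a warning, fit unchanged
  expect_warning(res2 <- regress_nuisance(ts, cbind(nuis, nuis[, 1])),
                 "collinear")
  expect_lt(max(abs(res2 - res)), 1e-8)
})

test_that("linear detrend removes exactly the best-fit line", {
  t <- 1:50
  expect_lt(max(abs(detrend_linear(3 + 0.25 * t))), 1e-10)
  set.seed(8)
  x <- rnorm(50)
  d1 <- detrend_linear(x)
  expect_lt(max(abs(detrend_linear(d1) - d1)), 1e-10)
  expect_equal(d1, unname(stats::residuals(stats::lm(x ~ t))), tolerance = 1e-10)
  expect_lt(abs(sum(d1)), 1e-10)
  expect_lt(abs(sum(d1 * t)), 1e-8)
})

test_that("ideal band-pass keeps the passband and kills the stopband", {
  tr <- 2
  T <- 200
  t <- (0:(T - 1)) * tr
  power <- function(x) sum(x^2)
  stop_sig <- sin(2 * pi * 0.2 * t)           # 0.2 Hz, above the band
  expect_lt(power(bandpass(stop_sig, tr)) / power(stop_sig), 0.01)
  pass_sig <- sin(2 * pi * 0.05 * t)          # 0.05 Hz, inside the band
  expect_equal(power(bandpass(pass_sig, tr)) / power(pass_sig), 1,
               tolerance = 0.01)
  expect_lt(max(abs(bandpass(rep(5, T), tr))), 1e-12)
  expect_error(bandpass(rnorm(T), tr, low = 0.1, high = 0.3), "Nyquist")
})

test_that("Gaussian smoothing has the nominal FWHM and conserves intensity", {
  img <- toy_bold(c(11, 11, 11), T = 2)
  expect_identical(smooth_gaussian(img, 0), img)
  # constant volume unchanged away from the boundary
  img$data[] <- 4
  sm <- smooth_gaussian(img, 6)
  expect_equal(sm$data[5:7, 5:7, 5:7, 1], img$data[5:7, 5:7, 5:7, 1],
               tolerance = 1e-12)
  # unit impulse: half-maximum at 3 mm (= FWHM/2 = 1 voxel on this grid),
  # and total intensity conserved
  img$data[] <- 0
  img$data[6, 6, 6, 1] <- 1
  sm <- smooth_gaussian(img, 6)
  peak <- sm$data[6, 6, 6, 1]
  expect_equal(sm$data[7, 6, 6, 1] / peak, 0.5, tolerance = 0.02)
  expect_equal(sum(sm$data[, , , 1]), 1, tolerance = 1e-6)
})

test_that("temporal operators are linear", {
  set.seed(10)
  x <- rnorm(80)
  y <- rnorm(80)
  a <- 2.5
  b <- -1.25
  for (op in list(detrend_linear, function(v) bandpass(v, 2))) {
    expect_equal(op(a * x + b * y), a * op(x) + b * op(y), tolerance = 1e-8)
  }
  nuis <- matrix(rnorm(80 * 3), 80, 3)
  expect_equal(regress_nuisance(a * x + b * y, nuis),
               a * regress_nuisance(x, nuis) + b * regress_nuisance(y, nuis),
               tolerance = 1e-8)
})

test_that("the preprocessing pipeline applies the fixed stage order", {
  d <- small_cohort_design(n_volumes = 60)
  sub <- simulate_subject(d, "HC", 3)
  masks <- tissue_masks(d)
  pp <- preprocess_bold(sub$bold, sub$motion, discard = 10,
                        wm_mask = masks$wm, csf_mask = masks$csf)
  prov <- attr(pp, "provenance")
  expect_identical(prov$steps, c("discard", "detrend", "nuisance_regression",
                                 "bandpass", "smooth"))
  expect_equal(prov$n_nuisance, 27)  # Friston-24 + global + WM + CSF
  expect_equal(dim(pp$data)[4], 50)
})
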