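test_that("logistic fits recover generating coefficients and flag separation", {
  set.seed(41)
  # uninformative constant predictor: coefficient 0, intercept = logit prevalence
  y <- rbinom(100, 1, 0.3)
  fit <- fit_logistic(matrix(1, 100, 1), y)
  expect_equal(unname(fit$coefficients[2]), 0)
  expect_equal(unname(fit$coefficients[1]), stats::qlogis(mean(y)),
               tolerance = 1e-6)
  # parameter recovery at n = 2000 within 2 SE
  n <- 2000
  X <- cbind(a = rnorm(n), b = rnorm(n))
  beta <- c(-0.5, 1.2, -0.8)
  p <- stats::plogis(beta[1] + X %*% beta[2:3])
  y <- rbinom(n, 1, p)
  fit <- fit_logistic(X, y)
  se <- sqrt(diag(stats::vcov(stats::glm(y ~ X, family = binomial()))))
  expect_true(all(abs(fit$coefficients - beta) < 2 * se))
  expect_true(fit$converged)
  expect_false(fit$separation)
  # log-likelihood matches a brute-force optimiser on a 20-row fixture
  set.seed(42)
  X20 <- matrix(rnorm(20), 20, 1)
  y20 <- rbinom(20, 1, stats::plogis(0.5 + X20[, 1]))
  fit20 <- fit_logistic(X20, y20)
  nll <- function(b) -sum(stats::dbinom(y20, 1, stats::plogis(b[1] + b[2] * X20[, 1]),
                                        log = TRUE))
  opt <- stats::optim(c(0, 0), nll, method = "BFGS")
  expect_equal(fit20$loglik, -opt$value, tolerance = 1e-5)
  # complete separation is detected, not silently diverged
  ys <- rep(0:1, each = 10)
  Xs <- matrix(c(rnorm(10, -3), rnorm(10, 3)), 20, 1)
  expect_true(fit_logistic(Xs, ys)$separation)
  expect_error(fit_logistic(X20, rep(1, 20)), "both classes")
})

test_that("likelihood-ratio backward elimination keeps signal, drops noise", {
  set.seed(43)
  n <- 400
  signal <- rnorm(n)
  noise <- matrix(rnorm(n * 3), n, 3,
                  dimnames = list(NULL, c("n1", "n2", "n3")))
  y <- rbinom(n, 1, stats::plogis(2 * signal))
  X <- cbind(signal = signal, noise)
  bw <- backward_eliminate(X, y)
  expect_true("signal" %in% bw$retained)
  # the LR statistic is definitional: 2 * (llh_full - llh_reduced)
  full <- fit_logistic(X, y)
  red <- fit_logistic(X[, -1, drop = FALSE], y)
  lr <- lr_test(full, red, df = 1)
  expect_equal(lr$statistic, 2 * (full$loglik - red$loglik))
  expect_equal(lr$p, stats::pchisq(lr$statistic, 1, lower.tail = FALSE))
  # pure-noise candidates are all eliminated in most repeats
  all_gone <- vapply(1:20, function(i) {
    Xn <- matrix(rnorm(500 * 3), 500, 3)
    yn <- rbinom(500, 1, 0.5)
    length(backward_eliminate(Xn, yn)$retained) == 0
  }, logical(1))
  expect_gte(sum(all_gone), 15)
})

test_that("ROC summary equals the rank-sum oracle and picks the Youden point", {
  # perfectly ranked scores
  y <- rep(c(0, 1), each = 6)
  perfect <- roc_summary(seq_len(12), y)
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  # 12-point fixture with ties: AUC = Mann-Whitney U / (n1 * n0)
  set.seed(44)
  scores <- c(1, 3, 3, 2, 5, 4, 4, 6, 2, 7, 5, 8)
  y <- c(0, 0, 1, 0, 1, 0, 1, 1, 0, 1, 0, 1)
  rs <- roc_summary(scores, y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  U <- sum(rank(scores)[y == 1]) - n1 * (n1 + 1) / 2
  expect_equal(rs$auc, U / (n1 * n0), tolerance = 1e-12)
  # operating point maximises Youden's J
  expect_equal(rs$youden_j, max(rs$roc$sensitivity + rs$roc$specificity - 1))
  # invariance under strictly increasing transforms
  rs2 <- roc_summary(exp(scores / 2), y)
  expect_equal(rs2$auc, rs$auc)
  expect_equal(rs2$sensitivity, rs$sensitivity)
  # uninformative scores: AUC near 1/2
  yy <- rbinom(1000, 1, 0.5)
  ss <- rnorm(1000)
  n1 <- sum(yy); n0 <- 1000 - n1
  se <- sqrt((n1 + n0 + 1) / (12 * n1 * n0))
  expect_lt(abs(roc_summary(ss, yy)$auc - 0.5), 3 * se)
})

test_that("ROC summary agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(45)
  scores <- rnorm(80)
  y <- rbinom(80, 1, stats::plogis(scores))
  rs <- roc_summary(scores, y)
  ref <- pROC::roc(y, scores, quiet = TRUE, direction = "<")
  expect_equal(rs$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-10)
})

test_that("the multivariable model dominates its retained univariate models", {
  set.seed(46)
  n <- 120
  d <- data.frame(group = rep(c("HC", "aMCI"), each = n / 2),
                  p1 = rnorm(n), p2 = rnorm(n), p3 = rnorm(n))
  d$p1 <- d$p1 + 1.2 * (d$group == "aMCI")
  d$p2 <- d$p2 - 0.9 * (d$group == "aMCI")
  res <- classify_contrast(d, c("HC", "aMCI"), c("p1", "p2", "p3"))
  multi_auc <- res$multivariable$roc$auc
  for (p in res$multivariable$retained) {
    expect_gte(multi_auc, res$univariate[[p]]$roc$auc - 1e-12)
  }
  expect_true(all(c("p1", "p2") %in% res$multivariable$retained))
})
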