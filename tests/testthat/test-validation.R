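test_that("error metrics match definitions and a brute-force oracle", {
  y <- c(10, 20, 30)
  m <- error_metrics(y, y)
  expect_equal(m$rmse, 0); expect_equal(m$mean_recovery, 100)
  expect_equal(m$slope, 1); expect_equal(m$intercept, 0); expect_equal(m$r, 1)
  m2 <- error_metrics(y, y + 1)
  expect_equal(m2$rmse, 1); expect_equal(m2$slope, 1); expect_equal(m2$intercept, 1)
  set.seed(14)
  a <- runif(20, 5, 50); p <- a + rnorm(20)
  m3 <- error_metrics(a, p)
  expect_equal(m3$rmse, sqrt(sum((p - a)^2) / 20), tolerance = 1e-12)
  expect_equal(m3$r, sum((a - mean(a)) * (p - mean(p))) /
                 sqrt(sum((a - mean(a))^2) * sum((p - mean(p))^2)),
               tolerance = 1e-12)
  expect_equal(m3$r2, m3$r^2)
  rec <- 100 * p / a
  expect_equal(m3$rsd_percent, 100 * sd(rec) / mean(rec), tolerance = 1e-12)
  expect_error(error_metrics(c(0, 1), c(1, 1)), "zero")
})

test_that("rmse_reduction reproduces the headline arithmetic", {
  expect_equal(round(rmse_reduction(0.3913, 0.0317), 1), 91.9)
  expect_equal(round(rmse_reduction(0.4068, 0.0949), 1), 76.7)
  expect_equal(round(rmse_reduction(0.3913, 0.3287), 1), 16.0)
  expect_equal(round(rmse_reduction(0.4068, 0.1996), 1), 50.9)
  expect_equal(rmse_reduction(0.5, 0.5), 0)
  expect_error(rmse_reduction(0, 1), "base")
})

test_that("pooled t and variance-ratio F match summary-statistic formulas", {
  tt <- pooled_t_test(95.99, 1.913, 5, 98.34, 1.354, 5)
  expect_equal(round(tt$t, 3), 2.242)
  expect_equal(tt$df, 8)
  expect_equal(round(tt$critical, 3), 2.306)
  expect_equal(pooled_t_test(10, 1, 5, 10, 2, 5)$t, 0)
  # symmetry
  t1 <- pooled_t_test(99.42, 1.410, 5, 98.02, 1.520, 5)
  t2 <- pooled_t_test(98.02, 1.520, 5, 99.42, 1.410, 5)
  expect_equal(t1$t, t2$t)
  expect_error(pooled_t_test(1, 0, 5, 1, 0, 5), "zero")
  ff <- variance_ratio_f(1.913, 5, 1.354, 5)
  expect_equal(round(ff$f, 3), 1.996)
  expect_equal(round(ff$critical, 2), 6.39)
  expect_equal(variance_ratio_f(2, 5, 2, 5)$f, 1)
  expect_equal(variance_ratio_f(1.5, 5, 3, 7)$f *
                 variance_ratio_f(3, 7, 1.5, 5)$f, 1)
})

test_that("friedman test matches hand computation and the stats oracle", {
  # 2 blocks x 3 treatments, identical orderings: chisq = 4
  m <- matrix(c(1, 2, 3,
                4, 5, 6), 2, 3, byrow = TRUE)
  expect_equal(friedman_test(m)$chisq, 4)
  expect_equal(friedman_test(m)$df, 2)
  # all equal: chisq = 0 (with a tie warning)
  expect_warning(r0 <- friedman_test(matrix(1, 3, 3)), "tied")
  expect_equal(r0$chisq, 0)
  # random matrices against stats::friedman.test
  set.seed(15)
  for (i in 1:20) {
    b <- sample(4:12, 1); k <- sample(3:5, 1)
    x <- matrix(rnorm(b * k), b, k)
    ours <- friedman_test(x)
    ref <- stats::friedman.test(x)
    expect_equal(ours$chisq, unname(ref$statistic), tolerance = 1e-8)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-8)
  }
  expect_error(friedman_test(matrix(1, 1, 3)), "at least 2")
})

test_that("nested CV pools outer predictions without leakage", {
  factory <- function(X, Y) {
    k <- select_lv_loocv(X, Y, min(3, nrow(X) - 2L), rule = "min")$n_lv
    fit_pls(X, Y, k)
  }
  # zero-noise linear data: pooled RMSECV and CI collapse
  fx <- calibration_fixture()
  s <- fx$spectra
  r0 <- nested_cv(s$absorbance, s$concentrations, factory, n_boot = 200, seed = 16)
  expect_lt(r0$pooled_rmsecv, 1e-6)
  expect_lt(diff(r0$ci), 1e-6)
  # recorded fold rows are disjoint and cover everything
  for (f in r0$fold_rows) {
    expect_length(intersect(f$train, f$test), 0)
    expect_setequal(c(f$train, f$test), seq_len(nrow(s$absorbance)))
  }
  # bootstrap CI from constant residuals has zero width
  # (constant-prediction factory on constant-ish response)
  const_factory <- function(X, Y) {
    structure(list(mean = colMeans(Y)), class = "const_model")
  }
  assign("predict.const_model",
         function(object, newdata, ...)
           matrix(object$mean, nrow(newdata), length(object$mean), byrow = TRUE),
         envir = globalenv())
  on.exit(rm("predict.const_model", envir = globalenv()), add = TRUE)
  Yc <- matrix(rep(c(1, 2), each = 10), 20, 1)
  Xc <- matrix(rnorm(40), 20, 2)
  rc <- nested_cv(Xc, 0 * Yc + 5, const_factory, n_boot = 50, seed = 17)
  expect_equal(diff(rc$ci), 0)
})

test_that("leakage sentinel: clean nested CV ignores test-row coincidences", {
  set.seed(18)
  n <- 40; p <- 30
  y <- rnorm(n)
  X <- matrix(rnorm(n * p), n, p)  # pure noise predictors
  # factory picks the single column most correlated with its TRAINING data
  pick_factory <- function(Xtr, Ytr) {
    cors <- abs(apply(Xtr, 2, cor, y = Ytr[, 1]))
    j <- which.max(cors)
    b <- coef(lm(Ytr[, 1] ~ Xtr[, j]))
    structure(list(j = j, b = b), class = "pick_model")
  }
  assign("predict.pick_model",
         function(object, newdata, ...)
           matrix(object$b[1] + object$b[2] * newdata[, object$j], ncol = 1),
         envir = globalenv())
  on.exit(rm("predict.pick_model", envir = globalenv()), add = TRUE)
  clean <- nested_cv(X, matrix(y), pick_factory, n_boot = 50, seed = 19)
  # deliberately leaky variant: per fold, choose the column most correlated
  # with the TEST rows, then refit on training rows
  folds <- clean$folds
  leaky_res <- numeric(0)
  for (f in sort(unique(folds))) {
    te <- which(folds == f); tr <- which(folds != f)
    j <- which.max(abs(apply(X[te, , drop = FALSE], 2, cor, y = y[te])))
    b <- coef(lm(y[tr] ~ X[tr, j]))
    leaky_res <- c(leaky_res, y[te] - (b[1] + b[2] * X[te, j]))
  }
  leaky_rmse <- sqrt(mean(leaky_res^2))
  # clean outer RMSE stays near sd(y) (within 2x), leaky collapses below it
  expect_lt(clean$pooled_rmsecv, 2 * sd(y))
  expect_gt(clean$pooled_rmsecv, 0.8 * sd(y))
  expect_lt(leaky_rmse, clean$pooled_rmsecv)
})

test_that("bootstrap CI covers the true RMSE on Gaussian residuals", {
  # 200 seeded replicates; CI target 95%, assert coverage >= 90%
  factory <- function(X, Y) structure(list(), class = "zero_model")
  assign("predict.zero_model",
         function(object, newdata, ...) matrix(0, nrow(newdata), 1),
         envir = globalenv())
  on.exit(rm("predict.zero_model", envir = globalenv()), add = TRUE)
  hit <- 0
  for (rep in 1:200) {
    set.seed(rep + 300)
    y <- matrix(rnorm(40), 40, 1)  # true RMSE of the zero predictor = 1
    X <- matrix(rnorm(40), 40, 1)
    r <- nested_cv(X, y, factory, outer_folds = 5, n_boot = 200, seed = rep)
    if (r$ci[1] <= 1 && 1 <= r$ci[2]) hit <- hit + 1
  }
  expect_gte(hit / 200, 0.9)
})

test_that("y-randomization detects genuine structure", {
  fx <- calibration_fixture(noise = noise_model(seed = 20))
  s <- fx$spectra
  factory <- function(X, y) fit_pls(X, y, 3)
  r <- y_randomization(s$absorbance, s$concentrations[, 1], factory,
                       n_permutations = 20, seed = 21)
  expect_gt(r$original_r, 0.99)
  expect_lt(r$mean_permuted_r, 0.5)
  expect_true(r$verdict)
  expect_error(y_randomization(s$absorbance, rep(1, 25), factory, seed = 1),
               "constant")
  expect_error(y_randomization(s$absorbance, s$concentrations[, 1], factory,
                               n_permutations = 5), "n_permutations")
})

test_that("applicability domain flags constructed outliers only", {
  fx <- calibration_fixture(noise = noise_model(seed = 22))
  s <- fx$spectra
  m <- fit_pls(s$absorbance, s$concentrations, 3)
  res <- s$concentrations[, 1] - m$fitted[, 1]
  ad <- applicability_domain(m, res)
  # hat-trace identity: leverages sum to p + 1
  expect_equal(sum(ad$leverage), 3 + 1, tolerance = 1e-8)
  expect_true(all(ad$in_domain))
  # far-outside spectrum has leverage above the critical limit
  far <- matrix(m$x_means + 50 * apply(s$absorbance, 2, sd), 1)
  lev_far <- prediction_leverage(m, far)
  expect_gt(lev_far, attr(ad, "h_star"))
  # equal residuals: standardized residuals are not flaggable
  expect_error(applicability_domain(matrix(0, 5, 2), rep(1, 5)), "singular")
  ad2 <- applicability_domain(m$scores, rep(2, nrow(s$absorbance)))
  expect_true(all(abs(ad2$std_residual) < 3))
})
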