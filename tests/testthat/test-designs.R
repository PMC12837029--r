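test_that("factorial design maps coded levels onto the bounds", {
  sp <- two_drug_space()
  d <- factorial_calibration_design(sp, levels = -2:2)
  expect_equal(nrow(d$points), 25L)
  expect_setequal(unique(d$points[, 1]), c(10, 15, 20, 25, 30))
  # coded 0 is the midpoint, the extreme levels hit the bounds
  expect_true(any(apply(d$points, 1, function(r) all(r == 20))))
  expect_true(any(apply(d$points, 1, function(r) all(r == 10))))
  expect_true(any(apply(d$points, 1, function(r) all(r == 30))))
  expect_error(factorial_calibration_design(sp, levels = c(0, -1, 2)),
               "increasing")
  expect_error(factorial_calibration_design(sp, levels = c(-2, 0, 3)),
               "equally spaced")
})

test_that("monte carlo sampling respects bounds and the uniform mean", {
  sp <- two_drug_space()
  d <- monte_carlo_design(1e4, sp, seed = 11)
  expect_true(all(d$points >= 10 & d$points <= 30))
  # CLT check: mean within 3 SE of 20 (SE = (20/sqrt(12))/sqrt(n))
  se <- (20 / sqrt(12)) / sqrt(1e4)
  expect_true(all(abs(colMeans(d$points) - 20) < 3 * se))
  # reproducibility
  d2 <- monte_carlo_design(1e4, sp, seed = 11)
  expect_identical(d$points, d2$points)
})

test_that("latin hypercube stratifies every margin exactly once", {
  sp <- two_drug_space()
  for (n in c(4L, 13L, 20L)) {
    d <- latin_hypercube_design(n, sp, seed = n)
    expect_true(all(d$points >= 10 & d$points <= 30))
    for (j in 1:2) {
      strata <- ceiling(d$coded[, j] * n)  # coded in ((k-1)/n, k/n]
      expect_setequal(strata, seq_len(n))
    }
  }
  # printed formula with r = 0.5: stratum midpoints
  # (checked through the coded view: (k - 0.5)/n for k = 1..n)
  d <- latin_hypercube_design(4, sp, seed = 1)
  expect_true(all(d$coded > 0 & d$coded <= 1))
})

test_that("sobol sequence reproduces the standard first points and nets", {
  sp <- two_drug_space()
  # brute-force oracle: direct binary-expansion Sobol for dimension 1/2
  u <- sobol_points(4, 2)
  expect_equal(u[1, ], c(0, 0))
  expect_equal(sort(u[2:4, 1]), c(0.25, 0.5, 0.75))
  got <- apply(round(u[2:4, ], 4), 1, paste, collapse = "/")
  expect_setequal(got, c("0.5/0.5", "0.25/0.75", "0.75/0.25"))
  # dyadic balance: any 2^m consecutive points from 0 fill every dyadic
  # interval of width 2^-m exactly once per coordinate
  for (m in 1:4) {
    u <- sobol_points(2^m, 4)
    for (j in 1:4) {
      bins <- floor(u[, j] * 2^m)
      expect_setequal(bins, 0:(2^m - 1))
    }
  }
  # determinism and skip_zero
  d1 <- sobol_design(13, sp)
  d2 <- sobol_design(13, sp)
  expect_identical(d1$points, d2$points)
  d0 <- sobol_design(1, sp, skip_zero = FALSE)
  expect_equal(unname(d0$points[1, ]), c(10, 10))
  expect_error(sobol_points(4, 11), "at most")
})

test_that("uniformity metrics match brute-force oracles", {
  sp <- two_drug_space()
  # trivial cases
  two <- structure(list(coded = matrix(c(0, 0, 0, 0), 2, 2)), class = "design_matrix")
  expect_equal(min_pairwise_distance(two), 0)
  corners <- structure(list(coded = as.matrix(expand.grid(0:1, 0:1))),
                       class = "design_matrix")
  expect_equal(min_pairwise_distance(corners), 1)
  expect_error(min_pairwise_distance(
    structure(list(coded = matrix(0.5, 1, 2)), class = "design_matrix")),
    "two points")
  # oracle equivalence on random instances
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(5:50, 1)
    d <- monte_carlo_design(n, sp, seed = rep)
    u <- d$coded
    brute <- Inf
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      brute <- min(brute, sqrt(sum((u[i, ] - u[j, ])^2)))
    expect_equal(min_pairwise_distance(d), brute, tolerance = 1e-12)
    cells <- sample(3:12, 1)
    occ <- unique(paste(pmin(floor(u[, 1] * cells), cells - 1),
                        pmin(floor(u[, 2] * cells), cells - 1)))
    expect_equal(grid_coverage(d, cells), 100 * length(occ) / cells^2,
                 tolerance = 1e-12)
  }
  # boundary point belongs to the last cell; coincident points
  b <- structure(list(coded = matrix(c(1, 1), 1, 2)), class = "design_matrix")
  expect_equal(grid_coverage(b, 10), 1)
  coin <- structure(list(coded = matrix(0.35, 6, 2)), class = "design_matrix")
  expect_equal(grid_coverage(coin, 10), 1)
})

test_that("coded/physical views round-trip and stay in bounds", {
  sp <- design_space(A = c(2, 8), B = c(-1, 1), C = c(100, 400))
  for (sampler in list(
    function(s) monte_carlo_design(31, sp, seed = s),
    function(s) latin_hypercube_design(31, sp, seed = s),
    function(s) sobol_design(31, sp))) {
    for (s in 1:3) {
      d <- sampler(s)
      expect_true(all(d$coded >= 0 & d$coded <= 1))
      lo <- sp$variables$lower; hi <- sp$variables$upper
      expect_true(all(t(d$points) >= lo & t(d$points) <= hi))
      expect_equal(to_physical(to_coded(d$points, sp), sp),
                   unname(d$points), ignore_attr = TRUE, tolerance = 1e-12)
    }
  }
})

test_that("structured samplers dominate MC on coverage and spread (averaged)", {
  sp <- two_drug_space()
  seeds <- 1:50
  cov_mc <- cov_lhs <- md_mc <- md_lhs <- numeric(length(seeds))
  for (i in seq_along(seeds)) {
    mc <- monte_carlo_design(13, sp, seed = seeds[i])
    lhs <- latin_hypercube_design(13, sp, seed = seeds[i])
    cov_mc[i] <- grid_coverage(mc, 10); cov_lhs[i] <- grid_coverage(lhs, 10)
    md_mc[i] <- min_pairwise_distance(mc); md_lhs[i] <- min_pairwise_distance(lhs)
  }
  expect_gte(mean(cov_lhs), mean(cov_mc))
  expect_gte(mean(md_lhs), mean(md_mc))
})

test_that("design CSV + sidecar round-trips", {
  sp <- two_drug_space()
  d <- latin_hypercube_design(13, sp, seed = 3)
  path <- file.path(tempdir(), "design_rt.csv")
  write_design_csv(d, path)
  d2 <- read_design_csv(path)
  expect_equal(unname(d2$points), unname(d$points), tolerance = 1e-12)
  expect_equal(d2$sampler, "lhs")
  expect_equal(d2$space$variables$upper, c(30, 30))
  unlink(c(path, paste0(path, ".json")))
})
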