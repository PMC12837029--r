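test_that("pure spectra follow the Gaussian band definition", {
  m <- band_model("X", data.frame(center = 250, width = 15, peak = 0.02))
  expect_equal(pure_spectrum(m, 250), 0.02)
  expect_equal(pure_spectrum(m, c(235, 265)), rep(0.02 * exp(-0.5), 2))
  m2 <- band_model("X", data.frame(center = c(250, 300), width = c(15, 20),
                                   peak = c(0.02, 0.01)))
  grid <- seq(200, 400, 1)
  expect_equal(pure_spectrum(m2, grid),
               pure_spectrum(band_model("a", m2$bands[1, ]), grid) +
                 pure_spectrum(band_model("b", m2$bands[2, ]), grid))
  expect_error(pure_spectrum(m, numeric(0)), "empty")
  expect_error(band_model("bad", data.frame(center = 1, width = 0, peak = 1)),
               "width")
})

test_that("Beer-Lambert additivity is exact at zero noise", {
  fx <- calibration_fixture()
  s <- fx$spectra
  lib <- default_band_library(c("AZM", "MPM"))
  eps <- sapply(lib, pure_spectrum, grid = s$wavelengths)
  expect_equal(unname(s$absorbance), unname(s$concentrations %*% t(eps)),
               tolerance = 1e-12)
  # doubling concentrations doubles absorbance
  d2 <- fx$design; d2$points <- d2$points * 2
  s2 <- simulate_mixtures(d2, lib, s$wavelengths, no_noise())
  expect_equal(unname(s2$absorbance), 2 * unname(s$absorbance), tolerance = 1e-12)
  # OLS on the two pure spectra recovers every concentration
  chat <- t(qr.solve(eps, t(s$absorbance)))
  expect_lt(max(abs(chat - s$concentrations)), 1e-8)
  # all-zero concentrations give all-zero spectra
  dz <- fx$design; dz$points[] <- 0
  expect_true(all(simulate_mixtures(dz, lib, s$wavelengths, no_noise())$absorbance == 0))
})

test_that("default band library forces overlapping, correlated pure spectra", {
  lib <- default_band_library()
  wl <- default_grid()
  wl <- wl[wl >= 200 & wl <= 335]
  e1 <- pure_spectrum(lib[[1]], wl); e2 <- pure_spectrum(lib[[2]], wl)
  expect_gt(cor(e1, e2), 0.2)
  # component A dominates 200-250, component B dominates 260-330
  expect_gt(mean(e1[wl <= 250]), mean(e2[wl <= 250]))
  expect_gt(mean(e2[wl >= 260 & wl <= 330]), mean(e1[wl >= 260 & wl <= 330]))
})

test_that("trimming keeps the inclusive window", {
  fx <- calibration_fixture()
  expect_equal(length(fx$spectra$wavelengths), 676L)  # 0.2 nm grid, 200-335
  s01 <- simulate_mixtures(fx$design, grid = default_grid(step = 0.1),
                           noise = no_noise())
  expect_equal(length(trim_wavelengths(s01, 200, 335)$wavelengths), 1351L)
  # identity trim
  s <- fx$spectra
  expect_equal(trim_wavelengths(s, 0, 1000)$absorbance, s$absorbance)
  expect_error(trim_wavelengths(s, 500, 600), "no grid points")
})

test_that("mean centering stores reusable means", {
  fx <- calibration_fixture(noise = noise_model(seed = 4))
  s <- fx$spectra
  c1 <- mean_center(s)
  expect_lt(max(abs(colMeans(c1$absorbance))), 1e-12)
  # single sample centers to zero
  one <- simulate_mixtures(sobol_design(1, two_drug_space()), grid = s$wavelengths,
                           noise = no_noise())
  expect_true(all(mean_center(one)$absorbance == 0))
  # centering new data with stored means round-trips
  v <- validation_fixture(noise = noise_model(seed = 5))$spectra
  vc <- apply_centering(v, c1$center_means)
  back <- apply_centering(vc, c1$center_means, undo = TRUE)
  expect_equal(back$absorbance, v$absorbance, tolerance = 1e-12)
})

test_that("binning averages windows and conserves the mean", {
  fx <- calibration_fixture()
  s <- fx$spectra  # 676 points at 0.2 nm
  expect_identical(bin_spectra(s, 0.2), s)
  expect_error(bin_spectra(s, 0.3), "integer multiple")
  b <- suppressWarnings(bin_spectra(s, 1))  # 676 = 135*5 + 1
  expect_equal(length(b$wavelengths), 135L)
  expect_equal(diff(b$wavelengths[1:2]), 1)
  # mean conservation over complete bins
  keep <- seq_len(135 * 5)
  expect_equal(rowMeans(b$absorbance), rowMeans(s$absorbance[, keep]),
               tolerance = 1e-10)
  # linear ramp: binned values are the ramp at window centers
  ramp <- s
  ramp$absorbance <- matrix(rep(2 * s$wavelengths + 1, each = nrow(s$absorbance)),
                            nrow(s$absorbance))
  br <- suppressWarnings(bin_spectra(ramp, 1))
  expect_equal(unname(br$absorbance[1, ]), 2 * br$wavelengths + 1,
               tolerance = 1e-10)
  # constant spectrum stays constant
  const <- s; const$absorbance[] <- 0.7
  expect_true(all(abs(suppressWarnings(bin_spectra(const, 1))$absorbance - 0.7) < 1e-12))
})

test_that("noise is seed-reproducible and SNR behaves", {
  d <- sobol_design(5, two_drug_space())
  nm <- noise_model(seed = 10)
  s1 <- simulate_mixtures(d, noise = nm)
  s2 <- simulate_mixtures(d, noise = nm)
  expect_identical(s1$absorbance, s2$absorbance)
  # zero noise: SNR undefined everywhere (flat residuals after detrend)
  s0 <- simulate_mixtures(d, noise = no_noise())
  flat <- s0; flat$absorbance[1, ] <- 0.5
  prof <- snr_profile(flat, window = 5)
  expect_true(all(!prof$defined))
  # flat signal + noise: SNR near a/s
  set.seed(2)
  a <- 0.8; sdn <- 0.02
  noisy <- s0
  noisy$absorbance[1, ] <- a + rnorm(ncol(s0$absorbance), sd = sdn)
  pr <- snr_profile(noisy, window = 10)
  expect_equal(median(pr$snr, na.rm = TRUE), a / sdn, tolerance = 0.1)
  # pure noise, zero signal: SNR near 0
  zn <- s0
  zn$absorbance[1, ] <- rnorm(ncol(s0$absorbance), sd = 0.01)
  expect_lt(median(snr_profile(zn, window = 10)$snr, na.rm = TRUE), 1)
  expect_error(snr_profile(s0, window = 0.5), "at least 5")
})

test_that("spectra CSV round-trips including dialects", {
  fx <- calibration_fixture(noise = noise_model(seed = 3))
  s <- fx$spectra
  p1 <- file.path(tempdir(), "spec_rt.csv")
  p2 <- file.path(tempdir(), "conc_rt.csv")
  write_spectra_csv(s, p1, p2)
  r <- read_spectra_csv(p1, p2)
  expect_equal(unname(r$absorbance), unname(s$absorbance), tolerance = 1e-10)
  expect_equal(unname(r$concentrations), unname(s$concentrations))
  # semicolon dialect
  txt <- readLines(p1)
  writeLines(gsub(",", ";", txt, fixed = TRUE), p1)
  r2 <- read_spectra_csv(p1)
  expect_equal(unname(r2$absorbance), unname(s$absorbance), tolerance = 1e-10)
  unlink(c(p1, p2))
})
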