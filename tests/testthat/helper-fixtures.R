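# Shared fixtures, built in code at test time.

two_drug_space <- function() design_space(AZM = c(10, 30), MPM = c(10, 30))

# 25-mixture factorial calibration + spectra on the working window
calibration_fixture <- function(noise = no_noise(), step = 0.2) {
  d <- factorial_calibration_design(two_drug_space())
  s <- simulate_mixtures(d, grid = default_grid(step = step), noise = noise)
  list(design = d, spectra = trim_wavelengths(s, 200, 335))
}

validation_fixture <- function(n = 13, sampler = "sobol", noise = no_noise(),
                               seed = 99, step = 0.2) {
  sp <- two_drug_space()
  d <- switch(sampler,
              sobol = sobol_design(n, sp),
              mc = monte_carlo_design(n, sp, seed = seed),
              lhs = latin_hypercube_design(n, sp, seed = seed))
  s <- simulate_mixtures(d, grid = default_grid(step = step), noise = noise)
  list(design = d, spectra = trim_wavelengths(s, 200, 335))
}

# small dense regression problem for oracle comparisons
small_regression <- function(n = 12, p = 4, q = 1, seed = 1, noise_sd = 0.1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  B <- matrix(rnorm(p * q), p, q)
  Y <- X %*% B + matrix(rnorm(n * q, sd = noise_sd), n, q)
  list(X = X, Y = Y)
}
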