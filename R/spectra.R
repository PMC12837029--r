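#' Gaussian band model of a pure component
#'
#' UV absorptivity of a component is modelled as a sum of Gaussian bands,
#' each with a center (nm), width (Gaussian sigma, nm), and peak molar-like
#' absorptivity expressed per ug/mL so Beer-Lambert mixing is a plain
#' weighted sum.
#'
#' @param name component name.
#' @param bands data.frame with columns `center`, `width`, `peak`.
#' @return object of class `band_model`.
#' @export
band_model <- function(name, bands) {
  bands <- as.data.frame(bands)
  stopifnot(all(c("center", "width", "peak") %in% names(bands)))
  if (nrow(bands) < 1L) stop("at least one band required")
  if (any(bands$width <= 0)) stop("band widths must be > 0")
  if (any(bands$peak < 0)) stop("peak absorptivities must be >= 0")
  structure(list(name = name, bands = bands), class = "band_model")
}

#' Default two-component overlapping band library
#'
#' Emulates a pair of strongly overlapping UV absorbers on 200-400 nm:
#' component A absorbs mainly at 200-250 nm with a broad shoulder extending
#' to ~340 nm; component B has its dominant broad band at 260-330 nm with a
#' secondary short-wavelength contribution. Band amplitudes are set so that
#' (a) 10-30 ug/mL mixtures give absorbances of roughly 0.1-1.2 AU and
#' (b) the two pure spectra are positively correlated on the 200-335 nm
#' working window (r about 0.3) — the collinearity that makes univariate
#' quantification fail and motivates multivariate calibration.
#'
#' @param names character vector of length 2 naming the components.
#' @return list of two [band_model()] objects.
#' @export
default_band_library <- function(names = c("AZM", "MPM")) {
  stopifnot(length(names) == 2L)
  list(
    band_model(names[1], data.frame(
      center = c(220, 290), width = c(12, 30), peak = c(0.030, 0.016))),
    band_model(names[2], data.frame(
      center = c(298, 215), width = c(20, 15), peak = c(0.028, 0.016)))
  )
}

#' Pure-component absorptivity spectrum
#'
#' @param model a [band_model()].
#' @param grid numeric wavelength grid (nm).
#' @return absorptivity per ug/mL at each grid point.
#' @export
pure_spectrum <- function(model, grid) {
  stopifnot(inherits(model, "band_model"))
  if (length(grid) < 1L) stop("empty wavelength grid")
  out <- numeric(length(grid))
  for (i in seq_len(nrow(model$bands))) {
    b <- model$bands[i, ]
    out <- out + b$peak * exp(-0.5 * ((grid - b$center) / b$width)^2)
  }
  out
}

#' Instrument noise model
#'
#' @param additive_sd additive absorbance noise SD (AU).
#' @param relative_sd heteroscedastic noise as a fraction of the signal.
#' @param baseline_sd per-spectrum baseline offset SD (AU).
#' @param slope_sd per-spectrum baseline slope SD (AU per full grid span).
#' @param seed integer seed.
#' @return object of class `noise_model`.
#' @export
noise_model <- function(additive_sd = 0.003, relative_sd = 0.005,
                        baseline_sd = 0.002, slope_sd = 0, seed = NULL) {
  stopifnot(additive_sd >= 0, relative_sd >= 0, baseline_sd >= 0, slope_sd >= 0)
  structure(list(additive_sd = additive_sd, relative_sd = relative_sd,
                 baseline_sd = baseline_sd, slope_sd = slope_sd, seed = seed),
            class = "noise_model")
}

#' Zero-noise model (exact Beer-Lambert mixing)
#' @export
no_noise <- function() noise_model(0, 0, 0, 0, seed = NULL)

#' Default wavelength grid
#'
#' 200.0-400.0 nm at a 0.2 nm step (1001 points); the common export
#' spacing for which the 200.0-335.0 nm working window holds 676 points.
#' A finer 0.1 nm instrument-style grid is available via `step`.
#'
#' @param from,to,step grid limits and spacing in nm.
#' @return numeric vector.
#' @export
default_grid <- function(from = 200, to = 400, step = 0.2) {
  seq(from, to, by = step)
}

new_spectra_set <- function(wavelengths, absorbance, concentrations,
                            centered = FALSE, center_means = NULL,
                            trim_window = NULL) {
  absorbance <- as.matrix(absorbance)
  concentrations <- as.matrix(concentrations)
  stopifnot(length(wavelengths) == ncol(absorbance),
            nrow(absorbance) == nrow(concentrations))
  if (length(wavelengths) > 1L) {
    d <- diff(wavelengths)
    if (any(d <= 0)) stop("wavelength grid must be strictly increasing")
    if (max(d) - min(d) > 1e-6 * mean(d))
      stop("wavelength grid must have a constant step")
  }
  structure(list(
    wavelengths = as.numeric(wavelengths),
    absorbance = absorbance,
    concentrations = concentrations,
    centered = centered,
    center_means = center_means,
    trim_window = trim_window
  ), class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("Spectra set: %d samples x %d wavelengths (%.1f-%.1f nm, step %.3g nm)\n",
              nrow(x$absorbance), length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths),
              if (length(x$wavelengths) > 1) diff(x$wavelengths[1:2]) else NA))
  cat(sprintf("Components: %s%s\n",
              paste(colnames(x$concentrations), collapse = ", "),
              if (x$centered) " (mean-centered)" else ""))
  invisible(x)
}

#' Simulate mixture spectra from a design under Beer-Lambert additivity
#'
#' Absorbance of each mixture is the concentration-weighted sum of the
#' pure-component absorptivity spectra, plus (optionally) additive noise,
#' signal-proportional noise and a per-spectrum baseline offset/tilt.
#'
#' @param design a `design_matrix` whose variables match the library names.
#' @param library list of [band_model()] objects (default
#'   [default_band_library()] with the design's variable names).
#' @param grid wavelength grid (default [default_grid()]).
#' @param noise a [noise_model()] (default zero noise).
#' @return a `spectra_set`.
#' @export
simulate_mixtures <- function(design, library = NULL, grid = default_grid(),
                              noise = no_noise()) {
  conc <- design$points
  if (is.null(library)) library <- default_band_library(colnames(conc))
  libnames <- vapply(library, function(m) m$name, "")
  if (!setequal(colnames(conc), libnames))
    stop("design variables and component library names do not match")
  library <- library[match(colnames(conc), libnames)]
  eps <- vapply(library, pure_spectrum, numeric(length(grid)), grid = grid)
  a <- conc %*% t(eps)  # n x wavelengths
  if (noise$additive_sd > 0 || noise$relative_sd > 0 ||
      noise$baseline_sd > 0 || noise$slope_sd > 0) {
    n <- nrow(a); p <- ncol(a)
    a <- with_seed(noise$seed, {
      e <- a
      if (noise$additive_sd > 0)
        e <- e + matrix(stats::rnorm(n * p, sd = noise$additive_sd), n, p)
      if (noise$relative_sd > 0)
        e <- e + a * matrix(stats::rnorm(n * p, sd = noise$relative_sd), n, p)
      if (noise$baseline_sd > 0)
        e <- e + stats::rnorm(n, sd = noise$baseline_sd)
      if (noise$slope_sd > 0) {
        span <- (grid - grid[1]) / (grid[length(grid)] - grid[1])
        e <- e + outer(stats::rnorm(n, sd = noise$slope_sd), span)
      }
      e
    })
  }
  new_spectra_set(grid, a, conc)
}

#' Trim a spectra set to a wavelength window
#'
#' Retains grid points with `low <= lambda <= high` (inclusive on both
#' ends). On the default 0.2 nm grid the 200.0-335.0 nm working window
#' keeps exactly 676 points.
#'
#' @param s a `spectra_set`.
#' @param low,high window limits in nm.
#' @return trimmed `spectra_set` with the window recorded.
#' @export
trim_wavelengths <- function(s, low, high) {
  keep <- s$wavelengths >= low & s$wavelengths <= high
  if (!any(keep)) stop("trim window contains no grid points")
  new_spectra_set(s$wavelengths[keep], s$absorbance[, keep, drop = FALSE],
                  s$concentrations, centered = s$centered,
                  center_means = s$center_means[keep],
                  trim_window = c(low, high))
}

#' Mean-center a spectra set
#'
#' Subtracts the per-wavelength mean absorbance; the means are stored so
#' the identical centering can be applied to new samples (see
#' [apply_centering()]).
#'
#' @param s a `spectra_set`.
#' @return centered `spectra_set` with `center_means` recorded.
#' @export
mean_center <- function(s) {
  m <- colMeans(s$absorbance)
  new_spectra_set(s$wavelengths, sweep(s$absorbance, 2, m), s$concentrations,
                  centered = TRUE, center_means = m, trim_window = s$trim_window)
}

#' Apply (or undo) stored centering to new spectra
#'
#' @param s a `spectra_set` to transform.
#' @param means per-wavelength training means.
#' @param undo add the means back instead of subtracting.
#' @return transformed `spectra_set`.
#' @export
apply_centering <- function(s, means, undo = FALSE) {
  stopifnot(length(means) == length(s$wavelengths))
  a <- sweep(s$absorbance, 2, means, if (undo) "+" else "-")
  new_spectra_set(s$wavelengths, a, s$concentrations, centered = !undo,
                  center_means = if (undo) NULL else means,
                  trim_window = s$trim_window)
}

#' Bin (downsample) spectra to a coarser wavelength step
#'
#' Averages non-overlapping windows of consecutive grid points; the new
#' grid sits at the window centers. The new step must be an integer
#' multiple of the current step; a trailing incomplete window is dropped
#' with a warning.
#'
#' @param s a `spectra_set`.
#' @param new_step target step in nm.
#' @return binned `spectra_set`.
#' @export
bin_spectra <- function(s, new_step) {
  step <- diff(s$wavelengths[1:2])
  f <- new_step / step
  if (abs(f - round(f)) > 1e-6)
    stop("new step must be an integer multiple of the current step")
  f <- as.integer(round(f))
  if (f == 1L) return(s)
  p <- length(s$wavelengths)
  nb <- p %/% f
  if (nb * f < p) {
    warning(sprintf("dropping %d trailing grid point(s) in an incomplete bin",
                    p - nb * f))
  }
  idx <- rep(seq_len(nb), each = f)
  keep <- seq_len(nb * f)
  wl <- as.numeric(tapply(s$wavelengths[keep], idx, mean))
  grp <- matrix(0, nrow = nb * f, ncol = nb)
  grp[cbind(keep, idx)] <- 1 / f
  a <- s$absorbance[, keep, drop = FALSE] %*% grp
  new_spectra_set(wl, a, s$concentrations, centered = s$centered,
                  trim_window = s$trim_window)
}

#' Per-wavelength signal-to-noise profile
#'
#' For each wavelength, points within a moving window are linearly
#' detrended; SNR is the absolute window mean divided by the residual SD.
#' Wavelengths where the residual SD falls below machine tolerance are
#' flagged undefined (`NA` SNR).
#'
#' @param s a `spectra_set`.
#' @param window window width in nm (must span at least 5 grid points).
#' @param sample which spectrum row to profile (default 1).
#' @return data.frame with `wavelength_nm`, `snr`, `defined`.
#' @export
snr_profile <- function(s, window = 5, sample = 1L) {
  wl <- s$wavelengths
  step <- diff(wl[1:2])
  half <- window / 2
  if (window / step < 4) stop("window must span at least 5 grid points")
  y <- s$absorbance[sample, ]
  n <- length(wl)
  snr <- numeric(n); defined <- logical(n)
  tol <- 1e3 * .Machine$double.eps
  for (i in seq_len(n)) {
    in_w <- which(abs(wl - wl[i]) <= half + 1e-9)
    yy <- y[in_w]; xx <- wl[in_w]
    fit <- stats::lm.fit(cbind(1, xx - mean(xx)), yy)
    sdres <- stats::sd(fit$residuals)
    if (!is.finite(sdres) || sdres < tol) {
      snr[i] <- NA_real_; defined[i] <- FALSE
    } else {
      snr[i] <- abs(mean(yy)) / sdres; defined[i] <- TRUE
    }
  }
  data.frame(wavelength_nm = wl, snr = snr, defined = defined)
}

#' Write / read spectra as CSV
#'
#' Column 1 is `wavelength_nm`; each further column is one sample's
#' absorbance (AU). The reader detects comma vs semicolon dialects. The
#' concentration table travels in its own sample x component CSV.
#'
#' @param s a `spectra_set`.
#' @param path spectra CSV path.
#' @param conc_path optional path for the concentration CSV.
#' @return `path` invisibly (writer); a `spectra_set` (reader; zero-filled
#'   concentrations when `conc_path` is missing).
#' @export
write_spectra_csv <- function(s, path, conc_path = NULL) {
  df <- data.frame(wavelength_nm = s$wavelengths, t(s$absorbance))
  names(df)[-1] <- paste0("sample_", seq_len(nrow(s$absorbance)))
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(conc_path))
    utils::write.csv(as.data.frame(s$concentrations), conc_path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @export
read_spectra_csv <- function(path, conc_path = NULL) {
  first <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(first, gregexpr(";", first))) >
             lengths(regmatches(first, gregexpr(",", first)))) ";" else ","
  df <- utils::read.csv(path, sep = sep, check.names = FALSE)
  wl <- df[[1]]
  a <- t(as.matrix(df[, -1, drop = FALSE]))
  conc <- if (!is.null(conc_path)) as.matrix(utils::read.csv(conc_path, sep = sep))
          else matrix(0, nrow = nrow(a), ncol = 1,
                      dimnames = list(NULL, "unknown"))
  new_spectra_set(wl, a, conc)
}
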