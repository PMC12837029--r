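#' Define a mixture design space
#'
#' A design space is an ordered set of analyte concentration variables with
#' lower and upper bounds (conventionally in ug/mL). All samplers draw
#' points inside this hyper-rectangle.
#'
#' @param ... named numeric vectors of length 2, e.g. `AZM = c(10, 30)`.
#'   Alternatively a single data.frame with columns `name`, `lower`, `upper`.
#' @return an object of class `design_space`.
#' @examples
#' design_space(AZM = c(10, 30), MPM = c(10, 30))
#' @export
design_space <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.data.frame(args[[1]])) {
    df <- args[[1]]
    stopifnot(all(c("name", "lower", "upper") %in% names(df)))
  } else {
    if (length(args) < 1L) stop("a design space needs at least one variable")
    if (is.null(names(args)) || any(names(args) == ""))
      stop("variables must be named, e.g. design_space(AZM = c(10, 30))")
    df <- data.frame(
      name = names(args),
      lower = vapply(args, function(b) as.numeric(b[1]), 0),
      upper = vapply(args, function(b) as.numeric(b[2]), 0)
    )
  }
  if (anyDuplicated(df$name)) stop("duplicate variable names")
  if (any(!is.finite(df$lower)) || any(!is.finite(df$upper)))
    stop("bounds must be finite")
  if (any(df$lower >= df$upper)) stop("each lower bound must be < upper bound")
  structure(list(variables = df), class = "design_space")
}

#' @export
print.design_space <- function(x, ...) {
  cat("Design space with", nrow(x$variables), "variable(s):\n")
  print(x$variables, row.names = FALSE)
  invisible(x)
}

space_dim <- function(space) nrow(space$variables)

#' Map physical concentrations to the coded unit hypercube (and back)
#'
#' Coded coordinates are the affine image of the bounds onto `[0, 1]`;
#' all space-filling metrics are computed in coded space so they are
#' scale-free.
#'
#' @param x numeric matrix (points in rows).
#' @param space a [design_space()].
#' @return matrix of the same shape.
#' @export
to_coded <- function(x, space) {
  x <- as.matrix(x)
  lo <- space$variables$lower; hi <- space$variables$upper
  sweep(sweep(x, 2, lo, "-"), 2, hi - lo, "/")
}

#' @rdname to_coded
#' @export
to_physical <- function(x, space) {
  x <- as.matrix(x)
  lo <- space$variables$lower; hi <- space$variables$upper
  sweep(sweep(x, 2, hi - lo, "*"), 2, lo, "+")
}

new_design_matrix <- function(points, space, sampler, seed = NULL, params = list()) {
  points <- as.matrix(points)
  colnames(points) <- space$variables$name
  structure(list(
    points = points,
    coded = to_coded(points, space),
    space = space,
    sampler = sampler,
    seed = seed,
    params = params
  ), class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("Design matrix: %d points x %d variables (sampler: %s)\n",
              nrow(x$points), ncol(x$points), x$sampler))
  print(utils::head(as.data.frame(x$points)), row.names = FALSE)
  if (nrow(x$points) > 6L) cat("...\n")
  invisible(x)
}

#' @export
as.data.frame.design_matrix <- function(x, ...) as.data.frame(x$points, ...)

#' Full factorial calibration design on coded levels
#'
#' Builds the full factorial of a set of equally spaced coded levels; each
#' level list maps linearly onto the variable bounds so that the lowest
#' level hits the lower bound and the highest the upper bound. The default
#' five levels (-2..2) on a two-variable space give the classical 25-mixture
#' multilevel calibration set.
#'
#' @param space a [design_space()].
#' @param levels numeric vector of coded levels, strictly increasing and
#'   equally spaced (default `-2:2`).
#' @return a `design_matrix`.
#' @examples
#' sp <- design_space(AZM = c(10, 30), MPM = c(10, 30))
#' d <- factorial_calibration_design(sp)
#' nrow(d$points)  # 25
#' @export
factorial_calibration_design <- function(space, levels = -2:2) {
  levels <- as.numeric(levels)
  if (length(levels) < 2L) stop("need at least two levels")
  if (any(diff(levels) <= 0)) stop("levels must be strictly increasing")
  if (length(levels) > 2L &&
      max(abs(diff(diff(levels)))) > 1e-9 * max(abs(diff(levels))))
    stop("levels must be equally spaced")
  d <- space_dim(space)
  u <- (levels - levels[1]) / (levels[length(levels)] - levels[1])
  grid <- as.matrix(expand.grid(rep(list(u), d), KEEP.OUT.ATTRS = FALSE))
  new_design_matrix(to_physical(grid, space), space, "factorial",
                    params = list(levels = levels))
}

#' Monte Carlo (uniform random) mixture design
#'
#' Each coordinate is drawn as `x = x_min + r * (x_max - x_min)` with
#' `r ~ U[0, 1)`, independently per point and variable.
#'
#' @param n number of mixtures.
#' @param space a [design_space()].
#' @param seed integer seed (reproducible for a fixed seed).
#' @return a `design_matrix`.
#' @export
monte_carlo_design <- function(n, space, seed = NULL) {
  n <- stop_if_not_scalar_count(n, "n")
  d <- space_dim(space)
  r <- with_seed(seed, matrix(stats::runif(n * d), nrow = n, ncol = d))
  new_design_matrix(to_physical(r, space), space, "mc", seed = seed)
}

#' Latin hypercube mixture design
#'
#' Divides each variable's range into `n` equal strata and places exactly
#' one point in each stratum: `x = x_min + ((k - r) / n) * (x_max - x_min)`
#' with stratum index `k` in `1..n` randomly permuted per variable and
#' `r ~ U[0, 1)` drawn fresh per stratum.
#'
#' @inheritParams monte_carlo_design
#' @return a `design_matrix`.
#' @export
latin_hypercube_design <- function(n, space, seed = NULL) {
  n <- stop_if_not_scalar_count(n, "n")
  d <- space_dim(space)
  u <- with_seed(seed, {
    vapply(seq_len(d), function(j) {
      k <- sample.int(n)
      r <- stats::runif(n)
      (k - r) / n
    }, numeric(n))
  })
  u <- matrix(u, nrow = n, ncol = d)
  new_design_matrix(to_physical(u, space), space, "lhs", seed = seed)
}

#' Sobol-sequence mixture design
#'
#' Deterministic low-discrepancy points generated by XOR of direction
#' numbers (Gray-code order, standard primitive-polynomial direction
#' numbers for up to 10 dimensions). Index 0 is the origin — the
#' all-lower-bound corner — and is skipped by default because a blank
#' mixture usually lies outside the working range.
#'
#' @param n number of points to return.
#' @param space a [design_space()].
#' @param skip_zero drop the index-0 origin point (default `TRUE`).
#' @param scramble apply a seeded digital (XOR) scramble; default `FALSE`,
#'   giving the plain deterministic sequence.
#' @param seed only used when `scramble = TRUE`.
#' @return a `design_matrix`.
#' @export
sobol_design <- function(n, space, skip_zero = TRUE, scramble = FALSE, seed = NULL) {
  n <- stop_if_not_scalar_count(n, "n")
  d <- space_dim(space)
  u <- sobol_points(n + as.integer(skip_zero), d)
  if (skip_zero) u <- u[-1L, , drop = FALSE]
  if (scramble) {
    mask <- with_seed(seed, floor(stats::runif(d) * 2^SOBOL_BITS))
    ui <- round(u * 2^SOBOL_BITS)
    u <- vapply(seq_len(d), function(j)
      bitwXor(as.integer(ui[, j]), as.integer(mask[j])) / 2^SOBOL_BITS,
      numeric(nrow(u)))
    u <- matrix(u, ncol = d)
  }
  new_design_matrix(to_physical(u, space), space, "sobol",
                    seed = if (scramble) seed else NULL,
                    params = list(skip_zero = skip_zero, scramble = scramble))
}

#' Minimum pairwise distance of a design (coded space)
#'
#' Smallest Euclidean distance between any two design points, computed on
#' the coded unit-hypercube view so that the metric does not depend on the
#' concentration units.
#'
#' @param design a `design_matrix`.
#' @return a single non-negative number, at most `sqrt(d)`.
#' @export
min_pairwise_distance <- function(design) {
  x <- design$coded
  if (nrow(x) < 2L) stop("need at least two points")
  min(stats::dist(x))
}

#' Grid coverage of a design (coded space)
#'
#' Percentage of cells of a regular grid over the coded unit hypercube that
#' contain at least one design point. Points on the upper boundary belong
#' to the last cell.
#'
#' @param design a `design_matrix`.
#' @param cells_per_dim cells per dimension (default 10, i.e. a 10 x 10
#'   grid for two analytes).
#' @return percentage in `(0, 100]`.
#' @export
grid_coverage <- function(design, cells_per_dim = 10L) {
  cells_per_dim <- stop_if_not_scalar_count(cells_per_dim, "cells_per_dim")
  u <- design$coded
  idx <- pmin(floor(u * cells_per_dim), cells_per_dim - 1L)
  keys <- apply(idx, 1L, paste, collapse = ",")
  100 * length(unique(keys)) / cells_per_dim^ncol(u)
}

#' Space-filling uniformity report
#'
#' @param design a `design_matrix`.
#' @param cells_per_dim grid resolution for [grid_coverage()].
#' @return list with `min_pairwise_distance`, `grid_coverage_percent`,
#'   `grid_resolution`, `n`, `sampler`.
#' @export
uniformity_report <- function(design, cells_per_dim = 10L) {
  list(
    sampler = design$sampler,
    n = nrow(design$points),
    min_pairwise_distance = min_pairwise_distance(design),
    grid_coverage_percent = grid_coverage(design, cells_per_dim),
    grid_resolution = as.integer(cells_per_dim)
  )
}

#' Write / read a design as CSV plus JSON sidecar
#'
#' The CSV holds one mixture per row in physical units with a header of
#' variable names; the sidecar (same path with `.json` appended) records
#' sampler, seed, bounds and the coded matrix so a design round-trips
#' losslessly.
#'
#' @param design a `design_matrix`.
#' @param path CSV file path.
#' @return `path`, invisibly (writer); a `design_matrix` (reader).
#' @export
write_design_csv <- function(design, path) {
  utils::write.csv(as.data.frame(design$points), path, row.names = FALSE)
  side <- list(
    sampler = design$sampler,
    seed = design$seed,
    params = design$params,
    variables = design$space$variables,
    coded = design$coded
  )
  jsonlite::write_json(side, paste0(path, ".json"), digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_design_csv
#' @export
read_design_csv <- function(path) {
  pts <- as.matrix(utils::read.csv(path, check.names = FALSE))
  sidep <- paste0(path, ".json")
  if (file.exists(sidep)) {
    side <- jsonlite::read_json(sidep, simplifyVector = TRUE)
    sp <- design_space(as.data.frame(side$variables))
    new_design_matrix(pts, sp, side$sampler %||% "unknown",
                      seed = side$seed, params = as.list(side$params))
  } else {
    sp <- design_space(data.frame(name = colnames(pts),
                                  lower = apply(pts, 2, min),
                                  upper = apply(pts, 2, max)))
    new_design_matrix(pts, sp, "unknown")
  }
}
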