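#' Information-complexity (ICOMP) score of a regression fit
#'
#' `ICOMP = -2 log L + 2 C(Sigma)`, combining a Gaussian log-likelihood
#' fit term with Bozdogan's covariance-complexity penalty. With the
#' maximum-likelihood variance `sigma^2 = RSS / n` the fit term reduces to
#' `n log(2 pi sigma^2) + n`; the penalty is
#' `C(Sigma) = 1/2 [ (tr Sigma)^2 - tr(Sigma^2) ]`, computed from the
#' residual covariance across responses. For a scalar (single-response)
#' Sigma the printed penalty is identically zero; set `c1 = TRUE` to use
#' Bozdogan's C1 penalty instead in that case.
#'
#' @param y reference responses (vector, possibly stacked responses).
#' @param y_hat predictions, same length.
#' @param residual_cov residual covariance matrix (symmetric PSD); for a
#'   multi-response calibration this is the responses x responses
#'   covariance of the residual matrix.
#' @param c1 use the C1 complexity `p/2 log(mean eig) - 1/2 sum log eig`
#'   instead of the trace form.
#' @return a single number (lower is better). A perfect fit (`RSS = 0`)
#'   returns `-Inf` with a warning.
#' @export
icomp_score <- function(y, y_hat, residual_cov, c1 = FALSE) {
  y <- as.numeric(y); y_hat <- as.numeric(y_hat)
  n <- length(y)
  stopifnot(length(y_hat) == n, n >= 2L)
  S <- as.matrix(residual_cov)
  if (nrow(S) != ncol(S) || max(abs(S - t(S))) > 1e-8 * max(1, max(abs(S))))
    stop("residual_cov must be a symmetric matrix")
  rss <- sum((y - y_hat)^2)
  if (rss <= 0) {
    warning("perfect fit: RSS = 0, ICOMP reported as -Inf")
    return(-Inf)
  }
  sigma2 <- rss / n
  minus2ll <- n * log(2 * pi * sigma2) + n
  cplx <- if (c1) {
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    ev <- ev[ev > 1e-300]
    length(ev) / 2 * log(mean(ev)) - 0.5 * sum(log(ev))
  } else {
    0.5 * (sum(diag(S))^2 - sum(diag(S %*% S)))
  }
  minus2ll + 2 * cplx
}

#' Genetic-algorithm configuration for wavelength selection
#'
#' @param pop_size population size (default 30).
#' @param generations number of generations (default 50).
#' @param crossover_rate probability a mating pair undergoes uniform
#'   crossover (default 0.9).
#' @param mutation_rate per-bit flip probability (default 0.01).
#' @param elitism number of best chromosomes copied unchanged (default 1).
#' @param fitness `"cv_rmse"` (inner-CV RMSE, the conventional GA-PLS
#'   fitness) or `"icomp"` (information-complexity fitness).
#' @param cv_folds inner-CV fold count for `cv_rmse` fitness (default 5).
#' @param min_selected,max_selected bounds on selected wavelengths; short
#'   chromosomes are repaired by switching random bits on.
#' @param lv_cap latent-variable cap per chromosome; the LV count is picked
#'   by leave-one-out CV up to this cap (`lv_rule = "fixed"` always uses
#'   `lv_cap`).
#' @param lv_rule `"loocv_capped"` (default) or `"fixed"`.
#' @param init_prob probability a bit starts switched on (default 0.5).
#' @param seed integer seed.
#' @return object of class `ga_config`.
#' @export
ga_config <- function(pop_size = 30L, generations = 50L, crossover_rate = 0.9,
                      mutation_rate = 0.01, elitism = 1L,
                      fitness = c("cv_rmse", "icomp"), cv_folds = 5L,
                      min_selected = 5L, max_selected = NULL, lv_cap = 5L,
                      lv_rule = c("loocv_capped", "fixed"),
                      init_prob = 0.5, seed = NULL) {
  pop_size <- stop_if_not_scalar_count(pop_size, "pop_size", min = 2L)
  generations <- stop_if_not_scalar_count(generations, "generations", min = 0L)
  stopifnot(crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            init_prob > 0, init_prob <= 1)
  structure(list(pop_size = pop_size, generations = generations,
                 crossover_rate = crossover_rate, mutation_rate = mutation_rate,
                 elitism = as.integer(elitism), fitness = match.arg(fitness),
                 cv_folds = as.integer(cv_folds),
                 min_selected = as.integer(min_selected),
                 max_selected = max_selected, lv_cap = as.integer(lv_cap),
                 lv_rule = match.arg(lv_rule), init_prob = init_prob,
                 seed = seed),
            class = "ga_config")
}

repair_chromosome <- function(bits, min_selected, max_selected = NULL) {
  on <- sum(bits)
  if (on < min_selected) {
    off <- which(bits == 0L)
    bits[sample(off, min_selected - on)] <- 1L
  }
  if (!is.null(max_selected) && sum(bits) > max_selected) {
    onidx <- which(bits == 1L)
    bits[sample(onidx, sum(bits) - max_selected)] <- 0L
  }
  bits
}

# fitness of one chromosome: lower is better
chromosome_fitness <- function(bits, X, Y, config) {
  cols <- which(bits == 1L)
  Xs <- X[, cols, drop = FALSE]
  n <- nrow(Xs)
  cap <- min(config$lv_cap, n - 2L, length(cols))
  k <- if (config$lv_rule == "fixed") cap
       else select_lv_loocv(Xs, Y, cap, rule = "min")$n_lv
  if (config$fitness == "icomp") {
    m <- fit_pls(Xs, Y, k)
    E <- m$fitted - Y
    icomp_score(as.numeric(Y), as.numeric(m$fitted), stats::cov(E))
  } else {
    folds <- rep_len(seq_len(config$cv_folds), n)  # deterministic fold map
    sq <- 0
    for (f in seq_len(config$cv_folds)) {
      te <- which(folds == f)
      m <- fit_pls(Xs[-te, , drop = FALSE], Y[-te, , drop = FALSE],
                   min(k, n - length(te) - 1L, length(cols)))
      sq <- sq + sum((predict(m, Xs[te, , drop = FALSE]) - Y[te, ])^2)
    }
    sqrt(sq / (n * ncol(as.matrix(Y))))
  }
}

#' Genetic-algorithm wavelength selection for PLS
#'
#' Binary-coded GA (tournament selection of size 2, uniform crossover,
#' per-bit mutation, elitism) minimising either an inner-cross-validated
#' RMSE or the ICOMP score of the PLS fit on the selected wavelengths.
#' Fitness values are memoized by chromosome, and the chromosome with the
#' lowest fitness ever seen is returned together with a refitted PLS model
#' on its wavelengths.
#'
#' @param X raw spectra (samples x wavelengths) or a `spectra_set`.
#' @param Y concentrations (samples x responses).
#' @param config a [ga_config()].
#' @return object of class `selection_result`: `mask` (0/1 per
#'   wavelength), `fitness`, `trace` (best/median per generation,
#'   `generations + 1` rows), `frequency` (per-wavelength selection
#'   frequency in the final population), `model` (PLS refit), `config`.
#' @export
ga_select <- function(X, Y, config = ga_config()) {
  if (inherits(X, "spectra_set")) {
    wl <- X$wavelengths; X <- X$absorbance
  } else wl <- NULL
  X <- as.matrix(X); Y <- as.matrix(Y)
  p <- ncol(X)
  if (!is.null(config$max_selected) && config$max_selected < config$min_selected)
    stop("max_selected < min_selected")
  memo <- new.env(parent = emptyenv())
  fit_of <- function(bits) {
    key <- paste(which(bits == 1L), collapse = ",")
    if (key == "") stop("all-zero chromosome after repair")
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    val <- chromosome_fitness(bits, X, Y, config)
    memo[[key]] <- val
    val
  }
  with_seed(config$seed, {
    pop <- lapply(seq_len(config$pop_size), function(i)
      repair_chromosome(as.integer(stats::runif(p) < config$init_prob),
                        config$min_selected, config$max_selected))
    fitv <- vapply(pop, fit_of, numeric(1))
    best_bits <- pop[[which.min(fitv)]]; best_fit <- min(fitv)
    trace <- data.frame(generation = 0L, best = best_fit,
                        median = stats::median(fitv))
    if (config$generations > 0L) for (gen in seq_len(config$generations)) {
      ord <- order(fitv)
      newpop <- pop[ord[seq_len(config$elitism)]]
      while (length(newpop) < config$pop_size) {
        pick <- function() {
          c2 <- sample.int(config$pop_size, 2L)
          pop[[c2[which.min(fitv[c2])]]]
        }
        p1 <- pick(); p2 <- pick()
        if (stats::runif(1) < config$crossover_rate) {
          swap <- stats::runif(p) < 0.5
          ch1 <- as.integer(ifelse(swap, p2, p1))
          ch2 <- as.integer(ifelse(swap, p1, p2))
        } else { ch1 <- p1; ch2 <- p2 }
        for (ch in list(ch1, ch2)) {
          flip <- stats::runif(p) < config$mutation_rate
          ch <- as.integer(xor(ch == 1L, flip))
          ch <- repair_chromosome(ch, config$min_selected, config$max_selected)
          if (length(newpop) < config$pop_size) newpop[[length(newpop) + 1L]] <- ch
        }
      }
      pop <- newpop
      fitv <- vapply(pop, fit_of, numeric(1))
      if (min(fitv) < best_fit) {
        best_fit <- min(fitv); best_bits <- pop[[which.min(fitv)]]
      }
      trace <- rbind(trace, data.frame(generation = gen,
                                       best = best_fit,
                                       median = stats::median(fitv)))
    }
    freq <- Reduce(`+`, pop) / length(pop)
    cols <- which(best_bits == 1L)
    cap <- min(config$lv_cap, nrow(X) - 2L, length(cols))
    k <- if (config$lv_rule == "fixed") cap
         else select_lv_loocv(X[, cols, drop = FALSE], Y, cap, rule = "min")$n_lv
    model <- fit_pls(X[, cols, drop = FALSE], Y, k)
    structure(list(mask = best_bits, fitness = best_fit, trace = trace,
                   frequency = freq, model = model, selected = cols,
                   wavelengths = wl, config = config),
              class = "selection_result")
  })
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("GA selection (%s fitness): %d / %d wavelengths selected, best fitness %.6g\n",
              x$config$fitness, sum(x$mask), length(x$mask), x$fitness))
  invisible(x)
}

#' Benchmark wavelength-selection strategies against full-spectrum PLS
#'
#' Evaluates full-spectrum PLS and each supplied GA configuration with an
#' identical cross-validation fold assignment, reporting selected-variable
#' counts, RMSECV and RMSEP on a supplied validation set.
#'
#' @param X,Y calibration data.
#' @param X_val,Y_val independent validation data (required).
#' @param configs named list of [ga_config()] objects.
#' @param cv_folds folds for the shared RMSECV protocol.
#' @param max_lv LV bound for the full-spectrum model.
#' @return data.frame, one row per candidate, plus attribute `fold_hash`
#'   recording the shared fold assignment.
#' @export
compare_selection <- function(X, Y, X_val, Y_val, configs, cv_folds = 5L,
                              max_lv = 5L) {
  if (inherits(X, "spectra_set")) X <- X$absorbance
  if (inherits(X_val, "spectra_set")) X_val <- X_val$absorbance
  X <- as.matrix(X); Y <- as.matrix(Y)
  X_val <- as.matrix(X_val); Y_val <- as.matrix(Y_val)
  if (length(configs) < 1L) stop("at least one GA config required")
  n <- nrow(X)
  folds <- rep_len(seq_len(cv_folds), n)
  fold_hash <- paste(folds, collapse = "")
  cv_rmse_masked <- function(cols, k) {
    sq <- 0
    for (f in seq_len(cv_folds)) {
      te <- which(folds == f)
      m <- fit_pls(X[-te, cols, drop = FALSE], Y[-te, , drop = FALSE], k)
      sq <- sq + sum((predict(m, X[te, cols, drop = FALSE]) - Y[te, ])^2)
    }
    sqrt(sq / (n * ncol(Y)))
  }
  rows <- list()
  k_full <- select_lv_loocv(X, Y, min(max_lv, n - 2L, ncol(X)), rule = "min")$n_lv
  m_full <- fit_pls(X, Y, k_full)
  rows[["full_spectrum"]] <- data.frame(
    candidate = "full_spectrum", n_selected = ncol(X), n_lv = k_full,
    rmsecv = cv_rmse_masked(seq_len(ncol(X)), k_full),
    rmsep = sqrt(mean((predict(m_full, X_val) - Y_val)^2)))
  for (nm in names(configs)) {
    sel <- ga_select(X, Y, configs[[nm]])
    rows[[nm]] <- data.frame(
      candidate = nm, n_selected = length(sel$selected), n_lv = sel$model$n_lv,
      rmsecv = cv_rmse_masked(sel$selected, sel$model$n_lv),
      rmsep = sqrt(mean((predict(sel$model, X_val[, sel$selected, drop = FALSE]) -
                           Y_val)^2)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fold_hash") <- fold_hash
  out
}

#' Export a selection mask as a plotting table
#'
#' @param result a `selection_result` from [ga_select()].
#' @return data.frame with `wavelength_nm` (or index) and `selected` 0/1.
#' @export
selection_mask_table <- function(result) {
  data.frame(
    wavelength_nm = result$wavelengths %||% seq_along(result$mask),
    selected = as.integer(result$mask)
  )
}
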