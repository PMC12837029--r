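#' Figures of merit for predicted vs actual concentrations
#'
#' Computes RMSE (`sqrt(mean((yhat - y)^2))`, denominator `n` in every
#' context so RMSEC/RMSECV/RMSEP share one formula), per-sample recovery
#' percent (`100 * yhat / y`), its mean, SD and %RSD, and the slope,
#' intercept, correlation `r` and `R^2 = r^2` of the predicted-vs-actual
#' regression line.
#'
#' @param actual,predicted aligned numeric vectors (n >= 2).
#' @param context one of `"calibration"`, `"cv"`, `"prediction"` — only
#'   labels which RMSE is being reported.
#' @return list of class `metrics_report`.
#' @export
error_metrics <- function(actual, predicted,
                          context = c("prediction", "calibration", "cv")) {
  context <- match.arg(context)
  actual <- as.numeric(actual); predicted <- as.numeric(predicted)
  n <- length(actual)
  stopifnot(length(predicted) == n, n >= 2L)
  if (any(actual == 0)) stop("recovery percent undefined for zero actual values")
  rmse <- sqrt(mean((predicted - actual)^2))
  rec <- 100 * predicted / actual
  fit <- stats::lm.fit(cbind(1, actual), predicted)
  r <- stats::cor(actual, predicted)
  structure(list(
    context = context,
    rmse = rmse,
    recovery = rec,
    mean_recovery = mean(rec),
    sd = stats::sd(rec),
    rsd_percent = 100 * stats::sd(rec) / mean(rec),
    slope = unname(fit$coefficients[2]),
    intercept = unname(fit$coefficients[1]),
    r = r,
    r2 = r^2,
    n = n
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Metrics (%s): RMSE %.4f | mean %%R %.2f (SD %.3f, %%RSD %.3f)\n",
              x$context, x$rmse, x$mean_recovery, x$sd, x$rsd_percent))
  cat(sprintf("  predicted ~ actual: slope %.4f, intercept %.4f, r %.4f\n",
              x$slope, x$intercept, x$r))
  invisible(x)
}

#' Percent reduction of an error metric
#'
#' `100 * (base - improved) / base`: the headline "RMSE lessened by x%"
#' arithmetic used when comparing a variable-selected or nonlinear model
#' against the baseline full-spectrum model.
#'
#' @param base baseline RMSE (> 0).
#' @param improved RMSE of the improved model.
#' @return percent reduction (negative if the "improved" model is worse).
#' @export
rmse_reduction <- function(base, improved) {
  if (!is.finite(base) || base <= 0) stop("base RMSE must be > 0")
  100 * (base - improved) / base
}

#' Nested cross-validation with bootstrap confidence interval
#'
#' Outer folds estimate generalization error; all hyperparameter tuning
#' happens inside `model_factory`, which only ever receives the outer-fold
#' training rows. Outer predictions are concatenated into a pooled RMSECV;
#' a seeded percentile bootstrap over the pooled outer residuals gives the
#' 95% interval.
#'
#' @param X,Y data matrices (rows aligned).
#' @param model_factory `function(X_train, Y_train)` returning an object
#'   with a `predict(model, X_new)` method; any inner-fold tuning happens
#'   inside this function.
#' @param outer_folds number of outer folds (default 5).
#' @param n_boot bootstrap resamples (default 1000).
#' @param conf confidence level (default 0.95).
#' @param seed integer seed (fold shuffling + bootstrap).
#' @return list with `fold_rmse`, `pooled_rmsecv`, `ci` (percentile
#'   bootstrap), `folds` (per-sample outer fold id), and the recorded
#'   per-fold train/test row indices (`fold_rows`) for leakage audits.
#' @export
nested_cv <- function(X, Y, model_factory, outer_folds = 5L, n_boot = 1000L,
                      conf = 0.95, seed = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  outer_folds <- stop_if_not_scalar_count(outer_folds, "outer_folds", min = 2L)
  if (outer_folds > n) stop("more outer folds than samples")
  with_seed(seed, {
    folds <- sample(rep_len(seq_len(outer_folds), n))
    preds <- matrix(NA_real_, n, ncol(Y))
    fold_rmse <- numeric(outer_folds)
    fold_rows <- vector("list", outer_folds)
    for (f in seq_len(outer_folds)) {
      te <- which(folds == f); tr <- which(folds != f)
      fold_rows[[f]] <- list(train = tr, test = te)
      m <- model_factory(X[tr, , drop = FALSE], Y[tr, , drop = FALSE])
      preds[te, ] <- predict(m, X[te, , drop = FALSE])
      fold_rmse[f] <- sqrt(mean((preds[te, ] - Y[te, ])^2))
    }
    res <- as.numeric(preds - Y)
    pooled <- sqrt(mean(res^2))
    boot <- vapply(seq_len(n_boot), function(b)
      sqrt(mean(sample(res, length(res), replace = TRUE)^2)), numeric(1))
    alpha <- (1 - conf) / 2
    list(fold_rmse = fold_rmse, pooled_rmsecv = pooled,
         ci = unname(stats::quantile(boot, c(alpha, 1 - alpha))),
         folds = folds, fold_rows = fold_rows, predictions = preds)
  })
}

#' Y-randomization (response permutation) test
#'
#' Refits the modelling protocol on randomly permuted responses (identity
#' permutation excluded) and compares predictive correlation against the
#' original model. With many more wavelengths than samples even a permuted
#' response can be fitted almost perfectly, so `r` is computed from
#' cross-validated predictions (the identical k-fold protocol for the
#' original and every permuted refit), not training fits. Passing means
#' the original r exceeds every permuted r and the mean permuted r is
#' below 0.5.
#'
#' @param X predictor matrix.
#' @param Y single-response vector (or one column of a response matrix).
#' @param model_factory `function(X, y)` returning a model with `predict`.
#' @param n_permutations at least 10 (default 20).
#' @param cv_folds folds of the shared CV protocol (default 5).
#' @param seed integer seed.
#' @return list with `original_r`, `permuted_r`, `permuted_rmse`,
#'   `mean_permuted_r`, `verdict`.
#' @export
y_randomization <- function(X, Y, model_factory, n_permutations = 20L,
                            cv_folds = 5L, seed = NULL) {
  X <- as.matrix(X); y <- as.numeric(as.matrix(Y)[, 1])
  n <- length(y)
  n_permutations <- stop_if_not_scalar_count(n_permutations, "n_permutations",
                                             min = 10L)
  if (stats::sd(y) == 0) stop("constant response: correlation undefined")
  folds <- rep_len(seq_len(cv_folds), n)
  cv_pred <- function(yy) {
    out <- numeric(n)
    for (f in seq_len(cv_folds)) {
      te <- which(folds == f)
      m <- model_factory(X[-te, , drop = FALSE], yy[-te])
      out[te] <- as.numeric(predict(m, X[te, , drop = FALSE]))
    }
    out
  }
  p0 <- cv_pred(y)
  r0 <- stats::cor(p0, y)
  with_seed(seed, {
    rs <- numeric(n_permutations); rmses <- numeric(n_permutations)
    for (i in seq_len(n_permutations)) {
      repeat {
        perm <- sample(n)
        if (any(perm != seq_len(n))) break
      }
      yp <- y[perm]
      ph <- cv_pred(yp)
      rs[i] <- if (stats::sd(ph) < 1e-300) 0 else stats::cor(ph, yp)
      rmses[i] <- sqrt(mean((ph - yp)^2))
    }
    verdict <- (r0 > max(rs)) && (mean(rs) < 0.5)
    list(original_r = r0, permuted_r = rs, permuted_rmse = rmses,
         mean_permuted_r = mean(rs), verdict = verdict)
  })
}

#' Applicability domain (Williams plot) report
#'
#' Leverage of sample i in latent-score space is
#' `h_i = t_i' (T'T)^-1 t_i + 1/n`; the critical limit is
#' `h* = 3 (p + 1) / n` with `p` the number of latent variables.
#' Standardized residuals divide by the SD of the assessed residuals. A
#' sample is in-domain iff `|std residual| < 3` and `h < h*`.
#'
#' @param scores latent-score matrix `T` of the training model (n x p), or
#'   a `pls_model` (its training scores are used).
#' @param residuals numeric residual vector aligned with the score rows.
#' @return data.frame of class `ad_report` with `leverage`,
#'   `std_residual`, `in_domain`, and attributes `h_star`, `p`.
#' @export
applicability_domain <- function(scores, residuals) {
  if (inherits(scores, "pls_model")) scores <- scores$scores
  Tm <- as.matrix(scores)
  n <- nrow(Tm); p <- ncol(Tm)
  residuals <- as.numeric(residuals)
  stopifnot(length(residuals) == n)
  G <- crossprod(Tm)
  if (rcond(G) < 1e-14) stop("singular score covariance")
  lev <- rowSums((Tm %*% solve(G)) * Tm) + 1 / n
  sdr <- stats::sd(residuals)
  stdres <- if (sdr < 1e-300) rep(0, n) else residuals / sdr
  h_star <- 3 * (p + 1) / n
  out <- data.frame(sample = seq_len(n), leverage = lev,
                    std_residual = stdres,
                    in_domain = abs(stdres) < 3 & lev < h_star)
  attr(out, "h_star") <- h_star
  attr(out, "p") <- p
  class(out) <- c("ad_report", "data.frame")
  out
}

#' Leverage of new samples relative to a trained model's score space
#'
#' @param model a `pls_model`.
#' @param X_new raw spectra on the model grid.
#' @return numeric leverages (using the training `(T'T)^-1` metric).
#' @export
prediction_leverage <- function(model, X_new) {
  X <- if (inherits(X_new, "spectra_set")) X_new$absorbance else as.matrix(X_new)
  Xc <- sweep(X, 2, model$x_means)
  # scores of new samples: t = x R with R = W (P'W)^-1
  R <- model$W %*% solve(crossprod(model$P, model$W))
  Tn <- Xc %*% R
  G <- crossprod(model$scores)
  rowSums((Tn %*% solve(G)) * Tn) + 1 / model$n_train
}

#' Pooled two-sample t statistic from summary data
#'
#' `t = |m1 - m2| / sqrt(sp^2 (1/n1 + 1/n2))` with the pooled variance
#' `sp^2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2)`; the two-tailed
#' critical value at `p = 0.05` accompanies the statistic.
#'
#' @param mean1,sd1,n1 summary statistics of group 1.
#' @param mean2,sd2,n2 summary statistics of group 2.
#' @return list with `t`, `df`, `critical` (two-tailed 0.05), `pass`
#'   (`TRUE` when `t < critical`, i.e. no significant difference).
#' @export
pooled_t_test <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  if (sd1 == 0 && sd2 == 0) stop("both variances are zero")
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  tstat <- abs(mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  crit <- stats::qt(0.975, df)
  list(t = tstat, df = df, critical = crit, pass = tstat < crit)
}

#' Variance-ratio F statistic from summary data
#'
#' `F = sd_num^2 / sd_den^2` with caller-chosen numerator (published
#' comparison tables are not always consistent about which variance goes
#' on top, so the convention is explicit here). The one-tailed critical
#' value at `p = 0.05` with `(n_num - 1, n_den - 1)` degrees of freedom
#' accompanies the statistic.
#'
#' @param sd_num,n_num numerator group SD and size.
#' @param sd_den,n_den denominator group SD and size.
#' @return list with `f`, `df`, `critical`, `pass`.
#' @export
variance_ratio_f <- function(sd_num, n_num, sd_den, n_den) {
  stopifnot(sd_den > 0, sd_num >= 0, n_num >= 2, n_den >= 2)
  f <- sd_num^2 / sd_den^2
  df <- c(n_num - 1, n_den - 1)
  crit <- stats::qf(0.95, df[1], df[2])
  list(f = f, df = df, critical = crit, pass = f < crit)
}

#' Friedman rank test across treatments in matched blocks
#'
#' Rank-based nonparametric ANOVA with average-rank tie handling and the
#' tie-corrected chi-square statistic, referred to a chi-square
#' distribution with `treatments - 1` degrees of freedom.
#'
#' @param scores numeric matrix, blocks x treatments (e.g. replicate
#'   simulations x sampling strategies, entries = RMSEP).
#' @return list with `chisq`, `df`, `p_value`.
#' @export
friedman_test <- function(scores) {
  scores <- as.matrix(scores)
  b <- nrow(scores); k <- ncol(scores)
  if (b < 2L || k < 2L) stop("need at least 2 blocks and 2 treatments")
  ranks <- t(apply(scores, 1L, rank))
  if (any(apply(scores, 1L, function(z) length(unique(z)) == 1L)))
    warning("at least one block is entirely tied; ranks averaged")
  Rj <- colSums(ranks)
  A <- sum(ranks^2)
  C <- b * k * (k + 1)^2 / 4
  denom <- A - C
  chisq <- if (denom <= 0) 0 else (k - 1) * sum((Rj - b * (k + 1) / 2)^2) / denom
  df <- k - 1
  list(chisq = chisq, df = df, p_value = stats::pchisq(chisq, df, lower.tail = FALSE))
}

#' Full validation report for a fitted model on a validation set
#'
#' @param model a `pls_model` or `ann_model`.
#' @param spectra validation `spectra_set` (or raw matrix).
#' @param conc actual concentrations (defaults to the spectra set's).
#' @return nested list: per-response `metrics_report`s plus the prediction
#'   matrix.
#' @export
validation_report <- function(model, spectra, conc = NULL) {
  X <- if (inherits(spectra, "spectra_set")) spectra$absorbance else as.matrix(spectra)
  if (is.null(conc)) {
    stopifnot(inherits(spectra, "spectra_set"))
    conc <- spectra$concentrations
  }
  conc <- as.matrix(conc)
  pred <- predict(model, X)
  per <- lapply(seq_len(ncol(conc)), function(j)
    error_metrics(conc[, j], pred[, j], context = "prediction"))
  names(per) <- colnames(conc) %||% paste0("y", seq_len(ncol(conc)))
  list(metrics = per, predictions = pred,
       rmsep_overall = sqrt(mean((pred - conc)^2)))
}
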