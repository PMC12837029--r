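# NIPALS core: extracts up to max_lv components from centered data,
# stopping early when the residual rank is exhausted. Returns the
# weights/loadings/scores actually attained, so callers decide whether a
# shortfall is an error (fit_pls) or just the end of the CV curve.
nipals_components <- function(E, F, max_lv, tol = 1e-10) {
  n <- nrow(E); p <- ncol(E); q <- ncol(F)
  W <- matrix(0, p, max_lv); P <- matrix(0, p, max_lv)
  Q <- matrix(0, q, max_lv); Tm <- matrix(0, n, max_lv)
  attained <- 0L
  for (a in seq_len(max_lv)) {
    u <- F[, which.max(apply(F, 2, stats::var))]
    if (all(abs(u) < 1e-14)) u <- F[, 1]
    t_old <- rep(Inf, n)
    ok <- TRUE
    repeat {
      w <- crossprod(E, u)
      nw <- sqrt(sum(w^2))
      if (nw < 1e-12 * max(1, sqrt(sum(E^2)))) { ok <- FALSE; break }
      w <- w / nw
      tt <- E %*% w
      qv <- crossprod(F, tt) / sum(tt^2)
      if (q == 1L) break  # single response: one pass is exact
      u <- F %*% qv / sum(qv^2)
      if (sqrt(sum((tt - t_old)^2)) < tol * sqrt(sum(tt^2))) break
      t_old <- tt
    }
    if (!ok) break
    tt2 <- sum(tt^2)
    if (tt2 < 1e-16 * max(1, sum(E^2))) break
    pv <- crossprod(E, tt) / tt2
    qv <- crossprod(F, tt) / tt2
    E <- E - tcrossprod(tt, pv)
    F <- F - tcrossprod(tt, qv)
    W[, a] <- w; P[, a] <- pv; Q[, a] <- qv; Tm[, a] <- tt
    attained <- a
  }
  k <- seq_len(attained)
  list(W = W[, k, drop = FALSE], P = P[, k, drop = FALSE],
       Q = Q[, k, drop = FALSE], Tm = Tm[, k, drop = FALSE],
       attained = attained)
}

# centered-scale coefficient matrix using the first k components
nipals_coef <- function(cmp, k) {
  idx <- seq_len(k)
  W <- cmp$W[, idx, drop = FALSE]; P <- cmp$P[, idx, drop = FALSE]
  Q <- cmp$Q[, idx, drop = FALSE]
  W %*% solve(crossprod(P, W), t(Q))
}

#' Fit a PLS regression model (NIPALS)
#'
#' NIPALS partial least squares with per-component deflation, supporting
#' multi-response Y (PLS2). Inputs are centered internally; the stored
#' means let the model map raw spectra to concentrations at predict time.
#'
#' @param X numeric matrix, samples x wavelengths (raw absorbances), or a
#'   `spectra_set`.
#' @param Y numeric matrix or vector, samples x responses (raw units).
#' @param n_lv number of latent variables (1 to `min(n - 1, p)`).
#' @param tol NIPALS inner-loop convergence tolerance.
#' @return object of class `pls_model` with weights `W`, X-loadings `P`,
#'   Y-loadings `Q`, scores, regression coefficients `B` (centered
#'   scale), the centering means, fitted values and training RMSE per
#'   response.
#' @export
fit_pls <- function(X, Y, n_lv, tol = 1e-10) {
  if (inherits(X, "spectra_set")) X <- X$absorbance
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y))
  n <- nrow(X); p <- ncol(X)
  n_lv <- stop_if_not_scalar_count(n_lv, "n_lv")
  if (n_lv > min(n - 1L, p))
    stop("n_lv exceeds min(samples - 1, wavelengths)")
  xm <- colMeans(X); ym <- colMeans(Y)
  cmp <- nipals_components(sweep(X, 2, xm), sweep(Y, 2, ym), n_lv, tol)
  if (cmp$attained < n_lv)
    stop(sprintf("rank deficiency at component %d", cmp$attained + 1L))
  B <- nipals_coef(cmp, n_lv)
  fitted <- sweep(sweep(X, 2, xm) %*% B, 2, ym, "+")
  structure(list(
    n_lv = n_lv, W = cmp$W, P = cmp$P, Q = cmp$Q, scores = cmp$Tm, B = B,
    x_means = xm, y_means = ym, fitted = fitted,
    rmsec = sqrt(colMeans((fitted - Y)^2)),
    y_names = colnames(Y) %||% paste0("y", seq_len(ncol(Y))),
    n_train = n
  ), class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("PLS model: %d latent variable(s), %d wavelengths, %d response(s)\n",
              x$n_lv, nrow(x$B), ncol(x$B)))
  cat("Training RMSEC:", paste(signif(x$rmsec, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Predict concentrations from a fitted calibration model
#'
#' Applies the stored preprocessing (centering / scaling) and the model
#' map; the model object is never modified.
#'
#' @param object a `pls_model`.
#' @param newdata matrix of raw spectra (samples x wavelengths on the
#'   training grid), or a `spectra_set`.
#' @param ... unused.
#' @return matrix of predicted concentrations.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "spectra_set")) newdata$absorbance else as.matrix(newdata)
  if (ncol(X) != nrow(object$B))
    stop("wavelength grid of newdata does not match the model")
  out <- sweep(sweep(X, 2, object$x_means) %*% object$B, 2, object$y_means, "+")
  colnames(out) <- object$y_names
  out
}

# leave-one-out squared prediction errors for every LV count up to max_lv;
# one NIPALS decomposition per left-out sample covers the whole LV path.
pls_loocv_sqerr <- function(X, Y, max_lv) {
  n <- nrow(X)
  sqerr <- matrix(NA_real_, n, max_lv)
  for (i in seq_len(n)) {
    Xi <- X[-i, , drop = FALSE]; Yi <- Y[-i, , drop = FALSE]
    xm <- colMeans(Xi); ym <- colMeans(Yi)
    cmp <- nipals_components(sweep(Xi, 2, xm), sweep(Yi, 2, ym), max_lv)
    xc <- X[i, ] - xm
    for (k in seq_len(cmp$attained)) {
      pred <- drop(xc %*% nipals_coef(cmp, k)) + ym
      sqerr[i, k] <- sum((pred - Y[i, ])^2)
    }
  }
  sqerr
}

#' Select the PLS latent-variable count by leave-one-out cross-validation
#'
#' Computes RMSECV(k) for k = 1..`max_lv` from n leave-one-out refits and
#' picks, by default, the smallest k whose pooled RMSECV is within one
#' standard error of the curve minimum (`rule = "min"` picks the plain
#' minimiser). When the data rank is below `max_lv` the curve simply ends
#' at the attainable count.
#'
#' @param X,Y training data as in [fit_pls()].
#' @param max_lv largest latent-variable count to try.
#' @param rule `"one_se"` (default) or `"min"`.
#' @return list with `n_lv`, `rmsecv` (k-indexed, pooled over responses),
#'   `rule`, and the per-leave-out-fold squared errors (`sqerr`).
#' @export
select_lv_loocv <- function(X, Y, max_lv, rule = c("one_se", "min")) {
  rule <- match.arg(rule)
  if (inherits(X, "spectra_set")) X <- X$absorbance
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  max_lv <- stop_if_not_scalar_count(max_lv, "max_lv")
  if (max_lv > min(n - 2L, ncol(X)))
    stop("max_lv exceeds the leave-one-out rank bound")
  sqerr <- pls_loocv_sqerr(X, Y, max_lv)
  attained <- which(colSums(is.na(sqerr)) == 0L)
  if (length(attained) == 0L) stop("no latent variable count is attainable")
  max_lv <- max(attained)
  sqerr <- sqerr[, seq_len(max_lv), drop = FALSE]
  q <- ncol(Y)
  rmsecv <- sqrt(colMeans(sqerr) / q)
  kmin <- which.min(rmsecv)
  if (rule == "min") {
    k <- kmin
  } else {
    # SE of the mean squared error, mapped through the sqrt at the minimum
    se_mse <- stats::sd(sqerr[, kmin] / q) / sqrt(n)
    thresh <- sqrt(mean(sqerr[, kmin]) / q + se_mse)
    k <- min(which(rmsecv <= thresh))
  }
  list(n_lv = k, rmsecv = rmsecv, rule = rule, sqerr = sqerr)
}
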