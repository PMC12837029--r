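#' Training configuration for the feed-forward network
#'
#' @param hidden hidden-layer size (default 6 neurons).
#' @param max_epochs training epoch limit (default 400).
#' @param mu_init,mu_raise,mu_lower Levenberg-Marquardt damping schedule:
#'   initial value, factor applied on a rejected step, factor applied on an
#'   accepted step.
#' @param patience early-stopping patience in epochs (default 6).
#' @param val_fraction fraction of samples held out for early stopping
#'   (default 0.1).
#' @param hidden_transfer `"purelin"` (identity, default) or `"tansig"`.
#' @param seed seed for the validation split and weight initialization.
#' @return object of class `ann_config`.
#' @export
ann_config <- function(hidden = 6L, max_epochs = 400L, mu_init = 1e-3,
                       mu_raise = 10, mu_lower = 0.1, patience = 6L,
                       val_fraction = 0.1, hidden_transfer = c("purelin", "tansig"),
                       seed = NULL) {
  hidden <- stop_if_not_scalar_count(hidden, "hidden")
  max_epochs <- stop_if_not_scalar_count(max_epochs, "max_epochs")
  patience <- stop_if_not_scalar_count(patience, "patience")
  stopifnot(mu_init > 0, mu_raise > 1, mu_lower < 1, mu_lower > 0,
            val_fraction > 0, val_fraction < 1)
  structure(list(hidden = hidden, max_epochs = max_epochs, mu_init = mu_init,
                 mu_raise = mu_raise, mu_lower = mu_lower, patience = patience,
                 val_fraction = val_fraction,
                 hidden_transfer = match.arg(hidden_transfer), seed = seed),
            class = "ann_config")
}

transfer_fun <- function(kind) {
  switch(kind,
         purelin = list(f = identity, df = function(z) rep(1, length(z))),
         tansig = list(f = tanh, df = function(z) 1 - tanh(z)^2),
         stop("unknown transfer function"))
}

ann_forward <- function(W1, b1, W2, b2, X, g) {
  Z <- X %*% t(W1) + matrix(b1, nrow(X), length(b1), byrow = TRUE)
  H <- g$f(Z)
  Yhat <- H %*% t(W2) + matrix(b2, nrow(X), length(b2), byrow = TRUE)
  list(Z = Z, H = H, Yhat = Yhat)
}

# Jacobian of the stacked residual vector (sample-major, response-minor)
# with respect to the packed parameter vector (W1, b1, W2, b2).
ann_jacobian <- function(W1, b1, W2, b2, X, g) {
  n <- nrow(X); d <- ncol(X); h <- nrow(W1); q <- nrow(W2)
  fwd <- ann_forward(W1, b1, W2, b2, X, g)
  dH <- matrix(g$df(fwd$Z), n, h)
  nres <- n * q
  npar <- h * d + h + q * h + q
  J <- matrix(0, nres, npar)
  for (o in seq_len(q)) {
    rows <- (seq_len(n) - 1L) * q + o
    # d yhat_o / d W1[j,k] = W2[o,j] * g'(z_j) * x_k
    S <- dH * matrix(W2[o, ], n, h, byrow = TRUE)     # n x h
    for (j in seq_len(h)) {
      cols <- ((j - 1L) * d + 1L):(j * d)
      J[rows, cols] <- S[, j] * X
    }
    J[rows, h * d + seq_len(h)] <- S                  # d/d b1
    J[rows, h * d + h + (o - 1L) * h + seq_len(h)] <- fwd$H  # d/d W2[o, ]
    J[rows, h * d + h + q * h + o] <- 1               # d/d b2[o]
  }
  list(J = J, Yhat = fwd$Yhat)
}

pack_params <- function(W1, b1, W2, b2) c(t(W1)[TRUE], b1, t(W2)[TRUE], b2)

unpack_params <- function(w, d, h, q) {
  i <- 0L
  W1 <- matrix(w[i + seq_len(h * d)], h, d, byrow = TRUE); i <- i + h * d
  b1 <- w[i + seq_len(h)]; i <- i + h
  W2 <- matrix(w[i + seq_len(q * h)], q, h, byrow = TRUE); i <- i + q * h
  b2 <- w[i + seq_len(q)]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

#' Fit a single-hidden-layer network by Levenberg-Marquardt
#'
#' Trains `yhat = f(W2 g(W1 x + b1) + b2)` (output transfer `f` is the
#' identity) to minimise the mean squared error, using damped Gauss-Newton
#' steps `w <- w - (J'J + mu I)^-1 J' e`: the damping `mu` is raised when a
#' step fails to reduce the training MSE (the step is rejected) and
#' lowered on acceptance. A random validation split drives early stopping;
#' the weights with the best validation MSE are kept. Inputs are centered
#' and scaled to unit SD per wavelength, outputs are centered/scaled too;
#' all scaling is stored in the model.
#'
#' @param X raw spectra (samples x wavelengths) or a `spectra_set`.
#' @param Y raw concentrations (samples x responses).
#' @param config an [ann_config()].
#' @return object of class `ann_model` with weights, scaling state and a
#'   training record (`$record`: per-epoch train/validation MSE, accepted
#'   flag, mu, and `stop_epoch`).
#' @export
fit_ann <- function(X, Y, config = ann_config()) {
  if (inherits(X, "spectra_set")) X <- X$absorbance
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y))
  n <- nrow(X); d <- ncol(X); q <- ncol(Y); h <- config$hidden
  if (n < 2L * h)
    warning(sprintf("only %d samples for %d hidden neurons; fit may be unstable",
                    n, h))
  xm <- colMeans(X); xs <- apply(X, 2, stats::sd); xs[xs < 1e-12] <- 1
  ym <- colMeans(Y); ys <- apply(Y, 2, stats::sd); ys[ys < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, xm), 2, xs, "/")
  Ys <- sweep(sweep(Y, 2, ym), 2, ys, "/")
  g <- transfer_fun(config$hidden_transfer)

  state <- with_seed(config$seed, {
    n_val <- max(1L, round(config$val_fraction * n))
    val_idx <- sample.int(n, n_val)
    w <- stats::runif(h * d + h + q * h + q, -0.1, 0.1)
    list(val_idx = val_idx, w = w)
  })
  val_idx <- state$val_idx
  tr_idx <- setdiff(seq_len(n), val_idx)
  Xtr <- Xs[tr_idx, , drop = FALSE]; Ytr <- Ys[tr_idx, , drop = FALSE]
  Xva <- Xs[val_idx, , drop = FALSE]; Yva <- Ys[val_idx, , drop = FALSE]
  w <- state$w
  mu <- config$mu_init
  mse <- function(par, Xm, Ym) {
    pp <- unpack_params(par, d, h, q)
    mean((ann_forward(pp$W1, pp$b1, pp$W2, pp$b2, Xm, g)$Yhat - Ym)^2)
  }
  train_mse <- mse(w, Xtr, Ytr)
  val_mse <- mse(w, Xva, Yva)
  best_val <- val_mse; best_w <- w; best_epoch <- 0L
  rec <- data.frame(epoch = 0L, train_mse = train_mse, val_mse = val_mse,
                    mu = mu, accepted = TRUE)
  stall <- 0L; stop_epoch <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    pp <- unpack_params(w, d, h, q)
    jac <- ann_jacobian(pp$W1, pp$b1, pp$W2, pp$b2, Xtr, g)
    e <- as.vector(t(jac$Yhat - Ytr))  # sample-major, response-minor
    J <- jac$J
    accepted <- FALSE
    for (try in 1:30) {
      step <- tryCatch({
        if (nrow(J) >= ncol(J)) {
          A <- crossprod(J); diag(A) <- diag(A) + mu
          solve(A, crossprod(J, e))
        } else {
          A <- tcrossprod(J); diag(A) <- diag(A) + mu
          crossprod(J, solve(A, e))
        }
      }, error = function(err) NULL)
      if (is.null(step)) { mu <- mu * config$mu_raise; next }
      w_new <- w - as.vector(step)
      new_mse <- mse(w_new, Xtr, Ytr)
      if (is.finite(new_mse) && new_mse <= train_mse) {
        w <- w_new; train_mse <- new_mse
        mu <- max(mu * config$mu_lower, 1e-20)
        accepted <- TRUE
        break
      }
      mu <- mu * config$mu_raise
      if (mu > 1e12) break
    }
    val_mse <- mse(w, Xva, Yva)
    rec <- rbind(rec, data.frame(epoch = epoch, train_mse = train_mse,
                                 val_mse = val_mse, mu = mu,
                                 accepted = accepted))
    stop_epoch <- epoch
    if (val_mse < best_val - 1e-15) {
      best_val <- val_mse; best_w <- w; best_epoch <- epoch; stall <- 0L
    } else stall <- stall + 1L
    if (stall >= config$patience) break
    if (!accepted && mu > 1e12) break
    if (train_mse < 1e-24) { best_w <- w; best_val <- val_mse; break }
  }
  pp <- unpack_params(best_w, d, h, q)
  structure(list(
    W1 = pp$W1, b1 = pp$b1, W2 = pp$W2, b2 = pp$b2,
    hidden_transfer = config$hidden_transfer,
    x_means = xm, x_sds = xs, y_means = ym, y_sds = ys,
    config = config,
    record = list(trace = rec, stop_epoch = stop_epoch,
                  best_epoch = best_epoch, val_idx = val_idx),
    y_names = colnames(Y) %||% paste0("y", seq_len(q))
  ), class = "ann_model")
}

#' @export
print.ann_model <- function(x, ...) {
  cat(sprintf("ANN model: %d-%d-%d (%s hidden transfer), stopped at epoch %d\n",
              ncol(x$W1), nrow(x$W1), nrow(x$W2), x$hidden_transfer,
              x$record$stop_epoch))
  invisible(x)
}

#' @rdname predict.pls_model
#' @export
predict.ann_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "spectra_set")) newdata$absorbance else as.matrix(newdata)
  if (ncol(X) != ncol(object$W1))
    stop("wavelength grid of newdata does not match the model")
  Xs <- sweep(sweep(X, 2, object$x_means), 2, object$x_sds, "/")
  g <- transfer_fun(object$hidden_transfer)
  Ys <- ann_forward(object$W1, object$b1, object$W2, object$b2, Xs, g)$Yhat
  out <- sweep(sweep(Ys, 2, object$y_sds, "*"), 2, object$y_means, "+")
  colnames(out) <- object$y_names
  out
}
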