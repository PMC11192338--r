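# Single-hidden-layer back-propagation network (n_in -> hidden(tanh) -> 1)
# with a Levenberg-Marquardt trainer using the analytic Jacobian. The flat
# parameter vector is the object the whale optimizer searches, so its layout
# is part of the contract:
#   [ W1 (n_in x hidden, column-major) | b1 (hidden) | w2 (hidden) | b2 ]
# giving D = n_in*hidden + 2*hidden + 1 (85 for the 5-input, 12-neuron net).

#' Number of BPNN parameters
#' @param n_in number of input features.
#' @param hidden hidden-layer size.
#' @return flat parameter-vector length.
#' @export
bpnn_n_params <- function(n_in, hidden = 12) n_in * hidden + 2 * hidden + 1

bpnn_unpack <- function(params, n_in, hidden) {
  D <- bpnn_n_params(n_in, hidden)
  if (length(params) != D)
    stop_cgmi("BPNN parameter vector has length %d, expected %d", length(params), D)
  if (any(!is.finite(params))) stop_cgmi("BPNN parameters must be finite")
  i <- n_in * hidden
  list(W1 = matrix(params[1:i], n_in, hidden),
       b1 = params[(i + 1):(i + hidden)],
       w2 = params[(i + hidden + 1):(i + 2 * hidden)],
       b2 = params[D])
}

#' BPNN forward pass
#'
#' `yhat = w2' tanh(W1' x + b1) + b2` per row (tansig == tanh).
#'
#' @param params flat parameter vector (see [bpnn_n_params()] for the layout).
#' @param X numeric matrix of feature rows (already on the training scale).
#' @param hidden hidden-layer size (default 12).
#' @return numeric vector of predictions.
#' @export
bpnn_forward <- function(params, X, hidden = 12) {
  X <- as.matrix(X)
  p <- bpnn_unpack(params, ncol(X), hidden)
  H <- tanh(sweep(X %*% p$W1, 2, p$b1, `+`))
  as.numeric(H %*% p$w2 + p$b2)
}

# Jacobian of the forward map wrt the flat parameters, n x D.
bpnn_jacobian <- function(params, X, hidden) {
  X <- as.matrix(X)
  n_in <- ncol(X)
  p <- bpnn_unpack(params, n_in, hidden)
  H <- tanh(sweep(X %*% p$W1, 2, p$b1, `+`))
  A <- (1 - H^2) * matrix(p$w2, nrow(X), hidden, byrow = TRUE)
  JW1 <- do.call(cbind, lapply(seq_len(hidden), function(k) X * A[, k]))
  cbind(JW1, A, H, 1)
}

bpnn_mse <- function(params, X, y, hidden) {
  mean((y - bpnn_forward(params, X, hidden))^2)
}

# Validation hold-out rows for early stopping, deterministic in the seed.
# Shared with the WOA wiring so the search never scores the rows the trainer
# monitors.
bpnn_val_split <- function(n, val_fraction = 0.15, seed = NULL) {
  n_val <- floor(val_fraction * n)
  if (n_val < 1) return(integer(0))
  with_seed(if (is.null(seed)) 0L else seed + 7L, sample.int(n, n_val))
}

scale_minmax_fit <- function(X) {
  X <- as.matrix(X)
  lo <- apply(X, 2, min); hi <- apply(X, 2, max)
  rng <- hi - lo
  rng[rng == 0] <- 1         # constant feature maps to 0
  list(lo = lo, rng = rng)
}
scale_minmax_apply <- function(X, sc) {
  sweep(sweep(as.matrix(X), 2, sc$lo, `-`), 2, sc$rng, `/`)
}

#' Train the back-propagation network
#'
#' Minimizes training mean squared error from `init` (uniform in `[-1, 1]`,
#' seeded, if absent). The default trainer is full-batch Levenberg-Marquardt
#' with the analytic Jacobian; `algorithm = "gd"` is a mini-batch
#' gradient-descent fallback honoring `lr` and `batch`.
#'
#' With 85 free parameters and a few dozen plots the network can interpolate
#' its training set, so by default a fraction `val_fraction` of the rows is
#' held out and training stops once held-out MSE has not improved for
#' `max_fail` consecutive accepted steps (the convention of the classic NN
#' toolchains); the best-validation parameters are returned. Training also
#' stops at `maxit` iterations or as soon as the optimized MSE reaches
#' `goal`. `val_fraction = 0` trains on everything and stops on goal/maxit
#' only. The returned parameters never have a worse full-training-set MSE
#' than `init`.
#'
#' Features are min-max scaled to `[0, 1]` internally; the target is used as
#' given (a composite growth index already lives in `[0, 1]`).
#'
#' @param X feature matrix/data.frame; `y` numeric target.
#' @param y numeric target vector.
#' @param hidden hidden neurons (default 12).
#' @param maxit maximum iterations (default 1000).
#' @param goal MSE stopping target (default 1e-4).
#' @param lr learning rate for the gradient-descent fallback (default 0.1).
#' @param batch mini-batch size for the fallback (default 9).
#' @param init optional flat parameter start vector.
#' @param seed seed for the random start and the validation split.
#' @param algorithm `"lm"` (default) or `"gd"`.
#' @param val_fraction fraction of rows held out for early stopping
#'   (default 0.15; 0 disables).
#' @param max_fail early-stopping patience (default 6).
#' @return object of class `cgmi_bpnn` with the fitted flat parameters, the
#'   per-iteration loss trace, and the feature scaling.
#' @export
train_bpnn <- function(X, y, hidden = 12, maxit = 1000, goal = 1e-4,
                       lr = 0.1, batch = 9, init = NULL, seed = NULL,
                       algorithm = c("lm", "gd"),
                       val_fraction = 0.15, max_fail = 6) {
  algorithm <- match.arg(algorithm)
  X <- as.matrix(X)
  if (!all(is.finite(X)) || !all(is.finite(y))) stop_cgmi("non-finite training data")
  if (nrow(X) != length(y)) stop_cgmi("X and y disagree on sample count")
  D <- bpnn_n_params(ncol(X), hidden)
  n <- nrow(X)
  if (n < 2 * D / 10)
    warning(sprintf("only %d samples for %d parameters; fit may be unstable",
                    n, D), call. = FALSE)
  sc <- scale_minmax_fit(X)
  Xs <- scale_minmax_apply(X, sc)
  if (is.null(init)) init <- with_seed(seed, stats::runif(D, -1, 1))
  params <- init

  val_idx <- if (algorithm == "lm") bpnn_val_split(n, val_fraction, seed)
             else integer(0)
  n_val <- length(val_idx)
  fit_idx <- setdiff(seq_len(n), val_idx)
  Xf <- Xs[fit_idx, , drop = FALSE]; yf <- y[fit_idx]
  Xv <- Xs[val_idx, , drop = FALSE]; yv <- y[val_idx]

  mse <- bpnn_mse(params, Xf, yf, hidden)
  trace <- mse
  best_params <- params
  best_val <- if (n_val) bpnn_mse(params, Xv, yv, hidden) else Inf
  fails <- 0L

  if (algorithm == "lm") {
    lambda <- 0.01
    it <- 0
    while (it < maxit && mse > goal) {
      Fm <- bpnn_jacobian(params, Xf, hidden)
      e <- yf - bpnn_forward(params, Xf, hidden)
      FtF <- crossprod(Fm)
      Fte <- crossprod(Fm, e)
      dmarq <- pmax(diag(FtF), 1e-8)
      improved <- FALSE
      while (!improved && lambda <= 1e10) {
        delta <- tryCatch(
          solve(FtF + lambda * diag(dmarq, length(dmarq)), Fte),
          error = function(e2) NULL)
        if (!is.null(delta)) {
          cand <- params + as.numeric(delta)
          cmse <- bpnn_mse(cand, Xf, yf, hidden)
          if (is.finite(cmse) && cmse < mse) {
            params <- cand; mse <- cmse
            lambda <- max(lambda * 0.2, 1e-12)
            improved <- TRUE
          }
        }
        if (!improved) lambda <- lambda * 10
      }
      it <- it + 1
      trace <- c(trace, mse)
      if (!improved) break                       # damping exhausted: converged
      if (!is.finite(mse)) stop_cgmi("BPNN training diverged (non-finite loss)")
      if (n_val) {
        vmse <- bpnn_mse(params, Xv, yv, hidden)
        if (vmse < best_val) {
          best_val <- vmse; best_params <- params; fails <- 0L
        } else {
          fails <- fails + 1L
          if (fails >= max_fail) break           # validation stopped improving
        }
      }
    }
    if (n_val) params <- best_params
    mse <- bpnn_mse(params, Xf, yf, hidden)   # loss of the returned iterate
  } else {
    n <- nrow(Xs)
    rng_seed <- if (is.null(seed)) 0L else seed
    with_seed(rng_seed + 1L, {
      it <- 0
      while (it < maxit && mse > goal) {
        ord <- sample.int(n)
        for (start in seq(1, n, by = batch)) {
          idx <- ord[start:min(start + batch - 1, n)]
          Fm <- bpnn_jacobian(params, Xs[idx, , drop = FALSE], hidden)
          e <- y[idx] - bpnn_forward(params, Xs[idx, , drop = FALSE], hidden)
          params <- params + lr * 2 / length(idx) * as.numeric(crossprod(Fm, e))
        }
        mse <- bpnn_mse(params, Xs, y, hidden)
        if (!is.finite(mse)) stop_cgmi("BPNN training diverged (non-finite loss)")
        it <- it + 1
        trace <- c(trace, mse)
      }
    })
  }

  # monotone acceptance wrt the provided start, on the full training set
  full_mse <- bpnn_mse(params, Xs, y, hidden)
  init_mse <- bpnn_mse(init, Xs, y, hidden)
  if (full_mse > init_mse) {
    params <- init; full_mse <- init_mse
  }
  structure(list(params = params, hidden = hidden, n_in = ncol(X),
                 scaling = sc, trace = trace, iterations = length(trace) - 1L,
                 final_mse = full_mse, fit_mse = mse, goal = goal,
                 reached_goal = mse <= goal, n_val = n_val,
                 feature_names = colnames(X)),
            class = c("cgmi_bpnn", "cgmi_model"))
}

#' @export
predict.cgmi_bpnn <- function(object, newdata, ...) {
  X <- as.matrix(if (is.data.frame(newdata) && !is.null(object$feature_names))
    newdata[, object$feature_names, drop = FALSE] else newdata)
  bpnn_forward(object$params, scale_minmax_apply(X, object$scaling), object$hidden)
}
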