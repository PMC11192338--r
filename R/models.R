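# Baseline regressors with the reference hyperparameters:
#   MLR   ordinary least squares with intercept
#   PLS   2-component partial least squares (NIPALS, PLS1)
#   SVR   eps-insensitive, RBF kernel, penalty 20, kernel parameter 30
#   RF    100 trees, minimum leaf size 4
#   RBFNN incremental radial basis network, spread 100
#   BPNN  see models-bpnn.R
# SVR and RF go through e1071 / randomForest; PLS and RBFNN are implemented
# here (no PLS or RBF-network package is part of this stack).

MODEL_NAMES <- c("MLR", "PLS", "SVR", "RF", "RBFNN", "BPNN")

default_hyperparams <- function(name) {
  switch(name,
    MLR   = list(),
    PLS   = list(ncomp = 2),
    SVR   = list(cost = 20, rbf_param = 30, epsilon = 0.01),
    RF    = list(ntree = 100, nodesize = 4),
    RBFNN = list(spread = 100, max_centers = 25, goal = 1e-4),
    BPNN  = list(hidden = 12, maxit = 1000, goal = 1e-4, lr = 0.1, batch = 9,
                 algorithm = "lm"))
}

#' Model configuration
#'
#' @param name one of `MLR, PLS, SVR, RF, RBFNN, BPNN`.
#' @param ... hyperparameter overrides; unknown keys are rejected.
#' @param seed seed for stochastic fits (RF bootstrap, BPNN start).
#' @return object of class `cgmi_model_config`.
#' @export
model_config <- function(name, ..., seed = NULL) {
  name <- match.arg(name, MODEL_NAMES)
  hp <- default_hyperparams(name)
  over <- list(...)
  bad <- setdiff(names(over), names(hp))
  if (length(bad))
    stop_cgmi("unknown hyperparameter(s) for %s: %s", name, toString(bad))
  hp[names(over)] <- over
  num <- hp[vapply(hp, is.numeric, TRUE)]
  if (any(unlist(num) <= 0)) stop_cgmi("hyperparameters must be positive")
  structure(list(name = name, hyperparams = hp, seed = seed),
            class = "cgmi_model_config")
}

#' Fit one of the benchmark regressors
#'
#' @param name model name (see [model_config()]).
#' @param X_train feature data.frame/matrix (>= 5 rows).
#' @param y_train numeric target.
#' @param config optional [model_config()]; defaults to the reference
#'   hyperparameters for `name`.
#' @param seed convenience override for `config$seed`.
#' @return fitted model of class `cgmi_model`; use `predict()` on it.
#' @export
fit_model <- function(name, X_train, y_train, config = NULL, seed = NULL) {
  if (is.null(config)) config <- model_config(name, seed = seed)
  stopifnot(inherits(config, "cgmi_model_config"))
  if (!is.null(seed)) config$seed <- seed
  if (config$name != name) stop_cgmi("config is for %s, not %s", config$name, name)
  X <- as.data.frame(X_train)
  if (nrow(X) < 5) stop_cgmi("need at least 5 training rows")
  if (nrow(X) != length(y_train)) stop_cgmi("X and y disagree on sample count")
  hp <- config$hyperparams
  fit <- switch(name,
    MLR = fit_mlr(X, y_train),
    PLS = fit_pls(X, y_train, ncomp = hp$ncomp),
    SVR = {
      m <- e1071::svm(as.matrix(X), y_train, type = "eps-regression",
                      kernel = "radial", cost = hp$cost,
                      gamma = 1 / hp$rbf_param^2, epsilon = hp$epsilon)
      structure(list(svm = m, feature_names = names(X)),
                class = c("cgmi_svr", "cgmi_model"))
    },
    RF = with_seed(if (is.null(config$seed)) 0L else config$seed, {
      m <- randomForest::randomForest(as.matrix(X), y_train,
                                      ntree = hp$ntree, nodesize = hp$nodesize)
      structure(list(rf = m, feature_names = names(X)),
                class = c("cgmi_rf", "cgmi_model"))
    }),
    RBFNN = fit_rbfnn(X, y_train, spread = hp$spread,
                      max_centers = hp$max_centers, goal = hp$goal),
    BPNN = train_bpnn(X, y_train, hidden = hp$hidden, maxit = hp$maxit,
                      goal = hp$goal, lr = hp$lr, batch = hp$batch,
                      seed = config$seed, algorithm = hp$algorithm))
  fit$model_name <- name
  fit
}

# --- MLR ---------------------------------------------------------------

fit_mlr <- function(X, y) {
  M <- cbind(`(Intercept)` = 1, as.matrix(X))
  qrM <- qr(M)
  if (qrM$rank < ncol(M)) {
    drop <- colnames(M)[qrM$pivot[(qrM$rank + 1):ncol(M)]]
    stop_cgmi("singular design; collinear column(s): %s", toString(drop))
  }
  df <- data.frame(.y = y, X, check.names = FALSE)
  m <- stats::lm(.y ~ ., data = df)
  structure(list(lm = m, feature_names = names(X)),
            class = c("cgmi_mlr", "cgmi_model"))
}

#' @export
predict.cgmi_mlr <- function(object, newdata, ...) {
  nd <- as.data.frame(newdata)[, object$feature_names, drop = FALSE]
  unname(stats::predict(object$lm, newdata = nd))
}

#' @export
predict.cgmi_svr <- function(object, newdata, ...) {
  nd <- as.matrix(as.data.frame(newdata)[, object$feature_names, drop = FALSE])
  unname(stats::predict(object$svm, nd))
}

#' @export
predict.cgmi_rf <- function(object, newdata, ...) {
  nd <- as.matrix(as.data.frame(newdata)[, object$feature_names, drop = FALSE])
  unname(stats::predict(object$rf, nd))
}

# --- PLS (NIPALS, single response) -------------------------------------

fit_pls <- function(X, y, ncomp = 2) {
  Xm <- as.matrix(X)
  if (ncomp < 1 || ncomp > min(nrow(Xm) - 1, ncol(Xm)))
    stop_cgmi("ncomp must lie in [1, min(n-1, p)]")
  xbar <- colMeans(Xm); ybar <- mean(y)
  E <- sweep(Xm, 2, xbar); f <- y - ybar
  W <- P <- matrix(0, ncol(Xm), ncomp)
  q <- numeric(ncomp)
  for (h in seq_len(ncomp)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { ncomp <- h - 1L; break }   # residual exhausted
    w <- w / nw
    t_ <- E %*% w
    tt <- sum(t_^2)
    p <- crossprod(E, t_) / tt
    qh <- sum(f * t_) / tt
    E <- E - t_ %*% t(p)
    f <- f - qh * t_
    W[, h] <- w; P[, h] <- p; q[h] <- qh
  }
  W <- W[, seq_len(ncomp), drop = FALSE]
  P <- P[, seq_len(ncomp), drop = FALSE]
  q <- q[seq_len(ncomp)]
  beta <- W %*% solve(crossprod(P, W), q)
  structure(list(beta = as.numeric(beta),
                 intercept = ybar - sum(xbar * beta),
                 ncomp = ncomp, feature_names = names(X)),
            class = c("cgmi_pls", "cgmi_model"))
}

#' @export
predict.cgmi_pls <- function(object, newdata, ...) {
  nd <- as.matrix(as.data.frame(newdata)[, object$feature_names, drop = FALSE])
  as.numeric(nd %*% object$beta + object$intercept)
}

# --- RBFNN (incremental center addition, Gaussian basis) ----------------
# Gaussian width follows the classic spread convention: the basis drops to
# 0.5 at distance `spread` from its center, phi(d) = exp(-(0.8326 d / spread)^2).

fit_rbfnn <- function(X, y, spread = 100, max_centers = 25, goal = 1e-4) {
  Xm <- as.matrix(X)
  n <- nrow(Xm)
  max_centers <- min(max_centers, n)
  bw <- sqrt(-log(0.5)) / spread
  centers <- matrix(numeric(0), 0, ncol(Xm))
  pick <- integer(0)
  err <- y - mean(y)
  w <- c(mean(y))                                 # bias-only start
  for (k in seq_len(max_centers)) {
    cand <- setdiff(order(-abs(err)), pick)[1]    # worst-fit training point
    pick <- c(pick, cand)
    centers <- Xm[pick, , drop = FALSE]
    Phi <- rbf_design(Xm, centers, bw)
    # wide spreads make the basis near-collinear; lm.fit handles the
    # rank-deficient solve, aliased weights are zeroed
    fit <- stats::lm.fit(cbind(1, Phi), y)
    w <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
    err <- fit$residuals
    if (mean(err^2) <= goal) break
  }
  structure(list(centers = centers, bw = bw, weights = w,
                 feature_names = names(X), final_mse = mean(err^2)),
            class = c("cgmi_rbfnn", "cgmi_model"))
}

rbf_design <- function(X, centers, bw) {
  d2 <- outer(rowSums(X^2), rep(1, nrow(centers))) +
    outer(rep(1, nrow(X)), rowSums(centers^2)) - 2 * X %*% t(centers)
  exp(-(bw^2) * pmax(d2, 0))
}

#' @export
predict.cgmi_rbfnn <- function(object, newdata, ...) {
  nd <- as.matrix(as.data.frame(newdata)[, object$feature_names, drop = FALSE])
  Phi <- rbf_design(nd, object$centers, object$bw)
  as.numeric(cbind(1, Phi) %*% object$weights)
}
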