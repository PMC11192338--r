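# Whale optimization algorithm: a population metaheuristic for bounded
# continuous minimization mimicking humpback bubble-net hunting. Each
# iteration every agent either encircles a leader (the best agent while the
# coefficient |A| < 1, a random agent otherwise -- the exploration branch) or
# follows a logarithmic spiral around the best agent; the shrinking
# coefficient a falls linearly from 2 to 0 over the run. Coefficient draws
# are per dimension, as in the original formulation.

#' WOA configuration
#'
#' @param pop population size (reference protocol: 10).
#' @param iters maximum iterations T (reference protocol: 60).
#' @param lower,upper box bounds, scalar or per-dimension.
#' @param b logarithmic-spiral shape constant (default 1).
#' @param seed integer seed; runs are deterministic given it.
#' @param explore keep the random-agent exploration branch (default TRUE);
#'   `FALSE` always encircles the best agent (ablation).
#' @return object of class `cgmi_woa_config`.
#' @export
woa_config <- function(pop = 10, iters = 60, lower = -1, upper = 1,
                       b = 1, seed = NULL, explore = TRUE) {
  if (pop < 2) stop_cgmi("population must be >= 2")
  if (iters < 1) stop_cgmi("iters must be >= 1")
  if (any(lower >= upper)) stop_cgmi("need lower < upper bounds")
  structure(list(pop = as.integer(pop), iters = as.integer(iters),
                 lower = lower, upper = upper, b = b, seed = seed,
                 explore = isTRUE(explore)),
            class = "cgmi_woa_config")
}

# Logarithmic-spiral (bubble-net) update: x' = best + |best - x| e^{bl} cos(2*pi*l).
# At l = 0 this reduces to best + |best - x|.
woa_spiral_step <- function(best, x, b, l) {
  best + abs(best - x) * exp(b * l) * cos(2 * pi * l)
}

#' Minimize a function over a box with the whale optimization algorithm
#'
#' @param objective function mapping a length-`dim` numeric vector to a
#'   finite scalar.
#' @param dim problem dimension.
#' @param config a [woa_config()].
#' @return list of class `cgmi_woa_result`: `best` (position), `best_fitness`,
#'   and `trace` (best fitness after initialization and after each iteration;
#'   length `iters + 1`, monotone non-increasing).
#' @export
woa_minimize <- function(objective, dim, config = woa_config()) {
  stopifnot(inherits(config, "cgmi_woa_config"))
  lo <- rep_len(config$lower, dim)
  hi <- rep_len(config$upper, dim)
  pop <- config$pop; T <- config$iters; b <- config$b

  with_seed(config$seed, {
    X <- matrix(stats::runif(pop * dim, rep(lo, each = pop), rep(hi, each = pop)),
                pop, dim)
    fit <- apply(X, 1, objective)
    if (any(!is.finite(fit)))
      stop_cgmi("objective non-finite at initial position (%s)",
                toString(signif(X[which(!is.finite(fit))[1], ], 4)))
    ibest <- which.min(fit)
    best <- X[ibest, ]; best_fit <- fit[ibest]
    trace <- best_fit

    for (t in seq_len(T)) {
      a <- 2 - 2 * t / T
      for (i in seq_len(pop)) {
        x <- X[i, ]
        p <- stats::runif(1)
        if (p < 0.5) {
          A <- 2 * a * stats::runif(dim) - a
          C <- 2 * stats::runif(dim)
          ref <- best
          if (config$explore) {
            xr <- X[sample.int(pop, 1), ]
            exploring <- abs(A) >= 1               # per-dimension switch
            ref <- ifelse(exploring, xr, best)
          }
          step <- abs(C * ref - x)                 # encircling step
          xnew <- ref - A * step
        } else {
          xnew <- woa_spiral_step(best, x, b, stats::runif(1, -1, 1))
        }
        X[i, ] <- pmin(pmax(xnew, lo), hi)
      }
      fit <- apply(X, 1, objective)
      if (any(!is.finite(fit))) fit[!is.finite(fit)] <- Inf
      ibest <- which.min(fit)
      if (fit[ibest] < best_fit) {                 # greedy leader update
        best_fit <- fit[ibest]; best <- X[ibest, ]
      }
      trace <- c(trace, best_fit)
    }
    structure(list(best = best, best_fitness = best_fit, trace = trace),
              class = "cgmi_woa_result")
  })
}

#' WOA-initialised back-propagation network
#'
#' Searches the flat BPNN weight/threshold vector (dimension
#' `bpnn_n_params(ncol(X), hidden)`, 85 for five inputs) inside
#' `[-1, 1]` per dimension, scoring each position by the raw network's
#' training MSE (no inner training during the search). The best position then
#' seeds the Levenberg-Marquardt trainer, replacing its random start.
#'
#' @param X_train,y_train training data (features on their natural scale;
#'   min-max scaling is applied internally, identically to [train_bpnn()]).
#' @param woa a [woa_config()] (reference protocol: pop 10, iters 60).
#' @param bpnn a [model_config()] for `"BPNN"`, or NULL for defaults.
#' @return object of class `cgmi_woa_bpnn`: the refined `cgmi_bpnn` model
#'   (`$model`) plus the WOA search result (`$woa`). `predict()` delegates to
#'   the refined model.
#' @export
woa_bpnn <- function(X_train, y_train, woa = woa_config(), bpnn = NULL) {
  if (is.null(bpnn)) bpnn <- model_config("BPNN")
  stopifnot(inherits(bpnn, "cgmi_model_config"), bpnn$name == "BPNN")
  hp <- bpnn$hyperparams
  X <- as.matrix(X_train)
  sc <- scale_minmax_fit(X)
  Xs <- scale_minmax_apply(X, sc)
  dim <- bpnn_n_params(ncol(X), hp$hidden)
  # score only the rows the trainer will fit: its validation monitor must
  # stay unseen by the search
  val_idx <- bpnn_val_split(nrow(Xs), seed = woa$seed)
  fit_idx <- setdiff(seq_len(nrow(Xs)), val_idx)
  Xfit <- Xs[fit_idx, , drop = FALSE]; yfit <- y_train[fit_idx]
  fitness <- function(pos) bpnn_mse(pos, Xfit, yfit, hp$hidden)
  search <- woa_minimize(fitness, dim, woa)
  model <- train_bpnn(X_train, y_train, hidden = hp$hidden, maxit = hp$maxit,
                      goal = hp$goal, lr = hp$lr, batch = hp$batch,
                      init = search$best, seed = woa$seed,
                      algorithm = hp$algorithm)
  model$model_name <- "WOA-BPNN"
  structure(list(model = model, woa = search),
            class = c("cgmi_woa_bpnn", "cgmi_model"))
}

#' @export
predict.cgmi_woa_bpnn <- function(object, newdata, ...) {
  predict(object$model, newdata, ...)
}
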