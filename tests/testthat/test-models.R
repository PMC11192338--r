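test_that("bpnn forward pass matches scalar hand computation", {
  # 1-input, 1-hidden toy: params = (w1, b1, w2, b2)
  expect_equal(bpnn_forward(c(1, 0, 2, 0.5), matrix(0.5), hidden = 1),
               2 * tanh(0.5) + 0.5, tolerance = 1e-12)
  # all-zero params: prediction identically 0
  D <- bpnn_n_params(5, 12)
  expect_equal(D, 85)
  X <- matrix(runif(20 * 5), 20, 5)
  expect_equal(bpnn_forward(rep(0, D), X), rep(0, 20))
  # only the output bias set: constant prediction
  p <- rep(0, D); p[D] <- 0.7
  expect_equal(bpnn_forward(p, X), rep(0.7, 20))
  expect_error(bpnn_forward(rep(0, 10), X), "length")
})

test_that("analytic Jacobian agrees with finite differences", {
  set.seed(2)
  X <- matrix(runif(6 * 2), 6, 2)
  params <- runif(bpnn_n_params(2, 3), -1, 1)
  J <- cgmi:::bpnn_jacobian(params, X, 3)
  eps <- 1e-6
  Jnum <- sapply(seq_along(params), function(k) {
    up <- params; up[k] <- up[k] + eps
    dn <- params; dn[k] <- dn[k] - eps
    (bpnn_forward(up, X, 3) - bpnn_forward(dn, X, 3)) / (2 * eps)
  })
  expect_equal(J, Jnum, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("L-M training reaches the goal on clean data and is deterministic", {
  set.seed(42)
  X <- matrix(runif(90 * 3), 90, 3)
  y <- as.numeric(X %*% c(2, -1, 0.5)) + 0.1
  m1 <- train_bpnn(X, y, seed = 1)
  expect_true(m1$reached_goal)
  expect_lt(m1$fit_mse, 1e-4)
  m2 <- train_bpnn(X, y, seed = 1)
  expect_identical(m1$trace, m2$trace)
  # training loss trace is monotone non-increasing
  expect_true(all(diff(m1$trace) <= 1e-12))
})

test_that("training with zero additional iterations returns the start unchanged", {
  set.seed(3)
  X <- matrix(runif(40 * 2), 40, 2)
  y <- sin(3 * X[, 1])
  base <- train_bpnn(X, y, hidden = 4, seed = 5)
  again <- train_bpnn(X, y, hidden = 4, maxit = 0, init = base$params)
  expect_equal(predict(again, X), predict(base, X), tolerance = 1e-12)
})

test_that("our L-M trainer tracks an independent Levenberg-Marquardt solver", {
  set.seed(7)
  X <- matrix(runif(30 * 2), 30, 2)
  y <- sin(3 * X[, 1]) + X[, 2]
  ours <- train_bpnn(X, y, hidden = 3, seed = 3, val_fraction = 0)
  D <- bpnn_n_params(2, 3)
  init <- cgmi:::with_seed(3, runif(D, -1, 1))
  sc <- cgmi:::scale_minmax_fit(X)
  Xs <- cgmi:::scale_minmax_apply(X, sc)
  ref <- minpack.lm::nls.lm(init, fn = function(p) y - bpnn_forward(p, Xs, 3),
                            control = minpack.lm::nls.lm.control(maxiter = 1000))
  expect_equal(ours$final_mse, mean(residuals(ref)^2), tolerance = 0.05)
})

test_that("gradient-descent fallback honors batch training and reduces loss", {
  set.seed(8)
  X <- matrix(runif(45 * 2), 45, 2)
  y <- as.numeric(X %*% c(1, -1))
  m <- train_bpnn(X, y, hidden = 4, maxit = 200, algorithm = "gd", seed = 2)
  expect_lt(m$final_mse, m$trace[1])
  expect_identical(m$trace,
                   train_bpnn(X, y, hidden = 4, maxit = 200,
                              algorithm = "gd", seed = 2)$trace)
})

test_that("MLR recovers exact coefficients and flags collinearity", {
  set.seed(9)
  X <- data.frame(x1 = runif(20), x2 = runif(20))
  y <- 3 * X$x1 - 2 * X$x2 + 1
  m <- fit_model("MLR", X, y)
  expect_equal(unname(coef(m$lm)), c(1, 3, -2), tolerance = 1e-8)
  X$x3 <- 2 * X$x1
  expect_error(fit_model("MLR", X, y), "x3")
})

test_that("PLS saturates to OLS at full rank and a 1-component fit is sane", {
  set.seed(10)
  X <- as.data.frame(matrix(rnorm(40 * 3), 40, 3))
  y <- rnorm(40)
  pls <- fit_model("PLS", X, y, config = model_config("PLS", ncomp = 3))
  mlr <- fit_model("MLR", X, y)
  expect_equal(predict(pls, X), predict(mlr, X), tolerance = 1e-6)
  # one NIPALS component on X with a single informative direction recovers it
  t_ <- rnorm(50)
  X1 <- data.frame(a = t_ + rnorm(50, sd = 1e-3), b = -t_ + rnorm(50, sd = 1e-3))
  y1 <- 2 * t_
  p1 <- fit_model("PLS", X1, y1, config = model_config("PLS", ncomp = 1))
  expect_gt(r2_conventional(predict(p1, X1), y1), 0.999)
})

test_that("RF reproduces a noise-free step function at training points", {
  X <- data.frame(x = seq(0, 1, length.out = 20))
  y <- ifelse(X$x < 0.5, 1, 3)
  m <- suppressWarnings(fit_model("RF", X, y, seed = 1))
  pr <- predict(m, X)
  expect_true(all(abs(pr[X$x < 0.35] - 1) < 0.5))
  expect_true(all(abs(pr[X$x > 0.65] - 3) < 0.5))
  # seeded: refitting gives identical predictions
  expect_equal(pr, predict(suppressWarnings(fit_model("RF", X, y, seed = 1)), X))
})

test_that("SVR and RBFNN mechanisms fit a smooth nonlinear target", {
  # kernel widths matched to the unit-interval toy; the reference spread of
  # 100 is meant for wider feature scales and underfits here by design
  set.seed(11)
  X <- data.frame(x = runif(60))
  y <- 0.5 + 0.3 * sin(2 * pi * X$x)
  sv <- fit_model("SVR", X, y, config = model_config("SVR", rbf_param = 0.5))
  expect_gt(r2_conventional(predict(sv, X), y), 0.9)
  rb <- fit_model("RBFNN", X, y, config = model_config("RBFNN", spread = 0.3))
  expect_gt(r2_conventional(predict(rb, X), y), 0.9)
  # reference hyperparameters still give finite, sane predictions
  for (name in c("SVR", "RBFNN")) {
    m <- suppressWarnings(fit_model(name, X, y))
    expect_true(all(is.finite(predict(m, X))))
  }
})

test_that("every model achieves non-negative training R2 on clean linear data", {
  set.seed(12)
  X <- as.data.frame(matrix(runif(60 * 5), 60, 5))
  names(X) <- paste0("v", 1:5)
  y <- as.numeric(as.matrix(X) %*% c(0.2, 0.1, -0.1, 0.3, 0.2)) + 0.3
  for (name in c("MLR", "PLS", "SVR", "RF", "RBFNN", "BPNN")) {
    m <- suppressWarnings(fit_model(name, X, y, seed = 3))
    expect_gte(r2_ratio(predict(m, X), y), 0)
  }
})

test_that("model configs validate names and hyperparameters", {
  expect_error(model_config("XGB"), "arg")
  expect_error(model_config("RF", banana = 2), "banana")
  expect_error(model_config("SVR", cost = -1), "positive")
  cfg <- model_config("BPNN", hidden = 6)
  expect_equal(cfg$hyperparams$hidden, 6)
  expect_error(fit_model("RF", data.frame(x = 1:3), 1:3), "at least 5")
})
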