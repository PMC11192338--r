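# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
stop_cgmi <- function(...) stop(sprintf(...), call. = FALSE)

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# Derive a stable sub-seed (< 2^31) from a master seed and a stage label, so
# stage-level reruns are reproducible independently of execution order.
#' @keywords internal
#' @noRd
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.double(seed) * 1009 + h) %% .Machine$integer.max)
}

#' Coefficient of variation
#'
#' Standard deviation divided by the mean. The population convention
#' (divide by `n`) is the default; `sample = TRUE` uses `n - 1`.
#'
#' @param x numeric vector with positive mean.
#' @param sample logical; use the sample (n-1) standard deviation.
#' @return scalar CV.
#' @export
coef_var <- function(x, sample = FALSE) {
  if (length(x) < 2) stop_cgmi("coef_var needs at least 2 values")
  m <- mean(x)
  if (m == 0) stop_cgmi("coef_var: mean is zero")
  s <- stats::sd(x)
  if (!sample) s <- s * sqrt((length(x) - 1) / length(x))
  s / m
}
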