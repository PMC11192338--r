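# Accuracy metrics and the train/test protocol.
#
# Two R-squared flavours are reported side by side: the ratio form
# SSR/SST = sum((pred - mean(obs))^2) / sum((obs - mean(obs))^2), which is
# not bounded above by 1 for arbitrary predictions, and the conventional
# 1 - SSE/SST. NRMSE normalizes RMSE by the range of the PREDICTED values by
# default (the convention the reference protocol prints); observed-range
# normalization is available via `denom = "observed"`.

#' Ratio-form R-squared (regression sum of squares over total)
#' @param pred,obs numeric vectors of equal length >= 2; `obs` non-constant.
#' @return scalar; equals 1 for perfect prediction, can exceed 1.
#' @export
r2_ratio <- function(pred, obs) {
  check_pair(pred, obs)
  bbar <- mean(obs)
  sst <- sum((obs - bbar)^2)
  if (sst == 0) stop_cgmi("constant observations: R-squared undefined")
  sum((pred - bbar)^2) / sst
}

#' Conventional R-squared (1 - SSE/SST)
#' @inheritParams r2_ratio
#' @export
r2_conventional <- function(pred, obs) {
  check_pair(pred, obs)
  sst <- sum((obs - mean(obs))^2)
  if (sst == 0) stop_cgmi("constant observations: R-squared undefined")
  1 - sum((obs - pred)^2) / sst
}

#' Root mean square error
#' @inheritParams r2_ratio
#' @export
rmse <- function(pred, obs) {
  check_pair(pred, obs)
  sqrt(mean((pred - obs)^2))
}

#' Normalized RMSE
#' @inheritParams r2_ratio
#' @param denom `"predicted"` (default) divides by the predicted range,
#'   `"observed"` by the observed range.
#' @export
nrmse <- function(pred, obs, denom = c("predicted", "observed")) {
  denom <- match.arg(denom)
  v <- if (denom == "predicted") pred else obs
  rng <- max(v) - min(v)
  if (rng == 0) stop_cgmi("zero %s range: NRMSE undefined", denom)
  rmse(pred, obs) / rng
}

#' Mean absolute percentage error (in percent)
#' @inheritParams r2_ratio
#' @export
mape <- function(pred, obs) {
  check_pair(pred, obs)
  if (any(obs == 0))
    stop_cgmi("zero observation at row %d: MAPE undefined", which(obs == 0)[1])
  100 * mean(abs((pred - obs) / obs))
}

check_pair <- function(pred, obs) {
  if (length(pred) != length(obs)) stop_cgmi("pred and obs differ in length")
  if (length(obs) < 2) stop_cgmi("need at least 2 observations")
  if (any(!is.finite(pred)) || any(!is.finite(obs)))
    stop_cgmi("non-finite values in pred/obs")
  invisible(TRUE)
}

#' Seeded random train/test partition
#'
#' @param n_total total sample count.
#' @param n_train training-set size (reference protocol: 52 of 66).
#' @param seed integer seed.
#' @return list with integer vectors `train` and `test`; disjoint, exhaustive.
#' @export
split_data <- function(n_total, n_train, seed = NULL) {
  if (n_train < 1 || n_train >= n_total)
    stop_cgmi("need 1 <= n_train < n_total (got %d of %d)", n_train, n_total)
  train <- sort(with_seed(seed, sample.int(n_total, n_train)))
  list(train = train, test = setdiff(seq_len(n_total), train))
}

#' All metrics for one prediction/observation pair
#' @inheritParams r2_ratio
#' @return named list: `r2_ratio`, `r2`, `rmse`, `nrmse`, `mape`.
#' @export
evaluate_predictions <- function(pred, obs) {
  list(r2_ratio = r2_ratio(pred, obs), r2 = r2_conventional(pred, obs),
       rmse = rmse(pred, obs), nrmse = nrmse(pred, obs), mape = mape(pred, obs))
}

#' Train/test accuracy table for a set of fitted models
#'
#' @param fits named list of fitted `cgmi_model` objects.
#' @param X feature data.frame (all plots); `y` target vector.
#' @param y numeric target vector, aligned with `X`.
#' @param split a [split_data()] partition.
#' @return data.frame: one row per model x set with all metrics.
#' @export
eval_report <- function(fits, X, y, split) {
  rows <- lapply(names(fits), function(nm) {
    do.call(rbind, lapply(c("train", "test"), function(set) {
      idx <- split[[set]]
      pred <- predict(fits[[nm]], X[idx, , drop = FALSE])
      m <- evaluate_predictions(pred, y[idx])
      data.frame(model = nm, set = set, n = length(idx),
                 r2_ratio = m$r2_ratio, r2 = m$r2, rmse = m$rmse,
                 nrmse = m$nrmse, mape = m$mape)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
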