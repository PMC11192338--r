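# Comprehensive growth monitoring index (CGMI).
#
# Four plot-level indicators (SPAD, plant height, leaf area index, aboveground
# biomass) are min-max normalized to [0,1]; CGMI1 averages them with equal
# weights, CGMI2 weights them by their coefficients of variation (an indicator
# that varies more across plots discriminates growth better and gets more
# weight). CVs are taken on the RAW indicator columns, before normalization:
# min-max scaling would distort the relative dispersion that the weighting is
# meant to capture.

#' Min-max normalization
#'
#' Maps a column affinely so the observed minimum hits 0 and the maximum 1.
#' Bounds are taken from (and recorded for) the full column.
#'
#' @param values numeric vector with at least two distinct values.
#' @return list: `u` (normalized values), `min`, `max`.
#' @export
normalize_minmax <- function(values) {
  if (length(values) < 2) stop_cgmi("normalize_minmax needs >= 2 values")
  lo <- min(values); hi <- max(values)
  if (hi == lo) stop_cgmi("normalize_minmax: constant column (zero range)")
  list(u = (values - lo) / (hi - lo), min = lo, max = hi)
}

#' Normalize a vector of CVs into weights
#'
#' @param cvs non-negative coefficients of variation, one per indicator.
#' @return weights `cvs / sum(cvs)`, summing to 1.
#' @export
weights_from_cvs <- function(cvs) {
  if (any(!is.finite(cvs)) || any(cvs < 0))
    stop_cgmi("CVs must be finite and >= 0")
  s <- sum(cvs)
  if (s == 0) stop_cgmi("all CVs are zero; weights undefined")
  cvs / s
}

#' Coefficient-of-variation weights for the growth indicators
#'
#' @param indicators data.frame or matrix with one raw (unnormalized) column
#'   per indicator, all means > 0, at least 2 rows.
#' @param sample logical; use the sample (n-1) standard deviation instead of
#'   the population (n) convention.
#' @return list with per-indicator `mean`, `sd`, `cv` and normalized `weights`.
#' @export
cv_weights <- function(indicators, sample = FALSE) {
  x <- as.data.frame(indicators)
  if (nrow(x) < 2) stop_cgmi("cv_weights needs >= 2 rows")
  cvs <- vapply(x, coef_var, numeric(1), sample = sample)
  n <- nrow(x)
  sds <- vapply(x, stats::sd, numeric(1))
  if (!sample) sds <- sds * sqrt((n - 1) / n)
  list(mean = vapply(x, mean, numeric(1)), sd = sds, cv = cvs,
       weights = weights_from_cvs(cvs))
}

#' Equal-weight composite index (CGMI1)
#'
#' @param U data.frame/matrix of normalized indicators in `[0,1]`, one column
#'   per indicator.
#' @return per-plot arithmetic mean of the normalized indicators.
#' @export
cgmi_equal <- function(U) {
  U <- as.matrix(U)
  if (any(U < -1e-9 | U > 1 + 1e-9)) stop_cgmi("normalized indicators must lie in [0,1]")
  rowMeans(U)
}

#' CV-weighted composite index (CGMI2)
#'
#' @inheritParams cgmi_equal
#' @param weights non-negative weights summing to 1, one per column of `U`.
#' @return per-plot weighted sum, bounded by the row-wise min/max of `U`.
#' @export
cgmi_weighted <- function(U, weights) {
  U <- as.matrix(U)
  if (length(weights) != ncol(U))
    stop_cgmi("got %d weights for %d indicators", length(weights), ncol(U))
  if (abs(sum(weights) - 1) > 1e-9) stop_cgmi("weights must sum to 1")
  if (any(weights < 0)) stop_cgmi("weights must be >= 0")
  as.numeric(U %*% weights)
}

#' Build the composite growth indices for a plot table
#'
#' Normalizes the four indicators, computes CV weights on the raw columns,
#' and returns both composite indices with the scaling bounds and weights.
#'
#' @param records plot table with columns `spad, ph, lai, agb`.
#' @param sample logical, passed to [cv_weights()].
#' @return list: `table` (data.frame `plot_id, U1..U4, CGMI1, CGMI2`),
#'   `weights`, `cv`, `bounds` (per-indicator min/max used for scaling).
#' @export
build_cgmi <- function(records, sample = FALSE) {
  missing <- setdiff(INDICATORS, names(records))
  if (length(missing)) stop_cgmi("missing indicator column(s): %s", toString(missing))
  raw <- records[INDICATORS]
  norms <- lapply(raw, normalize_minmax)
  U <- as.data.frame(lapply(norms, `[[`, "u"))
  names(U) <- paste0("U", seq_along(INDICATORS))
  w <- cv_weights(raw, sample = sample)
  tab <- data.frame(
    plot_id = if ("plot_id" %in% names(records)) records$plot_id
              else sprintf("plot_%02d", seq_len(nrow(records))),
    U,
    CGMI1 = cgmi_equal(U),
    CGMI2 = cgmi_weighted(U, w$weights)
  )
  bounds <- data.frame(indicator = INDICATORS,
                       min = vapply(norms, `[[`, numeric(1), "min"),
                       max = vapply(norms, `[[`, numeric(1), "max"),
                       row.names = NULL)
  list(table = tab, weights = stats::setNames(w$weights, INDICATORS),
       cv = stats::setNames(w$cv, INDICATORS), bounds = bounds)
}
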