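# Pearson screening of vegetation indices against growth targets.

#' Pearson correlation with significance
#'
#' Thin wrapper over [stats::cor.test()] (t-transform with n-2 degrees of
#' freedom, two-sided) with the input checks the screening stage needs.
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return list with `r` and `p`.
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) stop_cgmi("x and y must have equal length")
  if (length(x) < 3) stop_cgmi("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_cgmi("constant input: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Correlate every vegetation index with every growth target
#'
#' @param indices index table (`plot_id` + one column per index).
#' @param targets data.frame of growth targets (e.g. the four indicators plus
#'   `CGMI1`, `CGMI2`), rows aligned with `indices`.
#' @return list of class `cgmi_corr_report`: `r` and `p` matrices
#'   (index x target), and `index_r` (pairwise index-index correlations).
#' @export
correlation_report <- function(indices, targets) {
  X <- indices[setdiff(names(indices), "plot_id")]
  Y <- targets[setdiff(names(targets), "plot_id")]
  if (nrow(X) != nrow(Y)) stop_cgmi("indices and targets differ in row count")
  r <- matrix(NA_real_, ncol(X), ncol(Y), dimnames = list(names(X), names(Y)))
  p <- r
  for (i in names(X)) for (j in names(Y)) {
    ct <- pearson_with_p(X[[i]], Y[[j]])
    r[i, j] <- ct$r; p[i, j] <- ct$p
  }
  structure(list(r = r, p = p, index_r = stats::cor(as.matrix(X))),
            class = "cgmi_corr_report")
}

#' Select model-input indices
#'
#' Keeps indices significantly correlated with the target at level `alpha`,
#' then returns the `k` with largest absolute correlation (ties broken by
#' registry order). If fewer than `k` pass the significance filter, all that
#' pass are returned with a warning. The reference-protocol preset instead fixes
#' the selection to the five named chlorophyll/structure indices.
#'
#' @param report a [correlation_report()].
#' @param target target column name (default `"CGMI2"`).
#' @param k number of indices to keep (default 5).
#' @param alpha significance level (default 0.01).
#' @return character vector of index names, ordered by decreasing `|r|`.
#' @export
select_indices <- function(report, target = "CGMI2", k = 5, alpha = 0.01) {
  stopifnot(inherits(report, "cgmi_corr_report"))
  if (k < 1) stop_cgmi("k must be >= 1")
  if (!target %in% colnames(report$r))
    stop_cgmi("unknown target '%s'; available: %s", target,
              toString(colnames(report$r)))
  sig <- rownames(report$r)[report$p[, target] < alpha]
  if (length(sig) < k)
    warning(sprintf("only %d of %d requested indices significant at alpha = %g",
                    length(sig), k, alpha), call. = FALSE)
  ord <- sig[order(-abs(report$r[sig, target]), match(sig, rownames(report$r)))]
  utils::head(ord, k)
}

# The five indices the screening stage lands on in the reference protocol.
#' @export
REFERENCE_INDICES <- c("TCARI", "CIrededge", "OSAVI", "DVI", "MNVI")

#' Long-format correlation table
#'
#' @param report a [correlation_report()].
#' @return data.frame with columns `index`, `target`, `r`, `p`.
#' @export
correlation_long <- function(report) {
  stopifnot(inherits(report, "cgmi_corr_report"))
  grid <- expand.grid(index = rownames(report$r), target = colnames(report$r),
                      stringsAsFactors = FALSE)
  grid$r <- report$r[cbind(grid$index, grid$target)]
  grid$p <- report$p[cbind(grid$index, grid$target)]
  grid
}
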