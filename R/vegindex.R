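# Vegetation-index library: twelve broad-band indices over five bands
# (B = 450 nm, G = 550 nm, R = 660 nm, RE = 750 nm, NIR = 840 nm).
#
# Each registry entry carries a provenance flag. "as-printed" entries follow
# the source table verbatim; "literature-corrected" entries restore the
# canonical form from the index's original publication where the source
# table's string is a transcription artifact (e.g. MSR, MTVI). Where an
# artifactual string still parses (CIrededge, MNVI, MSR), the `as_printed`
# evaluation mode computes it literally for auditability.

index_entry <- function(literature, provenance, printed = NULL) {
  list(literature = literature, printed = printed, provenance = provenance)
}

INDEX_REGISTRY <- list(
  NDVI = index_entry(function(B, G, R, RE, NIR) {
    d <- NIR + R
    if (any(d == 0)) stop_cgmi("NDVI: zero denominator NIR+R")
    (NIR - R) / d
  }, "as-printed"),
  GNDVI = index_entry(function(B, G, R, RE, NIR) {
    d <- NIR + G
    if (any(d == 0)) stop_cgmi("GNDVI: zero denominator NIR+G")
    (NIR - G) / d
  }, "as-printed"),
  MSR = index_entry(function(B, G, R, RE, NIR) {
    sr <- NIR / R
    (sr - 1) / (sqrt(sr) + 1)
  }, "literature-corrected",
  printed = function(B, G, R, RE, NIR) {
    sr <- NIR / R
    (sr - 1) / sr + 1
  }),
  TCARI = index_entry(function(B, G, R, RE, NIR) {
    3 * ((RE - R) - 0.2 * (RE - G) * (RE / R))
  }, "as-printed"),
  CIrededge = index_entry(function(B, G, R, RE, NIR) {
    if (any(RE == 0)) stop_cgmi("CIrededge: zero denominator RE")
    NIR / RE - 1
  }, "literature-corrected",
  printed = function(B, G, R, RE, NIR) {
    d <- RE - 1
    if (any(d == 0)) stop_cgmi("CIrededge (as printed): zero denominator RE-1")
    NIR / d
  }),
  DVI = index_entry(function(B, G, R, RE, NIR) NIR - R, "as-printed"),
  OSAVI = index_entry(function(B, G, R, RE, NIR) {
    (NIR - R) / (NIR + R + 0.16)
  }, "as-printed"),
  VDVI = index_entry(function(B, G, R, RE, NIR) {
    d <- 2 * G + R + B
    if (any(d == 0)) stop_cgmi("VDVI: zero denominator 2G+R+B")
    (2 * G - R - B) / d
  }, "as-printed"),
  SIPI = index_entry(function(B, G, R, RE, NIR) {
    d <- NIR + B
    if (any(d == 0)) stop_cgmi("SIPI: zero denominator NIR+B")
    (NIR - B) / d
  }, "as-printed"),
  MTVI = index_entry(function(B, G, R, RE, NIR) {
    rad <- (2 * NIR + 1)^2 - (6 * NIR - 5 * sqrt(R)) - 0.5
    if (any(rad <= 0)) stop_cgmi("MTVI: non-positive radicand")
    1.5 * (1.2 * (NIR - G) - 2.5 * (R - G)) / sqrt(rad)
  }, "literature-corrected"),
  MNVI = index_entry(function(B, G, R, RE, NIR) {
    1.5 * (NIR^2 - R) / (NIR^2 + R + 0.5)
  }, "literature-corrected",
  printed = function(B, G, R, RE, NIR) {
    1.5 * (NIR^2 - 2) / (NIR^2 + R + 0.5)
  }),
  ARVI = index_entry(function(B, G, R, RE, NIR) {
    rb <- 2 * R - B
    d <- NIR + rb
    if (any(d == 0)) stop_cgmi("ARVI: zero denominator NIR+(2R-B)")
    (NIR - rb) / d
  }, "as-printed")
)

#' Vegetation-index registry
#'
#' @return data.frame with one row per index: `name`, `provenance`
#'   ("as-printed" or "literature-corrected"), and whether a literal
#'   as-printed variant is available.
#' @export
index_registry <- function() {
  data.frame(
    name = names(INDEX_REGISTRY),
    provenance = vapply(INDEX_REGISTRY, `[[`, "", "provenance"),
    has_printed_variant = !vapply(INDEX_REGISTRY, function(e) is.null(e$printed), TRUE),
    row.names = NULL
  )
}

band_args <- function(bands) {
  if (is.data.frame(bands)) bands <- unlist(bands[1, BANDS, drop = TRUE])
  b <- bands[BANDS]
  if (anyNA(b)) stop_cgmi("bands must name all of: %s", toString(BANDS))
  if (any(!is.finite(b)) || any(b <= 0))
    stop_cgmi("reflectances must be finite and > 0")
  list(B = b[["b450"]], G = b[["g550"]], R = b[["r660"]],
       RE = b[["re750"]], NIR = b[["nir840"]])
}

#' Compute one vegetation index
#'
#' @param name index name, one of `index_registry()$name`.
#' @param bands named numeric vector (or one-row data.frame) with reflectances
#'   `b450, g550, r660, re750, nir840`, each finite and > 0.
#' @param formulas `"literature"` (default) uses the corrected canonical
#'   forms; `"as-printed"` evaluates the source table's literal strings where
#'   they parse, falling back to the corrected form otherwise.
#' @return scalar index value.
#' @export
compute_index <- function(name, bands, formulas = c("literature", "as-printed")) {
  formulas <- match.arg(formulas)
  entry <- INDEX_REGISTRY[[name]]
  if (is.null(entry))
    stop_cgmi("unknown index '%s'; valid names: %s", name,
              toString(names(INDEX_REGISTRY)))
  fn <- if (formulas == "as-printed" && !is.null(entry$printed))
    entry$printed else entry$literature
  do.call(fn, band_args(bands))
}

#' Compute the full index table
#'
#' @param records plot table with the five band columns (and `plot_id`).
#' @inheritParams compute_index
#' @return data.frame: `plot_id` plus one column per registered index.
#' @export
compute_all_indices <- function(records, formulas = c("literature", "as-printed")) {
  formulas <- match.arg(formulas)
  if (!is.data.frame(records) || nrow(records) == 0)
    stop_cgmi("records must be a non-empty data.frame")
  ids <- if ("plot_id" %in% names(records)) records$plot_id
         else sprintf("plot_%02d", seq_len(nrow(records)))
  out <- data.frame(plot_id = ids)
  for (nm in names(INDEX_REGISTRY)) {
    vals <- vapply(seq_len(nrow(records)), function(i) {
      tryCatch(compute_index(nm, records[i, , drop = FALSE], formulas),
               error = function(e) stop_cgmi("plot %s: %s", ids[i], conditionMessage(e)))
    }, numeric(1))
    out[[nm]] <- vals
  }
  out
}
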