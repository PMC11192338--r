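# Synthetic plot-table generator.
#
# One latent "vigor" scalar per plot drives the four growth indicators and the
# five-band canopy reflectance, so indicators are positively cross-correlated
# and red/NIR indices track the composite index, mirroring the statistical
# structure a UAV multispectral campaign over an even-aged stand produces.

PLOT_COLUMNS <- c("plot_id", "b450", "g550", "r660", "re750", "nir840",
                  "spad", "ph", "lai", "agb")
INDICATORS <- c("spad", "ph", "lai", "agb")
BANDS <- c("b450", "g550", "r660", "re750", "nir840")

# Field-campaign marginals for an even-aged camphor stand: SPAD (unitless
# chlorophyll-meter reading), plant height (m), leaf area index, aboveground
# biomass (g per tree; units follow common nursery practice).
default_indicator_moments <- function() {
  list(
    spad = c(mean = 40.18, sd = 3.75),
    ph   = c(mean = 1.18,  sd = 0.20),
    lai  = c(mean = 2.90,  sd = 0.63),
    agb  = c(mean = 6347.70, sd = 1515.69)
  )
}

# Plot-mean reflectance of a young, sparse broadleaf canopy at
# 450/550/660/750/840 nm. The red baseline is relatively high (soil shows
# through a seedling canopy); vigor raises NIR and red-edge reflectance and
# deepens red absorption. NIR carries the largest plot-to-plot noise
# (canopy-structure variation), which keeps the NIR/red index family from
# saturating toward the latent vigor.
default_reflectance_params <- function() {
  list(
    baseline = c(b450 = 0.050, g550 = 0.110, r660 = 0.150,
                 re750 = 0.250, nir840 = 0.450),
    slope    = c(b450 = -0.002, g550 = 0.003, r660 = -0.010,
                 re750 = 0.010, nir840 = 0.042),
    noise_sd = c(b450 = 0.005, g550 = 0.005, r660 = 0.006,
                 re750 = 0.008, nir840 = 0.035)
  )
}

#' Configuration for the synthetic plot-table generator
#'
#' @param n_plots number of sample plots (default 66, one growing-season
#'   campaign over a 66-plot nursery block).
#' @param seed integer seed; the generator is deterministic given the seed.
#' @param vigor_loadings correlations (in `[0,1]`) between the latent plot
#'   vigor and each standardized indicator, named `spad, ph, lai, agb`. Plant
#'   height gets the weakest loading: height carries the least spectral signal.
#' @param noise_sd residual SD of each standardized indicator around its
#'   vigor projection; `NULL` (default) completes each loading to unit
#'   variance, `sqrt(1 - loading^2)`.
#' @param indicator_moments list of `c(mean, sd)` per indicator; defaults are
#'   the campaign marginals above.
#' @param reflectance_params list with per-band `baseline`, `slope` (per unit
#'   vigor) and `noise_sd`; reflectances are clamped to (0.01, 0.99).
#' @return object of class `cgmi_synth_config`.
#' @export
synthetic_config <- function(n_plots = 66, seed = 1,
                             vigor_loadings = c(spad = 0.88, ph = 0.72,
                                                lai = 0.85, agb = 0.85),
                             noise_sd = NULL,
                             indicator_moments = default_indicator_moments(),
                             reflectance_params = default_reflectance_params()) {
  if (length(n_plots) != 1 || !is.finite(n_plots) || n_plots < 10)
    stop_cgmi("n_plots must be a single number >= 10 (got %s)", toString(n_plots))
  vigor_loadings <- vigor_loadings[INDICATORS]
  if (anyNA(vigor_loadings))
    stop_cgmi("vigor_loadings must name all of: %s", toString(INDICATORS))
  if (any(vigor_loadings < 0 | vigor_loadings > 1))
    stop_cgmi("vigor_loadings must lie in [0, 1]")
  if (is.null(noise_sd)) {
    noise_sd <- sqrt(1 - vigor_loadings^2)
  } else {
    noise_sd <- noise_sd[INDICATORS]
    if (anyNA(noise_sd) || any(noise_sd < 0))
      stop_cgmi("noise_sd must be >= 0 for all of: %s", toString(INDICATORS))
  }
  for (ind in INDICATORS) {
    mo <- indicator_moments[[ind]]
    if (is.null(mo) || anyNA(mo[c("mean", "sd")]) || mo[["sd"]] < 0 || mo[["mean"]] <= 0)
      stop_cgmi("indicator_moments$%s must give a positive mean and sd >= 0", ind)
  }
  rp <- reflectance_params
  for (f in c("baseline", "slope", "noise_sd")) {
    if (anyNA(rp[[f]][BANDS]))
      stop_cgmi("reflectance_params$%s must name all of: %s", f, toString(BANDS))
  }
  if (any(rp$noise_sd[BANDS] < 0)) stop_cgmi("reflectance noise_sd must be >= 0")
  structure(list(n_plots = as.integer(n_plots), seed = seed,
                 vigor_loadings = vigor_loadings, noise_sd = noise_sd,
                 indicator_moments = indicator_moments,
                 reflectance_params = rp),
            class = "cgmi_synth_config")
}

#' Generate a synthetic plot table
#'
#' Draws one latent vigor score per plot from N(0, 1); each indicator is
#' `loading * vigor + noise`, standardized in population terms and affinely
#' mapped onto its configured mean/SD; each band is `baseline + slope * vigor
#' + noise`, clamped to (0.01, 0.99). If clamping touches more than 10% of
#' band values the configuration is rejected as unphysical.
#'
#' @param config a [synthetic_config()].
#' @return data.frame with columns
#'   `plot_id, b450, g550, r660, re750, nir840, spad, ph, lai, agb`.
#' @export
generate_plots <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "cgmi_synth_config"))
  n <- config$n_plots
  with_seed(config$seed, {
    vigor <- stats::rnorm(n)
    out <- data.frame(plot_id = sprintf("plot_%02d", seq_len(n)))
    rp <- config$reflectance_params
    clamped <- 0L
    for (b in BANDS) {
      refl <- rp$baseline[[b]] + rp$slope[[b]] * vigor +
        stats::rnorm(n, sd = rp$noise_sd[[b]])
      clamped <- clamped + sum(refl <= 0.01 | refl >= 0.99)
      out[[b]] <- pmin(pmax(refl, 0.01), 0.99)
    }
    if (clamped > 0.1 * n * length(BANDS))
      stop_cgmi("reflectance configuration unphysical: %d of %d band values clamped",
                clamped, n * length(BANDS))
    for (ind in INDICATORS) {
      l <- config$vigor_loadings[[ind]]
      s <- config$noise_sd[[ind]]
      z <- l * vigor + stats::rnorm(n, sd = s)
      denom <- sqrt(l^2 + s^2)
      if (denom > 0) z <- z / denom         # unit population variance
      mo <- config$indicator_moments[[ind]]
      val <- mo[["mean"]] + mo[["sd"]] * z
      out[[ind]] <- pmax(val, 1e-6)         # indicators are physical, > 0
    }
    out
  })
}

#' Write / read a plot table
#'
#' Plain CSV with the canonical column set; the round trip is lossless to
#' full double precision (values are written with 15 significant digits).
#'
#' @param records data.frame of plots as from [generate_plots()].
#' @param path file path.
#' @return `write_plot_table` returns `path` invisibly; `read_plot_table`
#'   returns the validated data.frame.
#' @export
write_plot_table <- function(records, path) {
  missing <- setdiff(PLOT_COLUMNS, names(records))
  if (length(missing))
    stop_cgmi("plot table is missing column(s): %s", toString(missing))
  rec <- records[PLOT_COLUMNS]
  num <- setdiff(PLOT_COLUMNS, "plot_id")
  rec[num] <- lapply(rec[num], function(x) formatC(x, digits = 15, format = "g"))
  utils::write.csv(rec, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_plot_table
#' @export
read_plot_table <- function(path) {
  if (!file.exists(path)) stop_cgmi("no such file: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop_cgmi("plot table %s is empty", path)
  missing <- setdiff(PLOT_COLUMNS, names(df))
  if (length(missing))
    stop_cgmi("plot table %s is missing column(s): %s", path, toString(missing))
  for (col in setdiff(PLOT_COLUMNS, "plot_id")) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop_cgmi("column '%s' is not numeric (first bad row: %d)", col,
                if (is.na(bad)) 1L else bad)
    }
    if (anyNA(v)) stop_cgmi("column '%s' has missing values (row %d)", col,
                            which(is.na(v))[1])
  }
  df[PLOT_COLUMNS]
}
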