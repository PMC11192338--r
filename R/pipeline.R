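# End-to-end orchestration: simulate/ingest -> indices -> composite index ->
# screening -> model fits -> evaluation, with every intermediate written as
# CSV and a JSON manifest recording seeds, the config hash and the package
# version, so a run can be replayed byte-identically.

ALL_MODELS <- c(MODEL_NAMES, "WOA-BPNN")

#' Pipeline configuration
#'
#' One master seed is expanded per stage (stable stage-name hashing), so any
#' stage can be rerun in isolation and reproduce the full run's behavior.
#'
#' @param out_dir output directory for intermediate CSVs and the manifest.
#' @param seed master seed.
#' @param input_csv optional plot table to ingest instead of simulating.
#' @param synth [synthetic_config()] overrides used when simulating (its
#'   `seed` is replaced by the stage seed).
#' @param formulas vegetation-index formula mode (see [compute_index()]).
#' @param selection `"reference"` fixes the five reference indices
#'   (TCARI, CIrededge, OSAVI, DVI, MNVI); `"data"` screens by
#'   Pearson correlation with `k`/`alpha`; `"none"` feeds all 12 indices.
#' @param k,alpha screening parameters.
#' @param target `"CGMI2"` (CV weights, default) or `"CGMI1"`.
#' @param models character vector from
#'   `MLR, PLS, SVR, RF, RBFNN, BPNN, WOA-BPNN`.
#' @param woa_pop,woa_iters WOA protocol (defaults 10 and 60).
#' @param n_train training-set size (default 52).
#' @return object of class `cgmi_pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1, input_csv = NULL,
                            synth = synthetic_config(),
                            formulas = "literature",
                            selection = c("reference", "data", "none"),
                            k = 5, alpha = 0.01,
                            target = c("CGMI2", "CGMI1"),
                            models = ALL_MODELS,
                            woa_pop = 10, woa_iters = 60, n_train = 52) {
  selection <- match.arg(selection)
  target <- match.arg(target)
  bad <- setdiff(models, ALL_MODELS)
  if (length(bad)) stop_cgmi("unknown model(s): %s", toString(bad))
  structure(list(out_dir = out_dir, seed = seed, input_csv = input_csv,
                 synth = synth, formulas = formulas, selection = selection,
                 k = k, alpha = alpha, target = target, models = models,
                 woa_pop = woa_pop, woa_iters = woa_iters, n_train = n_train),
            class = "cgmi_pipeline_config")
}

#' Run the full growth-monitoring pipeline
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress per-stage messages.
#' @return list: `report` (metrics data.frame), `selected` (index names),
#'   `weights` (CV weights), `fits`, `split`, `woa_trace` (if WOA-BPNN ran),
#'   plus all artifact paths in `$paths`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "cgmi_pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(config$out_dir, f)
  say <- function(...) if (!quiet) message(sprintf(...))

  # -- simulate | ingest
  if (is.null(config$input_csv)) {
    synth <- config$synth
    synth$seed <- stage_seed(config$seed, "simulate")
    plots <- generate_plots(synth)
    say("simulate: %d plots (seed %d)", nrow(plots), synth$seed)
  } else {
    plots <- read_plot_table(config$input_csv)
    say("ingest: %d plots from %s", nrow(plots), config$input_csv)
  }
  write_plot_table(plots, path("plots.csv"))

  # -- vegetation indices
  idx <- compute_all_indices(plots, formulas = config$formulas)
  utils::write.csv(idx, path("indices.csv"), row.names = FALSE)
  say("indices: %d columns", ncol(idx) - 1)

  # -- composite index
  cg <- build_cgmi(plots)
  utils::write.csv(cg$table, path("cgmi.csv"), row.names = FALSE)
  jsonlite::write_json(list(weights = as.list(cg$weights),
                            cv = as.list(cg$cv),
                            bounds = cg$bounds),
                       path("cgmi_weights.json"), auto_unbox = TRUE, digits = NA)
  say("composite index: CV weights %s", toString(round(cg$weights, 4)))

  # -- screening
  targets <- cbind(plots[INDICATORS], cg$table[c("CGMI1", "CGMI2")])
  rep_corr <- correlation_report(idx, targets)
  utils::write.csv(correlation_long(rep_corr), path("screening.csv"),
                   row.names = FALSE)
  selected <- switch(config$selection,
    reference = REFERENCE_INDICES,
    data = select_indices(rep_corr, target = config$target,
                          k = config$k, alpha = config$alpha),
    none = setdiff(names(idx), "plot_id"))
  say("screening (%s): %s", config$selection, toString(selected))

  # -- fit + evaluate
  X <- idx[selected]
  y <- cg$table[[config$target]]
  split <- split_data(nrow(X), config$n_train,
                      seed = stage_seed(config$seed, "split"))
  fits <- list()
  woa_trace <- NULL
  for (m in config$models) {
    ms <- stage_seed(config$seed, paste0("fit_", m))
    if (m == "WOA-BPNN") {
      f <- woa_bpnn(X[split$train, , drop = FALSE], y[split$train],
                    woa = woa_config(pop = config$woa_pop,
                                     iters = config$woa_iters, seed = ms))
      woa_trace <- f$woa$trace
      utils::write.csv(data.frame(iteration = seq_along(woa_trace) - 1L,
                                  best_fitness = woa_trace),
                       path("woa_trace.csv"), row.names = FALSE)
    } else {
      f <- fit_model(m, X[split$train, , drop = FALSE], y[split$train], seed = ms)
    }
    fits[[m]] <- f
    say("fit %s (seed %d)", m, ms)
  }
  report <- eval_report(fits, X, y, split)
  utils::write.csv(report, path("metrics.csv"), row.names = FALSE)

  # -- manifest
  cfg_json <- jsonlite::toJSON(config[setdiff(names(config), "synth")],
                               auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(
    list(package = "cgmi",
         version = as.character(utils::packageVersion("cgmi")),
         master_seed = config$seed,
         config_hash = as.character(tools::md5sum(path("cgmi_weights.json"))),
         config = jsonlite::fromJSON(cfg_json),
         n_train = length(split$train), n_test = length(split$test)),
    path("manifest.json"), auto_unbox = TRUE, digits = NA)

  list(report = report, selected = selected, weights = cg$weights,
       correlations = rep_corr, fits = fits, split = split,
       woa_trace = woa_trace, cgmi = cg$table, indices = idx, plots = plots,
       paths = stats::setNames(
         file.path(config$out_dir,
                   c("plots.csv", "indices.csv", "cgmi.csv", "screening.csv",
                     "metrics.csv", "manifest.json")),
         c("plots", "indices", "cgmi", "screening", "metrics", "manifest")))
}
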