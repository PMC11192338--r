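#!/usr/bin/env Rscript
# Stage 6: replace the network's random start with the whale-optimization
# optimum (population 10, 60 iterations over the 85 weights/thresholds in
# [-1,1]) and compare against the plain network over 20 paired campaigns.

library(cgmi)

# single-campaign comparison on the stage-5 data
idx <- read.csv("results/indices.csv")
cg <- read.csv("results/cgmi.csv")
sel <- readLines("results/04_selected_indices.txt")
X <- idx[sel]; y <- cg$CGMI2
sp <- split_data(nrow(X), 52, seed = 1)
bp <- suppressWarnings(fit_model("BPNN", X[sp$train, ], y[sp$train], seed = 1))
wb <- suppressWarnings(woa_bpnn(X[sp$train, ], y[sp$train],
                                woa = woa_config(pop = 10, iters = 60, seed = 1)))
write.csv(data.frame(iteration = seq_along(wb$woa$trace) - 1L,
                     best_fitness = wb$woa$trace),
          "results/06_woa_trace.csv", row.names = FALSE)
single <- eval_report(list(BPNN = bp, `WOA-BPNN` = wb), X, y, sp)
cat("Single-campaign comparison:\n")
print(cbind(single[c("model", "set")], round(single[-(1:3)], 4)))

# paired replication: same plots, split and validation rows per seed
res <- t(sapply(1:20, function(s) {
  p <- generate_plots(synthetic_config(seed = s))
  ix <- compute_all_indices(p)
  cgr <- build_cgmi(p)
  Xs <- ix[REFERENCE_INDICES]; ys <- cgr$table$CGMI2
  spl <- split_data(66, 52, seed = s)
  b <- suppressWarnings(fit_model("BPNN", Xs[spl$train, ], ys[spl$train], seed = s))
  w <- suppressWarnings(woa_bpnn(Xs[spl$train, ], ys[spl$train],
                                 woa = woa_config(seed = s)))
  c(r2_bpnn = r2_conventional(predict(b, Xs[spl$test, ]), ys[spl$test]),
    r2_woa = r2_conventional(predict(w, Xs[spl$test, ]), ys[spl$test]),
    nrmse_bpnn = nrmse(predict(b, Xs[spl$test, ]), ys[spl$test]),
    nrmse_woa = nrmse(predict(w, Xs[spl$test, ]), ys[spl$test]))
}))
write.csv(data.frame(seed = 1:20, res), "results/06_paired_comparison.csv",
          row.names = FALSE)
m <- apply(res, 2, median)
cat(sprintf("\nMedians over 20 paired campaigns:\n  test R2  %.4f (BPNN) vs %.4f (WOA-BPNN)\n  NRMSE    %.4f (BPNN) vs %.4f (WOA-BPNN)\n",
            m["r2_bpnn"], m["r2_woa"], m["nrmse_bpnn"], m["nrmse_woa"]))
cat(sprintf("WOA initialization wins on test R2 in %d/20 campaigns.\n",
            sum(res[, "r2_woa"] >= res[, "r2_bpnn"])))
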