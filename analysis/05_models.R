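#!/usr/bin/env Rscript
# Stage 5: invert CGMI2 from the five selected indices with the six baseline
# regressors on a 52/14 train/test split; tabulate R2, RMSE, NRMSE, MAPE.

library(cgmi)
seed <- 1

idx <- read.csv("results/indices.csv")
cg <- read.csv("results/cgmi.csv")
sel <- readLines("results/04_selected_indices.txt")
X <- idx[sel]
y <- cg$CGMI2

sp <- split_data(nrow(X), 52, seed = seed)
fits <- lapply(c("MLR", "PLS", "SVR", "RF", "RBFNN", "BPNN"), function(m)
  suppressWarnings(fit_model(m, X[sp$train, ], y[sp$train], seed = seed)))
names(fits) <- c("MLR", "PLS", "SVR", "RF", "RBFNN", "BPNN")

report <- eval_report(fits, X, y, sp)
write.csv(report, "results/05_baseline_metrics.csv", row.names = FALSE)

cat("Baseline model accuracy (52 train / 14 test):\n")
print(cbind(report[c("model", "set", "n")], round(report[-(1:3)], 4)))
best <- report[report$set == "test", ]
cat(sprintf("Best test R2: %s (%.4f).\n",
            best$model[which.max(best$r2)], max(best$r2)))
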