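#!/usr/bin/env Rscript
# Compare the secondary-structure composition of the native enzyme against
# the inhibitor-bound form (deconvolution percentages).

suppressPackageStartupMessages(library(enzchar))
dir.create("results", showWarnings = FALSE)

comps <- read_composition_csv("results/data/composition.csv")
d <- compare_composition(comps$control, comps$`lead-bound`)

cat("secondary-structure change on binding:\n")
cat(sprintf("  helix %+0.1f, turn %+0.1f, coil %+0.1f (percentage points)\n",
            d$delta_helix_pct, d$delta_turn_pct, d$delta_coil_pct))
cat(" ", d$summary, "\n")

writeLines(jsonlite::toJSON(d, auto_unbox = TRUE, digits = 6, pretty = TRUE),
           "results/cd.json")
cat("wrote results/cd.json\n")
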