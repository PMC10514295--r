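#!/usr/bin/env Rscript
# Fit logit-method IC50s for every compound in the assay table, compare the
# lead compound's potency to the reference inhibitor, and write a JSON
# summary under results/.

suppressPackageStartupMessages(library(enzchar))
dir.create("results", showWarnings = FALSE)

drs <- read_assay_csv("results/data/assay.csv")
fits <- lapply(drs, fit_ic50_logit)

for (f in fits) {
  cat(sprintf("%-10s IC50 = %6.2f +/- %.2f uM  (slope %.2f, r2 %.3f, n %d)\n",
              f$compound_id, f$ic50_uM, f$sd_uM, f$slope, f$r2, f$n_points))
}

fold <- fold_potency(fits$reference$ic50_uM, fits$lead$ic50_uM)
cat(sprintf("lead is %.1f-fold more potent than the reference\n", fold))

# per-replicate IC50s for the Welch comparison
rep_ic50 <- function(dr) {
  vapply(split(dr$points, dr$points$replicate), function(sub) {
    fit_ic50_logit(dose_response(sub$conc_uM, sub$pct_inhibition,
                                 compound_id = dr$compound_id))$ic50_uM
  }, numeric(1))
}
tt <- compare_to_reference(rep_ic50(drs$lead), rep_ic50(drs$reference))
cat(sprintf("Welch t-test lead vs reference: t = %.1f, p = %.2e\n", tt$t, tt$p))

out <- list(fits = lapply(fits, unclass), fold_potency_lead = fold,
            welch = tt)
writeLines(jsonlite::toJSON(out, auto_unbox = TRUE, digits = 6, pretty = TRUE),
           "results/ic50.json")
cat("wrote results/ic50.json\n")
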