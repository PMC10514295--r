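#!/usr/bin/env Rscript
# Assemble the single-compound characterization report from the preceding
# stages into one deterministic JSON document.

suppressPackageStartupMessages(library(enzchar))
dir.create("results", showWarnings = FALSE)

stage <- function(path) jsonlite::fromJSON(path, simplifyVector = FALSE)
ic50 <- stage("results/ic50.json")
kin <- stage("results/kinetics.json")
bt <- stage("results/binding_thermo.json")
cd <- stage("results/cd.json")

report <- build_report(
  "lead",
  ic50 = c(ic50$fits$lead, list(fold_potency_vs_reference = ic50$fold_potency_lead,
                                p_vs_reference = ic50$welch$p)),
  kinetics = kin[c("ki_uM", "km_mM", "mode")],
  binding = list(per_temperature = bt$binding, quenching = bt$quenching),
  thermo = bt$thermo,
  cd = cd,
  provenance = list(inputs = as.list(list.files("results/data",
                                                full.names = TRUE)),
                    generator_seed = 20260919))
write_report_json(report, "results/compound_report.json")
cat("wrote results/compound_report.json\n")
cat(sprintf("summary: IC50 %.2f uM, Ki %.2f uM (%s), quenching %s, forces %s\n",
            ic50$fits$lead$ic50_uM, kin$ki_uM, kin$mode, bt$quenching,
            bt$thermo$force_class))
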