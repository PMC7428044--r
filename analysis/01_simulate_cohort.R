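#!/usr/bin/env Rscript
# Stage 1: generate the synthetic multi-region cohort.
#
# Patient data for this study design are controlled-access, so the analysis
# runs on a simulated cohort built to the same design: 18 patients, 2-3
# whole-exome tumor samples each (177x) plus 8-22 targeted samples (508x) in
# a subset, precursor/cancer purity differences, planted LOH events, latent
# progression times, and occasional cancerization / independent-clone /
# multifocal scenarios. Writes the input bundle and the truth record.

library(cystevol)

seed <- 20260925L
cfg <- sim_config(seed = seed)
co <- generate_cohort(cfg)

dir.create("results", showWarnings = FALSE)
write_cohort(co$bundle, "results/cohort")
jsonlite::write_json(co$truth, "results/cohort/truth.json",
                     auto_unbox = TRUE, digits = 10, force = TRUE)

s <- co$bundle$samples
cat("cohort:", length(unique(s$patient_id)), "patients,",
    nrow(s), "samples (", sum(s$assay == "targeted"), "targeted )\n")
cat("variant sites:", length(unique(paste(co$bundle$variants$chrom,
                                          co$bundle$variants$pos))), "\n")
cat("wrote results/cohort/\n")
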