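#!/usr/bin/env Rscript
# Stage 3: shared vs private mutation burden per patient.
#
# For each patient with paired whole-exome samples, counts mutations called
# present in the high-grade (noninvasive) sample, in the cancer sample, and
# shared between them -- the quantities that establish common ancestry of
# the precursor and the invasive carcinoma.

library(cystevol)

cm <- read.delim("results/pipeline/call_matrix.tsv")
samples <- read.delim("results/cohort/samples.tsv")
present <- c("present_primary", "present_secondary")

rows <- lapply(unique(samples$patient_id), function(pid) {
  ps <- samples[samples$patient_id == pid, ]
  hg <- ps$sample_id[ps$component == "high_grade" & ps$assay == "wes"][1]
  ca <- ps$sample_id[ps$component == "cancer" & ps$assay == "wes"][1]
  if (is.na(hg) || is.na(ca)) return(NULL)
  pc <- cm[cm$patient_id == pid, ]
  hset <- pc$site_id[pc$sample_id == hg & pc$status %in% present]
  cset <- pc$site_id[pc$sample_id == ca & pc$status %in% present]
  data.frame(patient_id = pid,
             n_noninvasive = length(hset), n_cancer = length(cset),
             n_shared = length(intersect(hset, cset)),
             n_noninv_private = length(setdiff(hset, cset)),
             n_cancer_private = length(setdiff(cset, hset)))
})
burden <- do.call(rbind, rows)
write.table(burden, "results/mutation_burden.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("patients analyzed: %d\n", nrow(burden)))
cat(sprintf("mean mutations, noninvasive: %.1f (range %d-%d)\n",
            mean(burden$n_noninvasive), min(burden$n_noninvasive),
            max(burden$n_noninvasive)))
cat(sprintf("mean mutations, cancer:      %.1f (range %d-%d)\n",
            mean(burden$n_cancer), min(burden$n_cancer),
            max(burden$n_cancer)))
cat(sprintf("mean shared mutations:       %.1f\n", mean(burden$n_shared)))
cat(sprintf("mean cancer-private:         %.1f\n",
            mean(burden$n_cancer_private)))
cat("every patient shares mutations between components:",
    all(burden$n_shared > 0), "\n")
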