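#!/usr/bin/env Rscript
# Stage 4: evolutionary relationships across the cohort.
#
# Summarizes the per-patient maximum-parsimony trees and the ancestry
# classification of precursor-annotated samples: ordinary precursor
# lineages, cancerization of ducts (samples that descended from the
# invasive cancer), and genetically independent hotspot-initiated clones.

library(cystevol)

anc <- read.delim("results/pipeline/ancestry.tsv")
trees <- list.files("results/pipeline/trees", full.names = TRUE)

cat("patients with inferred trees:", length(trees), "\n")
for (f in trees) {
  nwk <- readLines(f)
  cat(sprintf("  %s: %d maximum-parsimony tree(s)\n",
              sub("\\.nwk$", "", basename(f)), length(nwk)))
}
cat("\nancestry of precursor-annotated samples:\n")
print(table(anc$label))
canc <- anc[anc$label == "cancerization", ]
if (nrow(canc)) {
  cat("\ncancerization detected (morphology suggested precursor, genotype",
      "descends from cancer):\n")
  print(canc[, c("patient_id", "sample_id", "component",
                 "n_shared_with_cancer", "n_private")])
}
indep <- anc[anc$label == "independent_clone", ]
if (nrow(indep)) {
  cat("\nindependent clones (no non-hotspot sharing with the cancer):\n")
  print(indep[, c("patient_id", "sample_id", "n_shared_with_cancer")])
}
write.table(anc, "results/evolution_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
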