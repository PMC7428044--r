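# Shared fixture builders: single-patient bundles simulated from a planted
# clone tree, and hand-built read-count tables for threshold tests.

# simulate one patient and assemble the variant/metadata tables needed by
# build_call_matrix (no SNPs, no panel unless asked)
sim_patient_bundle <- function(seed, targeted = FALSE, forced = NULL, ...) {
  cfg <- sim_config(n_patients = 1, fraction_targeted = as.numeric(targeted),
                    n_snps = 0, loh_events_per_patient = 0,
                    purity_range_precursor = c(0.6, 0.8),
                    purity_range_cancer = c(0.5, 0.7),
                    p_cancerization = 0, p_multifocal = 0,
                    p_independent_clone = 0, seed = seed, ...)
  set.seed(substream_seed(seed, "patient-fixture"))
  pat <- simulate_patient(cfg, "P1", targeted = targeted,
                          forced_scenarios = forced)
  sites <- unique(do.call(rbind, lapply(pat$nodes,
                                        function(n) n$alterations)))
  key <- paste(sites$chrom, sites$pos, sites$ref, sites$alt)
  vr <- do.call(rbind, lapply(seq_len(nrow(pat$samples)), function(i) {
    s <- pat$samples[i, ]
    g <- sample_genotype(pat, s$sample_id)
    rc <- simulate_read_counts(sites,
                               key %in% paste(g$chrom, g$pos, g$ref, g$alt),
                               s$purity, s$median_capture_coverage)
    data.frame(patient_id = "P1", sample_id = s$sample_id,
               rc[, c("chrom", "pos", "ref", "alt", "gene", "is_hotspot",
                      "depth", "alt_count")],
               origin = "wes", stringsAsFactors = FALSE)
  }))
  list(patient = pat,
       bundle = list(
         samples = pat$samples[, c("sample_id", "patient_id", "component",
                                   "assay", "median_capture_coverage")],
         variants = vr,
         driver_genes = cystevol:::DRIVER_GENES_15))
}

# minimal hand-built cohort: 1 normal + 1 tumor, 3 variants
tiny_bundle <- function() {
  samples <- data.frame(
    sample_id = c("N", "T"), patient_id = "P1",
    component = c("normal", "cancer"), assay = "wes",
    median_capture_coverage = c(150L, 150L), stringsAsFactors = FALSE)
  v <- expand.grid(sample_id = c("N", "T"), i = 1:3,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  variants <- data.frame(
    patient_id = "P1", sample_id = v$sample_id,
    chrom = paste0("chr", v$i), pos = 1000L * v$i,
    ref = "A", alt = "T", gene = paste0("G", v$i), is_hotspot = FALSE,
    depth = 100L, alt_count = ifelse(v$sample_id == "T", 30L, 0L),
    stringsAsFactors = FALSE)
  list(samples = samples, variants = variants,
       driver_genes = cystevol:::DRIVER_GENES_15)
}

# read-count row helper for threshold unit tests
rc_row <- function(sample_id, depth, alt, chrom = "chr1", pos = 100L,
                   patient_id = "P1", gene = "G1") {
  data.frame(patient_id = patient_id, sample_id = sample_id, chrom = chrom,
             pos = pos, ref = "A", alt = "T", gene = gene,
             is_hotspot = FALSE, depth = depth, alt_count = alt,
             stringsAsFactors = FALSE)
}

meta_row <- function(sample_id, component, assay = "wes", cov = 100L,
                     patient_id = "P1") {
  data.frame(sample_id = sample_id, patient_id = patient_id,
             component = component, assay = assay,
             median_capture_coverage = cov, stringsAsFactors = FALSE)
}
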