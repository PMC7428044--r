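# Integrated mutation calling: coverage-scaled thresholds, germline filter,
# primary/secondary two-tier rule.

test_that("targeted mutant-read threshold scales with coverage, ceiling, floor 2", {
  expect_identical(scaled_min_alt_reads(5, 600, 150), 20L)
  expect_identical(scaled_min_alt_reads(5, 150, 150), 5L)
  expect_identical(scaled_min_alt_reads(5, 75, 150), 3L)   # ceiling(2.5)
  expect_identical(scaled_min_alt_reads(5, 30, 150), 2L)   # floor of 2
  expect_error(scaled_min_alt_reads(5, 0, 150), "positive")
})

test_that("site coverage filter requires depth strictly above 20% of median in every sample", {
  expect_true(site_coverage_filter(c(21, 21, 21), c(100, 100, 100)))
  expect_false(site_coverage_filter(c(50, 20, 80), c(100, 100, 100)))  # 20 not > 20
  expect_true(site_coverage_filter(50, 100))
  expect_false(site_coverage_filter(c(NA, 50), c(100, 100)))
})

test_that("germline filter needs >= 10 normal reads and VAF < 2%", {
  expect_false(germline_somatic_filter(9, 0))
  expect_false(germline_somatic_filter(100, 2))     # VAF exactly 0.02
  expect_true(germline_somatic_filter(100, 1))
  expect_true(is.na(germline_somatic_filter(NA, NA)))
})

test_that("per-sample presence calls follow the assay-specific two-tier rules", {
  expect_identical(call_site_in_sample(100, 12, "wes"), "present_primary")
  expect_identical(call_site_in_sample(100, 3, "wes", present_elsewhere = TRUE),
                   "present_secondary")
  expect_identical(call_site_in_sample(100, 3, "wes", present_elsewhere = FALSE),
                   "absent")
  expect_identical(call_site_in_sample(100, 1, "wes", present_elsewhere = TRUE),
                   "absent")
  # targeted: no secondary tier; scaled minimum applies
  expect_identical(call_site_in_sample(400, 18, "targeted",
                                       present_elsewhere = TRUE,
                                       targeted_min_alt = 20L), "absent")
  expect_identical(call_site_in_sample(400, 24, "targeted",
                                       targeted_min_alt = 20L),
                   "present_primary")
  expect_identical(call_site_in_sample(0, 0, "wes"),
                   "indeterminate_low_coverage")
})

test_that("low-purity precursor is rescued by the secondary pass", {
  samples <- rbind(meta_row("N", "normal"), meta_row("HG", "high_grade"),
                   meta_row("C", "cancer"))
  variants <- rbind(rc_row("N", 100L, 0L), rc_row("HG", 100L, 3L),
                    rc_row("C", 100L, 30L))
  bundle <- list(samples = samples, variants = variants,
                 driver_genes = cystevol:::DRIVER_GENES_15)
  cm <- build_call_matrix(bundle)
  expect_identical(cm$status[cm$sample_id == "C"], "present_primary")
  expect_identical(cm$status[cm$sample_id == "HG"], "present_secondary")
})

test_that("no primary call anywhere means no secondary calls", {
  samples <- rbind(meta_row("N", "normal"), meta_row("HG", "high_grade"),
                   meta_row("C", "cancer"))
  variants <- rbind(rc_row("N", 100L, 0L), rc_row("HG", 100L, 3L),
                    rc_row("C", 100L, 4L))  # both below primary thresholds
  bundle <- list(samples = samples, variants = variants,
                 driver_genes = cystevol:::DRIVER_GENES_15)
  cm <- build_call_matrix(bundle)
  expect_true(all(cm$status == "absent"))
})

test_that("all-zero mutant counts give absent everywhere", {
  samples <- rbind(meta_row("N", "normal"), meta_row("T1", "high_grade"),
                   meta_row("T2", "cancer"))
  variants <- rbind(rc_row("N", 100L, 0L), rc_row("T1", 120L, 0L),
                    rc_row("T2", 110L, 0L))
  bundle <- list(samples = samples, variants = variants,
                 driver_genes = cystevol:::DRIVER_GENES_15)
  cm <- build_call_matrix(bundle)
  expect_true(all(cm$status == "absent"))
})

test_that("coverage and germline failures exclude the site in all samples", {
  samples <- rbind(meta_row("N", "normal"), meta_row("T", "cancer"))
  # site 1: tumor depth 15 at median 100 -> <= 20% -> excluded
  # site 2: normal VAF 0.05 -> germline -> excluded
  variants <- rbind(
    rc_row("N", 100L, 0L, pos = 100L), rc_row("T", 15L, 10L, pos = 100L),
    rc_row("N", 100L, 5L, pos = 200L), rc_row("T", 100L, 40L, pos = 200L))
  bundle <- list(samples = samples, variants = variants,
                 driver_genes = cystevol:::DRIVER_GENES_15)
  cm <- build_call_matrix(bundle)
  expect_true(all(cm$status == "site_excluded"))
})

test_that("raising thresholds never converts absent into present", {
  set.seed(1)
  base <- default_config()$calling
  stricter <- base
  stricter$wes_primary_min_vaf <- 0.2
  stricter$wes_primary_min_alt <- 8L
  stricter$wes_secondary_min_alt <- 4L
  for (i in 1:200) {
    depth <- sample(20:300, 1); alt <- rbinom(1, depth, runif(1, 0, 0.4))
    pe <- sample(c(TRUE, FALSE), 1)
    lo <- call_site_in_sample(depth, alt, "wes", base, pe)
    hi <- call_site_in_sample(depth, alt, "wes", stricter, pe)
    if (lo == "absent") expect_identical(hi, "absent")
  }
})

test_that("calling sensitivity rises with purity on simulated patients", {
  recall <- vapply(c(0.2, 0.5, 0.8), function(p) {
    cfg <- sim_config(n_patients = 1, fraction_targeted = 0, n_snps = 0,
                      loh_events_per_patient = 0,
                      purity_range_precursor = c(p, p),
                      purity_range_cancer = c(p, p),
                      p_cancerization = 0, p_multifocal = 0,
                      p_independent_clone = 0, seed = 99)
    set.seed(substream_seed(99L, "recall"))
    pat <- simulate_patient(cfg, "P1")
    fx <- sim_patient_bundle(99)  # same planted tree geometry, fixed seed
    # rebuild read counts at this purity for the fixture's sites
    sites <- unique(do.call(rbind, lapply(fx$patient$nodes,
                                          function(n) n$alterations)))
    key <- paste(sites$chrom, sites$pos, sites$ref, sites$alt)
    smp <- fx$patient$samples
    vr <- do.call(rbind, lapply(seq_len(nrow(smp)), function(i) {
      s <- smp[i, ]
      g <- sample_genotype(fx$patient, s$sample_id)
      pur <- if (s$component == "normal") 0 else p
      set.seed(substream_seed(99L, paste0("rc", p, i)))
      rc <- simulate_read_counts(sites, key %in%
                                   paste(g$chrom, g$pos, g$ref, g$alt),
                                 pur, s$median_capture_coverage)
      data.frame(patient_id = "P1", sample_id = s$sample_id,
                 rc[, c("chrom", "pos", "ref", "alt", "gene", "is_hotspot",
                        "depth", "alt_count")], origin = "wes")
    }))
    cm <- build_call_matrix(list(samples = smp, variants = vr,
                                 driver_genes = cystevol:::DRIVER_GENES_15))
    canc <- cm[cm$sample_id == smp$sample_id[smp$component == "cancer"][1], ]
    g <- sample_genotype(fx$patient, smp$sample_id[smp$component == "cancer"][1])
    truth <- paste0(g$chrom, ":", g$pos, ":", g$ref, ">", g$alt)
    mean(canc$status[canc$site_id %in% truth] %in%
           c("present_primary", "present_secondary"))
  }, numeric(1))
  expect_true(all(diff(recall) >= 0))
  expect_gt(recall[3], 0.98)
})
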