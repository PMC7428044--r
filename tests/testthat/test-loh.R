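# Minor-allele-frequency segmentation, LOH calling, tiers, patient-level
# harmonization, merging and targeted extension.

sim_maf_series <- function(n, levels, depth = 100) {
  # levels: vector of per-SNP expected minor fractions
  alt <- rbinom(n, depth, levels)
  pmin(alt, depth - alt) / depth
}

test_that("constant balanced series yields a single segment", {
  set.seed(21)
  pos <- sort(sample.int(100e6, 200))
  maf <- sim_maf_series(200, rep(0.5, 200))
  seg <- segment_maf(pos, maf, n_perm = 200)
  expect_identical(nrow(seg), 1L)
  expect_identical(seg$n_snps, 200L)
})

test_that("a planted mAF step is found within 3 SNPs", {
  set.seed(22)
  pos <- sort(sample.int(200e6, 200))
  maf <- sim_maf_series(200, rep(c(0.5, 0.2), each = 100))
  seg <- segment_maf(pos, maf, n_perm = 200)
  expect_identical(nrow(seg), 2L)
  # breakpoint lies between SNP 97 and SNP 103
  expect_gte(seg$end[1], pos[97])
  expect_lte(seg$end[1], pos[103])
})

test_that("two planted steps give three segments with accurate medians", {
  set.seed(23)
  pos <- sort(sample.int(240e6, 300))
  truth <- rep(c(0.5, 0.25, 0.45), each = 100)
  maf <- sim_maf_series(300, truth, depth = 150)
  seg <- segment_maf(pos, maf, n_perm = 200)
  expect_identical(nrow(seg), 3L)
  expect_true(all(abs(seg$segment_maf - c(0.5, 0.25, 0.45)) < 0.03))
})

test_that("segmentation partitions the series: SNP counts conserved, no overlap", {
  set.seed(24)
  for (r in 1:5) {
    n <- sample(50:300, 1)
    pos <- sort(sample.int(200e6, n))
    maf <- sim_maf_series(n, runif(n, 0.2, 0.5))
    seg <- segment_maf(pos, maf, n_perm = 100)
    expect_identical(sum(seg$n_snps), n)
    expect_true(all(seg$end[-nrow(seg)] == seg$start[-1]))
  }
})

test_that("LOH call needs a tumor-normal segment mAF drop of at least 0.1", {
  expect_true(call_segment_loh(0.38, 0.50))
  expect_false(call_segment_loh(0.45, 0.50))
  expect_true(call_segment_loh(0.40, 0.50))   # boundary inclusive
})

test_that("purity proxy is the minimum mAF over long, SNP-rich segments", {
  segs <- data.frame(start = c(0, 0, 0), end = c(20e6, 30e6, 15e6),
                     n_snps = c(50L, 40L, 60L),
                     segment_maf = c(0.48, 0.31, 0.22))
  expect_identical(sample_purity_proxy(segs), 0.22)
  short <- data.frame(start = 0, end = 5e6, n_snps = 100L, segment_maf = 0.1)
  expect_identical(sample_purity_proxy(short), 0.5)  # nothing eligible
  sparse <- data.frame(start = 0, end = 50e6, n_snps = 10L, segment_maf = 0.1)
  expect_identical(sample_purity_proxy(sparse), 0.5)
})

test_that("confidence tiers partition distance to the sample minimum mAF", {
  expect_identical(assign_tier(0.20, 0.15), "high")
  expect_identical(assign_tier(0.30, 0.15), "intermediate")
  expect_identical(assign_tier(0.40, 0.15), "low")
  expect_identical(assign_tier(0.25, 0.15), "intermediate")  # d = 0.1 boundary
  expect_identical(assign_tier(0.35, 0.15), "low")           # d = 0.2 boundary
})

# build a two-tumor-sample patient with one planted event in the cancer only
harmonized_grid <- function(seed, type = "copy_neutral_loh", purity = 0.5,
                            len = 30e6, both = FALSE, n_perm = 200) {
  set.seed(seed)
  ev <- data.frame(event_id = "e", chrom = "chr2", start = 50e6,
                   end = 50e6 + len, type = type, node = "x")
  snp_pos <- data.frame(chrom = rep(c("chr2", "chr3"), c(500, 400)),
                        pos = c(sort(sample.int(243e6, 500)),
                                sort(sample.int(198e6, 400))))
  params <- default_config()$loh
  params$seg_perms <- n_perm
  n <- cbind(sample_id = "N", simulate_snp_counts(snp_pos, NULL, 0, 170))
  hg <- cbind(sample_id = "HG",
              simulate_snp_counts(snp_pos, if (both) ev, purity, 170))
  ca <- cbind(sample_id = "C", simulate_snp_counts(snp_pos, ev, purity, 170))
  snps <- rbind(n, hg, ca)
  segs <- list(HG = segment_sample_maf(hg, params),
               C = segment_sample_maf(ca, params))
  grid <- harmonize_patient_segments(segs, snps, "N", params)
  list(grid = merge_adjacent(grid, snps, params), snps = snps,
       params = params, ev = ev)
}

test_that("cancer-only LOH is classified differential with the right partition", {
  h <- harmonized_grid(31)
  segs <- h$grid$segments
  hit <- segs[segs$chrom == "chr2" & segs$class == "differential", ]
  expect_gte(nrow(hit), 1)
  cells <- h$grid$cells[h$grid$cells$seg_id == hit$seg_id[1], ]
  expect_true(cells$loh[cells$sample_id == "C"])
  expect_false(cells$loh[cells$sample_id == "HG"])
  expect_identical(cells$tier[cells$sample_id == "C"], "high")
  expect_lt(abs(cells$segment_maf[cells$sample_id == "C"] - 0.25), 0.03)
})

test_that("LOH carried by all tumor samples is classified uniform", {
  h <- harmonized_grid(32, both = TRUE)
  segs <- h$grid$segments
  hit <- segs[segs$chrom == "chr2", ]
  expect_gte(nrow(hit), 1)
  expect_true(all(hit$class == "uniform"))
})

test_that("merging joins near-identical neighbours and is idempotent", {
  h <- harmonized_grid(33)
  params <- h$params
  m1 <- merge_adjacent(h$grid, h$snps, params)
  m2 <- merge_adjacent(m1, h$snps, params)
  expect_identical(m1$segments[, c("chrom", "start", "end", "class")],
                   m2$segments[, c("chrom", "start", "end", "class")])
  # merging never flips an LOH call
  before <- h$grid$cells[order(h$grid$cells$seg_id, h$grid$cells$sample_id), ]
  for (sid in unique(m1$cells$seg_id)) {
    cc <- m1$cells[m1$cells$seg_id == sid, ]
    orig <- before[before$seg_id == sid, ]
    if (nrow(orig)) expect_identical(cc$loh[order(cc$sample_id)],
                                     orig$loh[order(orig$sample_id)])
  }
})

test_that("adjacent-segment merge rules: window and identical call vectors", {
  grid <- list(
    segments = data.frame(seg_id = 1:2, chrom = "chr1",
                          start = c(0, 34e6), end = c(30e6, 60e6),
                          class = "differential", stringsAsFactors = FALSE),
    cells = rbind(
      data.frame(seg_id = 1, sample_id = c("N", "C"), n_snps = 30L,
                 segment_maf = c(0.5, 0.25), loh = c(FALSE, TRUE),
                 tier = c("none", "high")),
      data.frame(seg_id = 2, sample_id = c("N", "C"), n_snps = 30L,
                 segment_maf = c(0.5, 0.25), loh = c(FALSE, TRUE),
                 tier = c("none", "high"))),
    normal_id = "N", min_sample_maf = c(C = 0.25))
  class(grid) <- "patient_segment_grid"
  set.seed(34)
  snps <- data.frame(sample_id = rep(c("N", "C"), each = 120),
                     chrom = "chr1", pos = rep(sort(sample.int(60e6, 120)), 2),
                     ref_count = 50L, alt_count = 25L)
  params <- default_config()$loh
  merged <- merge_adjacent(grid, snps, params)   # 4 Mb gap -> merge
  expect_identical(nrow(merged$segments), 1L)
  expect_identical(merged$segments$end, 60e6)
  grid6 <- grid; grid6$segments$start[2] <- 36e6  # 6 Mb gap -> no merge
  expect_identical(nrow(merge_adjacent(grid6, snps, params)$segments), 2L)
  gdiff <- grid                                   # differing call vector
  gdiff$cells$loh[gdiff$cells$seg_id == 2 & gdiff$cells$sample_id == "C"] <- FALSE
  expect_identical(nrow(merge_adjacent(gdiff, snps, params)$segments), 2L)
})

test_that("targeted extension calls LOH from qualifying SNPs or flags unknown", {
  h <- harmonized_grid(35, purity = 0.5)
  seg2 <- h$grid$segments[h$grid$segments$chrom == "chr2", ]
  expect_gte(nrow(seg2), 1)
  set.seed(36)
  # targeted SNPs only inside the chr2 event, depth >= 20
  inside <- data.frame(
    chrom = "chr2", pos = sort(sample(seq(50e6 + 1, 80e6), 40)))
  t_snp <- cbind(sample_id = "T1",
                 simulate_snp_counts(inside, h$ev, 0.5, 120))
  t_snp <- data.frame(patient_id = "P1", t_snp)
  g2 <- extend_to_targeted(h$grid, t_snp, h$params)
  tc <- g2$cells[g2$cells$sample_id == "T1", ]
  hit <- tc[tc$seg_id %in% seg2$seg_id & tc$n_snps > 0, ]
  expect_gte(nrow(hit), 1)
  expect_true(any(hit$loh))
  expect_lt(min(abs(hit$segment_maf[hit$loh] - 0.25)), 0.03)
  # segments with no qualifying SNPs are unknown
  none <- tc[tc$n_snps == 0, ]
  if (nrow(none)) expect_true(all(none$tier == "unknown" & is.na(none$loh)))
  # low-coverage SNPs are discarded
  t_low <- t_snp
  keep <- t_low$ref_count + t_low$alt_count
  t_low$ref_count <- 5L; t_low$alt_count <- 5L
  g3 <- extend_to_targeted(h$grid, t_low, h$params)
  tl <- g3$cells[g3$cells$sample_id == "T1", ]
  expect_true(all(tl$n_snps == 0))
})
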