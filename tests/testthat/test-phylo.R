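# Alteration clusters, singleton rescue, copy-loss exclusion, clonal-mixing
# splits, and ancestry classification.

bin_mat <- function(rows, samples) {
  m <- do.call(rbind, rows)
  colnames(m) <- samples
  rownames(m) <- names(rows)
  attr(m, "events") <- data.frame(event_id = names(rows), kind = "mutation",
                                  gene = NA, is_hotspot = FALSE)
  m
}

test_that("binary matrix reflects calls, LOH segments and focal CNAs", {
  cm <- expand.grid(site_id = c("m1", "m2"), sample_id = c("s1", "s2", "s3"),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cm$patient_id <- "P1"
  cm$status <- c("present_primary", "present_primary",  # s1
                 "present_secondary", "absent",         # s2
                 "absent", "present_primary")           # s3
  cm$depth <- 100; cm$alt_count <- 10; cm$vaf <- 0.1
  cm$gene <- "G"; cm$is_hotspot <- FALSE
  grid <- list(segments = data.frame(seg_id = 1:2, chrom = c("chr1", "chr2"),
                                     start = 0, end = 30e6,
                                     class = c("differential", "uniform")),
               cells = rbind(
                 data.frame(seg_id = 1, sample_id = c("s1", "s2", "s3"),
                            n_snps = 30, segment_maf = 0.3,
                            loh = c(FALSE, FALSE, TRUE), tier = "high"),
                 data.frame(seg_id = 2, sample_id = c("s1", "s2", "s3"),
                            n_snps = 30, segment_maf = 0.3,
                            loh = TRUE, tier = "high")),
               normal_id = "N")
  class(grid) <- "patient_segment_grid"
  mat <- build_binary_matrix(cm, grid)
  expect_identical(dim(mat), c(4L, 3L))
  expect_identical(unname(mat["m1", ]), c(1L, 1L, 0L))
  expect_identical(unname(mat["loh:chr1:0-3e+07", ]), c(0L, 0L, 1L))
  expect_identical(unname(mat["loh:chr2:0-3e+07", ]), c(1L, 1L, 1L))
})

test_that("indeterminate calls are imputed to the majority and logged", {
  cm <- expand.grid(site_id = "m1", sample_id = c("s1", "s2", "s3"),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cm$patient_id <- "P1"
  cm$status <- c("present_primary", "present_primary",
                 "indeterminate_low_coverage")
  cm$depth <- 100; cm$alt_count <- 10; cm$vaf <- 0.1
  cm$gene <- "G"; cm$is_hotspot <- FALSE
  mat <- build_binary_matrix(cm)
  expect_identical(unname(mat["m1", "s3"]), 1L)
  expect_identical(attr(mat, "imputed")$sample_id, "s3")
})

test_that("patterns cluster by identity with a >= 2 member rule", {
  m <- bin_mat(list(a = c(1L,1L,0L), b = c(1L,1L,0L), c = c(1L,1L,0L),
                    d = c(0L,1L,1L), e = c(0L,1L,1L), f = c(1L,0L,0L)),
               c("s1", "s2", "s3"))
  cl <- cluster_patterns(m)
  expect_identical(nrow(cl$patterns), 2L)
  expect_identical(unname(sort(lengths(cl$members), decreasing = TRUE)),
                   c(3L, 2L))
  expect_identical(cl$singletons, "f")
  # all identical -> one cluster, no singletons
  m2 <- bin_mat(list(a = c(1L,1L), b = c(1L,1L)), c("s1", "s2"))
  cl2 <- cluster_patterns(m2)
  expect_identical(nrow(cl2$patterns), 1L)
  expect_identical(length(cl2$singletons), 0L)
  # all distinct -> no clusters
  m3 <- bin_mat(list(a = c(1L,0L), b = c(0L,1L)), c("s1", "s2"))
  expect_identical(nrow(cluster_patterns(m3)$patterns), 0L)
  expect_identical(length(cluster_patterns(m3)$singletons), 2L)
})

test_that("clustering output is invariant to row order", {
  set.seed(8)
  m <- bin_mat(setNames(lapply(1:8, function(i)
    as.integer(rbinom(3, 1, 0.5))), paste0("e", 1:8)), c("s1", "s2", "s3"))
  cl1 <- cluster_patterns(m)
  cl2 <- cluster_patterns(m[sample(nrow(m)), ])
  expect_identical(cl1$patterns, cl2$patterns)
  expect_identical(lapply(cl1$members, sort), lapply(cl2$members, sort))
  expect_identical(sort(cl1$singletons), sort(cl2$singletons))
})

rescue_fixture <- function(alt_in_s1, depth_in_s1, loh = FALSE) {
  m <- bin_mat(list(a = c(1L,1L,0L), b = c(1L,1L,0L), x = c(0L,1L,0L)),
               c("s1", "s2", "s3"))
  cm <- expand.grid(site_id = c("a", "b", "x"),
                    sample_id = c("s1", "s2", "s3"),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cm$patient_id <- "P1"
  cm$depth <- 100; cm$alt_count <- 20
  cm$depth[cm$site_id == "x" & cm$sample_id == "s1"] <- depth_in_s1
  cm$alt_count[cm$site_id == "x" & cm$sample_id == "s1"] <- alt_in_s1
  cm$vaf <- cm$alt_count / cm$depth
  cm$loh <- loh
  list(m = m, cm = cm)
}

test_that("a near-miss singleton is merged into its cluster and logged", {
  f <- rescue_fixture(4L, 100L)   # one read below the 5-read cut
  cl <- cluster_patterns(f$m)
  out <- rescue_singletons(cl, f$m, f$cm)
  expect_identical(length(out$singletons), 0L)
  expect_identical(out$corrections$event_id, "x")
  expect_identical(out$corrections$sample_id, "s1")
  expect_identical(out$corrections$reason, "near_miss_presence")
})

test_that("a confident absence is not merged, but LOH at the locus is", {
  f <- rescue_fixture(0L, 200L)
  out <- rescue_singletons(cluster_patterns(f$m), f$m, f$cm)
  expect_identical(out$singletons, "x")
  f2 <- rescue_fixture(0L, 200L, loh = TRUE)
  out2 <- rescue_singletons(cluster_patterns(f2$m), f2$m, f2$cm)
  expect_identical(length(out2$singletons), 0L)
  expect_identical(out2$corrections$reason, "loh_at_locus")
})

test_that("singletons differing in two samples are never merged", {
  m <- bin_mat(list(a = c(1L,1L,0L), b = c(1L,1L,0L), x = c(0L,0L,1L)),
               c("s1", "s2", "s3"))
  cm <- expand.grid(site_id = c("a", "b", "x"),
                    sample_id = c("s1", "s2", "s3"),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cm$patient_id <- "P1"; cm$depth <- 100; cm$alt_count <- 4
  cm$vaf <- 0.04; cm$loh <- TRUE
  out <- rescue_singletons(cluster_patterns(m), m, cm)
  expect_identical(out$singletons, "x")
})

test_that("copy-loss-ambiguous absences are excluded in fully-WES patients", {
  m <- bin_mat(list(a = c(1L, 0L), b = c(1L, 0L)), c("s1", "s2"))
  cm <- expand.grid(site_id = c("a", "b"), sample_id = c("s1", "s2"),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cm$patient_id <- "P1"; cm$depth <- 100; cm$alt_count <- 0; cm$vaf <- 0
  cm$loh <- c(FALSE, FALSE, TRUE, FALSE)  # s2 has LOH at site a only
  out <- exclude_cn_ambiguous(m, cm, wes_only = TRUE)
  expect_identical(rownames(out), "b")
  # rule not applied when targeted samples are present
  out2 <- exclude_cn_ambiguous(m, cm, wes_only = FALSE)
  expect_identical(nrow(out2), 2L)
})

test_that("non-nested co-occurring clusters split the mixed sample", {
  m <- bin_mat(list(a1 = c(1L,1L,0L), a2 = c(1L,1L,0L),
                    b1 = c(0L,1L,1L), b2 = c(0L,1L,1L)),
               c("s1", "s2", "s3"))
  cl <- cluster_patterns(m)
  out <- split_mixed_samples(cl)
  expect_false("s2" %in% out$samples)
  expect_identical(sum(grepl("^s2_clone", out$samples)), 2L)
  expect_identical(out$splits$sample_id, "s2")
  # membership unchanged
  expect_identical(lapply(cl$members, sort), lapply(out$members, sort))
  # each subclone carries exactly one of the pair
  pa <- out$patterns[, grepl("^s2_clone", colnames(out$patterns))]
  expect_equal(sort(unname(colSums(pa))), c(1, 1))
})

test_that("nested clusters do not trigger a split", {
  m <- bin_mat(list(a1 = c(1L,1L), a2 = c(1L,1L), b1 = c(1L,0L),
                    b2 = c(1L,0L)), c("s1", "s2"))
  out <- split_mixed_samples(cluster_patterns(m))
  expect_identical(out$samples, c("s1", "s2"))
  expect_null(out$splits)
})

test_that("a planted mixed sample is deconvolved into the sibling genotypes", {
  # siblings B and C diverge after A; sample sM pools B and C cells
  samples <- c("sA", "sB", "sC", "sM")
  m <- bin_mat(list(t1 = c(1L,1L,1L,1L), t2 = c(1L,1L,1L,1L),
                    b1 = c(0L,1L,0L,1L), b2 = c(0L,1L,0L,1L),
                    c1 = c(0L,0L,1L,1L), c2 = c(0L,0L,1L,1L)), samples)
  out <- split_mixed_samples(cluster_patterns(m))
  sub <- out$patterns[, grepl("^sM_clone", colnames(out$patterns)), drop = FALSE]
  got <- apply(sub, 2, paste, collapse = "")
  ref <- apply(out$patterns[, c("sB", "sC")], 2, paste, collapse = "")
  expect_setequal(unname(got), unname(ref))
})

ancestry_cm <- function(status_by_sample, hot = NULL) {
  sites <- names(status_by_sample[[1]])
  cm <- do.call(rbind, lapply(names(status_by_sample), function(s)
    data.frame(patient_id = "P1", site_id = sites, sample_id = s,
               status = unname(status_by_sample[[s]]),
               is_hotspot = sites %in% (hot %||% character()),
               stringsAsFactors = FALSE)))
  cm
}

test_that("ancestry labels: cancerization, independent clone, ordinary precursor", {
  `%||%` <- cystevol:::`%||%`
  sites <- c("t1", "t2", "c1", "x1", "k")
  pp <- "present_primary"; ab <- "absent"
  cm <- ancestry_cm(list(
    C  = setNames(c(pp, pp, pp, ab, pp), sites),
    X  = setNames(c(pp, pp, pp, pp, pp), sites),   # superset of C
    HG = setNames(c(pp, pp, ab, ab, pp), sites),   # shares trunk only
    I  = setNames(c(ab, ab, ab, ab, pp), sites)),  # hotspot only
    hot = "k")
  samples <- rbind(meta_row("C", "cancer"),
                   meta_row("X", "cancerization_suspect"),
                   meta_row("HG", "high_grade"), meta_row("I", "low_grade"))
  out <- classify_ancestry(cm, samples)
  expect_identical(out$label[out$sample_id == "X"], "cancerization")
  expect_identical(out$label[out$sample_id == "HG"], "precursor_lineage")
  expect_identical(out$label[out$sample_id == "I"], "independent_clone")
})

test_that("planted scenarios are labeled correctly end to end", {
  for (scn in c("cancerization", "independent_clone")) {
    fx <- sim_patient_bundle(300 + nchar(scn), forced = scn)
    cm <- build_call_matrix(fx$bundle)
    anc <- classify_ancestry(cm, fx$patient$samples)
    sid <- if (scn == "cancerization") "P1_X" else "P1_I"
    expect_identical(anc$label[anc$sample_id == sid], scn)
  }
})

test_that("removing driver-labeled alterations leaves the topology unchanged", {
  skip_if_not_installed("phangorn")
  fx <- sim_patient_bundle(411)
  cm <- build_call_matrix(fx$bundle)
  mat <- build_binary_matrix(cm)
  cl <- cluster_patterns(mat)
  t_all <- infer_parsimony_tree(cl$patterns, normal_label = "P1_N")
  drivers <- attr(mat, "events")$event_id[
    attr(mat, "events")$gene %in% cystevol:::DRIVER_GENES_15 |
      attr(mat, "events")$is_hotspot]
  m2 <- mat[setdiff(rownames(mat), drivers), , drop = FALSE]
  t_nodrv <- infer_parsimony_tree(cluster_patterns(m2)$patterns,
                                  normal_label = "P1_N")
  rf <- phangorn::RF.dist(ape::unroot(t_all$trees[[1]]),
                          ape::unroot(t_nodrv$trees[[1]]))
  expect_equal(unname(rf), 0)
})
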