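# End-to-end orchestration: calling -> copy number -> LOH -> phylogeny ->
# timing, with per-stage seeding, per-patient outputs, and a run log.

#' Run the full analysis pipeline on a cohort bundle
#'
#' Executes the stages in study order and writes per-patient and cohort
#' outputs under `out_dir`: `call_matrix.tsv`, `gene_copy.tsv`,
#' `focal_cna.tsv`, `loh_segments.tsv`, `clusters.tsv`, `ancestry.tsv`,
#' `trees/<patient>.nwk`, `timing.tsv`, `timing_summary.json` and
#' `run.log` (resolved config hash and seed). Stages with missing inputs
#' (no SNP table, no panel depths) are skipped with a warning and noted in
#' the log. Re-running with the same bundle, config and seed reproduces the
#' outputs byte for byte.
#'
#' @param bundle A validated cohort bundle.
#' @param config Pipeline configuration ([default_config()]).
#' @param out_dir Output directory.
#' @return Invisible list with the in-memory stage results.
#' @export
run_pipeline <- function(bundle, config = default_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out_dir, "trees"), showWarnings = FALSE)
  log_lines <- c(
    paste0("cystevol run ", "seed=", config$seed),
    paste0("config_md5=", config_hash(config)))
  note <- function(...) log_lines <<- c(log_lines, paste0(...))
  tsv <- function(d, f) utils::write.table(
    d, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)

  # --- mutation calling ---------------------------------------------------
  cm <- build_call_matrix(bundle, config$calling)
  tsv(cm[, c("patient_id", "site_id", "sample_id", "status", "depth",
             "alt_count", "vaf")], "call_matrix.tsv")
  note("calling: ", nrow(cm), " site x sample calls")

  # --- copy number --------------------------------------------------------
  gene_copy <- NULL; focal <- NULL
  if (!is.null(bundle$panel_depths) && nrow(bundle$panel_depths) > 0) {
    gene_copy <- panel_copy_ratios(bundle$panel_depths, bundle$panel,
                                   gc_correct = config$copy_number$gc_correct,
                                   params = config$copy_number)
    tsv(gene_copy, "gene_copy.tsv")
    note("copy_number: panel ratios for ",
         length(unique(gene_copy$sample_id)), " samples")
  } else note("copy_number: no panel depths; panel stage skipped")
  if (!is.null(bundle$cn_segments) && nrow(bundle$cn_segments) > 0) {
    focal <- screen_focal_cnas(bundle$cn_segments, bundle$driver_genes,
                               params = config$copy_number)
    tsv(focal, "focal_cna.tsv")
    cm <- annotate_mutation_loh(cm, bundle$cn_segments)
    note("copy_number: ", nrow(focal), " focal CNA candidates")
  } else {
    cm$loh <- NA
    note("copy_number: no allele-specific segments; focal screen skipped")
  }

  # --- LOH ----------------------------------------------------------------
  grids <- list()
  if (!is.null(bundle$snps) && nrow(bundle$snps) > 0) {
    for (pid in unique(bundle$samples$patient_id)) {
      ps <- bundle$samples[bundle$samples$patient_id == pid, ]
      normal_id <- ps$sample_id[ps$component == "normal"]
      wes_tumor <- ps$sample_id[ps$assay == "wes" & ps$component != "normal"]
      psnp <- bundle$snps[bundle$snps$patient_id == pid, ]
      if (length(wes_tumor) == 0 || nrow(psnp) == 0) next
      segs <- list()
      for (s in wes_tumor) {
        set.seed(substream_seed(config$seed, paste0("loh-", s)))
        segs[[s]] <- segment_sample_maf(psnp[psnp$sample_id == s, ],
                                        config$loh)
      }
      wes_snp <- psnp[psnp$sample_id %in% c(wes_tumor, normal_id), ]
      grid <- harmonize_patient_segments(segs, wes_snp, normal_id, config$loh)
      grid <- merge_adjacent(grid, wes_snp, config$loh)
      tsnp <- psnp[psnp$sample_id %in%
                     ps$sample_id[ps$assay == "targeted"], ]
      grid <- extend_to_targeted(grid, tsnp, config$loh)
      grids[[pid]] <- grid
    }
    loh_out <- do.call(rbind, lapply(names(grids), function(pid) {
      g <- grids[[pid]]
      if (nrow(g$segments) == 0) return(NULL)
      m <- merge(g$segments, g$cells, by = "seg_id")
      cbind(patient_id = pid, m)
    }))
    if (!is.null(loh_out)) tsv(loh_out, "loh_segments.tsv")
    note("loh: patient-level segments for ", length(grids), " patients")
  } else {
    warning("no SNP table; LOH stage skipped")
    note("loh: skipped (no SNP table)")
  }

  # --- phylogeny ----------------------------------------------------------
  clusters_out <- list(); ancestry_out <- list(); trees <- list()
  for (pid in unique(bundle$samples$patient_id)) {
    ps <- bundle$samples[bundle$samples$patient_id == pid, ]
    pcm <- cm[cm$patient_id == pid, ]
    if (nrow(pcm) == 0) next
    mat <- build_binary_matrix(pcm, grids[[pid]],
                               if (!is.null(focal))
                                 focal[focal$sample_id %in% ps$sample_id, ])
    if (nrow(mat) == 0) { note("phylogeny: ", pid, " no informative events"); next }
    wes_only <- all(ps$assay == "wes")
    mat <- exclude_cn_ambiguous(mat, pcm, wes_only = wes_only)
    if (nrow(mat) == 0) next
    cl <- cluster_patterns(mat)
    min_alt <- per_sample_min_alt(ps, config$calling)
    cl <- rescue_singletons(cl, mat, pcm, config$calling,
                            config$phylo$near_miss_margin, min_alt)
    cl <- split_mixed_samples(cl)
    ancestry_out[[pid]] <- cbind(patient_id = pid,
                                 classify_ancestry(pcm, ps))
    if (nrow(cl$patterns) > 0) {
      clusters_out[[pid]] <- data.frame(
        patient_id = pid, cluster_id = rownames(cl$patterns),
        pattern = apply(cl$patterns, 1, paste, collapse = ""),
        n_members = lengths(cl$members),
        members = vapply(cl$members, paste, character(1), collapse = ","),
        stringsAsFactors = FALSE)
      dedup <- dedup_pattern_columns(cl$patterns)
      n_leaves <- ncol(dedup$patterns) + 1
      if (n_leaves <= config$phylo$max_leaves) {
        tr <- infer_parsimony_tree(dedup$patterns,
                                   cluster_sizes = lengths(cl$members),
                                   max_leaves = config$phylo$max_leaves)
        trees[[pid]] <- tr
        write_newick(tr, file.path(out_dir, "trees", paste0(pid, ".nwk")))
        note("phylogeny: ", pid, " score=", tr$score, " trees=",
             length(tr$newick))
      } else note("phylogeny: ", pid, " skipped (", n_leaves,
                  " leaves exceeds cap)")
    }
  }
  if (length(clusters_out))
    tsv(do.call(rbind, clusters_out), "clusters.tsv")
  if (length(ancestry_out))
    tsv(do.call(rbind, ancestry_out), "ancestry.tsv")

  # --- timing -------------------------------------------------------------
  timing <- NULL
  pairs <- timing_pairs(bundle$samples)
  cancerized <- unlist(lapply(ancestry_out, function(a)
    a$patient_id[a$label == "cancerization" & a$component == "high_grade"]))
  if (nrow(pairs) > 0) {
    yd <- count_acquired_mutations(cm, pairs, exclude = cancerized)
    if (!is.null(yd) && nrow(yd) > 0) {
      timing <- summarize_mu_grid(
        yd$y, mu_grid = config$timing$mu_grid, patient_ids = yd$patient_id,
        seed = substream_seed(config$seed, "timing"),
        chains = config$timing$chains, iters = config$timing$iters,
        burn_in = config$timing$burn_in)
      tsv(timing$per_mu, "timing.tsv")
      jsonlite::write_json(
        list(cohort_average_median_T = timing$cohort_average_median_T,
             per_patient = timing$per_patient),
        file.path(out_dir, "timing_summary.json"),
        auto_unbox = TRUE, digits = 10, dataframe = "columns")
      note("timing: ", nrow(yd), " patients, cohort average median T = ",
           round(timing$cohort_average_median_T, 2), " years")
    }
  } else note("timing: no paired whole-exome samples; skipped")

  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(list(call_matrix = cm, gene_copy = gene_copy, focal = focal,
                 loh = grids, trees = trees, timing = timing))
}

# high-grade precursor / cancer whole-exome pairing per patient
timing_pairs <- function(samples) {
  rows <- list()
  for (pid in unique(samples$patient_id)) {
    ps <- samples[samples$patient_id == pid & samples$assay == "wes", ]
    prec <- ps$sample_id[ps$component == "high_grade"]
    canc <- ps$sample_id[ps$component == "cancer"]
    if (length(prec) >= 1 && length(canc) >= 1)
      rows[[pid]] <- data.frame(patient_id = pid, precursor_id = prec[1],
                                cancer_id = canc[1], stringsAsFactors = FALSE)
  }
  do.call(rbind, rows) %||%
    data.frame(patient_id = character(), precursor_id = character(),
               cancer_id = character())
}

per_sample_min_alt <- function(ps, thresholds) {
  medians <- setNames(ps$median_capture_coverage, ps$sample_id)
  wes_mean <- mean(medians[ps$assay == "wes"])
  vapply(seq_len(nrow(ps)), function(i) {
    if (ps$assay[i] == "targeted")
      scaled_min_alt_reads(thresholds$targeted_alt_scale_base,
                           medians[i], wes_mean)
    else as.integer(thresholds$wes_primary_min_alt)
  }, integer(1)) |> setNames(ps$sample_id)
}

# collapse samples with identical character columns into one leaf
dedup_pattern_columns <- function(patterns) {
  key <- apply(patterns, 2, paste, collapse = "")
  groups <- split(colnames(patterns), key)
  reps <- vapply(groups, function(g) g[1], character(1))
  newp <- patterns[, reps, drop = FALSE]
  colnames(newp) <- vapply(groups, paste, character(1), collapse = "+")
  list(patterns = newp, groups = groups)
}
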