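# Synthetic multi-region cohort simulator. Emulates the study design:
# 18-patient cohorts with 2-3 whole-exome samples per patient (high-grade
# precursor, invasive cancer, optionally low-grade precursor) plus deep
# targeted samples in a subset of patients, purity differences between
# precursor and cancer, branch-specific mutations, independent KRAS-initiated
# clones, cancerization of ducts, genome-scale LOH events, and latent
# progression times drawn from the timing model.

# KRAS codon-12 / GNAS codon-201 stand-ins: a small fixed pool of hotspot
# sites reused across independent clones.
HOTSPOT_SITES <- data.frame(
  chrom = c("chr12", "chr12", "chr12", "chr20"),
  pos = c(25398284L, 25398284L, 25398285L, 57484420L),
  ref = c("G", "G", "G", "C"),
  alt = c("T", "A", "C", "T"),
  gene = c("KRAS", "KRAS", "KRAS", "GNAS"),
  stringsAsFactors = FALSE
)

#' Simulation configuration
#'
#' Defaults reproduce the cohort scale of the study: 18 patients, 2-3
#' whole-exome tumor samples each, targeted sequencing (8-22 extra samples)
#' in 7/18 of patients, whole-exome coverage 177x, targeted coverage 508x,
#' higher purity in noninvasive than invasive samples, and per-sample
#' mutation totals in the observed 26-111 range (trunk mean 45, precursor
#' branch mean 15, cancer branch Poisson(mu * T) with T from the
#' Gamma(mode 3 y, sd 2 y) progression-time prior and mu = 5 mutations/year).
#'
#' @param n_patients Number of patients.
#' @param samples_per_patient Range of whole-exome tumor samples per patient.
#' @param fraction_targeted Fraction of patients with targeted multi-region
#'   sampling.
#' @param n_targeted_range Targeted samples per targeted patient.
#' @param mutation_rate_per_year True somatic mutation rate mu (mutations/yr).
#' @param progression_time_mode,progression_time_sd Mode and sd (years) of
#'   the Gamma distribution of latent progression times.
#' @param purity_range_precursor,purity_range_cancer Uniform purity ranges.
#' @param wes_mean_coverage,targeted_mean_coverage Mean sequencing depths.
#' @param n_snps Germline heterozygous SNPs simulated genome-wide.
#' @param loh_events_per_patient LOH events planted per patient.
#' @param p_cancerization Probability of adding a sample descended from the
#'   cancer (intraductal spread).
#' @param p_multifocal Probability of a second, independently diverging
#'   invasive branch.
#' @param p_independent_clone Probability of a genetically independent
#'   hotspot-initiated clone.
#' @param trunk_mean,shared_mean,precursor_mean Poisson means for trunk,
#'   shared precursor/cancer, and precursor-private mutation counts.
#' @param error_rate Per-read sequencing error rate at non-mutant sites.
#' @param seed Master seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_patients = 18L,
                       samples_per_patient = c(2L, 3L),
                       fraction_targeted = 7 / 18,
                       n_targeted_range = c(8L, 22L),
                       mutation_rate_per_year = 5,
                       progression_time_mode = 3,
                       progression_time_sd = 2,
                       purity_range_precursor = c(0.5, 0.8),
                       purity_range_cancer = c(0.3, 0.6),
                       wes_mean_coverage = 177,
                       targeted_mean_coverage = 508,
                       n_snps = 6000L,
                       loh_events_per_patient = 2L,
                       p_cancerization = 2 / 18,
                       p_multifocal = 1 / 18,
                       p_independent_clone = 2 / 18,
                       trunk_mean = 45,
                       shared_mean = 8,
                       precursor_mean = 15,
                       error_rate = 0.001,
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$mutation_rate_per_year > 0, cfg$progression_time_sd > 0,
            all(unlist(cfg[c("fraction_targeted", "p_cancerization",
                             "p_multifocal", "p_independent_clone")]) >= 0),
            cfg$wes_mean_coverage > 0, cfg$targeted_mean_coverage > 0)
  class(cfg) <- "sim_config"
  cfg
}

random_sites <- function(n, avoid = NULL, genes = NULL) {
  if (n == 0) return(data.frame(chrom = character(), pos = integer(),
                                ref = character(), alt = character(),
                                gene = character(), is_hotspot = logical()))
  chrom <- sample(names(CHROM_LENGTHS_MB), n, replace = TRUE,
                  prob = CHROM_LENGTHS_MB)
  pos <- vapply(chrom, function(ch) {
    for (try in 1:20) {
      p <- sample.int(CHROM_LENGTHS_MB[[ch]] * 1e6, 1)
      bad <- !is.null(avoid) && any(avoid$chrom == ch & avoid$start < p &
                                      avoid$end >= p)
      if (!bad) return(p)
    }
    p
  }, integer(1))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             gene = if (is.null(genes))
               sprintf("GENE%04d", sample.int(5000, n, replace = TRUE))
             else genes,
             is_hotspot = FALSE, stringsAsFactors = FALSE, row.names = NULL)
}

#' Simulate one patient's clonal history and sampling design
#'
#' Builds a rooted clone tree: a trunk of shared alterations initiated by a
#' hotspot mutation, a low-grade branch (when a third whole-exome sample is
#' drawn), a shared precursor/cancer ancestor, a high-grade branch, and a
#' cancer branch carrying Poisson(mu * T) private alterations with the
#' latent progression time T drawn from the Gamma(mode m, sd s) prior.
#' Optional scenario nodes: a cancerization sample descended from the
#' cancer, a second independently diverging invasive branch (multifocal
#' invasion), and an independent hotspot-initiated clone sharing no
#' alterations with the cancer lineage. Targeted samples are attached to
#' tree nodes with small private alteration sets.
#'
#' @param config A [sim_config()].
#' @param patient_id Patient label.
#' @param targeted Should this patient get targeted multi-region samples?
#' @param forced_scenarios Optional character vector forcing scenarios on
#'   (`"cancerization"`, `"multifocal"`, `"independent_clone"`).
#' @return A `sim_patient` list: `nodes` (per-node alteration tables and
#'   parents), `samples` (metadata incl. purity and node), `loh_events`,
#'   `T_true`, `y_true`, `tree_newick` (whole-exome leaves plus normal).
#' @export
simulate_patient <- function(config, patient_id = "P01", targeted = FALSE,
                             forced_scenarios = NULL) {
  mu <- config$mutation_rate_per_year
  ab <- gamma_hyperparams(config$progression_time_mode,
                          config$progression_time_sd)
  T_true <- stats::rgamma(1, ab["a"], ab["b"])
  y_true <- stats::rpois(1, mu * T_true)

  want <- function(tag, p) (tag %in% forced_scenarios) || stats::runif(1) < p
  has_canc <- want("cancerization", config$p_cancerization)
  has_multi <- want("multifocal", config$p_multifocal)
  has_indep <- want("independent_clone", config$p_independent_clone)
  n_wes <- sample(seq(config$samples_per_patient[1],
                      config$samples_per_patient[2]), 1)

  # LOH events first so mutation positions can avoid them
  ev <- list()
  for (k in seq_len(config$loh_events_per_patient)) {
    ch <- sample(names(CHROM_LENGTHS_MB), 1)
    len <- stats::runif(1, 10e6, 80e6)
    start <- floor(stats::runif(1, 0, max(1, CHROM_LENGTHS_MB[[ch]] * 1e6 - len)))
    ev[[k]] <- data.frame(
      event_id = paste0(patient_id, "_loh", k), chrom = ch,
      start = start, end = floor(start + len),
      type = sample(c("hemizygous_deletion", "copy_neutral_loh"), 1),
      node = sample(c("trunk", "cancer"), 1), stringsAsFactors = FALSE)
  }
  loh_events <- if (length(ev)) do.call(rbind, ev) else NULL

  hs <- HOTSPOT_SITES[sample.int(nrow(HOTSPOT_SITES), 1), ]
  hs$is_hotspot <- TRUE
  node_alt <- function(mean_n) random_sites(stats::rpois(1, mean_n),
                                            avoid = loh_events)
  nodes <- list(
    trunk = list(parent = "root", alterations = rbind(hs, node_alt(config$trunk_mean))),
    anc = list(parent = "trunk", alterations = node_alt(config$shared_mean)),
    hg = list(parent = "anc", alterations = node_alt(config$precursor_mean)),
    cancer = list(parent = "anc",
                  alterations = random_sites(y_true, avoid = loh_events))
  )
  if (n_wes >= 3)
    nodes$lg <- list(parent = "trunk", alterations = node_alt(config$precursor_mean))
  if (has_canc)
    nodes$canc <- list(parent = "cancer", alterations = node_alt(4))
  if (has_multi) {
    # second invasion diverges before the high-grade/cancer ancestor, which
    # keeps the clone tree strictly binary (mid = extra mutations shared by
    # the high-grade precursor and the first cancer but not the second)
    nodes$mid <- list(parent = "anc", alterations = node_alt(config$shared_mean))
    nodes$hg$parent <- "mid"
    nodes$cancer$parent <- "mid"
    nodes$cancer2 <- list(parent = "anc", alterations = node_alt(15))
  }
  if (has_indep) {
    ih <- HOTSPOT_SITES[sample.int(nrow(HOTSPOT_SITES), 1), ]
    ih$is_hotspot <- TRUE
    nodes$indep <- list(parent = "root", alterations = rbind(ih, node_alt(10)))
  }

  runifr <- function(r) stats::runif(1, r[1], r[2])
  smp <- list()
  add_sample <- function(id, component, assay, node, purity_range) {
    cov_mean <- if (assay == "wes") config$wes_mean_coverage
    else config$targeted_mean_coverage
    smp[[length(smp) + 1]] <<- data.frame(
      sample_id = id, patient_id = patient_id, component = component,
      assay = assay,
      median_capture_coverage = round(cov_mean * stats::runif(1, 0.9, 1.1)),
      purity = if (component == "normal") 0 else runifr(purity_range),
      node = node, stringsAsFactors = FALSE)
  }
  add_sample(paste0(patient_id, "_N"), "normal", "wes", "root", NULL)
  if (!is.null(nodes$lg))
    add_sample(paste0(patient_id, "_LG"), "low_grade", "wes", "lg",
               config$purity_range_precursor)
  add_sample(paste0(patient_id, "_HG"), "high_grade", "wes", "hg",
             config$purity_range_precursor)
  add_sample(paste0(patient_id, "_C"), "cancer", "wes", "cancer",
             config$purity_range_cancer)
  if (has_multi)
    add_sample(paste0(patient_id, "_C2"), "cancer", "wes", "cancer2",
               config$purity_range_cancer)
  canc_assay <- if (targeted) "targeted" else "wes"
  if (has_canc)
    add_sample(paste0(patient_id, "_X"), "cancerization_suspect", canc_assay,
               "canc", config$purity_range_precursor)
  if (has_indep)
    add_sample(paste0(patient_id, "_I"), "low_grade", canc_assay, "indep",
               config$purity_range_precursor)
  if (targeted) {
    n_t <- sample(seq(config$n_targeted_range[1], config$n_targeted_range[2]), 1)
    attach_nodes <- intersect(c("trunk", "lg", "anc", "hg", "cancer"),
                              names(nodes))
    for (k in seq_len(n_t)) {
      nd <- sample(attach_nodes, 1)
      comp <- switch(nd, cancer = "cancer", lg = "low_grade",
                     trunk = "low_grade", "high_grade")
      prange <- if (comp == "cancer") config$purity_range_cancer
      else config$purity_range_precursor
      add_sample(sprintf("%s_T%02d", patient_id, k), comp, "targeted", nd,
                 prange)
    }
  }
  samples <- do.call(rbind, smp)

  # genotype monotonicity comes from path-union construction
  parent_of <- vapply(nodes, function(n) n$parent, character(1))
  path_nodes <- function(node) {
    out <- character(0)
    while (node != "root") { out <- c(node, out); node <- parent_of[[node]] }
    out
  }
  tree_newick <- planted_newick(samples, parent_of)

  structure(list(patient_id = patient_id, nodes = nodes, samples = samples,
                 loh_events = loh_events, T_true = unname(T_true),
                 y_true = y_true, path_nodes = path_nodes,
                 tree_newick = tree_newick,
                 scenarios = c(cancerization = has_canc,
                               multifocal = has_multi,
                               independent_clone = has_indep)),
            class = "sim_patient")
}

# newick for the planted clone tree over whole-exome tumor leaves + normal
planted_newick <- function(samples, parent_of) {
  wes <- samples[samples$assay == "wes" & samples$component != "normal", ]
  lab <- setNames(wes$sample_id, wes$node)
  sub <- function(node) {
    kids <- names(parent_of)[parent_of == node]
    parts <- character(0)
    if (node %in% names(lab)) parts <- c(parts, lab[[node]])
    for (k in kids) {
      s <- sub(k)
      if (nzchar(s)) parts <- c(parts, s)
    }
    if (length(parts) == 0) return("")
    if (length(parts) == 1) return(parts)
    paste0("(", paste(sort(parts), collapse = ","), ")")
  }
  body <- sub("root")
  paste0("(", samples$sample_id[samples$component == "normal"], ",",
         body, ");")
}

#' Genotype (alteration table) of one simulated sample
#'
#' Union of the alterations on the path from the root to the sample's node;
#' descendants therefore always carry supersets of their ancestors.
#'
#' @param patient A `sim_patient`.
#' @param sample_id Sample id.
#' @return Alteration table (`chrom, pos, ref, alt, gene, is_hotspot`).
#' @export
sample_genotype <- function(patient, sample_id) {
  node <- patient$samples$node[patient$samples$sample_id == sample_id]
  if (node == "root")
    return(random_sites(0))
  alts <- lapply(patient$path_nodes(node),
                 function(nd) patient$nodes[[nd]]$alterations)
  do.call(rbind, alts)
}

#' Simulate read counts at candidate sites for one sample
#'
#' Depth is Poisson at the sample's coverage; mutant reads are Binomial at
#' the expected variant allele fraction. A clonal heterozygous mutation in
#' a diploid region has expected VAF purity/2; sites with allele-specific
#' copy state (`mult`, `total_cn` columns) use
#' `purity * mult / (purity * total_cn + 2 (1 - purity))`. Non-mutant sites
#' (including the matched normal) draw mutant reads at the sequencing error
#' rate.
#'
#' @param sites Candidate site table (`chrom, pos, ref, alt, ...`).
#' @param present Logical vector: does this sample carry each site?
#' @param purity Sample purity in [0, 1].
#' @param coverage Mean sequencing depth.
#' @param error_rate Error rate at non-mutant sites.
#' @return `sites` with `depth` and `alt_count` columns appended.
#' @export
simulate_read_counts <- function(sites, present, purity, coverage,
                                 error_rate = 0.001) {
  stopifnot(length(present) == nrow(sites), purity >= 0, purity <= 1)
  mult <- sites$mult %||% rep(1, nrow(sites))
  total_cn <- sites$total_cn %||% rep(2, nrow(sites))
  vaf <- ifelse(present,
                purity * mult / (purity * total_cn + 2 * (1 - purity)),
                error_rate)
  depth <- stats::rpois(nrow(sites), coverage)
  alt <- stats::rbinom(nrow(sites), depth, pmin(vaf, 1))
  cbind(sites, depth = depth, alt_count = alt)
}

#' Simulate germline heterozygous SNP read counts for one sample
#'
#' Outside LOH events the expected minor allele fraction is 0.5. Inside a
#' hemizygous deletion carried by the sample it is (1-p)/(2-p) (one tumor
#' allele lost, with proportionally reduced depth); inside copy-neutral LOH
#' it is (1-p)/2. Read counts are Binomial at the sample's coverage.
#'
#' @param snp_pos SNP position table (`chrom, pos`), shared by all samples
#'   of the patient.
#' @param loh_events Events carried by this sample (may be `NULL`).
#' @param purity Sample purity.
#' @param coverage Mean depth.
#' @return `snp_pos` with `ref_count` and `alt_count` appended.
#' @export
simulate_snp_counts <- function(snp_pos, loh_events, purity, coverage) {
  n <- nrow(snp_pos)
  minor_frac <- rep(0.5, n)
  depth_factor <- rep(1, n)
  if (!is.null(loh_events) && nrow(loh_events) > 0) {
    for (i in seq_len(nrow(loh_events))) {
      e <- loh_events[i, ]
      inside <- snp_pos$chrom == e$chrom & snp_pos$pos > e$start &
        snp_pos$pos <= e$end
      if (e$type == "hemizygous_deletion") {
        minor_frac[inside] <- (1 - purity) / (2 - purity)
        depth_factor[inside] <- (2 - purity) / 2
      } else {
        minor_frac[inside] <- (1 - purity) / 2
      }
    }
  }
  depth <- stats::rpois(n, coverage * depth_factor)
  alt <- stats::rbinom(n, depth, minor_frac)
  cbind(snp_pos, ref_count = depth - alt, alt_count = alt)
}

#' Build a targeted panel definition
#'
#' Intervals covering the coding regions of the 15 driver genes plus
#' background genes, with GC fractions; roughly 185 kb total.
#'
#' @param n_background Background genes added to the panel.
#' @param intervals_per_gene Capture intervals per gene.
#' @return Data.frame `interval_id, chrom, start, end, gc_fraction, gene`.
#' @export
build_panel <- function(n_background = 10L, intervals_per_gene = 8L) {
  genes <- c(DRIVER_GENES_15, sprintf("BG%03d", seq_len(n_background)))
  rows <- list()
  for (g in seq_along(genes)) {
    ch <- names(CHROM_LENGTHS_MB)[(g - 1) %% 22 + 1]
    base <- 1e6 + g * 2e5
    for (i in seq_len(intervals_per_gene)) {
      start <- base + (i - 1) * 1200
      rows[[length(rows) + 1]] <- data.frame(
        interval_id = sprintf("%s_iv%02d", genes[g], i), chrom = ch,
        start = start, end = start + 900,
        gc_fraction = round(stats::runif(1, 0.3, 0.7), 3), gene = genes[g],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Simulate per-interval panel depths under planted gene copy states
#'
#' Interval depth is Poisson at `coverage * dosage * gc_bias`, where dosage
#' is `(2 (1 - p) + cn p) / 2` for the interval's gene copy number and the
#' GC bias is a mild quadratic in GC fraction (removed downstream by the
#' GC-decile correction).
#'
#' @param panel Panel definition from [build_panel()].
#' @param gene_cn Named vector of tumor copy numbers (default 2 everywhere).
#' @param purity Sample purity.
#' @param coverage Mean panel depth.
#' @param sample_id Sample label.
#' @param gc_bias_strength Amplitude of the GC bias.
#' @return Data.frame `sample_id, interval_id, median_depth`.
#' @export
simulate_panel_depths <- function(panel, gene_cn = NULL, purity = 1,
                                  coverage = 508, sample_id = "S1",
                                  gc_bias_strength = 0.3) {
  cn <- rep(2, nrow(panel))
  if (!is.null(gene_cn)) {
    hit <- panel$gene %in% names(gene_cn)
    cn[hit] <- gene_cn[panel$gene[hit]]
  }
  dosage <- (2 * (1 - purity) + cn * purity) / 2
  gc_bias <- 1 - gc_bias_strength * (panel$gc_fraction - 0.5)^2 * 4
  data.frame(sample_id = sample_id, interval_id = panel$interval_id,
             median_depth = stats::rpois(nrow(panel),
                                         pmax(coverage * dosage * gc_bias,
                                              0.01)),
             stringsAsFactors = FALSE)
}

#' Generate a full synthetic cohort
#'
#' Simulates every patient, then every sample's variant read counts, SNP
#' counts, allele-specific copy-number segments and (for targeted patients)
#' panel depths, in the input formats of [load_cohort()]. Deterministic
#' given the config seed.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_cohort`: `bundle` (a cohort bundle) and
#'   `truth` (per-patient truth records).
#' @export
generate_cohort <- function(config = sim_config()) {
  set.seed(substream_seed(config$seed, "cohort"))
  n_targeted <- round(config$fraction_targeted * config$n_patients)
  targeted_patients <- sample.int(config$n_patients, n_targeted)
  panel <- build_panel()

  samples <- list(); variants <- list(); snps <- list(); cnsegs <- list()
  paneldepths <- list(); truth <- list()
  for (p in seq_len(config$n_patients)) {
    pid <- sprintf("MTP%02d", p)
    set.seed(substream_seed(config$seed, paste0("patient-", pid)))
    pat <- simulate_patient(config, pid, targeted = p %in% targeted_patients)
    samples[[p]] <- pat$samples

    # candidate sites: union of all alterations of the patient
    sites <- unique(do.call(rbind, lapply(names(pat$nodes), function(nd)
      pat$nodes[[nd]]$alterations)))
    site_key <- paste(sites$chrom, sites$pos, sites$ref, sites$alt)
    snp_pos <- data.frame(
      chrom = sample(names(CHROM_LENGTHS_MB), config$n_snps, replace = TRUE,
                     prob = CHROM_LENGTHS_MB),
      pos = NA_integer_, stringsAsFactors = FALSE)
    snp_pos$pos <- vapply(snp_pos$chrom, function(ch)
      sample.int(CHROM_LENGTHS_MB[[ch]] * 1e6, 1), integer(1))
    snp_pos <- snp_pos[order(snp_pos$chrom, snp_pos$pos), ]

    for (i in seq_len(nrow(pat$samples))) {
      s <- pat$samples[i, ]
      geno <- sample_genotype(pat, s$sample_id)
      present <- site_key %in% paste(geno$chrom, geno$pos, geno$ref, geno$alt)
      rc <- simulate_read_counts(sites, present, s$purity,
                                 s$median_capture_coverage,
                                 config$error_rate)
      variants[[length(variants) + 1]] <- data.frame(
        patient_id = pid, sample_id = s$sample_id, rc[, c(
          "chrom", "pos", "ref", "alt", "gene", "is_hotspot",
          "depth", "alt_count")], origin = "wes", stringsAsFactors = FALSE)

      sample_events <- if (!is.null(pat$loh_events)) {
        nodeset <- if (s$node == "root") character(0) else
          pat$path_nodes(s$node)
        pat$loh_events[pat$loh_events$node %in% nodeset, , drop = FALSE]
      }
      snps[[length(snps) + 1]] <- data.frame(
        patient_id = pid, sample_id = s$sample_id,
        simulate_snp_counts(snp_pos, sample_events, s$purity,
                            s$median_capture_coverage),
        stringsAsFactors = FALSE)
      if (s$assay == "wes" && s$component != "normal") {
        cnsegs[[length(cnsegs) + 1]] <- ascn_segments(s$sample_id,
                                                      sample_events, s$purity)
      }
      if (s$assay == "targeted") {
        paneldepths[[length(paneldepths) + 1]] <-
          simulate_panel_depths(panel, NULL, s$purity,
                                s$median_capture_coverage, s$sample_id)
      }
    }
    truth[[pid]] <- list(
      patient_id = pid,
      tree_newick = pat$tree_newick,
      T_true = pat$T_true, y_true = pat$y_true,
      purity = setNames(pat$samples$purity, pat$samples$sample_id),
      sample_nodes = setNames(pat$samples$node, pat$samples$sample_id),
      scenarios = pat$scenarios,
      loh_events = pat$loh_events,
      branch_alterations = lapply(pat$nodes, function(n)
        paste0(n$alterations$chrom, ":", n$alterations$pos, ":",
               n$alterations$ref, ">", n$alterations$alt))
    )
  }
  bundle <- list(
    samples = do.call(rbind, samples)[, c("sample_id", "patient_id",
                                          "component", "assay",
                                          "median_capture_coverage")],
    variants = do.call(rbind, variants),
    snps = do.call(rbind, snps),
    panel = panel,
    panel_depths = do.call(rbind, paneldepths) %||% NULL,
    cn_segments = do.call(rbind, cnsegs) %||% NULL,
    driver_genes = DRIVER_GENES_15
  )
  class(bundle) <- c("cohort_bundle", "list")
  structure(list(bundle = bundle, truth = truth), class = "sim_cohort")
}

# allele-specific segments consistent with the sample's LOH events
ascn_segments <- function(sample_id, events, purity, ploidy = 2) {
  rows <- list()
  for (ch in names(CHROM_LENGTHS_MB)) {
    len <- CHROM_LENGTHS_MB[[ch]] * 1e6
    evs <- if (!is.null(events) && nrow(events) > 0)
      events[events$chrom == ch, , drop = FALSE]
    else NULL
    bounds <- c(0, if (!is.null(evs) && nrow(evs)) c(evs$start, evs$end), len)
    bounds <- sort(unique(pmin(bounds, len)))
    for (i in seq_len(length(bounds) - 1)) {
      lo <- bounds[i]; hi <- bounds[i + 1]
      mid <- (lo + hi) / 2
      inside <- !is.null(evs) && nrow(evs) > 0 &&
        any(evs$start <= mid & evs$end >= mid)
      type <- if (inside) evs$type[evs$start <= mid & evs$end >= mid][1]
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = sample_id, chrom = ch,
        start = as.integer(lo), end = as.integer(hi),
        total_cn = if (inside && type == "hemizygous_deletion") 1L else 2L,
        minor_cn = if (inside) 0L else 1L,
        cellular_fraction = if (inside) 1 else NA_real_,
        purity = purity, ploidy = ploidy, genes = "",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
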