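# Integrated mutation analysis: cross-sample re-genotyping of candidate
# somatic sites with assay-specific, coverage-scaled presence thresholds.

CALL_LEVELS <- c("present_primary", "present_secondary", "absent",
                 "indeterminate_low_coverage", "site_excluded")

#' Coverage-scaled minimum mutant read count for a targeted sample
#'
#' Deep targeted sequencing allows calling at a lower allele fraction, but
#' the minimum mutant-read requirement must grow with coverage to keep the
#' sequencing-error false-positive rate in check. The whole-exome threshold
#' of 5 mutant reads is scaled by the ratio of the targeted sample's median
#' coverage to the mean median coverage of the patient's whole-exome samples.
#'
#' @param base Baseline mutant-read threshold (whole-exome value, 5).
#' @param targeted_median_cov Median capture coverage of the targeted sample.
#' @param mean_wes_median_cov Mean of median coverages over the patient's
#'   whole-exome samples.
#' @return Integer threshold: `ceiling(base * ratio)`, floored at 2.
#' @export
scaled_min_alt_reads <- function(base, targeted_median_cov, mean_wes_median_cov) {
  if (targeted_median_cov <= 0 || mean_wes_median_cov <= 0)
    stop("coverages must be positive")
  max(2L, as.integer(ceiling(base * targeted_median_cov / mean_wes_median_cov)))
}

#' Site-level capture-efficiency filter
#'
#' A candidate locus is analyzable in a patient only when every sequenced
#' sample of the patient covers it at a depth strictly exceeding 20% of that
#' sample's median capture coverage; otherwise the locus is excluded in all
#' samples (insufficient or inconsistent capture).
#'
#' @param depths Numeric vector of depths at the site, one per sample.
#' @param sample_medians Matching vector of per-sample median coverages.
#' @param floor_fraction Fraction of the median that must be exceeded (0.20).
#' @return `TRUE` to keep the site, `FALSE` to exclude it everywhere.
#' @export
site_coverage_filter <- function(depths, sample_medians, floor_fraction = 0.20) {
  stopifnot(length(depths) == length(sample_medians))
  d <- ifelse(is.na(depths), 0, depths)
  all(d > floor_fraction * sample_medians)
}

#' Germline/somatic filter on the matched normal
#'
#' A candidate site is accepted as somatic only when the matched normal has
#' at least 10 distinct reads and a mutant allele fraction below 2%.
#'
#' @param normal_depth,normal_alt Read counts in the matched normal.
#' @param min_depth Minimum normal depth (10).
#' @param max_vaf Exclusive upper bound on normal VAF (0.02).
#' @return `TRUE` if the site passes.
#' @export
germline_somatic_filter <- function(normal_depth, normal_alt,
                                    min_depth = 10L, max_vaf = 0.02) {
  if (is.na(normal_depth) || is.na(normal_alt)) return(NA)
  if (normal_depth < min_depth) return(FALSE)
  (normal_alt / normal_depth) < max_vaf
}

#' Presence call for one site in one tumor sample
#'
#' Whole-exome samples: primary presence requires VAF >= 10% and >= 5 mutant
#' reads; when the mutation is primary in at least one sample of the patient,
#' two mutant reads suffice (secondary call), accommodating low-purity
#' precursor samples. Targeted samples: VAF >= 5% and a coverage-scaled
#' mutant-read minimum (see [scaled_min_alt_reads()]); no secondary tier.
#'
#' @param depth,alt_count Read counts at the site in this sample.
#' @param assay "wes" or "targeted".
#' @param thresholds Calling block of the config (see [default_config()]).
#' @param present_elsewhere Is the site a primary call in any sample of the
#'   patient?
#' @param targeted_min_alt Scaled mutant-read threshold for this targeted
#'   sample.
#' @return One of `"present_primary"`, `"present_secondary"`, `"absent"`,
#'   `"indeterminate_low_coverage"`.
#' @export
call_site_in_sample <- function(depth, alt_count, assay,
                                thresholds = default_config()$calling,
                                present_elsewhere = FALSE,
                                targeted_min_alt = 5L) {
  if (is.na(depth) || depth == 0) return("indeterminate_low_coverage")
  vaf <- alt_count / depth
  if (assay == "wes") {
    if (vaf >= thresholds$wes_primary_min_vaf &&
        alt_count >= thresholds$wes_primary_min_alt) return("present_primary")
    if (present_elsewhere && alt_count >= thresholds$wes_secondary_min_alt)
      return("present_secondary")
    return("absent")
  }
  if (vaf >= thresholds$targeted_min_vaf && alt_count >= targeted_min_alt)
    return("present_primary")
  "absent"
}

#' Build the per-patient presence/absence call matrix
#'
#' Applies, in order: the optional site exclusion list (stand-in for
#' homology/visual review), the 20%-of-median coverage filter across all
#' samples, the matched-normal germline filter, the primary calling pass in
#' every tumor sample, and a secondary pass for whole-exome samples at sites
#' already primary somewhere in the patient. Targeted samples are restricted
#' to sites discovered in the patient's whole-exome data or lying in the 15
#' fully covered driver genes.
#'
#' @param bundle A validated cohort bundle (see [load_cohort()]).
#' @param thresholds Calling block of the config.
#' @return A data.frame with one row per (site, tumor sample):
#'   `patient_id, site_id, sample_id, status, depth, alt_count, vaf` plus
#'   per-site `gene`, `is_hotspot`.
#' @export
build_call_matrix <- function(bundle, thresholds = default_config()$calling) {
  v <- bundle$variants
  smp <- bundle$samples
  stopifnot(all(v$sample_id %in% smp$sample_id))
  out <- vector("list", length(unique(v$patient_id)))
  names(out) <- unique(v$patient_id)
  for (pid in unique(v$patient_id)) {
    ps <- smp[smp$patient_id == pid, , drop = FALSE]
    pv <- v[v$patient_id == pid, , drop = FALSE]
    out[[pid]] <- call_matrix_patient(pv, ps, bundle$driver_genes, thresholds)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

call_matrix_patient <- function(pv, ps, driver_genes, thresholds) {
  normal_id <- ps$sample_id[ps$component == "normal"]
  if (length(normal_id) != 1) stop("patient must have exactly one normal sample")
  tumor <- ps[ps$component != "normal", , drop = FALSE]

  pv$site_id <- paste0(pv$chrom, ":", pv$pos, ":", pv$ref, ">", pv$alt)
  sites <- unique(pv[, c("site_id", "chrom", "pos", "gene", "is_hotspot")])
  if (anyDuplicated(pv[, c("site_id", "sample_id")]))
    stop("duplicate (site, sample) read-count rows")
  if (is.null(pv$origin)) pv$origin <- "wes"
  site_origin <- tapply(pv$origin, pv$site_id, function(x) x[1])

  key <- function(site, samp) paste(site, samp, sep = "\r")
  depth <- alt <- setNames(
    rep(NA_real_, nrow(sites) * nrow(ps)),
    key(rep(sites$site_id, each = nrow(ps)), rep(ps$sample_id, nrow(sites))))
  depth[key(pv$site_id, pv$sample_id)] <- pv$depth
  alt[key(pv$site_id, pv$sample_id)] <- pv$alt_count

  medians <- setNames(ps$median_capture_coverage, ps$sample_id)
  wes_mean_median <- mean(medians[ps$sample_id[ps$assay == "wes"]])
  t_min_alt <- vapply(tumor$sample_id, function(s) {
    if (tumor$assay[tumor$sample_id == s] == "targeted")
      scaled_min_alt_reads(thresholds$targeted_alt_scale_base,
                           medians[s], wes_mean_median)
    else thresholds$wes_primary_min_alt
  }, integer(1))

  status <- matrix("absent", nrow(sites), nrow(tumor),
                   dimnames = list(sites$site_id, tumor$sample_id))

  excluded <- sites$site_id %in% (thresholds$exclude_sites %||% character())
  indeterminate_site <- rep(FALSE, nrow(sites))
  for (i in seq_len(nrow(sites))) {
    sid <- sites$site_id[i]
    if (excluded[i]) next
    # coverage filter over every sample of the patient (normal included)
    d_all <- depth[key(sid, ps$sample_id)]
    if (!site_coverage_filter(d_all, medians[ps$sample_id],
                              thresholds$coverage_floor_fraction)) {
      excluded[i] <- TRUE
      next
    }
    g <- germline_somatic_filter(depth[key(sid, normal_id)],
                                 alt[key(sid, normal_id)],
                                 thresholds$normal_min_depth,
                                 thresholds$normal_max_vaf)
    if (is.na(g)) {
      warning("missing normal read counts at ", sid, "; site indeterminate")
      indeterminate_site[i] <- TRUE
    } else if (!g) {
      excluded[i] <- TRUE
    }
  }

  # primary pass (all tumor samples)
  for (j in seq_len(nrow(tumor))) {
    s <- tumor$sample_id[j]
    assay <- tumor$assay[j]
    for (i in seq_len(nrow(sites))) {
      sid <- sites$site_id[i]
      if (excluded[i]) { status[i, j] <- "site_excluded"; next }
      if (indeterminate_site[i]) { status[i, j] <- "indeterminate_low_coverage"; next }
      if (assay == "targeted" &&
          !(site_origin[sid] == "wes" || sites$gene[i] %in% driver_genes)) {
        status[i, j] <- "indeterminate_low_coverage"  # not assessable on panel
        next
      }
      status[i, j] <- call_site_in_sample(
        depth[key(sid, s)], alt[key(sid, s)], assay, thresholds,
        present_elsewhere = FALSE, targeted_min_alt = t_min_alt[j])
    }
  }

  # secondary pass: whole-exome samples only, seeded by primary calls in any
  # sample of the patient; secondary presence does not chain
  primary_any <- apply(status == "present_primary", 1, any)
  for (j in which(tumor$assay == "wes")) {
    s <- tumor$sample_id[j]
    for (i in which(primary_any)) {
      if (status[i, j] != "absent") next
      sid <- sites$site_id[i]
      a <- alt[key(sid, s)]
      if (!is.na(a) && a >= thresholds$wes_secondary_min_alt)
        status[i, j] <- "present_secondary"
    }
  }

  grid <- expand.grid(site_id = sites$site_id, sample_id = tumor$sample_id,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d <- depth[key(grid$site_id, grid$sample_id)]
  a <- alt[key(grid$site_id, grid$sample_id)]
  data.frame(
    patient_id = ps$patient_id[1],
    site_id = grid$site_id,
    sample_id = grid$sample_id,
    status = as.vector(status),
    depth = unname(d),
    alt_count = unname(a),
    vaf = unname(ifelse(!is.na(d) & d > 0, a / d, NA_real_)),
    gene = sites$gene[match(grid$site_id, sites$site_id)],
    is_hotspot = sites$is_hotspot[match(grid$site_id, sites$site_id)],
    stringsAsFactors = FALSE
  )
}
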