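# Targeted-panel copy-ratio estimation with GC correction, per-gene
# classification, whole-exome focal-CNA screening, and mutation-locus LOH
# annotation from allele-specific copy number.

#' Per-gene log2 copy ratios from targeted-panel interval coverage
#'
#' The small size of the targeted panel rules out conventional copy-number
#' callers, so copy ratios are computed directly: per-interval median base
#' depth (floored at 1 read so log ratios stay finite), normalized by the
#' panel-wide median of
#' interval medians, GC-corrected by dividing each interval's ratio by the
#' median ratio of its GC decile (deciles with fewer than 5 intervals fall
#' back to the global median), re-centred so the median panel log2 ratio is
#' exactly 0, and summarized per gene by the median of its interval log2
#' ratios.
#'
#' @param interval_depths Data.frame `sample_id, interval_id, median_depth`.
#' @param panel Data.frame `interval_id, chrom, start, end, gc_fraction, gene`.
#' @param gc_correct Apply the GC-decile correction?
#' @param params Copy-number block of the config (classification cutoffs).
#' @return Data.frame `sample_id, gene, log2_ratio, call`; per-interval log2
#'   ratios are attached as attribute `"intervals"`.
#' @export
panel_copy_ratios <- function(interval_depths, panel, gc_correct = TRUE,
                              params = default_config()$copy_number) {
  stopifnot(all(interval_depths$interval_id %in% panel$interval_id))
  res <- list(); ivl <- list()
  for (s in unique(interval_depths$sample_id)) {
    d <- interval_depths[interval_depths$sample_id == s, , drop = FALSE]
    d <- d[match(panel$interval_id, d$interval_id), ]
    depth <- d$median_depth
    if (all(is.na(depth) | depth == 0)) stop("all-zero panel coverage in sample ", s)
    depth <- pmax(ifelse(is.na(depth), 0, depth), 1)  # floor avoids log2(-Inf)
    ratio <- depth / stats::median(depth)
    brk <- unique(stats::quantile(panel$gc_fraction, probs = seq(0, 1, 0.1),
                                  names = FALSE))
    if (gc_correct && length(brk) >= 3) {
      bins <- cut(panel$gc_fraction, breaks = brk, include.lowest = TRUE)
      for (b in levels(bins)) {
        idx <- which(bins == b)
        if (length(idx) >= 5) ratio[idx] <- ratio[idx] / stats::median(ratio[idx])
      }
    }
    ratio <- ratio / stats::median(ratio)  # re-centre: median log2 ratio = 0
    l2 <- log2(ratio)
    ivl[[s]] <- data.frame(sample_id = s, interval_id = panel$interval_id,
                           gene = panel$gene, log2_ratio = l2,
                           stringsAsFactors = FALSE)
    genes <- unique(panel$gene[!is.na(panel$gene) & panel$gene != ""])
    gl2 <- vapply(genes, function(g) stats::median(l2[panel$gene %in% g]),
                  numeric(1))
    res[[s]] <- data.frame(sample_id = s, gene = genes, log2_ratio = unname(gl2),
                           call = vapply(gl2, classify_gene_copy, character(1),
                                         homdel_log2 = params$homdel_log2,
                                         amp_log2 = params$amp_log2),
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "intervals") <- do.call(rbind, ivl)
  out
}

#' Classify a per-gene log2 copy ratio
#'
#' A ratio below -1.25 (a 0.25 margin beyond the -1 expected for hemizygous
#' loss) is called homozygous deletion; a ratio above 1.6 (copy number >= 6
#' in a largely diploid genome) is called focal amplification.
#'
#' @param log2_ratio Finite per-gene log2 copy ratio.
#' @param homdel_log2,amp_log2 Classification cutoffs.
#' @return `"homozygous_deletion"`, `"amplification"` or `"none"`.
#' @export
classify_gene_copy <- function(log2_ratio, homdel_log2 = -1.25, amp_log2 = 1.6) {
  stopifnot(is.finite(log2_ratio))
  if (log2_ratio < homdel_log2) return("homozygous_deletion")
  if (log2_ratio > amp_log2) return("amplification")
  "none"
}

#' Screen whole-exome allele-specific segments for focal CNAs
#'
#' Candidates are segments shorter than 3 Mb with total copy number 0
#' (homozygous deletion) or at least 3 times the sample ploidy (focal
#' amplification). Review routing encodes the study's manual triage: in
#' samples with purity >= 30%, events hitting one of the 15 driver genes
#' (any cellular fraction) or with cellular fraction >= 75% (likely clonal)
#' are flagged `needs_review`; in samples below 30% purity only events
#' hitting the extended driver list at cellular fraction >= 75% are flagged;
#' everything else is `dropped`. Nothing is auto-passed silently.
#'
#' @param segments Data.frame of allele-specific segments: `sample_id, chrom,
#'   start, end, total_cn, minor_cn, cellular_fraction, purity, ploidy` and a
#'   `genes` column (comma-separated symbols overlapped by the segment).
#' @param driver15 The 15-gene pancreatic driver list.
#' @param driver195 Extended driver list used at low purity.
#' @param params Copy-number block of the config.
#' @return Data.frame of focal candidates with `type` and `review_flag`.
#' @export
screen_focal_cnas <- function(segments, driver15 = DRIVER_GENES_15,
                              driver195 = driver15,
                              params = default_config()$copy_number) {
  if (any(is.na(segments$ploidy))) stop("sample ploidy required")
  seg <- segments[order(segments$sample_id, segments$chrom, segments$start), ,
                  drop = FALSE]
  len_mb <- (seg$end - seg$start) / 1e6
  cand <- len_mb < params$focal_max_mb &
    (seg$total_cn == 0 | seg$total_cn >= params$amp_ploidy_mult * seg$ploidy)
  seg <- seg[cand, , drop = FALSE]
  if (nrow(seg) == 0) {
    return(data.frame(sample_id = character(), chrom = character(),
                      start = integer(), end = integer(), total_cn = integer(),
                      type = character(), cellular_fraction = numeric(),
                      review_flag = character(), stringsAsFactors = FALSE))
  }
  genes <- strsplit(ifelse(is.na(seg$genes), "", seg$genes), ",", fixed = TRUE)
  hits15 <- vapply(genes, function(g) any(g %in% driver15), logical(1))
  hits195 <- vapply(genes, function(g) any(g %in% driver195), logical(1))
  flag <- ifelse(
    seg$purity >= params$purity_cut,
    ifelse(hits15 | seg$cellular_fraction >= params$ccf_cut,
           "needs_review", "dropped"),
    ifelse(hits195 & seg$cellular_fraction >= params$ccf_cut,
           "needs_review", "dropped"))
  data.frame(
    sample_id = seg$sample_id, chrom = seg$chrom, start = seg$start,
    end = seg$end, total_cn = seg$total_cn,
    type = ifelse(seg$total_cn == 0, "homozygous_deletion", "focal_amplification"),
    cellular_fraction = seg$cellular_fraction, genes = seg$genes,
    review_flag = flag, stringsAsFactors = FALSE)
}

#' Annotate mutation loci with LOH status from allele-specific copy number
#'
#' A mutated locus has undergone LOH in a sample when the overlapping
#' allele-specific segment has minor copy number 0. Loci in segment gaps are
#' flagged unknown (`NA`).
#'
#' @param call_matrix Output of [build_call_matrix()].
#' @param segments Allele-specific copy-number segments (0-based half-open).
#' @return `call_matrix` with an added logical `loh` column.
#' @export
annotate_mutation_loh <- function(call_matrix, segments) {
  pos <- as.integer(sub("^[^:]+:(\\d+):.*$", "\\1", call_matrix$site_id))
  chrom <- sub("^([^:]+):.*$", "\\1", call_matrix$site_id)
  loh <- rep(NA, nrow(call_matrix))
  for (k in seq_len(nrow(call_matrix))) {
    seg <- segments[segments$sample_id == call_matrix$sample_id[k] &
                      segments$chrom == chrom[k] &
                      segments$start <= pos[k] - 1 & segments$end > pos[k] - 1, ,
                    drop = FALSE]
    if (nrow(seg) > 1) stop("overlapping conflicting segments at ",
                            call_matrix$site_id[k])
    if (nrow(seg) == 1) loh[k] <- seg$minor_cn == 0
  }
  call_matrix$loh <- loh
  call_matrix
}
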