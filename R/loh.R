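# Genome-wide allelic imbalance: segmentation of germline-heterozygous-SNP
# minor allele frequencies, LOH calling with confidence tiers, patient-level
# harmonization, merging, and extension to targeted samples.

snp_maf <- function(ref_count, alt_count) {
  tot <- ref_count + alt_count
  ifelse(tot > 0, pmin(ref_count, alt_count) / tot, NA_real_)
}

#' Change-point segmentation of a minor-allele-frequency series
#'
#' Recursive binary segmentation of the ordered SNP mAF series of one sample
#' and chromosome: each step places the split maximizing a two-sample
#' t-like statistic between the flanks and accepts it when a permutation
#' p-value falls below `alpha`. Segment mAF is the median of member SNP
#' mAFs. Segments partition the input series.
#'
#' @param pos Sorted SNP positions.
#' @param maf SNP minor allele frequencies (same length).
#' @param alpha Permutation significance level for accepting a split.
#' @param n_perm Number of permutations per tested split.
#' @param min_width Minimum SNPs per flank when testing a split.
#' @return Data.frame `start, end, n_snps, segment_maf` (0-based half-open
#'   intervals; internal boundaries at midpoints between flanking SNPs).
#' @export
segment_maf <- function(pos, maf, alpha = 0.01, n_perm = 1000L,
                        min_width = 5L) {
  stopifnot(length(pos) == length(maf), !is.unsorted(pos))
  n <- length(maf)
  splits <- integer(0)
  recurse <- function(lo, hi) {
    m <- hi - lo + 1
    if (m < 2 * min_width) return(invisible())
    x <- maf[lo:hi]
    k <- best_split(x, min_width)
    if (is.null(k)) return(invisible())
    if (split_pvalue(x, min_width, k$stat, n_perm, alpha) >= alpha)
      return(invisible())
    splits <<- c(splits, lo + k$k - 1)   # split after index k (local)
    recurse(lo, lo + k$k - 1)
    recurse(lo + k$k, hi)
  }
  recurse(1, n)
  splits <- sort(splits)
  bounds <- c(pos[1] - 1,
              if (length(splits)) floor((pos[splits] + pos[splits + 1]) / 2),
              pos[n])
  starts <- c(1, splits + 1)
  ends <- c(splits, n)
  data.frame(
    start = bounds[-length(bounds)],
    end = bounds[-1],
    n_snps = as.integer(ends - starts + 1),
    segment_maf = vapply(seq_along(starts), function(i)
      stats::median(maf[starts[i]:ends[i]]), numeric(1))
  )
}

# max two-sample t-like statistic over eligible splits of x
best_split <- function(x, min_width) {
  n <- length(x)
  ks <- min_width:(n - min_width)
  if (length(ks) == 0) return(NULL)
  cs <- cumsum(x); cs2 <- cumsum(x^2); tot <- cs[n]; tot2 <- cs2[n]
  mL <- cs[ks] / ks
  mR <- (tot - cs[ks]) / (n - ks)
  ssL <- cs2[ks] - ks * mL^2
  ssR <- (tot2 - cs2[ks]) - (n - ks) * mR^2
  s2 <- pmax((ssL + ssR) / (n - 2), 1e-12)
  tstat <- abs(mL - mR) / sqrt(s2 * (1 / ks + 1 / (n - ks)))
  i <- which.max(tstat)
  list(k = ks[i], stat = tstat[i])
}

split_pvalue <- function(x, min_width, observed, n_perm, alpha = 1) {
  exceed <- 0L
  stop_at <- ceiling(alpha * (n_perm + 1))  # early exit once p >= alpha is certain
  for (b in seq_len(n_perm)) {
    s <- best_split(sample(x), min_width)
    if (!is.null(s) && s$stat >= observed) {
      exceed <- exceed + 1L
      if (exceed >= stop_at) return(alpha)
    }
  }
  (exceed + 1) / (n_perm + 1)
}

#' Segment every chromosome of one sample
#'
#' @param snps SNP table for one sample (`chrom, pos, ref_count, alt_count`).
#' @param params LOH block of the config.
#' @return Data.frame of segments with `chrom` prepended.
#' @export
segment_sample_maf <- function(snps, params = default_config()$loh) {
  out <- lapply(split(snps, snps$chrom), function(d) {
    d <- d[order(d$pos), ]
    seg <- segment_maf(d$pos, snp_maf(d$ref_count, d$alt_count),
                       alpha = params$seg_alpha, n_perm = params$seg_perms,
                       min_width = params$seg_min_width)
    cbind(chrom = d$chrom[1], seg)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call LOH on a segment by tumor-normal mAF difference
#'
#' @param tumor_maf,normal_maf Segment mAFs in tumor and matched normal.
#' @param diff_cut Required decrease (0.1, inclusive).
#' @return Logical.
#' @export
call_segment_loh <- function(tumor_maf, normal_maf, diff_cut = 0.1) {
  (normal_maf - tumor_maf) >= diff_cut - 1e-9  # inclusive, float-safe
}

#' Minimum segmental mAF as a tumor-purity proxy
#'
#' Over segments spanning more than `min_mb` megabases and overlapping at
#' least `min_snps` SNPs, the minimum segment mAF reflects the most complete
#' clonal allelic imbalance in the sample and hence its purity. Returns 0.5
#' (the balanced value) when no segment qualifies.
#'
#' @param segments Segment data.frame (`start, end, n_snps, segment_maf`).
#' @param min_mb Strict length threshold in Mb.
#' @param min_snps Inclusive SNP-count threshold.
#' @return The minimum eligible segment mAF, or 0.5.
#' @export
sample_purity_proxy <- function(segments, min_mb = 10, min_snps = 20L) {
  ok <- (segments$end - segments$start) > min_mb * 1e6 &
    segments$n_snps >= min_snps
  if (!any(ok)) return(0.5)
  min(segments$segment_maf[ok])
}

#' Confidence tier of an LOH segment
#'
#' Compares the segment mAF with the sample-level minimum mAF (the purity
#' proxy): within 0.1 is high confidence (consistent with a clonal event at
#' the sample's purity), 0.1-0.2 intermediate, at least 0.2 low.
#'
#' @param segment_maf Segment mAF (LOH already called).
#' @param min_sample_maf Sample-level minimum segmental mAF.
#' @param edges Tier boundaries, default `c(0.1, 0.2)`.
#' @return `"high"`, `"intermediate"` or `"low"`.
#' @export
assign_tier <- function(segment_maf, min_sample_maf, edges = c(0.1, 0.2)) {
  d <- segment_maf - min_sample_maf
  if (d < edges[1] - 1e-9) "high"
  else if (d < edges[2] - 1e-9) "intermediate"
  else "low"
}

#' Harmonize per-sample segments into patient-level LOH segments
#'
#' Takes the union of segment breakpoints across the patient's whole-exome
#' tumor samples, recomputes per patient-segment and per-sample median mAF
#' and SNP count, keeps segments spanning more than `min_mb`, overlapping at
#' least `min_snps` SNPs and reaching the high-confidence tier in at least
#' one sample, and classifies them as `uniform` (LOH in every whole-exome
#' tumor sample) or `differential` (a strict subset). Differential segments
#' are retained only when the segmental mAFs of samples with and without
#' LOH are separated by at least `diff_cut`.
#'
#' @param sample_segments Named list of per-sample segment data.frames (from
#'   [segment_sample_maf()]), whole-exome tumor samples only.
#' @param snps SNP table of all whole-exome samples of the patient.
#' @param normal_id Sample id of the matched normal.
#' @param params LOH block of the config.
#' @return List of class `patient_segment_grid` with elements `segments`
#'   (`seg_id, chrom, start, end, class`) and `cells` (`seg_id, sample_id,
#'   n_snps, segment_maf, loh, tier`).
#' @export
harmonize_patient_segments <- function(sample_segments, snps, normal_id,
                                       params = default_config()$loh) {
  tumor_ids <- names(sample_segments)
  min_maf <- vapply(sample_segments, sample_purity_proxy, numeric(1),
                    min_mb = params$min_mb, min_snps = params$min_snps)

  segs <- list(); cells <- list(); sid <- 0L
  chroms <- unique(unlist(lapply(sample_segments, function(s) s$chrom)))
  for (ch in chroms) {
    bp <- sort(unique(unlist(lapply(sample_segments, function(s) {
      s <- s[s$chrom == ch, ]; c(s$start, s$end)
    }))))
    if (length(bp) < 2) next
    for (i in seq_len(length(bp) - 1)) {
      lo <- bp[i]; hi <- bp[i + 1]
      sid <- sid + 1L
      cell <- patient_segment_cells(sid, ch, lo, hi, snps,
                                    c(tumor_ids, normal_id), normal_id,
                                    min_maf, params)
      keep_len <- (hi - lo) > params$min_mb * 1e6
      tc <- cell[cell$sample_id %in% tumor_ids, ]
      keep_snps <- nrow(tc) > 0 && all(tc$n_snps >= params$min_snps)
      keep_tier <- any(tc$loh & tc$tier == "high", na.rm = TRUE)
      if (!(keep_len && keep_snps && keep_tier)) { sid <- sid - 1L; next }
      with_loh <- tc$segment_maf[tc$loh]
      wo_loh <- tc$segment_maf[!tc$loh]
      cls <- if (all(tc$loh)) "uniform"
      else if (min(wo_loh) - max(with_loh) >= params$diff_cut) "differential"
      else "filtered"
      cell$seg_id <- sid
      segs[[length(segs) + 1]] <- data.frame(seg_id = sid, chrom = ch,
                                             start = lo, end = hi, class = cls,
                                             stringsAsFactors = FALSE)
      cells[[length(cells) + 1]] <- cell
    }
  }
  grid <- list(segments = do.call(rbind, segs) %||%
                 data.frame(seg_id = integer(), chrom = character(),
                            start = numeric(), end = numeric(),
                            class = character()),
               cells = do.call(rbind, cells) %||%
                 data.frame(seg_id = integer(), sample_id = character(),
                            n_snps = integer(), segment_maf = numeric(),
                            loh = logical(), tier = character()),
               normal_id = normal_id, min_sample_maf = min_maf)
  class(grid) <- "patient_segment_grid"
  grid
}

# per-sample median mAF / counts / call / tier for one candidate interval
patient_segment_cells <- function(seg_id, chrom, lo, hi, snps, sample_ids,
                                  normal_id, min_maf, params,
                                  summary_fn = stats::median) {
  rows <- lapply(sample_ids, function(s) {
    d <- snps[snps$sample_id == s & snps$chrom == chrom &
                snps$pos > lo & snps$pos <= hi, , drop = FALSE]
    m <- snp_maf(d$ref_count, d$alt_count)
    data.frame(seg_id = seg_id, sample_id = s, n_snps = nrow(d),
               segment_maf = if (nrow(d)) summary_fn(m, na.rm = TRUE) else NA_real_,
               stringsAsFactors = FALSE)
  })
  cell <- do.call(rbind, rows)
  nmaf <- cell$segment_maf[cell$sample_id == normal_id]
  cell$loh <- ifelse(cell$sample_id == normal_id, FALSE,
                     call_segment_loh(cell$segment_maf, nmaf, params$diff_cut))
  cell$loh[is.na(cell$loh)] <- FALSE
  cell$tier <- "none"
  for (i in which(cell$loh)) {
    mm <- min_maf[cell$sample_id[i]]
    if (is.na(mm)) mm <- 0.5
    cell$tier[i] <- assign_tier(cell$segment_maf[i], mm, params$tier_edges)
  }
  cell
}

#' Merge near-identical adjacent patient segments
#'
#' Consecutive same-chromosome segments whose facing boundaries are less
#' than `merge_window_mb` apart and whose per-sample LOH call vectors are
#' identical are merged (interval union; mAFs recomputed over the pooled
#' SNPs; LOH calls preserved). Applied iteratively to a fixpoint, so the
#' result is idempotent.
#'
#' @param grid A `patient_segment_grid`.
#' @param snps SNP table used to recompute pooled mAFs.
#' @param params LOH block of the config.
#' @return The merged `patient_segment_grid`.
#' @export
merge_adjacent <- function(grid, snps, params = default_config()$loh) {
  repeat {
    if (nrow(grid$segments) < 2) break
    segs <- grid$segments[order(grid$segments$chrom, grid$segments$start), ]
    merged <- FALSE
    for (i in seq_len(nrow(segs) - 1)) {
      a <- segs[i, ]; b <- segs[i + 1, ]
      if (a$chrom != b$chrom) next
      if (b$start - a$end >= params$merge_window_mb * 1e6) next
      ca <- grid$cells[grid$cells$seg_id == a$seg_id, ]
      cb <- grid$cells[grid$cells$seg_id == b$seg_id, ]
      ca <- ca[order(ca$sample_id), ]; cb <- cb[order(cb$sample_id), ]
      if (!identical(ca$loh, cb$loh) || a$class != b$class) next
      # merge b into a
      grid$segments <- grid$segments[grid$segments$seg_id != b$seg_id, ]
      grid$segments$end[grid$segments$seg_id == a$seg_id] <- b$end
      newcell <- patient_segment_cells(a$seg_id, a$chrom, a$start, b$end, snps,
                                       ca$sample_id, grid$normal_id,
                                       grid$min_sample_maf, params)
      newcell$loh <- ca$loh[match(newcell$sample_id, ca$sample_id)]
      grid$cells <- rbind(grid$cells[!(grid$cells$seg_id %in%
                                         c(a$seg_id, b$seg_id)), ], newcell)
      merged <- TRUE
      break
    }
    if (!merged) break
  }
  grid
}

#' Extend patient-level LOH segments to targeted samples
#'
#' For each candidate segment and targeted sample, SNPs with distinct
#' coverage of at least `targeted_min_depth` are collected; their count and
#' average mAF are computed and the LOH call and confidence tier applied
#' with the whole-exome rules. Segments with no qualifying SNPs in a sample
#' are marked unknown there (`loh = NA`, `tier = "unknown"`).
#'
#' @param grid A `patient_segment_grid` from whole-exome analysis.
#' @param targeted_snps SNP table of the patient's targeted samples.
#' @param params LOH block of the config.
#' @return The grid with targeted-sample rows appended to `cells`.
#' @export
extend_to_targeted <- function(grid, targeted_snps,
                               params = default_config()$loh) {
  if (nrow(grid$segments) == 0 || is.null(targeted_snps) ||
      nrow(targeted_snps) == 0) return(grid)
  ts <- targeted_snps[targeted_snps$ref_count + targeted_snps$alt_count >=
                        params$targeted_min_depth, , drop = FALSE]
  nmaf <- grid$cells$segment_maf[grid$cells$sample_id == grid$normal_id]
  names(nmaf) <- grid$cells$seg_id[grid$cells$sample_id == grid$normal_id]
  rows <- list()
  for (s in unique(targeted_snps$sample_id)) {
    d <- ts[ts$sample_id == s, , drop = FALSE]
    # sample-level minimum mAF over qualifying candidate segments
    per_seg <- lapply(seq_len(nrow(grid$segments)), function(i) {
      g <- grid$segments[i, ]
      x <- d[d$chrom == g$chrom & d$pos > g$start & d$pos <= g$end, ]
      m <- snp_maf(x$ref_count, x$alt_count)
      data.frame(seg_id = g$seg_id, n_snps = nrow(x),
                 segment_maf = if (nrow(x)) mean(m, na.rm = TRUE) else NA_real_,
                 span = g$end - g$start)
    })
    per_seg <- do.call(rbind, per_seg)
    elig <- per_seg$span > params$min_mb * 1e6 &
      per_seg$n_snps >= params$min_snps
    mm <- if (any(elig)) min(per_seg$segment_maf[elig]) else 0.5
    for (i in seq_len(nrow(per_seg))) {
      g <- per_seg[i, ]
      if (g$n_snps == 0) {
        rows[[length(rows) + 1]] <- data.frame(
          seg_id = g$seg_id, sample_id = s, n_snps = 0L,
          segment_maf = NA_real_, loh = NA, tier = "unknown",
          stringsAsFactors = FALSE)
        next
      }
      loh <- call_segment_loh(g$segment_maf, nmaf[as.character(g$seg_id)],
                              params$diff_cut)
      rows[[length(rows) + 1]] <- data.frame(
        seg_id = g$seg_id, sample_id = s, n_snps = g$n_snps,
        segment_maf = g$segment_maf, loh = loh,
        tier = if (isTRUE(loh)) assign_tier(g$segment_maf, mm,
                                            params$tier_edges) else "none",
        stringsAsFactors = FALSE)
    }
  }
  grid$cells <- rbind(grid$cells, do.call(rbind, rows))
  grid
}
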