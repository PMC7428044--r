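# From calls to phylogenetic characters: binary alteration matrix,
# alteration clusters, singleton rescue, copy-number ambiguity exclusion,
# clonal-mixing correction, and ancestry classification.

#' Build the binary alteration matrix for one patient
#'
#' Rows are alterations (mutations called present/absent, differential and
#' uniform LOH patient-segments, reviewed focal CNAs), columns are tumor
#' samples. Indeterminate calls are imputed with the majority value among
#' the event's determinate calls (ties to absent) and the imputation is
#' logged in the `"imputed"` attribute. Sites excluded by the calling
#' filters contribute no row.
#'
#' @param call_matrix Call rows of one patient ([build_call_matrix()]).
#' @param loh_grid Optional `patient_segment_grid` for the patient.
#' @param cnas Optional screened focal CNAs (rows with `review_flag ==
#'   "needs_review"` become events keyed by locus and type).
#' @return Binary matrix (events x samples) with attributes `events`
#'   (event metadata: `event_id, kind, gene, is_hotspot`) and `imputed`.
#' @export
build_binary_matrix <- function(call_matrix, loh_grid = NULL, cnas = NULL) {
  samples <- unique(call_matrix$sample_id)
  if (length(samples) == 0) stop("no tumor samples")
  rows <- list(); meta <- list(); imputed <- list()

  add_row <- function(event_id, kind, gene, hot, pres) {
    rows[[event_id]] <<- pres
    meta[[event_id]] <<- data.frame(event_id = event_id, kind = kind,
                                    gene = gene, is_hotspot = hot,
                                    stringsAsFactors = FALSE)
  }

  for (sid in unique(call_matrix$site_id)) {
    cm <- call_matrix[call_matrix$site_id == sid, ]
    st <- cm$status[match(samples, cm$sample_id)]
    if (any(st == "site_excluded", na.rm = TRUE)) next
    pres <- ifelse(st %in% c("present_primary", "present_secondary"), 1L,
                   ifelse(st == "absent", 0L, NA_integer_))
    if (all(is.na(pres))) next
    if (anyNA(pres)) {
      fill <- as.integer(mean(pres, na.rm = TRUE) > 0.5)
      imputed[[length(imputed) + 1]] <- data.frame(
        event_id = sid, sample_id = samples[is.na(pres)], value = fill,
        stringsAsFactors = FALSE)
      pres[is.na(pres)] <- fill
    }
    add_row(sid, "mutation", cm$gene[1], isTRUE(cm$is_hotspot[1]), pres)
  }

  if (!is.null(loh_grid) && nrow(loh_grid$segments) > 0) {
    keep <- loh_grid$segments$class %in% c("uniform", "differential")
    for (i in which(keep)) {
      g <- loh_grid$segments[i, ]
      cells <- loh_grid$cells[loh_grid$cells$seg_id == g$seg_id, ]
      loh <- cells$loh[match(samples, cells$sample_id)]
      if (all(is.na(loh))) next
      if (anyNA(loh)) {
        fill <- mean(loh, na.rm = TRUE) > 0.5
        imputed[[length(imputed) + 1]] <- data.frame(
          event_id = paste0("loh:", g$chrom, ":", g$start, "-", g$end),
          sample_id = samples[is.na(loh)], value = as.integer(fill),
          stringsAsFactors = FALSE)
        loh[is.na(loh)] <- fill
      }
      add_row(paste0("loh:", g$chrom, ":", g$start, "-", g$end),
              "loh_segment", NA_character_, FALSE, as.integer(loh))
    }
  }

  if (!is.null(cnas) && nrow(cnas) > 0) {
    cnas <- cnas[cnas$review_flag == "needs_review", , drop = FALSE]
    keys <- unique(paste0("cna:", cnas$chrom, ":", cnas$start, "-", cnas$end,
                          ":", cnas$type))
    for (k in keys) {
      sel <- paste0("cna:", cnas$chrom, ":", cnas$start, "-", cnas$end,
                    ":", cnas$type) == k
      pres <- as.integer(samples %in% cnas$sample_id[sel])
      add_row(k, "focal_cna", cnas$genes[sel][1], FALSE, pres)
    }
  }

  if (length(rows) == 0) {
    m <- matrix(integer(0), 0, length(samples),
                dimnames = list(NULL, samples))
  } else {
    m <- do.call(rbind, rows)
    colnames(m) <- samples
  }
  attr(m, "events") <- if (length(meta)) do.call(rbind, meta) else
    data.frame(event_id = character(), kind = character(),
               gene = character(), is_hotspot = logical())
  attr(m, "imputed") <- if (length(imputed)) do.call(rbind, imputed) else NULL
  rownames(attr(m, "events")) <- NULL
  m
}

#' Group alterations into clusters by shared presence pattern
#'
#' Alterations with an identical presence/absence pattern across the
#' patient's samples form one cluster (one phylogenetic character).
#' Patterns carried by a single alteration go to the singleton pool, since
#' a lone discordant call is as likely a calling error as a real branch.
#'
#' @param mat Binary matrix from [build_binary_matrix()].
#' @return List of class `alteration_clusters`: `patterns` (cluster x sample
#'   0/1 matrix), `members` (named list of event ids per cluster),
#'   `singletons` (event ids), `samples`.
#' @export
cluster_patterns <- function(mat) {
  stopifnot(nrow(mat) > 0)
  pat <- apply(mat, 1, paste, collapse = "")
  tab <- table(pat)
  keep <- names(tab)[tab >= 2]
  keep <- keep[order(-tab[keep], keep)]
  patterns <- if (length(keep))
    do.call(rbind, lapply(keep, function(p) mat[which(pat == p)[1], ]))
  else matrix(integer(0), 0, ncol(mat), dimnames = list(NULL, colnames(mat)))
  rownames(patterns) <- if (length(keep)) paste0("cluster_", seq_along(keep))
  members <- lapply(keep, function(p) rownames(mat)[pat == p])
  names(members) <- rownames(patterns)
  out <- list(patterns = patterns, members = members,
              singletons = rownames(mat)[pat %in% names(tab)[tab == 1]],
              samples = colnames(mat))
  class(out) <- "alteration_clusters"
  out
}

#' Attempt to merge singleton alterations into existing clusters
#'
#' A singleton whose pattern differs from a cluster's in at most one sample
#' is merged when, in the differing sample, the discordant call is
#' explainable: a missed presence whose mutant read count is within the
#' near-miss margin of the threshold, or whose locus shows LOH/copy loss in
#' that sample (mutation loss); or a marginal presence barely above the
#' calling threshold. Merged alterations have their calls corrected to the
#' cluster pattern; every correction is logged.
#'
#' @param clusters `alteration_clusters` from [cluster_patterns()].
#' @param mat The binary matrix (with `events` attribute).
#' @param call_matrix Call rows of the patient (for quality metrics);
#'   if LOH-annotated (see [annotate_mutation_loh()]), the `loh` column
#'   explains absences.
#' @param thresholds Calling block of the config.
#' @param margin Near-miss margin as a fraction of the violated threshold.
#' @param sample_min_alt Named vector of per-sample minimum mutant-read
#'   thresholds (defaults to the whole-exome value for all samples).
#' @return Updated `alteration_clusters` with a `corrections` data.frame.
#' @export
rescue_singletons <- function(clusters, mat, call_matrix,
                              thresholds = default_config()$calling,
                              margin = 0.20, sample_min_alt = NULL) {
  corrections <- list()
  if (is.null(sample_min_alt))
    sample_min_alt <- setNames(rep(thresholds$wes_primary_min_alt,
                                   length(clusters$samples)), clusters$samples)
  remaining <- character(0)
  for (ev in clusters$singletons) {
    pat <- mat[ev, ]
    merged <- FALSE
    if (nrow(clusters$patterns) > 0) {
      dists <- apply(clusters$patterns, 1, function(p) sum(p != pat))
      for (ci in order(dists)) {
        if (dists[ci] > 1) break
        if (dists[ci] == 0) next  # cannot happen post-clustering
        s <- clusters$samples[which(clusters$patterns[ci, ] != pat)]
        ok <- explainable_discrepancy(ev, s, clusters$patterns[ci, ],
                                      call_matrix, thresholds, margin,
                                      sample_min_alt)
        if (ok$explainable) {
          clusters$members[[ci]] <- c(clusters$members[[ci]], ev)
          corrections[[length(corrections) + 1]] <- data.frame(
            event_id = ev, sample_id = s,
            from = pat[clusters$samples == s],
            to = clusters$patterns[ci, clusters$samples == s],
            reason = ok$reason, cluster_id = rownames(clusters$patterns)[ci],
            stringsAsFactors = FALSE)
          merged <- TRUE
          break
        }
      }
    }
    if (!merged) remaining <- c(remaining, ev)
  }
  clusters$singletons <- remaining
  clusters$corrections <- if (length(corrections))
    do.call(rbind, corrections)
  else data.frame(event_id = character(), sample_id = character(),
                  from = integer(), to = integer(), reason = character(),
                  cluster_id = character())
  clusters
}

explainable_discrepancy <- function(ev, s, cluster_pat, call_matrix,
                                    thresholds, margin, sample_min_alt) {
  cm <- call_matrix[call_matrix$site_id == ev & call_matrix$sample_id == s, ]
  if (nrow(cm) != 1) return(list(explainable = FALSE, reason = ""))
  want <- unname(cluster_pat[match(s, names(cluster_pat))])
  min_alt <- unname(sample_min_alt[s])
  if (want == 1) {
    # cluster says present, event called absent: near-miss or allelic loss
    if (!is.na(cm$alt_count) && cm$alt_count >= ceiling((1 - margin) * min_alt))
      return(list(explainable = TRUE, reason = "near_miss_presence"))
    if (!is.null(cm$loh) && isTRUE(cm$loh))
      return(list(explainable = TRUE, reason = "loh_at_locus"))
    return(list(explainable = FALSE, reason = ""))
  }
  # cluster says absent, event called present: marginal presence
  vaf_req <- thresholds$wes_primary_min_vaf
  if (!is.na(cm$alt_count) &&
      (cm$alt_count <= ceiling((1 + margin) * min_alt) ||
         (!is.na(cm$vaf) && cm$vaf <= (1 + margin) * vaf_req)))
    return(list(explainable = TRUE, reason = "marginal_presence"))
  list(explainable = FALSE, reason = "")
}

#' Exclude alterations whose absence is ambiguous under copy loss
#'
#' In patients where every sample was whole-exome sequenced (so
#' allele-specific copy number is uniformly available), a mutation absent
#' only in samples that show loss of the locus (minor copy number 0) could
#' reflect either copy-number loss of the mutant allele or true
#' intra-tumoral heterogeneity; such alterations are removed from
#' phylogenetic analysis.
#'
#' @param mat Binary matrix.
#' @param call_matrix LOH-annotated call rows (`loh` column).
#' @param wes_only Is the patient fully whole-exome sequenced? If `FALSE`
#'   the rule is not applied.
#' @return The filtered matrix (attributes preserved for remaining rows).
#' @export
exclude_cn_ambiguous <- function(mat, call_matrix, wes_only = TRUE) {
  if (!wes_only || nrow(mat) == 0) return(mat)
  drop <- logical(nrow(mat))
  for (i in seq_len(nrow(mat))) {
    ev <- rownames(mat)[i]
    absent <- colnames(mat)[mat[i, ] == 0]
    if (length(absent) == 0) next
    loh <- vapply(absent, function(s) {
      cm <- call_matrix[call_matrix$site_id == ev &
                          call_matrix$sample_id == s, ]
      nrow(cm) == 1 && !is.null(cm$loh) && isTRUE(cm$loh)
    }, logical(1))
    drop[i] <- all(loh)
  }
  ev <- attr(mat, "events"); im <- attr(mat, "imputed")
  out <- mat[!drop, , drop = FALSE]
  attr(out, "events") <- ev[ev$event_id %in% rownames(out), , drop = FALSE]
  attr(out, "imputed") <- im
  out
}

#' Split clonally mixed samples into subclone pseudo-samples
#'
#' Two alteration clusters whose sample sets are non-nested must lie on
#' distinct branches of the phylogeny, so a sample harboring both can only
#' be a mixture of two clonal populations. Qualifying cluster pairs are
#' found (non-nested, co-occurring in at least one sample, and reduced so
#' that no retained pair's member has a potential ancestor also paired with
#' the same partner); each sample carrying both members of a retained pair
#' is replaced by two subclone pseudo-samples, each carrying one member and
#' lacking the other member and its potential descendants.
#'
#' @param clusters `alteration_clusters`.
#' @return Updated `alteration_clusters` with expanded sample columns and a
#'   `splits` data.frame (`sample_id, subclone_a, subclone_b`). Cluster
#'   membership is never altered.
#' @export
split_mixed_samples <- function(clusters) {
  P <- clusters$patterns
  if (nrow(P) < 2) { clusters$splits <- NULL; return(clusters) }
  sets <- lapply(seq_len(nrow(P)), function(i) which(P[i, ] == 1))
  nc <- nrow(P)
  pairs <- list()
  for (i in seq_len(nc - 1)) for (j in (i + 1):nc) {
    a <- sets[[i]]; b <- sets[[j]]
    if (length(a) == 0 || length(b) == 0) next
    if (all(a %in% b) || all(b %in% a)) next  # nested: ancestral order possible
    pairs[[length(pairs) + 1]] <- c(i, j)
  }
  if (length(pairs) == 0) { clusters$splits <- NULL; return(clusters) }
  # drop pairs where a potential ancestor of one member is paired with the
  # same partner (keep only the most ancestral conflicting pair)
  is_anc <- function(x, y) x != y && all(sets[[y]] %in% sets[[x]]) &&
    length(sets[[x]]) > length(sets[[y]])
  keep <- vapply(pairs, function(p) {
    for (q in pairs) {
      if (q[2] == p[2] && is_anc(q[1], p[1])) return(FALSE)
      if (q[1] == p[1] && is_anc(q[2], p[2])) return(FALSE)
      if (q[1] == p[2] && is_anc(q[2], p[1])) return(FALSE)
      if (q[2] == p[1] && is_anc(q[1], p[2])) return(FALSE)
    }
    TRUE
  }, logical(1))
  pairs <- pairs[keep]
  pairs <- Filter(function(p) length(intersect(sets[[p[1]]],
                                               sets[[p[2]]])) > 0, pairs)
  if (length(pairs) == 0) { clusters$splits <- NULL; return(clusters) }

  splits <- list()
  for (p in pairs) {
    a <- p[1]; b <- p[2]
    mixed <- intersect(which(P[a, ] == 1), which(P[b, ] == 1))
    mixed_names <- colnames(P)[mixed]
    for (s in mixed_names) {
      si <- which(colnames(P) == s)
      if (length(si) == 0) next  # already split by an earlier pair
      desc <- function(x) which(vapply(seq_len(nrow(P)), function(c2)
        c2 != x && all(which(P[c2, ] == 1) %in% which(P[x, ] == 1)),
        logical(1)))
      col_a <- P[, si]; col_b <- P[, si]
      col_a[c(b, desc(b))] <- 0L  # subclone with a: lacks b and its descendants
      col_b[c(a, desc(a))] <- 0L
      na <- paste0(s, "_clone", rownames(P)[a])
      nb <- paste0(s, "_clone", rownames(P)[b])
      P <- cbind(P[, -si, drop = FALSE], col_a, col_b)
      colnames(P)[ncol(P) - 1:0] <- c(na, nb)
      splits[[length(splits) + 1]] <- data.frame(
        sample_id = s, subclone_a = na, subclone_b = nb,
        stringsAsFactors = FALSE)
      sets <- lapply(seq_len(nrow(P)), function(i) which(P[i, ] == 1))
    }
  }
  clusters$patterns <- P
  clusters$samples <- colnames(P)
  clusters$splits <- if (length(splits)) do.call(rbind, splits) else NULL
  clusters
}

#' Classify the ancestry of precursor-annotated samples
#'
#' A sample annotated histologically as precursor is labeled
#' `cancerization` when its genotype covers every confident (primary)
#' mutation of an invasive cancer sample — it descended from the cancer
#' (intraductal spread) — and `independent_clone` when it shares zero
#' confidently called non-hotspot mutations with every cancer sample
#' (hotspot mutations such as KRAS codon 12 recur independently and are
#' excluded as evidence of shared ancestry); otherwise it is
#' `precursor_lineage`. Ancestry evidence is restricted to primary calls:
#' secondary calls (two mutant reads) are rescue calls for known-lineage
#' mutations and are too error-prone to establish or refute shared descent
#' on their own, though they count toward covering the cancer genotype.
#'
#' @param call_matrix Call rows of one patient ([build_call_matrix()]).
#' @param samples Sample metadata (`sample_id, component`).
#' @return Data.frame `sample_id, component, label, n_shared_with_cancer,
#'   n_private`.
#' @export
classify_ancestry <- function(call_matrix, samples) {
  sites <- unique(call_matrix$site_id)
  ids <- unique(call_matrix$sample_id)
  get <- function(statuses) {
    m <- matrix(FALSE, length(sites), length(ids),
                dimnames = list(sites, ids))
    sel <- call_matrix$status %in% statuses
    m[cbind(match(call_matrix$site_id[sel], sites),
            match(call_matrix$sample_id[sel], ids))] <- TRUE
    m
  }
  prim <- get("present_primary")
  any_p <- get(c("present_primary", "present_secondary"))
  hot <- call_matrix$is_hotspot[match(sites, call_matrix$site_id)]
  hot[is.na(hot)] <- FALSE
  cancer_ids <- intersect(samples$sample_id[samples$component == "cancer"], ids)
  prec <- samples[samples$component %in%
                    c("low_grade", "high_grade", "cancerization_suspect") &
                    samples$sample_id %in% ids, , drop = FALSE]
  out <- lapply(seq_len(nrow(prec)), function(i) {
    s <- prec$sample_id[i]
    label <- "precursor_lineage"
    shared <- 0L
    if (length(cancer_ids)) {
      shared <- max(vapply(cancer_ids, function(cs)
        sum(any_p[, s] & any_p[, cs]), integer(1)))
      shared_nonhot_prim <- max(vapply(cancer_ids, function(cs)
        sum(prim[, s] & prim[, cs] & !hot), integer(1)))
      covers <- vapply(cancer_ids, function(cs)
        sum(prim[, cs]) > 0 && all(any_p[prim[, cs], s]), logical(1))
      if (any(covers)) label <- "cancerization"
      else if (shared_nonhot_prim == 0) label <- "independent_clone"
    }
    data.frame(sample_id = s, component = prec$component[i], label = label,
               n_shared_with_cancer = shared,
               n_private = sum(any_p[, s]) - shared,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(sample_id = character(), component = character(),
                      label = character(), n_shared_with_cancer = integer(),
                      n_private = integer())
  res
}
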