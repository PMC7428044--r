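# Maximum-parsimony search over sample-labeled trees with binary
# alteration-cluster characters: Fitch small-parsimony scoring, exhaustive
# topology enumeration for small instances, branch-and-bound above.
#
# Unrooted binary topologies are built by stepwise leaf insertion; the
# normal sample (all characters absent) is always leaf 1 and supplies the
# outgroup root. Fitch scores are invariant to rooting, so the unrooted
# search solves the rooted problem.

# Fitch score of an unrooted tree given leaf state masks.
# edges: 2-column integer matrix; leaf_masks: n_chars x n_leaves integer
# matrix with 1 = state 0, 2 = state 1 (3 would mean either).
fitch_score <- function(edges, leaf_masks, root = 1L) {
  nmax <- max(edges)
  adj <- vector("list", nmax)
  for (e in seq_len(nrow(edges))) {
    u <- edges[e, 1]; v <- edges[e, 2]
    adj[[u]] <- c(adj[[u]], v)
    adj[[v]] <- c(adj[[v]], u)
  }
  cost <- 0L
  post <- function(node, parent) {
    nbrs <- adj[[node]]
    nbrs <- nbrs[nbrs != parent]
    if (length(nbrs) == 0) return(leaf_masks[, node])
    mask <- NULL
    for (nb in nbrs) {
      cm <- post(nb, node)
      if (is.null(mask)) mask <- cm
      else {
        inter <- bitwAnd(mask, cm)
        zero <- inter == 0L
        cost <<- cost + sum(zero)
        mask <- ifelse(zero, bitwOr(mask, cm), inter)
      }
    }
    mask
  }
  top <- post(root, 0L)
  # root is a leaf: combine its own state
  cost + sum(bitwAnd(top, leaf_masks[, root]) == 0L)
}

# stepwise leaf-insertion search; prune = FALSE gives exhaustive enumeration
mp_search <- function(leaf_masks, n_leaves, prune = TRUE, cap = 25L) {
  if (n_leaves > cap)
    stop("parsimony search capped at ", cap,
         " leaves; reduce the sample set or raise phylo$max_leaves")
  best <- Inf
  best_trees <- list()
  if (n_leaves == 2) {
    edges <- matrix(c(1L, 2L), 1, 2)
    return(list(score = fitch_score(edges, leaf_masks), trees = list(edges)))
  }
  start <- matrix(c(1L, n_leaves + 1L, 2L, n_leaves + 1L, 3L, n_leaves + 1L),
                  3, 2, byrow = TRUE)
  grow <- function(edges, k) {
    if (prune || k > n_leaves) {
      sc <- fitch_score(edges, leaf_masks)
      if (k > n_leaves) {
        if (sc < best) { best <<- sc; best_trees <<- list(edges) }
        else if (sc == best) best_trees[[length(best_trees) + 1]] <<- edges
        return(invisible())
      }
      if (sc > best) return(invisible())  # adding leaves never lowers the score
    }
    w <- n_leaves + k - 2L
    for (e in seq_len(nrow(edges))) {
      u <- edges[e, 1]; v <- edges[e, 2]
      new_edges <- rbind(edges[-e, , drop = FALSE],
                         c(u, w), c(w, v), c(k, w))
      grow(new_edges, k + 1L)
    }
  }
  grow(start, 4L)
  list(score = best, trees = best_trees)
}

#' Infer all maximum-parsimony trees from alteration-cluster patterns
#'
#' Each alteration cluster is one unweighted binary character. The matched
#' normal is added as an all-absent outgroup leaf and the tree is rooted on
#' its edge. The search is exhaustive for up to 7 leaves and branch-and-
#' bound above; all minimum-score topologies are returned in canonical
#' (sorted newick) order, with edge branch lengths equal to the number of
#' alterations assigned to the edge by Fitch reconstruction.
#'
#' @param patterns Binary matrix, clusters x samples (0/1).
#' @param cluster_sizes Alteration count per cluster (branch-length weights);
#'   defaults to 1 per cluster.
#' @param normal_label Leaf label for the outgroup.
#' @param max_leaves Hard cap on the leaf count.
#' @param exhaustive_cap Leaf count up to which the search enumerates every
#'   topology instead of pruning.
#' @return List of class `clone_phylo`: `score`, `trees` (list of
#'   `ape::phylo`), `newick` (canonical strings), `edge_clusters` (per tree,
#'   data.frame mapping cluster ids to edges), `samples`.
#' @export
infer_parsimony_tree <- function(patterns, cluster_sizes = NULL,
                                 normal_label = "normal", max_leaves = 25L,
                                 exhaustive_cap = 7L) {
  stopifnot(is.matrix(patterns), !is.null(colnames(patterns)))
  samples <- colnames(patterns)
  if (is.null(cluster_sizes)) cluster_sizes <- rep(1L, nrow(patterns))
  if (is.null(rownames(patterns)))
    rownames(patterns) <- paste0("c", seq_len(nrow(patterns)))
  n_leaves <- length(samples) + 1L
  labels <- c(normal_label, samples)
  if (anyDuplicated(labels)) stop("duplicate leaf labels")
  leaf_masks <- if (nrow(patterns) == 0) matrix(1L, 1, n_leaves)
  else cbind(1L, matrix(ifelse(patterns == 1, 2L, 1L), nrow = nrow(patterns)))
  res <- mp_search(leaf_masks, n_leaves,
                   prune = n_leaves > exhaustive_cap, cap = max_leaves)
  ann <- lapply(res$trees, function(e)
    annotate_tree(e, leaf_masks, labels, rownames(patterns), cluster_sizes))
  nwk <- vapply(ann, function(a) a$newick, character(1))
  keep <- !duplicated(nwk)
  ann <- ann[keep][order(nwk[keep])]
  out <- list(
    score = res$score,
    trees = lapply(ann, function(a) ape::read.tree(text = a$newick)),
    newick = vapply(ann, function(a) a$newick, character(1)),
    edge_clusters = lapply(ann, function(a) a$edge_clusters),
    samples = samples
  )
  class(out) <- "clone_phylo"
  out
}

# Root an unrooted edge matrix at leaf `root`, run Fitch up+down passes,
# emit a canonical newick (children sorted by smallest leaf label) with
# branch lengths = alterations per edge, and the cluster->edge assignment.
annotate_tree <- function(edges, leaf_masks, labels, cluster_ids,
                          cluster_sizes, root = 1L) {
  nmax <- max(edges)
  adj <- vector("list", nmax)
  for (e in seq_len(nrow(edges))) {
    u <- edges[e, 1]; v <- edges[e, 2]
    adj[[u]] <- c(adj[[u]], v)
    adj[[v]] <- c(adj[[v]], u)
  }
  n_chars <- nrow(leaf_masks)
  masks <- vector("list", nmax)
  post <- function(node, parent) {
    nbrs <- adj[[node]]
    nbrs <- nbrs[nbrs != parent]
    if (length(nbrs) == 0) { masks[[node]] <<- leaf_masks[, node]; return(invisible()) }
    mask <- NULL
    for (nb in nbrs) {
      post(nb, node)
      cm <- masks[[nb]]
      mask <- if (is.null(mask)) cm else {
        inter <- bitwAnd(mask, cm)
        ifelse(inter == 0L, bitwOr(mask, cm), inter)
      }
    }
    masks[[node]] <<- mask
  }
  post(root, 0L)

  edge_clusters <- list()
  # top-down state assignment; root (normal leaf) is all state-0
  build <- function(node, parent, parent_state) {
    mask <- if (length(adj[[node]]) == 1 && node <= length(labels))
      leaf_masks[, node] else masks[[node]]
    state <- ifelse(bitwAnd(mask, parent_state) != 0L, parent_state, mask)
    # mask may be 3 with parent 0/1 handled above; a bare 3 takes parent state
    changed <- which(state != parent_state)
    if (length(changed) && length(cluster_ids))
      edge_clusters[[length(edge_clusters) + 1]] <<-
        data.frame(node_label = node_label(node),
                   cluster_id = cluster_ids[changed],
                   stringsAsFactors = FALSE)
    len <- if (length(cluster_ids)) sum(cluster_sizes[changed]) else 0
    nbrs <- adj[[node]]
    nbrs <- nbrs[nbrs != parent]
    if (length(nbrs) == 0)
      return(list(str = paste0(labels[node], ":", len), min_leaf = labels[node]))
    subs <- lapply(nbrs, build, parent = node, parent_state = state)
    ord <- order(vapply(subs, function(s) s$min_leaf, character(1)))
    subs <- subs[ord]
    list(str = paste0("(", paste(vapply(subs, function(s) s$str, character(1)),
                                 collapse = ","), "):", len),
         min_leaf = min(vapply(subs, function(s) s$min_leaf, character(1))))
  }
  node_label <- function(node) if (node <= length(labels)) labels[node]
    else paste0("node", node)
  # root on the edge between the normal leaf and its neighbour
  v <- adj[[root]][1]
  sub <- build(v, root, rep(1L, n_chars))
  newick <- paste0("(", labels[root], ":0,", sub$str, ");")
  list(newick = newick,
       edge_clusters = if (length(edge_clusters))
         do.call(rbind, edge_clusters)
       else data.frame(node_label = character(), cluster_id = character()))
}

#' Write trees to a newick file
#'
#' Serializes one or more rooted clone trees (normal outgroup, branch
#' lengths = alteration counts) as newick, one per line.
#'
#' @param tree A `clone_phylo` (from [infer_parsimony_tree()]), an
#'   `ape::phylo`, or a newick character vector.
#' @param path Output file.
#' @export
write_newick <- function(tree, path) {
  nwk <- if (inherits(tree, "clone_phylo")) tree$newick
  else if (inherits(tree, "phylo")) {
    if (anyDuplicated(tree$tip.label)) stop("duplicate leaf labels")
    ape::write.tree(tree)
  } else as.character(tree)
  labs <- unlist(lapply(nwk, function(x)
    ape::read.tree(text = x)$tip.label))
  if (length(nwk) == 1 && anyDuplicated(labs)) stop("duplicate leaf labels")
  writeLines(nwk, path)
  invisible(path)
}
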