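# Fast UniFrac: a single post-order traversal precomputes, for every branch,
# the per-sample sum of abundances of the tips below it. All pairwise UniFrac
# distances are then sums over branches reusing that table, so the cost of the
# precomputation is O(edges x samples) and each pair costs O(edges).

#' Per-branch descendant abundance precomputation
#'
#' For a rooted tree and a matching abundance table, computes for every edge
#' the branch length and the per-sample total abundance of the tips descending
#' from it, together with per-sample grand totals and root-to-tip depths.
#' This is the shared precomputation behind every UniFrac variant.
#'
#' @param tree a rooted `ape::phylo` whose tips equal the table's taxa.
#' @param table an [abundance_table()] (or an `mb_experiment`, whose abundance
#'   is used).
#' @return An object of class `branch_abundance`: list with `edge_lengths`
#'   (per edge), `descendant_totals` (edges x samples matrix), `sample_totals`,
#'   `tip_depths` (named root-to-tip path lengths), and `tip_edges` (edge index
#'   of each tip's pendant edge).
#' @export
branch_abundance <- function(tree, table) {
  if (inherits(table, "mb_experiment")) table <- table$abundance
  x <- table$values
  tree <- normalize_tree(tree)
  if (!setequal(tree$tip.label, rownames(x))) {
    otk_stop("tree tips and abundance taxa differ")
  }
  if (!ape::is.rooted(tree)) {
    otk_stop("tree is unrooted; root it first (e.g. midpoint rooting via phangorn::midpoint)")
  }
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  post <- ape::reorder.phylo(tree, "postorder")
  edge <- post$edge
  # per-node accumulated descendant totals, tips initialized from the table
  node_tot <- matrix(0, n_node, ncol(x))
  node_tot[seq_len(n_tip), ] <- x[tree$tip.label, , drop = FALSE]
  desc <- matrix(0, nrow(edge), ncol(x))
  for (i in seq_len(nrow(edge))) {
    child <- edge[i, 2]
    desc[i, ] <- node_tot[child, ]
    node_tot[edge[i, 1], ] <- node_tot[edge[i, 1], ] + node_tot[child, ]
  }
  colnames(desc) <- colnames(x)
  depths <- ape::node.depth.edgelength(tree)[seq_len(n_tip)]
  names(depths) <- tree$tip.label
  tip_children <- match(seq_len(n_tip), post$edge[, 2])
  structure(list(edge_lengths = post$edge.length,
                 descendant_totals = desc,
                 sample_totals = colSums(x),
                 tip_depths = depths,
                 tip_edges = tip_children,
                 tree = post),
            class = "branch_abundance")
}

# Core pairwise computation over an explicit set of sample pairs.
# pairs: 2-column integer matrix of column indices into descendant_totals.
unifrac_pairs <- function(ba, pairs, weighted, normalized) {
  b <- ba$edge_lengths
  E <- ba$descendant_totals
  tot <- ba$sample_totals
  vapply(seq_len(nrow(pairs)), function(r) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    Ai <- E[, i]; Bi <- E[, j]
    if (weighted) {
      raw <- sum(b * abs(Ai / tot[i] - Bi / tot[j]))
      if (!normalized) return(raw)
      d <- ba$tip_depths
      pa <- E[ba$tip_edges, i] / tot[i]
      pb <- E[ba$tip_edges, j] / tot[j]
      D <- sum(d * (pa + pb))
      if (D == 0) return(0)
      raw / D
    } else {
      inA <- Ai > 0; inB <- Bi > 0
      denom <- sum(b[inA | inB])
      if (denom == 0) return(0)
      sum(b[xor(inA, inB)]) / denom
    }
  }, numeric(1))
}

#' UniFrac phylogenetic beta diversity
#'
#' Computes all pairwise UniFrac distances between samples using the fast
#' per-branch precomputation of [branch_abundance()]. The unweighted variant
#' reduces abundances to presence/absence of descendant tips:
#' (sum of branch lengths unique to one sample) / (sum of branch lengths
#' present in either). The weighted variant is
#' `sum_i b_i |A_i/A_T - B_i/B_T|`, optionally normalized by
#' `D = sum_j d_j (A_j/A_T + B_j/B_T)` over tips so values lie in `[0, 1]`.
#' Unrooted trees are midpoint-rooted deterministically first.
#'
#' @param exp an `mb_experiment` with a tree.
#' @param weighted use relative abundances rather than presence/absence.
#' @param normalized divide the weighted distance by its maximum attainable
#'   value for the pair (ignored for unweighted, which is normalized by
#'   construction).
#' @param chunks optionally split the set of sample pairs into this many
#'   consecutive chunks computed independently and merged; results are
#'   bitwise-identical to the serial computation (the parallelisation
#'   contract).
#' @return a `stats::dist` with attribute `method`.
#' @export
unifrac <- function(exp, weighted = FALSE, normalized = TRUE, chunks = 1L) {
  if (is.null(exp$tree)) otk_stop("UniFrac requires a phylogenetic tree")
  x <- abundances(exp)
  zero <- colnames(x)[colSums(x) == 0]
  if (length(zero) > 0L) {
    otk_stop("sample(s) with zero total abundance: %s", paste(zero, collapse = ", "))
  }
  tree <- exp$tree
  if (!ape::is.rooted(tree)) {
    otk_log("midpoint-rooting unrooted tree for UniFrac")
    tree <- normalize_tree(phangorn::midpoint(tree))
  }
  ba <- branch_abundance(tree, exp$abundance)
  n <- ncol(x)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 2], pairs[, 1]), , drop = FALSE]  # dist order: by column
  pairs <- cbind(pairs[, 1], pairs[, 2])
  chunks <- max(1L, min(as.integer(chunks), nrow(pairs)))
  idx <- if (chunks == 1L) list(seq_len(nrow(pairs)))
         else split(seq_len(nrow(pairs)), cut(seq_len(nrow(pairs)), chunks, labels = FALSE))
  vals <- unlist(lapply(idx, function(k) {
    unifrac_pairs(ba, pairs[k, , drop = FALSE], weighted, normalized)
  }), use.names = FALSE)
  # assemble dist (lower triangle, column-major over pairs (i<j))
  m <- matrix(0, n, n, dimnames = list(colnames(x), colnames(x)))
  m[cbind(pairs[, 1], pairs[, 2])] <- vals
  m[cbind(pairs[, 2], pairs[, 1])] <- vals
  d <- stats::as.dist(m)
  attr(d, "method") <- if (!weighted) "unifrac" else if (normalized) "wunifrac" else "wunifrac-raw"
  d
}
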