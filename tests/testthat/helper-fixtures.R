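# Shared fixtures and independent oracles, all built in code.

# 3 taxa x 4 samples with tree, taxonomy, sample table and sequences.
tiny_experiment <- function() {
  x <- matrix(c(5, 0, 1,
                0, 3, 1,
                2, 2, 2,
                0, 0, 4), nrow = 3,
              dimnames = list(c("A", "B", "C"), c("S1", "S2", "S3", "S4")))
  tree <- ape::read.tree(text = "((A:1,B:1):0.5,C:2);")
  tax <- taxonomy_table(rbind(A = c("Bacteria", "Firmicutes", "Bacilli"),
                              B = c("Bacteria", "Firmicutes", "Clostridia"),
                              C = c("Bacteria", "Bacteroidetes", NA)),
                        ranks = c("Kingdom", "Phylum", "Class"))
  smp <- sample_table(data.frame(Group = c("ctl", "ctl", "trt", "trt"),
                                 pH = c(6.8, 7.1, 6.5, 7.4),
                                 row.names = c("S1", "S2", "S3", "S4")))
  seqs <- ref_seqs(c(A = "ACGTACGT", B = "ACGTTCGT", C = "TTGTACGA"))
  build_experiment(abundance_table(x), samples = smp, taxonomy = tax,
                   tree = tree, refseq = seqs)
}

# Brute-force UniFrac: explicit recursive enumeration of the tips below every
# edge, no shared code with the traversal-based implementation.
oracle_unifrac <- function(tree, x, weighted, normalized, i, j) {
  edge <- tree$edge
  b <- tree$edge.length
  n_tip <- length(tree$tip.label)
  tips_below <- function(node) {
    if (node <= n_tip) return(node)
    unlist(lapply(edge[edge[, 1] == node, 2], tips_below))
  }
  At <- sum(x[, i]); Bt <- sum(x[, j])
  if (weighted) {
    raw <- 0
    for (k in seq_len(nrow(edge))) {
      tb <- tree$tip.label[tips_below(edge[k, 2])]
      raw <- raw + b[k] * abs(sum(x[tb, i]) / At - sum(x[tb, j]) / Bt)
    }
    if (!normalized) return(raw)
    dep <- ape::node.depth.edgelength(tree)
    D <- 0
    for (t in seq_len(n_tip)) {
      lab <- tree$tip.label[t]
      D <- D + dep[t] * (x[lab, i] / At + x[lab, j] / Bt)
    }
    return(if (D == 0) 0 else raw / D)
  }
  num <- 0; den <- 0
  for (k in seq_len(nrow(edge))) {
    tb <- tree$tip.label[tips_below(edge[k, 2])]
    inA <- sum(x[tb, i]) > 0; inB <- sum(x[tb, j]) > 0
    if (inA || inB) den <- den + b[k]
    if (xor(inA, inB)) num <- num + b[k]
  }
  num / den
}

# Fig 4-style preprocessing fixture: 6 designed taxa, 10 samples, the first
# five columns at raw depth 200 and the rest at 100, so the even-depth
# transform to 100 recovers the designed profile exactly.
preprocessing_chain_fixture <- function() {
  S <- rbind(
    OTU1 = rep(10, 10),
    OTU2 = c(80, 3, rep(0, 8)),
    OTU3 = c(5, rep(0, 9)),
    OTU4 = c(2, 2, 2, 0, 0, 2, 0, 0, 0, 0),
    OTU5 = c(3, 0, 85, 90, 90, 88, 90, 90, 90, 90),
    OTU6 = c(0, 85, 3, rep(0, 7)))
  colnames(S) <- sprintf("S%02d", 1:10)
  raw <- S %*% diag(c(rep(2, 5), rep(1, 5)))
  dimnames(raw) <- dimnames(S)
  list(raw = raw, scaled = S)
}
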